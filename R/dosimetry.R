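#' Decay schemes
#'
#' Bundled emission data for the supported radionuclides: photon lines with
#' energies (MeV) and yields per decay, plus one electron row whose energy is
#' the total non-penetrating energy per decay (beta mean energy, conversion
#' and Auger electrons). The CSV format (`kind,energy_MeV,yield`) lets users
#' supply other nuclides via `path`.
#'
#' @param nuclide `"I-131"` or `"Tc-99m"` (or any name when `path` is given).
#' @param path Optional CSV path overriding the bundled scheme.
#' @return Tibble with `kind`, `energy_MeV`, `yield`.
#' @export
decay_scheme <- function(nuclide, path = NULL) {
  path <- path %||% system.file("extdata", paste0("decay_", nuclide, ".csv"),
                                package = "phantomdose")
  if (path == "" || !file.exists(path)) stop("unknown nuclide: ", nuclide)
  df <- tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
  if (any(df$yield < 0) || any(df$energy_MeV[df$kind == "photon"] < 0.001))
    stop("invalid decay scheme")
  df
}

organ_masses <- function(phantom) {
  mt <- organ_mass_table(phantom)
  stats::setNames(mt$mass_kg, mt$organ)
}

#' Specific absorbed fractions from a tally
#'
#' SAF(target <- source, E) = E_dep(target) / (N * E * m_target), in 1/kg:
#' the fraction of emitted energy absorbed in the target per unit target
#' mass. Entries with batch CV above 20% are flagged as excluded.
#'
#' @param tally A `pd_tally` from [simulate_photons()].
#' @param phantom The phantom the tally was computed on.
#' @return Tibble of class `pd_saf`: `phantom`, `source`, `target`,
#'   `energy_MeV`, `saf_kg` (1/kg), `cv_percent`, `excluded`.
#' @export
compute_saf <- function(tally, phantom) {
  stopifnot(inherits(tally, "pd_tally"))
  masses <- organ_masses(phantom)
  st <- tally_stats(tally$dep, tally$batch_histories)
  st <- st[st$target != "(escaped)", ]
  m <- masses[st$target]
  if (any(is.na(m))) stop("unknown target mass")
  if (any(m <= 0)) {
    if (any(st$energy_dep_MeV[m <= 0] > 0)) stop("zero target mass")
    st <- st[m > 0, ]; m <- m[m > 0]
  }
  emitted <- tally$n_histories * tally$energy_MeV
  out <- tibble::tibble(
    phantom = tally$phantom, source = tally$source, target = st$target,
    energy_MeV = tally$energy_MeV,
    saf_kg = unname(st$energy_dep_MeV / (emitted * m)),
    cv_percent = st$cv_percent
  )
  out <- cv_filter(out)
  class(out) <- c("pd_saf", class(out))
  out
}

#' Flag results exceeding a CV threshold
#'
#' Entries whose coefficient of variation exceeds the threshold (strictly)
#' are marked excluded; table renderers print them as `"-"`.
#'
#' @param results Tibble with a `cv_percent` column.
#' @param threshold CV threshold in percent (default 20).
#' @return The input with an `excluded` logical column.
#' @export
cv_filter <- function(results, threshold = 20) {
  results$excluded <- !is.na(results$cv_percent) &
    results$cv_percent > threshold
  results
}

# deterministic sub-seed for each photon line (kept well below 2^31)
line_seed <- function(seed, i) (seed + 7919L * i) %% 2000000000L

#' MIRD S-values for a radionuclide source organ
#'
#' Photon lines are transported individually (a Monte Carlo run per line);
#' the photon S-value is the yield- and energy-weighted sum of line SAFs.
#' Non-penetrating emissions (the scheme's electron rows) are absorbed
#' entirely in the source organ and contribute only to the self S-value.
#' Conversion: 1 MeV/(kg decay) = 1.602e-13 Gy per decay, reported as
#' mGy/(MBq s). Line CVs are propagated in quadrature; the 20% CV exclusion
#' rule is applied to the combined value.
#'
#' @param phantom A `pd_phantom`.
#' @param nuclide Nuclide name understood by [decay_scheme()].
#' @param source Source organ.
#' @param targets Optional subset of target organs (default: all).
#' @param n_histories Histories per photon line.
#' @param n_batches Batches per run.
#' @param seed Integer seed; per-line seeds are derived deterministically.
#' @param cache Optional environment used to reuse line tallies across
#'   source organs / nuclides sharing lines.
#' @param scheme Optional decay-scheme tibble overriding the bundled one
#'   (columns `kind`, `energy_MeV`, `yield`).
#' @return Tibble of class `pd_svalue`: `nuclide`, `source`, `target`,
#'   `s_mGy_per_MBq_s`, `cv_percent`, `excluded`.
#' @export
compute_svalue <- function(phantom, nuclide, source, targets = NULL,
                           n_histories = 1e6, n_batches = 20, seed = 1,
                           cache = NULL, scheme = NULL) {
  scheme <- scheme %||% decay_scheme(nuclide)
  photons <- scheme[scheme$kind == "photon", ]
  electrons <- scheme[scheme$kind == "electron", ]
  masses <- organ_masses(phantom)

  safs <- vector("list", nrow(photons))
  for (i in seq_len(nrow(photons))) {
    E <- photons$energy_MeV[i]
    key <- paste(phantom$name, source, format(E, digits = 10), n_histories,
                 line_seed(seed, i), sep = "|")
    saf <- if (!is.null(cache) && !is.null(cache[[key]])) cache[[key]]
    else {
      tl <- simulate_photons(phantom, source, E, n_histories = n_histories,
                             n_batches = n_batches, seed = line_seed(seed, i))
      s <- compute_saf(tl, phantom)
      if (!is.null(cache)) cache[[key]] <- s
      s
    }
    saf$yield <- photons$yield[i]
    safs[[i]] <- saf
  }
  all <- dplyr::bind_rows(safs)
  per <- dplyr::summarise(
    dplyr::group_by(all, .data$target),
    photon = sum(.data$yield * .data$energy_MeV * .data$saf_kg),
    var = sum((.data$yield * .data$energy_MeV * .data$saf_kg *
                 dplyr::coalesce(.data$cv_percent, 0) / 100)^2),
    .groups = "drop")
  e_np <- sum(electrons$yield * electrons$energy_MeV)
  per$electron <- ifelse(per$target == source,
                         e_np / unname(masses[source]), 0)
  per$s_mGy_per_MBq_s <- (per$photon + per$electron) * MEVKG_TO_MGY_MBQS
  per$cv_percent <- ifelse(per$s_mGy_per_MBq_s > 0,
                           100 * sqrt(per$var) * MEVKG_TO_MGY_MBQS /
                             per$s_mGy_per_MBq_s, NA_real_)
  out <- tibble::tibble(
    nuclide = nuclide, source = source, target = per$target,
    s_mGy_per_MBq_s = per$s_mGy_per_MBq_s, cv_percent = per$cv_percent)
  if (!is.null(targets)) out <- out[out$target %in% targets, ]
  out <- cv_filter(out)
  class(out) <- c("pd_svalue", class(out))
  out
}

#' Ratio comparison of two result sets
#'
#' Joins two SAF or S-value tables on their shared identifying columns and
#' reports the ratio A/B with CVs propagated in quadrature, plus a summary
#' attribute with min/max/mean ratio. Keys missing from either side are
#' dropped with a warning.
#'
#' @param a,b Tibbles from [compute_saf()] or [compute_svalue()].
#' @return Tibble with the join keys, `ratio` and `cv_percent`.
#' @export
compare_phantoms <- function(a, b) {
  keys <- intersect(intersect(names(a), names(b)),
                    c("source", "target", "energy_MeV", "nuclide"))
  val <- if ("saf_kg" %in% names(a)) "saf_kg" else "s_mGy_per_MBq_s"
  j <- dplyr::inner_join(a, b, by = keys, suffix = c("_a", "_b"))
  n_miss <- nrow(a) - nrow(j)
  if (n_miss > 0)
    warning(n_miss, " entries had no counterpart and were omitted")
  va <- j[[paste0(val, "_a")]]; vb <- j[[paste0(val, "_b")]]
  out <- j[, keys]
  out$ratio <- ifelse(vb > 0, va / vb, NA_real_)
  out$cv_percent <- sqrt(dplyr::coalesce(j$cv_percent_a, 0)^2 +
                           dplyr::coalesce(j$cv_percent_b, 0)^2)
  attr(out, "summary") <- c(min = min(out$ratio, na.rm = TRUE),
                            max = max(out$ratio, na.rm = TRUE),
                            mean = mean(out$ratio, na.rm = TRUE))
  out
}

#' Render a result table in the conventional layout
#'
#' Values formatted in scientific notation with the CV in parentheses;
#' excluded entries (CV above the threshold) render as `"-"`.
#'
#' @param results A `pd_saf` or `pd_svalue` tibble.
#' @return Tibble with `target` and one formatted column per source organ.
#' @export
format_result_table <- function(results) {
  val <- if ("saf_kg" %in% names(results)) "saf_kg" else "s_mGy_per_MBq_s"
  results$cell <- ifelse(
    results$excluded, "-",
    sprintf("%.2E (%.1f%%)", results[[val]], results$cv_percent))
  tidyr::pivot_wider(results[, c("target", "source", "cell")],
                     names_from = "source", values_from = "cell")
}

#' Write results as CSV with a provenance header
#'
#' @param results Result tibble carrying a `seed` attribute or column.
#' @param path Output path.
#' @param seed Seed to record in the header.
#' @export
write_result_csv <- function(results, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# phantomdose %s; seed %s",
                     as.character(utils::packageVersion("phantomdose")),
                     format(seed)), con)
  utils::write.csv(as.data.frame(results), con, row.names = FALSE)
  invisible(path)
}
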