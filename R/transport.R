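MEVKG_TO_MGY_MBQS <- 1.602176634e-4 # 1 MeV/(kg decay) in mGy/(MBq s)

# per-material interaction tables in the layout the C++ kernel expects
pd_xs_list <- function(materials) {
  xs <- element_tables()
  ng <- length(xs$E)
  nm <- nrow(materials)
  sym <- xs$elements$symbol
  w <- as.matrix(materials[, sym]) / 100      # nm x ne mass fractions
  rho <- materials$Density
  chan <- function(tab) {
    out <- matrix(0, ng, nm)
    for (m in seq_len(nm)) out[, m] <- (tab %*% w[m, ]) * rho[m]
    out
  }
  pe <- chan(xs$pe); inc <- chan(xs$inc); coh <- chan(xs$coh); pr <- chan(xs$pair)
  tot <- pe + inc + coh + pr
  lg <- function(x) log(pmax(x, 1e-300))
  list(
    logE = log(xs$E),
    log_tot = lg(tot), log_pe = lg(pe), log_inc = lg(inc),
    log_coh = lg(coh), log_pair = lg(pr),
    log_maj = lg(apply(tot, 1, max)),
    elemZ = xs$elements$Z,
    mat_elem_w = w,
    log_elem_coh = lg(xs$coh),
    coh_logt = log(xs$coh_tab$tgrid),
    coh_cdf = xs$coh_tab$cdf
  )
}

phantom_xs <- function(phantom) {
  if (is.null(phantom$cache$xs)) phantom$cache$xs <- pd_xs_list(phantom$materials)
  phantom$cache$xs
}

#' Sample source points uniformly in an organ
#'
#' Rejection sampling in the organ's bounding box; every returned point lies
#' inside the organ region. Deterministic for a given seed.
#'
#' @param phantom A `pd_phantom`.
#' @param organ Organ name.
#' @param n Number of points.
#' @param seed Optional integer seed.
#' @return n x 3 matrix (cm).
#' @export
sample_in_organ <- function(phantom, organ, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geom <- pd_geometry(phantom)
  i <- match(organ, phantom$organs$organ)
  if (is.na(i)) stop("unknown organ: ", organ)
  bb <- geom$bbox[i, ]
  cpp_sample_region(geom$prim, geom$progs[[i]], bb[c(1, 3, 5)], bb[c(2, 4, 6)],
                    as.integer(n), 1e-4)
}

#' Sample isotropic directions
#'
#' Uniform on the unit sphere: cos(theta) uniform on \\[-1, 1\\], azimuth
#' uniform on \\[0, 2*pi).
#' @param n Number of directions.
#' @param seed Optional integer seed.
#' @return n x 3 matrix of unit vectors.
#' @export
sample_isotropic <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cpp_sample_iso(as.integer(n))
}

#' Sample Compton scattering
#'
#' Draws scattered photon energies and scattering-angle cosines from the
#' free-electron Klein-Nishina differential cross section (rejection
#' sampling, exact).
#'
#' @param energy_MeV Incident photon energy.
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @return Tibble with `energy_out_MeV` and `cos_theta`.
#' @export
sample_compton <- function(energy_MeV, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- cpp_sample_compton(energy_MeV, as.integer(n))
  tibble::tibble(energy_out_MeV = m[, 1], cos_theta = m[, 2])
}

#' Simulate monoenergetic photon transport
#'
#' Analog photon Monte Carlo with Woodcock delta-tracking: photons start
#' uniformly distributed in the source organ with isotropic directions;
#' flight lengths are sampled against the phantom majorant attenuation;
#' photoelectric events absorb locally, Compton events deposit the energy
#' transfer and continue, coherent events redirect without deposit, pair
#' production deposits `E - 1.022` MeV and emits two annihilation photons.
#' Secondary electrons deposit on the spot (kerma approximation), photons at
#' or below the cutoff deposit locally. Deposits are attributed to the organ
#' containing the collision point; energy leaving the body is tallied as
#' escaped.
#'
#' @param phantom A `pd_phantom` (or fixture, see [make_fixture()]).
#' @param source Source organ name.
#' @param energy_MeV Photon energy (within 0.002-4 MeV).
#' @param n_histories Number of primary photons.
#' @param n_batches Batches for the batch-statistics CV (default 20).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param coherent Include coherent scattering in the transport (default TRUE).
#' @param cutoff_MeV Energy cutoff below which photons deposit locally.
#' @return Object of class `pd_tally`.
#' @export
simulate_photons <- function(phantom, source, energy_MeV, n_histories = 1e6,
                             n_batches = 20, seed = 1, coherent = TRUE,
                             cutoff_MeV = 0.001) {
  stopifnot(n_histories >= n_batches, n_batches >= 2)
  i <- match(source, phantom$organs$organ)
  if (is.na(i)) stop("unknown source organ: ", source)
  xs <- element_tables()
  if (energy_MeV < min(xs$E) * 0.999 || energy_MeV > max(xs$E) * 1.001)
    stop("energy outside the cross-section grid (0.002-4 MeV)")
  geom <- pd_geometry(phantom)
  xsl <- phantom_xs(phantom)
  set.seed(seed)
  res <- cpp_simulate(geom, xsl, as.integer(i), energy_MeV,
                      as.integer(n_histories), as.integer(n_batches),
                      cutoff_MeV, coherent)
  dep <- res$dep
  rownames(dep) <- c(phantom$organs$organ, "Residual tissue", "(escaped)")
  nb <- rep(n_histories %/% n_batches, n_batches) +
    (seq_len(n_batches) <= n_histories %% n_batches)
  structure(list(
    phantom = phantom$name, source = source, energy_MeV = energy_MeV,
    n_histories = n_histories, n_batches = n_batches, seed = seed,
    batch_histories = nb, dep = dep
  ), class = "pd_tally")
}

# batch-statistics summary of a deposition matrix
tally_stats <- function(dep, nb) {
  total <- rowSums(dep)
  n <- sum(nb)
  means <- sweep(dep, 2, nb, "/")
  grand <- total / n
  se <- apply(means, 1, stats::sd) / sqrt(length(nb))
  cv <- ifelse(grand > 0, 100 * se / grand, NA_real_)
  tibble::tibble(target = rownames(dep), energy_dep_MeV = total,
                 mean_dep_MeV = grand, cv_percent = cv)
}

#' @export
print.pd_tally <- function(x, ...) {
  cat("<pd_tally> ", x$phantom, ", source ", x$source, ", ",
      x$energy_MeV, " MeV, ", format(x$n_histories, big.mark = ","),
      " histories\n", sep = "")
  print(utils::head(tidy(x), 8))
  invisible(x)
}

#' Tidy a tally
#'
#' @param x A `pd_tally`.
#' @param ... Unused.
#' @return Tibble with per-target deposited energy, mean deposit per history
#'   and the batch-statistics CV (%), plus identifying columns.
#' @export
tidy.pd_tally <- function(x, ...) {
  out <- tally_stats(x$dep, x$batch_histories)
  out$phantom <- x$phantom
  out$source <- x$source
  out$energy_MeV <- x$energy_MeV
  out$n_histories <- x$n_histories
  out
}

#' One-line tally summary
#'
#' @param x A `pd_tally`.
#' @param ... Unused.
#' @return Tibble with total emitted, deposited and escaped energy and the
#'   worst-case relative energy-balance error.
#' @export
glance.pd_tally <- function(x, ...) {
  emitted <- x$n_histories * x$energy_MeV
  dep <- sum(x$dep[rownames(x$dep) != "(escaped)", ])
  esc <- sum(x$dep["(escaped)", ])
  tibble::tibble(
    phantom = x$phantom, source = x$source, energy_MeV = x$energy_MeV,
    n_histories = x$n_histories,
    emitted_MeV = emitted, deposited_MeV = dep, escaped_MeV = esc,
    balance_rel_error = abs(dep + esc - emitted) / emitted
  )
}
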