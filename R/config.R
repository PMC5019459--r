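#' Run configuration
#'
#' A validated description of a reproducible run. Simulation tasks (`saf`,
#' `svalue`) require an explicit seed; outputs produced from the same
#' configuration and seed are byte-identical.
#'
#' @param task One of `"build"`, `"saf"`, `"svalue"`, `"validate"`.
#' @param phantom Phantom name (`"TRM"`, `"TRW"`, `"ORNL"`).
#' @param source Source organ (simulation tasks).
#' @param targets Optional target subset.
#' @param energies Photon energies in MeV (`saf` task).
#' @param nuclide Nuclide name (`svalue` task).
#' @param histories,batches Monte Carlo size (histories >= batches).
#' @param seed Integer seed (mandatory for simulation tasks).
#' @param out_dir Output directory.
#' @param coherent Physics toggle: include coherent scattering.
#' @return Object of class `pd_run_config`.
#' @export
run_config <- function(task, phantom, source = NULL, targets = NULL,
                       energies = NULL, nuclide = NULL, histories = 1e6,
                       batches = 20, seed = NULL, out_dir = ".",
                       coherent = TRUE) {
  cfg <- structure(list(
    task = task, phantom = phantom, source = source, targets = targets,
    energies = energies, nuclide = nuclide, histories = histories,
    batches = batches, seed = seed, out_dir = out_dir, coherent = coherent
  ), class = "pd_run_config")
  validate_run_config(cfg)
  cfg
}

#' @rdname run_config
#' @param config A `pd_run_config` (or plain list).
#' @export
validate_run_config <- function(config) {
  fail <- function(field, msg) stop("invalid config field '", field, "': ",
                                    msg, call. = FALSE)
  if (!config$task %in% c("build", "saf", "svalue", "validate"))
    fail("task", "must be build, saf, svalue or validate")
  if (is.null(config$phantom)) fail("phantom", "is required")
  sim <- config$task %in% c("saf", "svalue")
  if (sim && is.null(config$seed)) fail("seed", "is mandatory for simulation tasks")
  if (sim && is.null(config$source)) fail("source", "is required")
  if (config$task == "saf" && is.null(config$energies))
    fail("energies", "is required for the saf task")
  if (config$task == "svalue" && is.null(config$nuclide))
    fail("nuclide", "is required for the svalue task")
  if (config$histories < config$batches)
    fail("histories", "must be at least the number of batches")
  invisible(config)
}

#' Read / write run configurations as YAML
#'
#' Round-trips losslessly: `read_run_config(write_run_config(cfg, f))` is
#' identical to `cfg`.
#' @param path YAML file path.
#' @param config A `pd_run_config`.
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(run_config, lst)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  lst <- unclass(config)
  lst <- lst[!vapply(lst, is.null, logical(1))]
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Serialize a phantom to the config dialect
#'
#' @param phantom A `pd_phantom`.
#' @param path YAML output path.
#' @export
write_phantom_config <- function(phantom, path) {
  lst <- list(
    name = phantom$name,
    frame = unclass(phantom$frame),
    organs = lapply(seq_len(nrow(phantom$organs)), function(i)
      as.list(phantom$organs[i, ])),
    regions = lapply(phantom$regions, region_to_list)
  )
  yaml::write_yaml(lst, path, precision = 12)
  invisible(path)
}

#' Execute a configured run
#'
#' Writes the task outputs as CSV (with a provenance comment header) plus a
#' `manifest.yaml` echoing the configuration and package version next to
#' them.
#'
#' @param config A `pd_run_config`.
#' @return Invisibly, the list of files written.
#' @export
run <- function(config) {
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  phantom <- assemble_phantom(config$phantom)
  files <- character(0)
  out <- function(name) file.path(config$out_dir, name)

  if (config$task %in% c("build", "validate")) {
    mt <- organ_mass_table(phantom)
    f <- out(paste0(config$phantom, "_organ_masses.csv"))
    write_result_csv(mt, f, seed = config$seed %||% NA)
    files <- c(files, f)
    f2 <- out(paste0(config$phantom, "_phantom.yaml"))
    write_phantom_config(phantom, f2)
    files <- c(files, f2)
    if (config$task == "validate") {
      chk <- validate_phantom(phantom, seed = config$seed %||% 1)
      f3 <- out(paste0(config$phantom, "_validation.csv"))
      write_result_csv(chk, f3, seed = config$seed %||% NA)
      files <- c(files, f3)
      if (!all(chk$pass)) stop("phantom validation failed: ",
                               paste(chk$check[!chk$pass], collapse = ", "))
    }
  } else if (config$task == "saf") {
    res <- dplyr::bind_rows(lapply(config$energies, function(E) {
      tl <- simulate_photons(phantom, config$source, E,
                             n_histories = config$histories,
                             n_batches = config$batches, seed = config$seed,
                             coherent = config$coherent)
      compute_saf(tl, phantom)
    }))
    if (!is.null(config$targets)) res <- res[res$target %in% config$targets, ]
    f <- out(sprintf("%s_saf_%s.csv", config$phantom, config$source))
    write_result_csv(res, f, seed = config$seed)
    files <- c(files, f)
  } else if (config$task == "svalue") {
    res <- compute_svalue(phantom, config$nuclide, config$source,
                          targets = config$targets,
                          n_histories = config$histories,
                          n_batches = config$batches, seed = config$seed)
    f <- out(sprintf("%s_svalue_%s_%s.csv", config$phantom, config$nuclide,
                     config$source))
    write_result_csv(res, f, seed = config$seed)
    files <- c(files, f)
  }
  manifest <- out("manifest.yaml")
  yaml::write_yaml(list(
    package = "phantomdose",
    version = as.character(utils::packageVersion("phantomdose")),
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    outputs = basename(files)
  ), manifest)
  invisible(c(files, manifest))
}

#' Geometry validation checks
#'
#' Monte Carlo verification that every organ lies inside the body envelope,
#' that calibrated volumes are consistent with point-classification volumes
#' (detecting inter-organ overlap), and that the phantom height matches the
#' frame exactly.
#'
#' @param phantom A `pd_phantom`.
#' @param n Points per organ for the containment check.
#' @param seed Integer seed.
#' @return Tibble with `check`, `value`, `pass`.
#' @export
validate_phantom <- function(phantom, n = 1e4, seed = 1) {
  set.seed(seed)
  checks <- list()
  env_flat <- region_flatten(phantom$envelope)
  escapes <- 0
  for (org in phantom$organs$organ) {
    pts <- sample_in_organ(phantom, org, n)
    escapes <- escapes + sum(!cpp_contains(env_flat$prim, env_flat$prog, pts))
  }
  checks[["organs_inside_envelope"]] <-
    tibble::tibble(check = "organs_inside_envelope", value = escapes,
                   pass = escapes == 0)
  # classification consistency: classified share of each organ's own samples
  mis <- 0
  for (org in phantom$organs$organ) {
    pts <- sample_in_organ(phantom, org, 2000)
    lab <- classify_points(phantom, pts)
    # walls/contents and carved organs legitimately share boundaries with
    # their partners; everything else must classify to itself
    mis <- mis + mean(lab != org & !is.na(lab) &
                        !startsWith(lab, sub(" .*", "", org)))
  }
  checks[["classification_consistency"]] <-
    tibble::tibble(check = "mean_misclassified_fraction", value = mis /
                     nrow(phantom$organs), pass = mis / nrow(phantom$organs) < 0.02)
  h <- phantom$total_height_cm
  hf <- phantom$frame$C_H + phantom$frame$C_T + phantom$frame$C_L
  checks[["height"]] <- tibble::tibble(check = "total_height_cm", value = h,
                                       pass = identical(h, hf))
  dplyr::bind_rows(checks)
}
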