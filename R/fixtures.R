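#' Analytic toy phantoms for verification
#'
#' Fixtures with exactly known masses used as transport oracles:
#' * `one_sphere`: a single soft-tissue sphere (default mass exactly 1 kg)
#'   surrounded by vacuum;
#' * `two_sphere`: a source sphere and a detached target sphere separated by
#'   a surface-to-surface gap along z;
#' * `slab`: a wide tissue slab of given thickness.
#'
#' The fixtures behave like assembled phantoms: [simulate_photons()],
#' [compute_saf()] and [organ_mass_table()] all work on them, and the
#' sphere fixtures additionally support the independent surface-to-surface
#' ray tracer [ray_trace_spheres()].
#'
#' @param kind `"one_sphere"`, `"two_sphere"` or `"slab"`.
#' @param radius_cm,radius2_cm Sphere radii (defaults: 1 kg soft-tissue
#'   sphere; 4 cm target sphere).
#' @param gap_cm Surface-to-surface separation for `two_sphere`.
#' @param thickness_cm Slab thickness.
#' @param material Material name from [tissue_materials()].
#' @return Object of class `pd_phantom`.
#' @export
make_fixture <- function(kind = c("one_sphere", "two_sphere", "slab"),
                         radius_cm = NULL, radius2_cm = 4, gap_cm = 10,
                         thickness_cm = 5, material = "Soft tissue") {
  kind <- match.arg(kind)
  mats <- tissue_materials()
  rho <- mats$Density[match(material, mats$Organ)]
  if (is.na(rho)) stop("unknown material: ", material)
  r1 <- radius_cm %||% (3 * 1000 / (4 * pi * rho))^(1 / 3) # 1 kg sphere

  if (kind == "one_sphere") {
    sph <- ellipsoid(r1, r1, r1)
    organs <- tibble::tibble(
      organ = "Sphere", group = "solid", material = material,
      volume_cm3 = 4 / 3 * pi * r1^3, density_g_cm3 = rho,
      mass_kg = 4 / 3 * pi * r1^3 * rho / 1000, s = 1, z_ratio = 1)
    regions <- list(Sphere = sph)
    envelope <- sph
    spheres <- cbind(0, 0, 0, r1)
  } else if (kind == "two_sphere") {
    z2 <- r1 + gap_cm + radius2_cm
    s1 <- ellipsoid(r1, r1, r1)
    s2 <- ellipsoid(radius2_cm, radius2_cm, radius2_cm, center = c(0, 0, z2))
    vol <- 4 / 3 * pi * c(r1^3, radius2_cm^3)
    organs <- tibble::tibble(
      organ = c("Source sphere", "Target sphere"), group = "solid",
      material = material, volume_cm3 = vol, density_g_cm3 = rho,
      mass_kg = vol * rho / 1000, s = 1, z_ratio = 1)
    regions <- list(`Source sphere` = s1, `Target sphere` = s2)
    envelope <- region_union(s1, s2)
    spheres <- rbind(c(0, 0, 0, r1), c(0, 0, z2, radius2_cm))
  } else {
    slab <- elliptic_cylinder(40, 40, z_range = c(0, thickness_cm))
    vol <- pi * 40 * 40 * thickness_cm
    organs <- tibble::tibble(
      organ = "Slab", group = "solid", material = material, volume_cm3 = vol,
      density_g_cm3 = rho, mass_kg = vol * rho / 1000, s = 1, z_ratio = 1)
    regions <- list(Slab = slab)
    envelope <- slab
    spheres <- NULL
  }
  structure(list(
    name = paste0("fixture_", kind), frame = NULL, organs = organs,
    regions = regions, envelope = envelope,
    materials = mats[match(unique(c(material, "Soft tissue")), mats$Organ), ],
    residual_material = "Soft tissue", residual_volume_cm3 = 0,
    residual_mass_kg = 0,
    total_height_cm = NA_real_, spheres = spheres,
    cache = new.env(parent = emptyenv())
  ), class = "pd_phantom")
}

#' Reference surface-to-surface ray tracer for sphere fixtures
#'
#' Independent of the Woodcock tracker: flight distances are sampled against
#' the local material attenuation and sphere boundaries are crossed by exact
#' ray-sphere intersection. Same collision physics, same cross sections;
#' used as the two-tracker equivalence oracle.
#'
#' @param fixture A sphere fixture from [make_fixture()].
#' @param source Source organ name.
#' @param energy_MeV Photon energy.
#' @param n_histories,n_batches,seed,coherent,cutoff_MeV As in
#'   [simulate_photons()].
#' @return Object of class `pd_tally`.
#' @export
ray_trace_spheres <- function(fixture, source, energy_MeV, n_histories = 1e5,
                              n_batches = 20, seed = 1, coherent = TRUE,
                              cutoff_MeV = 0.001) {
  if (is.null(fixture$spheres)) stop("ray tracer requires a sphere fixture")
  i <- match(source, fixture$organs$organ)
  if (is.na(i)) stop("unknown source organ: ", source)
  smat <- match(fixture$organs$material, fixture$materials$Organ)
  xsl <- phantom_xs(fixture)
  world_r <- max(sqrt(rowSums(fixture$spheres[, 1:3, drop = FALSE]^2)) +
                   fixture$spheres[, 4]) + 5
  set.seed(seed)
  res <- cpp_ray_trace_spheres(fixture$spheres, as.integer(smat), xsl,
                               as.integer(i), energy_MeV,
                               as.integer(n_histories), as.integer(n_batches),
                               cutoff_MeV, coherent, world_r)
  dep <- res$dep
  # insert an empty residual row so the tally matches the phantom layout
  dep <- rbind(dep[-nrow(dep), , drop = FALSE],
               matrix(0, 1, ncol(dep)),
               dep[nrow(dep), , drop = FALSE])
  rownames(dep) <- c(fixture$organs$organ, "Residual tissue", "(escaped)")
  nb <- rep(n_histories %/% n_batches, n_batches) +
    (seq_len(n_batches) <= n_histories %% n_batches)
  structure(list(
    phantom = fixture$name, source = source, energy_MeV = energy_MeV,
    n_histories = n_histories, n_batches = n_batches, seed = seed,
    batch_histories = nb, dep = dep
  ), class = "pd_tally")
}

#' Uncollided transmission through a slab by delta-tracking
#'
#' Transports photons at normal incidence through a homogeneous slab with
#' Woodcock sampling against an inflated majorant and reports the fraction
#' that crosses without a real collision; the expectation is the
#' Beer-Lambert transmission `exp(-mu_total * d)`.
#'
#' @param material Material name.
#' @param thickness_cm Slab thickness.
#' @param energy_MeV Photon energy.
#' @param n Number of photons.
#' @param seed Integer seed.
#' @param majorant_factor Inflation factor (> 1) exercising fictitious
#'   collisions.
#' @return Tibble with `transmission`, `expected` and `stderr`.
#' @export
slab_transmission <- function(material, thickness_cm, energy_MeV, n = 1e5,
                              seed = 1, majorant_factor = 1.7) {
  mu <- mixture_mu(material, energy_MeV)$total
  mu_maj <- mu * majorant_factor
  set.seed(seed)
  z <- rep(0, n)
  alive <- rep(TRUE, n)
  transmitted <- rep(FALSE, n)
  while (any(alive)) {
    idx <- which(alive)
    z[idx] <- z[idx] - log(stats::runif(length(idx))) / mu_maj
    crossed <- alive & z >= thickness_cm
    transmitted[crossed] <- TRUE
    alive[crossed] <- FALSE
    idx <- which(alive)
    real <- stats::runif(length(idx)) < mu / mu_maj
    alive[idx[real]] <- FALSE # first real collision: photon counted as lost
  }
  p <- mean(transmitted)
  tibble::tibble(transmission = p,
                 expected = exp(-mu * thickness_cm),
                 stderr = sqrt(p * (1 - p) / n))
}
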