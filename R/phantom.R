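#' Body frames
#'
#' The whole-body envelope of a stylized phantom: an elliptic head cylinder
#' of cross-section semi-axes `A_H`, `B_H` and height `C_H` stacked on a
#' trunk cylinder (`A_T`, `B_T`, height `C_T`), with two mirror leg cones of
#' length `C_L` below the trunk base (z = 0).
#'
#' @param phantom One of `"ORNL"`, `"TRM"`, `"TRW"`, or a named list/vector
#'   with elements `A_H, B_H, C_H, A_T, B_T, C_T, C_L` (cm).
#' @return Object of class `pd_body_frame`.
#' @export
body_frame <- function(phantom) {
  if (is.character(phantom)) {
    path <- system.file("extdata", "body_frames.csv", package = "phantomdose")
    df <- utils::read.csv(path, comment.char = "#")
    i <- match(phantom, df$phantom)
    if (is.na(i)) stop("unknown phantom name: ", phantom)
    fr <- as.list(df[i, -1])
    fr$name <- phantom
  } else {
    fr <- as.list(phantom)
    fr$name <- fr$name %||% "custom"
  }
  need <- c("A_H", "B_H", "C_H", "A_T", "B_T", "C_T", "C_L")
  if (!all(need %in% names(fr))) stop("frame needs ", paste(need, collapse = ", "))
  if (any(unlist(fr[need]) <= 0)) stop("frame parameters must be positive")
  structure(fr, class = "pd_body_frame")
}

#' Build the three body-segment regions
#'
#' @param frame A [body_frame()].
#' @return List with `head`, `trunk`, `legs` regions and `total_height_cm`
#'   (`C_H + C_T + C_L`).
#' @export
build_body <- function(frame) {
  list(
    head = elliptic_cylinder(frame$A_H, frame$B_H,
                             z_range = c(frame$C_T, frame$C_T + frame$C_H)),
    trunk = elliptic_cylinder(frame$A_T, frame$B_T, z_range = c(0, frame$C_T)),
    legs = cone_pair(frame$A_T, frame$C_L),
    total_height_cm = frame$C_H + frame$C_T + frame$C_L
  )
}

#' Reference organ volume targets
#'
#' @param phantom `"TRM"`, `"TRW"` or `"ORNL"`.
#' @return Tibble with `organ` and `volume_cm3` (NA rows dropped).
#' @export
organ_volume_targets <- function(phantom) {
  path <- system.file("extdata", "organ_volumes.csv", package = "phantomdose")
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!phantom %in% names(df)) stop("unknown phantom: ", phantom)
  out <- tibble::tibble(organ = df$organ, volume_cm3 = df[[phantom]])
  out[!is.na(out$volume_cm3), ]
}

# volume of a list of world-placed, z-scaled parts at lateral scale 1
# (exact where a closed form exists, else Monte Carlo with a fixed seed)
parts_volume_zscaled <- function(parts, mc_n = 2e6) {
  tot <- 0
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    reg <- region_scale(p$shape, c(1, 1, p$zr), p$anchor)
    v <- tryCatch(analytic_volume(reg), error = function(e) NULL)
    if (is.null(v))
      v <- mc_volume(reg, n = mc_n, seed = 774321 + i)$volume
    tot <- tot + v
  }
  tot
}

scaled_parts_region <- function(parts, s) {
  regs <- lapply(parts, function(p)
    region_scale(p$shape, c(s, s, p$zr), p$anchor))
  if (length(regs) == 1) regs[[1]] else do.call(region_union, regs)
}

overlap_volume <- function(parts, s, subtract_region, n = 4e5) {
  own <- scaled_parts_region(parts, s)
  reg <- region_intersection(own, subtract_region)
  b1 <- region_bbox(subtract_region)
  b2 <- region_bbox(own)
  bb <- cbind(pmax(b1[, 1], b2[, 1]), pmin(b1[, 2], b2[, 2]))
  if (any(bb[, 1] >= bb[, 2])) return(0)
  mc_volume(reg, n = n, bbox = bb, seed = 88111)$volume
}

#' Scale and calibrate an organ template
#'
#' Applies the segment height ratio `z_ratio` to the template's z extents and
#' anchors, then solves for the common lateral semi-axis factor `s` so that
#' the organ volume equals `target_volume`. When the volume is separable
#' (`V(s) = s^2 * V_z`) the factor is closed form,
#' `s = sqrt(target / V_z)`; when another region is carved out of the organ
#' the factor is found by bisection against Monte Carlo volume integration.
#' The x:y semi-axis ratio is preserved by construction.
#'
#' @param template A template entry as in [organ_templates()].
#' @param z_ratio Segment height ratio (dimensionless, > 0).
#' @param target_volume Target volume, cm^3 (> 0).
#' @param subtract_region Optional region carved out of the organ.
#' @param lateral_anchor Optional `c(ax, by)` factors applied to part anchor
#'   x/y positions (defaults to no lateral anchor scaling).
#' @return List with `region` (the calibrated `quadric_region`), `s`,
#'   `volume_cm3` (the achieved volume) and `z_ratio`.
#' @export
scale_and_calibrate <- function(template, z_ratio, target_volume,
                                subtract_region = NULL,
                                lateral_anchor = c(1, 1)) {
  if (target_volume <= 0 || z_ratio <= 0) stop("z_ratio and target_volume must be positive")
  parts <- lapply(template$parts, function(p) {
    list(shape = p$shape,
         anchor = c(p$anchor[1] * lateral_anchor[1],
                    p$anchor[2] * lateral_anchor[2],
                    p$anchor[3] * z_ratio),
         zr = z_ratio)
  })
  calibrate_parts(parts, target_volume, subtract_region)
}

calibrate_parts <- function(parts, target_volume, subtract_region = NULL,
                            tol = 0.002) {
  V_z <- parts_volume_zscaled(parts)
  if (is.null(subtract_region)) {
    s <- sqrt(target_volume / V_z)
    return(list(region = scaled_parts_region(parts, s), s = s,
                volume_cm3 = target_volume,
                z_ratio = parts[[1]]$zr))
  }
  f <- function(s) s^2 * V_z - overlap_volume(parts, s, subtract_region) -
    target_volume
  lo <- 0.15; hi <- 3.0
  if (f(lo) > 0 || f(hi) < 0) stop("calibration bracket failed")
  for (it in 1:45) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  s <- (lo + hi) / 2
  vol <- s^2 * V_z - overlap_volume(parts, s, subtract_region)
  if (abs(vol - target_volume) / target_volume > 5 * tol)
    stop("calibration failed to converge")
  region <- region_difference(scaled_parts_region(parts, s), subtract_region)
  list(region = region, s = s, volume_cm3 = target_volume,
       z_ratio = parts[[1]]$zr)
}

build_envelope <- function(frame, extra_regions = list()) {
  body <- build_body(frame)
  regs <- c(list(body$head, body$trunk, body$legs), extra_regions)
  do.call(region_union, regs)
}

skin_region <- function(frame) {
  t <- 0.2
  outer <- build_envelope(frame)
  inner <- region_union(
    elliptic_cylinder(frame$A_H - t, frame$B_H - t,
                      z_range = c(frame$C_T - 0.5, frame$C_T + frame$C_H - t)),
    elliptic_cylinder(frame$A_T - t, frame$B_T - t, z_range = c(0, frame$C_T - t)),
    cone_pair(frame$A_T - 2 * t, frame$C_L - t)
  )
  region_difference(outer, inner)
}

#' Assemble a stylized phantom
#'
#' Builds the body frame, instantiates every organ template with a volume
#' target for the requested phantom, z-scales organs by their segment height
#' ratio, calibrates lateral semi-axes to the target volumes, and adds skin
#' (a 0.2 cm outer shell), the simplified skeleton and residual soft tissue.
#' The male phantom carries testes; the female phantom carries uterus,
#' ovaries and breasts; the baseline adult phantom carries all gonadal
#' organs (no breasts).
#'
#' Organ overlap is resolved by a fixed classification precedence
#' (breasts > skin > skeleton > walls > contents > solid organs > residual
#' tissue); the built-in layout keeps organs mutually disjoint so precedence
#' only matters at shared boundaries.
#'
#' @param name `"TRM"`, `"TRW"` or `"ORNL"`.
#' @param templates Organ template registry (default [organ_templates()]).
#' @param breast_volume Total breast volume (cm^3) for the female phantom;
#'   there is no tabulated target so this is a documented default.
#' @return Object of class `pd_phantom`: organ table, named region list,
#'   envelope, materials, and per-organ masses (target volume x density).
#' @export
assemble_phantom <- function(name, templates = organ_templates(),
                             breast_volume = 350) {
  frame <- body_frame(name)
  ratios <- segment_ratios(frame)
  targets <- organ_volume_targets(name)
  mats <- tissue_materials()

  want <- targets$organ
  if (name == "TRW") want <- c(want, "Breasts")
  # build order: walls/contents/solids first, then the skeleton (needs the
  # brain region), then lungs (carved by the heart outer region and ribs)
  build_order <- c(setdiff(want, c("Lungs", "Bone")), "Bone", "Lungs")

  regions <- list()
  info <- list()
  heart_outer <- NULL

  world_parts <- function(tpl) {
    lapply(tpl$parts, function(p) {
      seg <- part_segment(p$anchor, tpl$segment)
      r <- ratios[[seg]]
      list(shape = p$shape,
           anchor = map_anchor(p$anchor, frame, seg),
           zr = r$zr)
    })
  }

  for (org in build_order) {
    tpl <- templates[[org]]
    if (is.null(tpl)) stop("no template for organ: ", org)
    tgt <- if (org == "Breasts") breast_volume
           else targets$volume_cm3[match(org, targets$organ)]
    if (!is.null(tpl$content_of)) {
      # content: inner region of a concentric shell, calibrated to its own row
      cal <- calibrate_parts(world_parts(tpl), tgt)
    } else if (identical(tpl$group, "wall")) {
      content_name <- sub(" wall", " content", org)
      ctgt <- targets$volume_cm3[match(content_name, targets$organ)]
      cal_out <- calibrate_parts(world_parts(tpl), tgt + ctgt)
      heart_flag <- org == "Heart wall"
      if (heart_flag) heart_outer <- cal_out$region
      # wall = outer minus the content region (built from the content row)
      cal_in <- calibrate_parts(world_parts(templates[[content_name]]), ctgt)
      cal <- list(region = region_difference(cal_out$region, cal_in$region),
                  s = cal_out$s, volume_cm3 = tgt, z_ratio = cal_out$z_ratio)
    } else if (!is.null(tpl$subtract)) {
      subs <- lapply(tpl$subtract, function(nm)
        if (nm == "Heart outer") heart_outer else regions[[nm]])
      if (any(vapply(subs, is.null, logical(1))))
        stop("dependency not built for: ", org)
      sub_reg <- if (length(subs) == 1) subs[[1]] else do.call(region_union, subs)
      cal <- calibrate_parts(world_parts(tpl), tgt, subtract_region = sub_reg)
    } else {
      cal <- calibrate_parts(world_parts(tpl), tgt)
    }
    regions[[org]] <- cal$region
    rho <- mats$Density[match(tpl$material, mats$Organ)]
    info[[org]] <- tibble::tibble(
      organ = org, group = tpl$group, material = tpl$material,
      volume_cm3 = tgt, density_g_cm3 = rho, mass_kg = tgt * rho / 1000,
      s = cal$s, z_ratio = cal$z_ratio)
  }

  # skin shell (not calibrated; volume estimated once by MC)
  regions[["Skin"]] <- skin_region(frame)
  skin_vol <- mc_volume(regions[["Skin"]], n = 4e5, seed = 99017)$volume
  rho_skin <- mats$Density[match("Skin", mats$Organ)]
  info[["Skin"]] <- tibble::tibble(
    organ = "Skin", group = "skin", material = "Skin", volume_cm3 = skin_vol,
    density_g_cm3 = rho_skin, mass_kg = skin_vol * rho_skin / 1000,
    s = 1, z_ratio = 1)

  organs <- dplyr::bind_rows(info)
  precedence <- c("Breasts", "Skin", "Bone",
                  "Heart wall", "Stomach wall", "UB wall",
                  "Heart content", "Stomach content", "UB content",
                  "Brain", "Thyroid", "Lungs", "Gall bladder", "Liver",
                  "Kidneys", "Pancreas", "Spleen", "Testes", "Uterus",
                  "Ovaries")
  order_idx <- order(match(organs$organ, precedence))
  organs <- organs[order_idx, ]
  regions <- regions[organs$organ]

  envelope <- build_envelope(frame,
                             if (name == "TRW") regions["Breasts"] else list())
  env_vol <- pi * frame$A_H * frame$B_H * frame$C_H +
    pi * frame$A_T * frame$B_T * frame$C_T +
    pi * frame$A_T^2 * frame$C_L / 6 +
    if (name == "TRW") breast_volume else 0
  resid_vol <- env_vol - sum(organs$volume_cm3)
  rho_soft <- mats$Density[match("Soft tissue", mats$Organ)]

  used <- unique(c(organs$material, "Soft tissue"))
  materials <- mats[match(used, mats$Organ), ]

  phantom <- structure(list(
    name = name, frame = frame, organs = organs, regions = regions,
    envelope = envelope, materials = materials,
    residual_material = "Soft tissue",
    residual_volume_cm3 = resid_vol,
    residual_mass_kg = resid_vol * rho_soft / 1000,
    total_height_cm = frame$C_H + frame$C_T + frame$C_L,
    cache = new.env(parent = emptyenv())
  ), class = "pd_phantom")
  phantom
}

#' @export
print.pd_phantom <- function(x, ...) {
  cat("<pd_phantom ", x$name, ">: ", nrow(x$organs), " organ regions, ",
      "height ", x$total_height_cm, " cm\n", sep = "")
  invisible(x)
}

#' Organ mass table
#'
#' One row per organ region: calibrated volume, tissue density and mass
#' (exactly volume x density), plus the residual soft tissue row.
#'
#' @param phantom A `pd_phantom`.
#' @return Tibble with `organ`, `volume_cm3`, `density_g_cm3`, `mass_kg`.
#' @export
organ_mass_table <- function(phantom) {
  out <- phantom$organs[, c("organ", "volume_cm3", "density_g_cm3", "mass_kg")]
  rho_soft <- phantom$materials$Density[
    match(phantom$residual_material, phantom$materials$Organ)]
  dplyr::bind_rows(out, tibble::tibble(
    organ = "Residual tissue", volume_cm3 = phantom$residual_volume_cm3,
    density_g_cm3 = rho_soft, mass_kg = phantom$residual_mass_kg))
}

# compiled geometry for the kernels (cached on the phantom)
pd_geometry <- function(phantom) {
  if (!is.null(phantom$cache$geom)) return(phantom$cache$geom)
  env_bb <- region_bbox(phantom$envelope)
  flats <- lapply(phantom$regions, region_flatten)
  env_flat <- region_flatten(phantom$envelope)
  prim <- do.call(rbind, c(lapply(flats, `[[`, "prim"), list(env_flat$prim)))
  offs <- cumsum(c(0, vapply(flats, function(f) nrow(f$prim), 0)))
  progs <- lapply(seq_along(flats), function(i) {
    p <- flats[[i]]$prog
    ifelse(p > 0, p + offs[i], p)
  })
  env_prog <- ifelse(env_flat$prog > 0,
                     env_flat$prog + offs[length(offs)], env_flat$prog)
  bbox <- t(vapply(phantom$regions, function(r) {
    bb <- region_bbox(r)
    lo <- pmax(bb[, 1], env_bb[, 1]); hi <- pmin(bb[, 2], env_bb[, 2])
    c(lo[1], hi[1], lo[2], hi[2], lo[3], hi[3])
  }, numeric(6)))
  mat_idx <- match(phantom$organs$material, phantom$materials$Organ)
  world_r <- sqrt(max(rowSums(expand.grid(env_bb[1, ], env_bb[2, ],
                                          env_bb[3, ])^2))) + 5
  geom <- list(prim = prim, progs = progs, bbox = bbox,
               env_prog = as.integer(env_prog), mat = as.integer(mat_idx),
               mat_residual = as.integer(
                 match(phantom$residual_material, phantom$materials$Organ)),
               world_r = world_r)
  phantom$cache$geom <- geom
  geom
}

#' Classify points into organ labels
#'
#' Applies the phantom's precedence order: the first organ region containing
#' a point claims it; points inside the body envelope but in no organ are
#' residual tissue; points outside are vacuum.
#'
#' @param phantom A `pd_phantom`.
#' @param points n x 3 matrix (cm).
#' @return Character vector of organ names, `"Residual tissue"` or `NA`
#'   (outside the body).
#' @export
classify_points <- function(phantom, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  geom <- pd_geometry(phantom)
  out <- rep(NA_character_, nrow(points))
  inside <- cpp_contains(geom$prim, geom$env_prog, points)
  out[inside] <- "Residual tissue"
  left <- which(inside)
  for (i in seq_along(geom$progs)) {
    if (!length(left)) break
    hit <- cpp_contains(geom$prim, geom$progs[[i]], points[left, , drop = FALSE])
    out[left[hit]] <- phantom$organs$organ[i]
    left <- left[!hit]
  }
  out
}
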