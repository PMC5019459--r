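#' Quadric region constructors
#'
#' Constructive solid geometry atoms used to build stylized phantoms. Every
#' region supports point containment ([region_contains()]), closed-form
#' volume where one exists ([analytic_volume()]) and Monte Carlo volume
#' integration ([mc_volume()]). Boundary points (equality in the quadric
#' inequality) count as inside.
#'
#' @param a,b,c Semi-axes in cm (all `> 0`).
#' @param center Length-3 numeric, region center in cm.
#' @param z_range Optional `c(z_lo, z_hi)` clip in the region's own frame
#'   (same frame as `center`), with `z_lo < z_hi`.
#' @param A Cone-pair aperture in cm: each leg cone satisfies
#'   `x^2 + y^2 <= |x| * (A + (A/L) * z)` for `z` in `[-L, 0]`, giving two
#'   mirror cones that taper from diameter `A` at `z = 0` to a point.
#' @param L Cone-pair length in cm.
#' @param normal,d Half-space `normal %*% p <= d`.
#' @return An object of class `quadric_region`.
#' @name quadric-primitives
NULL

new_region <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "quadric_region")
}

check_semiaxes <- function(...) {
  v <- c(...)
  if (any(!is.finite(v)) || any(v <= 0)) stop("all semi-axes must be positive")
  invisible(v)
}

check_zrange <- function(z_range) {
  if (is.null(z_range)) return(invisible(NULL))
  if (length(z_range) != 2 || z_range[1] >= z_range[2])
    stop("z_range must be c(z_lo, z_hi) with z_lo < z_hi")
  invisible(z_range)
}

#' @rdname quadric-primitives
#' @export
ellipsoid <- function(a, b, c, center = c(0, 0, 0), z_range = NULL) {
  check_semiaxes(a, b, c)
  check_zrange(z_range)
  new_region("ellipsoid", a = a, b = b, c = c, center = center, z_range = z_range)
}

#' @rdname quadric-primitives
#' @export
elliptic_cylinder <- function(a, b, z_range, center = c(0, 0, 0)) {
  check_semiaxes(a, b)
  check_zrange(z_range)
  if (is.null(z_range)) stop("elliptic_cylinder requires a finite z_range")
  new_region("elliptic_cylinder", a = a, b = b, center = center, z_range = z_range)
}

#' @rdname quadric-primitives
#' @export
cone_pair <- function(A, L, center = c(0, 0, 0), z_range = NULL) {
  check_semiaxes(A, L)
  if (is.null(z_range)) z_range <- c(-L, 0) + center[3]
  check_zrange(z_range)
  new_region("cone_pair", A = A, L = L, center = center, z_range = z_range)
}

#' @rdname quadric-primitives
#' @export
half_space <- function(normal, d) {
  if (length(normal) != 3 || all(normal == 0)) stop("normal must be a nonzero length-3 vector")
  new_region("half_space", normal = as.numeric(normal), d = as.numeric(d))
}

#' Boolean composition and affine scaling of regions
#'
#' `region_intersection()`, `region_union()` and `region_difference()`
#' compose regions with short-circuit boolean semantics; `region_scale()`
#' wraps a region in an affine map so that a world point `p` is inside iff
#' `(p - shift) / scale` is inside the child. Scaling by `(s, s, r)` is how
#' organ templates are z-stretched and laterally calibrated.
#'
#' @param ... Regions to combine (at least two for intersection/union).
#' @param x,y For `region_difference()`: keep points in `x` but not in `y`.
#' @param region Child region for `region_scale()`.
#' @param scale,shift Length-3 numerics.
#' @return A `quadric_region`.
#' @name quadric-composition
NULL

#' @rdname quadric-composition
#' @export
region_intersection <- function(...) {
  new_region("intersection", children = list(...))
}

#' @rdname quadric-composition
#' @export
region_union <- function(...) {
  new_region("union", children = list(...))
}

#' @rdname quadric-composition
#' @export
region_difference <- function(x, y) {
  new_region("difference", children = list(x, y))
}

#' @rdname quadric-composition
#' @export
region_scale <- function(region, scale = c(1, 1, 1), shift = c(0, 0, 0)) {
  if (any(scale <= 0)) stop("scale factors must be positive")
  new_region("scale", children = list(region), scale = as.numeric(scale),
             shift = as.numeric(shift))
}

#' @export
print.quadric_region <- function(x, ...) {
  cat("<quadric_region:", x$kind, ">\n")
  if (x$kind %in% c("intersection", "union", "difference", "scale"))
    cat("  children:", length(x$children), "\n")
  invisible(x)
}

is_primitive <- function(region) {
  region$kind %in% c("ellipsoid", "elliptic_cylinder", "cone_pair", "half_space")
}

# --- flattening to the compiled representation ------------------------------

prim_row <- function(region, scale, shift) {
  row <- numeric(15)
  row[2:4] <- shift
  row[5:7] <- scale
  ctr <- region$center %||% c(0, 0, 0)
  zr <- region$z_range
  if (region$kind == "ellipsoid") {
    row[1] <- 1
    row[8:10] <- c(region$a, region$b, region$c)
    row[11:12] <- if (is.null(zr)) c(-Inf, Inf) else zr
    # fold the primitive's own center into the shift (applied after scale)
    row[2:4] <- shift + scale * ctr
    row[11:12] <- row[11:12] - ctr[3]
  } else if (region$kind == "elliptic_cylinder") {
    row[1] <- 2
    row[8:9] <- c(region$a, region$b)
    row[2:4] <- shift + scale * ctr
    row[10:11] <- zr - ctr[3]
  } else if (region$kind == "cone_pair") {
    row[1] <- 3
    row[8:9] <- c(region$A, region$L)
    row[2:4] <- shift + scale * ctr
    row[10:11] <- zr - ctr[3]
  } else if (region$kind == "half_space") {
    row[1] <- 4
    row[8:10] <- region$normal
    row[11] <- region$d
  } else stop("not a primitive: ", region$kind)
  row
}

#' Flatten a region to its compiled form
#'
#' Internal representation used by the C++ kernels: a primitive parameter
#' matrix plus a postfix boolean program (positive tokens push primitive
#' containment, -1 AND, -2 OR, -3 DIFF).
#' @param region A `quadric_region`.
#' @return List with elements `prim` (matrix) and `prog` (integer vector).
#' @keywords internal
region_flatten <- function(region) {
  prims <- list()
  # depth-first emission of the postfix program
  prog <- integer(0)
  emit <- function(r, scale, shift) {
    if (is_primitive(r)) {
      prims[[length(prims) + 1]] <<- prim_row(r, scale, shift)
      prog <<- c(prog, length(prims))
      return(invisible(NULL))
    }
    if (r$kind == "scale") {
      emit(r$children[[1]], scale * r$scale, shift + scale * r$shift)
      return(invisible(NULL))
    }
    op <- switch(r$kind, intersection = -1L, union = -2L, difference = -3L,
                 stop("unknown region kind: ", r$kind))
    emit(r$children[[1]], scale, shift)
    for (ch in r$children[-1]) {
      emit(ch, scale, shift)
      prog <<- c(prog, op)
    }
    invisible(NULL)
  }
  emit(region, c(1, 1, 1), c(0, 0, 0))
  prim <- do.call(rbind, prims)
  list(prim = prim, prog = prog)
}

#' Point containment
#'
#' @param region A `quadric_region`.
#' @param points Numeric matrix (n x 3) or length-3 vector, cm.
#' @return Logical vector; boundary points count as inside.
#' @export
region_contains <- function(region, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  fl <- region_flatten(region)
  cpp_contains(fl$prim, fl$prog, points)
}

# --- bounding boxes ---------------------------------------------------------

prim_bbox <- function(region) {
  ctr <- region$center %||% c(0, 0, 0)
  switch(region$kind,
    ellipsoid = {
      zr <- region$z_range %||% c(ctr[3] - region$c, ctr[3] + region$c)
      rbind(ctr[1] + c(-1, 1) * region$a,
            ctr[2] + c(-1, 1) * region$b,
            c(max(zr[1], ctr[3] - region$c), min(zr[2], ctr[3] + region$c)))
    },
    elliptic_cylinder = rbind(ctr[1] + c(-1, 1) * region$a,
                              ctr[2] + c(-1, 1) * region$b,
                              region$z_range),
    cone_pair = rbind(ctr[1] + c(-1, 1) * region$A,
                      ctr[2] + c(-1, 1) * region$A / 2,
                      region$z_range),
    half_space = rbind(c(-Inf, Inf), c(-Inf, Inf), c(-Inf, Inf))
  )
}

#' Axis-aligned bounding box of a region
#'
#' Conservative: the returned box always contains the region (intersection
#' boxes are intersected, union boxes unioned, differences use the minuend).
#' @param region A `quadric_region`.
#' @return 3 x 2 matrix (rows x/y/z, columns lo/hi), possibly infinite for
#'   half-spaces.
#' @export
region_bbox <- function(region) {
  if (is_primitive(region)) return(unname(prim_bbox(region)))
  if (region$kind == "scale") {
    bb <- region_bbox(region$children[[1]])
    bb * region$scale + region$shift
  } else if (region$kind == "intersection") {
    boxes <- lapply(region$children, region_bbox)
    lo <- do.call(pmax, lapply(boxes, function(b) b[, 1]))
    hi <- do.call(pmin, lapply(boxes, function(b) b[, 2]))
    cbind(lo, hi, deparse.level = 0)
  } else if (region$kind == "union") {
    boxes <- lapply(region$children, region_bbox)
    lo <- do.call(pmin, lapply(boxes, function(b) b[, 1]))
    hi <- do.call(pmax, lapply(boxes, function(b) b[, 2]))
    cbind(lo, hi, deparse.level = 0)
  } else {
    region_bbox(region$children[[1]])
  }
}

# --- volumes ----------------------------------------------------------------

clipped_ellipsoid_volume <- function(a, b, c, z_lo, z_hi) {
  # integral of pi*a*b*(1 - (z/c)^2) over the clipped range (z relative center)
  lo <- max(z_lo, -c); hi <- min(z_hi, c)
  if (hi <= lo) return(0)
  f <- function(z) z - z^3 / (3 * c^2)
  pi * a * b * (f(hi) - f(lo))
}

#' Closed-form region volume
#'
#' Exact volume for primitives and affine-scaled primitives: ellipsoid
#' `4/3*pi*a*b*c` (with z-clipping handled as a spherical-cap integral),
#' elliptic cylinder `pi*a*b*h`, cone pair `pi*A^2*L/6` for the full pair.
#' Composites have no general closed form and raise an error.
#'
#' @param region A `quadric_region`.
#' @return Volume in cm^3.
#' @export
analytic_volume <- function(region) {
  if (region$kind == "scale")
    return(prod(region$scale) * analytic_volume(region$children[[1]]))
  switch(region$kind,
    ellipsoid = {
      if (is.null(region$z_range)) 4 / 3 * pi * region$a * region$b * region$c
      else {
        ctr <- region$center %||% c(0, 0, 0)
        clipped_ellipsoid_volume(region$a, region$b, region$c,
                                 region$z_range[1] - ctr[3],
                                 region$z_range[2] - ctr[3])
      }
    },
    elliptic_cylinder = pi * region$a * region$b * diff(region$z_range),
    cone_pair = {
      ctr <- region$center %||% c(0, 0, 0)
      zr <- region$z_range - ctr[3]
      if (!isTRUE(all.equal(zr, c(-region$L, 0))))
        stop("no closed form: partially clipped cone_pair")
      # each leg cross-section is a circle of diameter A*(1 + z/L)
      pi * region$A^2 * region$L / 6
    },
    half_space = stop("no closed form: unbounded region"),
    stop("no closed form: composite region")
  )
}

#' Monte Carlo volume integration
#'
#' Hit-or-miss integration in a bounding box. Deterministic for a given
#' `seed` (set it with [set.seed()] before calling, or pass `seed`).
#'
#' @param region A `quadric_region`.
#' @param n Number of sample points.
#' @param bbox Optional 3 x 2 bounding box (defaults to [region_bbox()]);
#'   must contain the region.
#' @param seed Optional integer seed applied with [set.seed()].
#' @return Tibble with `volume` (cm^3) and `stderr` (binomial standard error).
#' @export
mc_volume <- function(region, n = 1e5, bbox = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bb <- bbox %||% region_bbox(region)
  if (any(!is.finite(bb))) stop("region has an unbounded bounding box; supply bbox")
  vol_box <- prod(bb[, 2] - bb[, 1])
  if (vol_box <= 0) stop("empty bounding box")
  fl <- region_flatten(region)
  hits <- cpp_mc_hits(fl$prim, fl$prog, bb[, 1], bb[, 2], as.integer(n))
  p <- hits / n
  tibble::tibble(volume = p * vol_box,
                 stderr = sqrt(p * (1 - p) / n) * vol_box)
}

# --- serialization ----------------------------------------------------------

#' Serialize a region to / from a plain list
#'
#' The list dialect round-trips losslessly through YAML: primitives carry
#' `kind`, their parameters and optional `z_range`; composites carry `kind`
#' and `children`; scale nodes carry `scale` and `shift`.
#' @param region A `quadric_region` (for `region_to_list`).
#' @param x A list produced by `region_to_list` (for `region_from_list`).
#' @return A plain list, or a `quadric_region`.
#' @export
region_to_list <- function(region) {
  r <- unclass(region)
  if (!is.null(r$children)) r$children <- lapply(r$children, region_to_list)
  r
}

#' @rdname region_to_list
#' @export
region_from_list <- function(x) {
  if (!is.null(x$children)) x$children <- lapply(x$children, region_from_list)
  structure(x, class = "quadric_region")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
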