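#' Plot SAF results
#'
#' SAF against photon energy on log-log axes, one line per source/target
#' pair, coloured by phantom when several phantoms are present.
#'
#' @param object A `pd_saf` tibble (rows from one or more energies).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pd_saf <- function(object, ...) {
  df <- object[!object$excluded & object$saf_kg > 0, ]
  df$pair <- paste(df$target, "←", df$source)
  ggplot2::ggplot(df, ggplot2::aes(.data$energy_MeV, .data$saf_kg,
                                   colour = .data$phantom,
                                   linetype = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Photon energy (MeV)",
                  y = expression(SAF ~ (kg^-1)),
                  colour = "Phantom", linetype = "Target ← Source") +
    ggplot2::theme_minimal()
}

#' Plot S-value results
#'
#' @param object A `pd_svalue` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pd_svalue <- function(object, ...) {
  df <- object[!object$excluded & object$s_mGy_per_MBq_s > 0, ]
  df$target <- stats::reorder(df$target, df$s_mGy_per_MBq_s)
  ggplot2::ggplot(df, ggplot2::aes(.data$s_mGy_per_MBq_s, .data$target)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "S-value (mGy / MBq s)", y = NULL,
                  title = paste(df$nuclide[1], "source:", df$source[1])) +
    ggplot2::theme_minimal()
}

#' Organ mass bar chart
#'
#' @param phantom A `pd_phantom`.
#' @return A ggplot.
#' @export
plot_organ_masses <- function(phantom) {
  mt <- organ_mass_table(phantom)
  mt <- mt[mt$organ != "Residual tissue", ]
  mt$organ <- stats::reorder(mt$organ, mt$mass_kg)
  ggplot2::ggplot(mt, ggplot2::aes(.data$mass_kg, .data$organ)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Mass (kg)", y = NULL,
                  title = paste(phantom$name, "organ masses")) +
    ggplot2::theme_minimal()
}

#' Voxelize a phantom to an integer label mask
#'
#' Classifies a regular grid of points; useful for visual inspection and
#' export. Labels index the phantom's organ precedence order, with residual
#' tissue and vacuum as dedicated codes.
#'
#' @param phantom A `pd_phantom`.
#' @param voxel_cm Isotropic voxel edge length.
#' @return List with `mask` (3-D integer array), `labels` (named codes) and
#'   `voxel_cm`.
#' @export
voxelize_phantom <- function(phantom, voxel_cm = 2) {
  bb <- region_bbox(phantom$envelope)
  xs <- seq(bb[1, 1] + voxel_cm / 2, bb[1, 2], by = voxel_cm)
  ys <- seq(bb[2, 1] + voxel_cm / 2, bb[2, 2], by = voxel_cm)
  zs <- seq(bb[3, 1] + voxel_cm / 2, bb[3, 2], by = voxel_cm)
  grid <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  lab <- classify_points(phantom, grid)
  names <- c(phantom$organs$organ, "Residual tissue")
  codes <- stats::setNames(seq_along(names), names)
  m <- array(0L, dim = c(length(xs), length(ys), length(zs)))
  m[] <- ifelse(is.na(lab), 0L, codes[lab])
  list(mask = m, labels = c(Vacuum = 0L, codes), voxel_cm = voxel_cm,
       origin = bb[, 1])
}
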