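#' Tissue materials
#'
#' Tissue compositions and densities of the stylized phantoms: density in
#' g/cm^3 and elemental mass fractions in percent for H, C, N, O, Ca, Na, P,
#' S, Cl, K. Rows are self-consistent: the fractions sum to 100% within
#' 0.5%. Hollow-organ contents (heart, stomach, urinary bladder) use the
#' wall's composition since no separate content material is tabulated.
#'
#' @param path Optional path to a CSV with the same column order
#'   (Organ, Density, H, C, N, O, Ca, Na, P, S, Cl, K); defaults to the
#'   bundled table.
#' @return Tibble, one row per material.
#' @export
tissue_materials <- function(path = NULL) {
  path <- path %||% system.file("extdata", "tissue_compositions.csv",
                                package = "phantomdose")
  df <- utils::read.csv(path, check.names = FALSE)
  sums <- rowSums(df[, pd_elements()$symbol])
  bad <- abs(sums - 100) > 0.5
  if (any(bad))
    stop("material fractions do not sum to 100% within 0.5%: ",
         paste(df$Organ[bad], collapse = ", "))
  if (any(df$Density <= 0)) stop("densities must be positive")
  tibble::as_tibble(df)
}

#' Write a materials table as CSV
#'
#' Column order matches the bundled composition table exactly.
#' @param materials Tibble from [tissue_materials()].
#' @param path Output file.
#' @export
write_materials <- function(materials, path) {
  cols <- c("Organ", "Density", "H", "C", "N", "O", "Ca", "Na", "P", "S",
            "Cl", "K") # canonical composition-table column order
  utils::write.csv(as.data.frame(materials)[, cols], path, row.names = FALSE)
  invisible(path)
}

material_row <- function(materials, name) {
  i <- match(name, materials$Organ)
  if (is.na(i)) stop("unknown material: ", name)
  materials[i, ]
}

#' Linear attenuation coefficients of a tissue mixture
#'
#' Mass-fraction-weighted sum of the elemental mass interaction coefficients
#' (log-log interpolated on the energy grid), multiplied by the material
#' density.
#'
#' @param material A material name (looked up in [tissue_materials()]) or a
#'   single-row materials tibble.
#' @param energy_MeV Photon energies (within the 0.002-4 MeV grid).
#' @return Tibble with one row per energy: partial linear attenuation
#'   coefficients (cm^-1) for `photoelectric`, `incoherent`, `coherent`,
#'   `pair`, and their sum `total`.
#' @export
mixture_mu <- function(material, energy_MeV) {
  if (is.character(material)) material <- material_row(tissue_materials(), material)
  xs <- element_tables()
  if (any(energy_MeV < min(xs$E)) || any(energy_MeV > max(xs$E)))
    stop("energy outside the cross-section grid (0.002-4 MeV)")
  w <- as.numeric(material[, xs$elements$symbol]) / 100
  rho <- material$Density
  chan <- function(tab) {
    m <- vapply(seq_len(ncol(tab)), function(e)
      loglog_interp(energy_MeV, xs$E, tab[, e]), numeric(length(energy_MeV)))
    as.numeric(matrix(m, ncol = ncol(tab)) %*% w) * rho
  }
  pe <- chan(xs$pe); inc <- chan(xs$inc); coh <- chan(xs$coh); pr <- chan(xs$pair)
  pr[energy_MeV <= 1.0219978] <- 0
  tibble::tibble(energy_MeV = energy_MeV, photoelectric = pe, incoherent = inc,
                 coherent = coh, pair = pr, total = pe + inc + coh + pr)
}

#' Majorant attenuation coefficient of a phantom
#'
#' Upper bound used by Woodcock tracking: at least the maximum total linear
#' attenuation over all materials present in the phantom at the requested
#' energy.
#'
#' @param phantom A `pd_phantom` (see [assemble_phantom()]).
#' @param energy_MeV Photon energies.
#' @return Numeric vector, cm^-1.
#' @export
majorant_mu <- function(phantom, energy_MeV) {
  mats <- phantom$materials
  mus <- vapply(seq_len(nrow(mats)), function(i)
    mixture_mu(mats[i, ], energy_MeV)$total, numeric(length(energy_MeV)))
  apply(matrix(mus, ncol = nrow(mats)), 1, max)
}
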