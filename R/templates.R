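#' Organ template registry
#'
#' Built-in quadric recipes for the stylized organs, expressed in the
#' baseline adult body frame (trunk base at z = 0, trunk height 70 cm, head
#' segment above, legs below). Each template lists one or more parts; a part
#' is a `quadric_region` in part-local coordinates plus an anchor position.
#' During assembly the anchor is mapped into the target body frame (z by the
#' segment height ratio, x and y by the segment's lateral semi-axis ratios)
#' and the shape is wrapped in an affine scale `(s, s, z_ratio)` where the
#' common lateral factor `s` is solved so the organ volume matches its
#' calibration target; the x:y semi-axis ratio is therefore preserved.
#'
#' The baseline recipes reproduce the classic stylized-adult organ volumes
#' closely (e.g. kidneys 288 cm^3, spleen 175.9 cm^3, stomach 402 cm^3,
#' ovaries 8.38 cm^3), so the baseline phantom calibrates with `s` near 1.
#' Users can substitute their own recipes via the `templates` argument of
#' [assemble_phantom()].
#'
#' @return Named list of organ templates.
#' @export
organ_templates <- function() {
  tpl <- list()
  add <- function(name, segment, group, material, parts, subtract = NULL,
                  content_of = NULL) {
    tpl[[name]] <<- list(name = name, segment = segment, group = group,
                         material = material, parts = parts,
                         subtract = subtract, content_of = content_of)
  }
  part <- function(anchor, shape) list(anchor = anchor, shape = shape)

  add("Brain", "head", "solid", "Brain",
      list(part(c(0, 0, 87.2), ellipsoid(6, 9, 6.55))))
  add("Thyroid", "head", "solid", "Thyroid",
      list(part(c(0, -5, 73), ellipsoid(2.0, 1.0, 2.4))))
  # two half-ellipsoid lungs clipped to their base plane; the heart region is
  # carved out after the heart is built
  add("Lungs", "trunk", "solid", "Lungs",
      list(part(c(-8.5, 0, 43.5), ellipsoid(5, 7.5, 24, z_range = c(0, 24))),
           part(c(8.5, 0, 43.5), ellipsoid(5, 7.5, 24, z_range = c(0, 24)))),
      subtract = c("Heart outer", "Bone"))
  add("Heart wall", "trunk", "wall", "Heart",
      list(part(c(2, -3, 51), ellipsoid(6.5, 5, 5.5))))
  add("Heart content", "trunk", "content", "Heart",
      list(part(c(2, -3, 51), ellipsoid(6.5, 5, 5.5))),
      content_of = "Heart wall")
  add("Stomach wall", "trunk", "wall", "Stomach",
      list(part(c(8, -4, 35), ellipsoid(4, 3, 8))))
  add("Stomach content", "trunk", "content", "Stomach",
      list(part(c(8, -4, 35), ellipsoid(4, 3, 8))),
      content_of = "Stomach wall")
  # cut elliptic cylinder: the classic wedge-shaped stylized liver
  add("Liver", "trunk", "solid", "Liver",
      list(part(c(0, 0, 0),
                region_intersection(
                  elliptic_cylinder(16.5, 8, z_range = c(27, 43)),
                  half_space(c(1 / 35, 1 / 45, -1 / 43), -1)))))
  add("Gall bladder", "trunk", "solid", "Soft tissue",
      list(part(c(-4.5, -4.5, 30), ellipsoid(1.21, 0.968, 2.057))))
  # paired kidneys, each an ellipsoid cut by the medial plane
  add("Kidneys", "trunk", "solid", "Kidneys",
      list(part(c(-6, 6, 32.5),
                region_intersection(ellipsoid(4.5, 1.5, 5.5),
                                    half_space(c(1, 0, 0), 3))),
           part(c(6, 6, 32.5),
                region_intersection(ellipsoid(4.5, 1.5, 5.5),
                                    half_space(c(-1, 0, 0), 3)))))
  # half-ellipsoid pancreas elongated towards the left
  add("Pancreas", "trunk", "solid", "Pancreas",
      list(part(c(0, 0, 37),
                region_intersection(ellipsoid(15, 1, 3),
                                    half_space(c(-1, 0, 0), 0)))))
  add("Spleen", "trunk", "solid", "Spleen",
      list(part(c(11, 3, 37), ellipsoid(3.5, 2, 6))))
  add("UB wall", "trunk", "wall", "Urinary bladder",
      list(part(c(0, -4.5, 8), ellipsoid(4.958, 3.458, 3.458))))
  add("UB content", "trunk", "content", "Urinary bladder",
      list(part(c(0, -4.5, 8), ellipsoid(4.958, 3.458, 3.458))),
      content_of = "UB wall")
  add("Testes", "trunk", "solid", "Testes",
      list(part(c(-1.5, -7.5, 2.5), ellipsoid(1.3, 1.5, 2.3)),
           part(c(1.5, -7.5, 2.5), ellipsoid(1.3, 1.5, 2.3))))
  add("Uterus", "trunk", "solid", "Uterus",
      list(part(c(0, -2, 14), ellipsoid(2.5, 5, 1.5))))
  add("Ovaries", "trunk", "solid", "Ovaries",
      list(part(c(-6, 0, 15), ellipsoid(1, 0.5, 2)),
           part(c(6, 0, 15), ellipsoid(1, 0.5, 2))))
  # simplified axial skeleton: leg bones, arm bones, spine, rib cage shell,
  # pelvis half-ring, skull shell; calibrated jointly by one lateral factor
  add("Bone", "multi", "skeleton", "Bone",
      list(part(c(0, 0, 0), cone_pair(7.2, 80)),                       # legs
           part(c(-18.2, 0, 34.5), elliptic_cylinder(1.4, 2.7, c(-34.5, 34.5))),
           part(c(18.2, 0, 34.5), elliptic_cylinder(1.4, 2.7, c(-34.5, 34.5))),
           part(c(0, 5.5, 46), elliptic_cylinder(2, 2.5, c(-24, 24))), # spine
           part(c(0, 0, 56),
                region_difference(elliptic_cylinder(16.5, 9.3, c(-12, 12)),
                                  elliptic_cylinder(15.5, 8.3, c(-13, 13)))),
           part(c(0, 0, 7),
                region_intersection(
                  region_difference(elliptic_cylinder(11, 9, c(-7, 7)),
                                    elliptic_cylinder(10, 8, c(-8, 8))),
                  half_space(c(0, -1, 0), 0))),                        # pelvis
           part(c(0, 0, 87.2),
                region_difference(ellipsoid(7.4, 9.9, 7.8),
                                  ellipsoid(6.8, 9.3, 7.2)))),         # skull
      subtract = "Brain")
  # breasts attach to the anterior trunk surface (female phantom only)
  add("Breasts", "trunk", "breast", "Breasts",
      list(part(c(-8.5, -9.06, 52.5),
                region_intersection(ellipsoid(4.4, 4.3, 4.4),
                                    half_space(c(0, 1, 0), 0))),
           part(c(8.5, -9.06, 52.5),
                region_intersection(ellipsoid(4.4, 4.3, 4.4),
                                    half_space(c(0, 1, 0), 0)))))
  tpl
}

# segment mapping ratios relative to the baseline adult frame
baseline_frame <- function() {
  list(A_H = 8.0, B_H = 10.0, C_H = 28.6, A_T = 20.0, B_T = 10.0,
       C_T = 70.0, C_L = 80.0)
}

segment_ratios <- function(frame) {
  b <- baseline_frame()
  list(
    head = list(ax = frame$A_H / b$A_H, by = frame$B_H / b$B_H,
                zr = frame$C_H / b$C_H),
    trunk = list(ax = frame$A_T / b$A_T, by = frame$B_T / b$B_T,
                 zr = frame$C_T / b$C_T),
    legs = list(ax = frame$A_T / b$A_T, by = frame$A_T / b$A_T,
                zr = frame$C_L / b$C_L)
  )
}

part_segment <- function(anchor, segment) {
  if (segment != "multi") return(segment)
  b <- baseline_frame()
  if (anchor[3] > b$C_T) "head" else if (anchor[3] <= 0) "legs" else "trunk"
}

# anchor in the target frame; baseline z in (0, 70] is trunk, above is head,
# at or below 0 is legs (segment must already be resolved per part)
map_anchor <- function(anchor, frame, segment) {
  r <- segment_ratios(frame)
  b <- baseline_frame()
  if (segment == "head") {
    c(anchor[1] * r$head$ax, anchor[2] * r$head$by,
      frame$C_T + (anchor[3] - b$C_T) * r$head$zr)
  } else if (segment == "legs") {
    c(anchor[1] * r$legs$ax, anchor[2] * r$legs$by, anchor[3] * r$legs$zr)
  } else {
    c(anchor[1] * r$trunk$ax, anchor[2] * r$trunk$by, anchor[3] * r$trunk$zr)
  }
}
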