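# 32-channel montage on an idealised spherical head.

biosemi32_angles <- function() {
  # (label, inclination from vertex, azimuth clockwise from nasion; degrees)
  m <- matrix(c(
    "Fp1", 90, -18,  "Fp2", 90,  18,
    "AF3", 74, -25,  "AF4", 74,  25,
    "F7",  90, -54,  "F8",  90,  54,
    "F3",  62, -39,  "F4",  62,  39,
    "Fz",  45,   0,  "Cz",   0,   0,
    "FC5", 72, -69,  "FC6", 72,  69,
    "FC1", 34, -45,  "FC2", 34,  45,
    "T7",  90, -90,  "T8",  90,  90,
    "C3",  45, -90,  "C4",  45,  90,
    "CP5", 72, -111, "CP6", 72, 111,
    "CP1", 34, -135, "CP2", 34, 135,
    "P7",  90, -126, "P8",  90, 126,
    "P3",  62, -141, "P4",  62, 141,
    "Pz",  45, 180,
    "PO3", 74, -155, "PO4", 74, 155,
    "O1",  90, -162, "O2",  90, 162,
    "Oz",  90, 180
  ), ncol = 3, byrow = TRUE)
  data.frame(
    label = m[, 1],
    theta = as.numeric(m[, 2]),
    phi = as.numeric(m[, 3]),
    stringsAsFactors = FALSE
  )
}

#' Standard 32-channel 10-20 montage
#'
#' Electrode positions of the 32-channel 10-20 layout used by BioSemi-style
#' caps, on an idealised unit-sphere head (x right, y anterior, z superior).
#' Positions are the textbook 10-20 arc geometry, adequate for
#' nearest-neighbour channel interpolation and tabular topography export;
#' they are not digitised coordinates.
#'
#' @return A tibble with columns `label`, `x`, `y`, `z`.
#' @examples
#' montage_biosemi32()
#' @export
montage_biosemi32 <- function() {
  ang <- biosemi32_angles()
  th <- ang$theta * pi / 180
  ph <- ang$phi * pi / 180
  tibble::tibble(
    label = ang$label,
    x = sin(th) * sin(ph),
    y = sin(th) * cos(ph),
    z = cos(th)
  )
}
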