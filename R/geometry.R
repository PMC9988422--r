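#' Transwell insert geometry
#'
#' Describes a two-chamber culture insert: the porous membrane area and the
#' volumes of the luminal (apical, "A") and abluminal (basolateral, "B")
#' compartments. The dosing ("donor") and receiving sides swap with assay
#' direction: A2B doses the luminal side, B2A the abluminal side.
#'
#' Defaults correspond to a conventional 24-well transwell insert
#' (0.33 cm^2 membrane, 200 uL apical, 600 uL basolateral); the plate format
#' is configurable because insert lines differ.
#'
#' @param membrane_area_cm2 membrane surface area S in cm^2.
#' @param luminal_uL volume of the luminal (apical) compartment, uL.
#' @param abluminal_uL volume of the abluminal (basolateral) compartment, uL.
#' @return An object of class `insert_geometry`.
#' @examples
#' geom <- insert_geometry(0.33, 200, 600)
#' receiver_volume(geom, "A2B")  # abluminal side receives
#' @export
insert_geometry <- function(membrane_area_cm2 = 0.33,
                            luminal_uL = 200,
                            abluminal_uL = 600) {
  check_number(membrane_area_cm2, "membrane_area_cm2", positive = TRUE)
  check_number(luminal_uL, "luminal_uL", positive = TRUE)
  check_number(abluminal_uL, "abluminal_uL", positive = TRUE)
  structure(
    list(membrane_area_cm2 = membrane_area_cm2,
         luminal_uL = luminal_uL,
         abluminal_uL = abluminal_uL),
    class = "insert_geometry"
  )
}

#' @export
print.insert_geometry <- function(x, ...) {
  cat(sprintf(
    "Transwell insert geometry: S = %.3g cm^2, luminal %.4g uL, abluminal %.4g uL\n",
    x$membrane_area_cm2, x$luminal_uL, x$abluminal_uL))
  invisible(x)
}

#' Donor- and receiver-side compartment volumes for an assay direction
#'
#' @param geometry an [insert_geometry()].
#' @param direction `"A2B"` (dose luminal, receive abluminal) or `"B2A"`.
#' @return Volume in uL.
#' @export
receiver_volume <- function(geometry, direction = c("A2B", "B2A")) {
  direction <- match.arg(direction)
  stopifnot(inherits(geometry, "insert_geometry"))
  if (direction == "A2B") geometry$abluminal_uL else geometry$luminal_uL
}

#' @rdname receiver_volume
#' @export
donor_volume <- function(geometry, direction = c("A2B", "B2A")) {
  direction <- match.arg(direction)
  stopifnot(inherits(geometry, "insert_geometry"))
  if (direction == "A2B") geometry$luminal_uL else geometry$abluminal_uL
}
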