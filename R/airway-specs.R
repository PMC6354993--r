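# Geometry of the normal and constricted bronchiole models (classes A0-A4).

#' Dimensions of the normal and diseased airway models
#'
#' Returns the reference parameterization of the five disease classes used
#' throughout the package: the minimum bronchiolar diameter and
#' cross-sectional area at the constriction site (seventh- to
#' ninth-generation bronchioles) and the volume of the disease-affected
#' region. Severity is derived from the areas as
#' \eqn{1 - A_{min}/A_{min}(A0)}, a dimensionless fraction in \[0, 1\] that
#' is 0 for the normal airway and strictly increases with class index.
#'
#' @return A data frame with one row per class (`A0`-`A4`) and columns
#'   `label`, `min_diameter` (mm), `min_area` (mm^2), `affected_volume`
#'   (mm^3) and `severity` (fraction).
#' @examples
#' airway_disease_specs()
#' @export
airway_disease_specs <- function() {
  specs <- data.frame(
    label = c("A0", "A1", "A2", "A3", "A4"),
    min_diameter = c(3.74, 1.88, 1.13, 0.87, 0.25),
    min_area = c(11.0, 2.8, 1.0, 0.6, 0.05),
    affected_volume = c(189.9, 77.6, 50.5, 46.6, 37.9),
    stringsAsFactors = FALSE
  )
  specs$severity <- 1 - specs$min_area / specs$min_area[1]
  validate_airway_specs(specs)
  specs
}

#' @noRd
validate_airway_specs <- function(specs) {
  abort_if(any(specs$min_diameter <= 0) || any(specs$min_area <= 0) ||
             any(specs$affected_volume <= 0),
           "airway dimensions must all be positive")
  # printed areas are circular-section areas of the printed diameters,
  # up to the table's own rounding (A4 is printed to two decimals)
  circ <- area_from_diameter(specs$min_diameter)
  abort_if(any(abs(circ - specs$min_area) > 0.05),
           "min_area inconsistent with pi * d^2 / 4 for class %s",
           paste(specs$label[abs(circ - specs$min_area) > 0.05],
                 collapse = ", "))
  abort_if(specs$severity[1] != 0, "severity of the normal class must be 0")
  abort_if(any(diff(specs$severity) <= 0),
           "severity must strictly increase with class index")
  invisible(specs)
}

#' Circular cross-sectional area from a diameter
#'
#' @param d diameter in mm (vectorized, all values >= 0).
#' @return area(s) in mm^2, \eqn{\pi d^2 / 4}.
#' @examples
#' round(area_from_diameter(3.74), 1) # 11.0, the normal-airway area
#' @export
area_from_diameter <- function(d) {
  abort_if(!is.numeric(d) || any(!is.finite(d)), "d must be finite numeric")
  abort_if(any(d < 0), "diameter must be nonnegative")
  pi * d^2 / 4
}

#' Percent constriction of one airway class relative to a reference
#'
#' Computes `100 * (1 - spec$min_area / ref$min_area)`, the percentage by
#' which the minimum cross-sectional area is reduced relative to the
#' reference (normally the healthy class A0). The two most constricted
#' classes correspond to 94.5% and 99.5% area reduction.
#'
#' @param spec,ref single rows of [airway_disease_specs()] (or any lists
#'   with a positive `min_area` field; `ref$min_area` must be > 0).
#' @return percent constriction (not rounded).
#' @examples
#' specs <- airway_disease_specs()
#' severity_percent(specs[4, ], specs[1, ]) # ~94.5 for A3 vs A0
#' @export
severity_percent <- function(spec, ref) {
  abort_if(is.null(spec$min_area) || is.null(ref$min_area),
           "spec and ref must carry a min_area field")
  abort_if(!is_number(ref$min_area) || ref$min_area <= 0,
           "reference min_area must be a positive number")
  100 * (1 - spec$min_area / ref$min_area)
}

#' Relative difference of two positive dimensions, in percent
#'
#' `100 * (a - b) / a`, rounded to the nearest integer as reported for
#' between-class geometry differences (e.g. a 23% diameter difference
#' between the two most-confused classes). The caller orders the operands;
#' `a` must be the larger.
#'
#' @param a,b positive scalars with `a >= b`.
#' @return integer percent difference.
#' @examples
#' relative_difference_percent(1.13, 0.87) # 23
#' @export
relative_difference_percent <- function(a, b) {
  abort_if(!is_number(a) || !is_number(b), "a and b must be finite scalars")
  abort_if(b <= 0, "operands must be positive")
  abort_if(b > a, "b must not exceed a; order the operands")
  round(100 * (a - b) / a)
}
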