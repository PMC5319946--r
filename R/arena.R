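#' Arena geometries
#'
#' `of_arena()` describes the circular open field: a 90-cm outer circle with
#' a concentric 60-cm inner zone (the remaining 15-cm-wide ring is the outer
#' annulus).  `epm_arena()` describes the elevated plus maze: four
#' axis-aligned arms at 90 degrees around a central square of side
#' `arm_width`; the two arms along the x axis are open, the two along the y
#' axis closed.  Arm dimensions are configuration, not constants: the
#' percentage formulas do not depend on them, but zone classification does.
#'
#' @param outer_diameter,inner_diameter open-field diameters in cm.
#' @return object of class `arena` with element `kind` (`"open_field"` or
#'   `"epm"`) plus the geometry fields.
#' @export
of_arena <- function(outer_diameter = 90, inner_diameter = 60) {
  check_number(outer_diameter, "outer_diameter", lower = 1e-6)
  check_number(inner_diameter, "inner_diameter", lower = 1e-6)
  if (inner_diameter >= outer_diameter)
    abort_validation("inner_diameter must be smaller than outer_diameter")
  structure(list(kind = "open_field",
                 outer_radius = outer_diameter / 2,
                 inner_radius = inner_diameter / 2),
            class = "arena")
}

#' @rdname of_arena
#' @param arm_length,arm_width elevated-plus-maze arm dimensions in cm
#'   (arm length measured from the edge of the central square).
#' @export
epm_arena <- function(arm_length = 50, arm_width = 10) {
  check_number(arm_length, "arm_length", lower = 1e-6)
  check_number(arm_width, "arm_width", lower = 1e-6)
  structure(list(kind = "epm", arm_length = arm_length, arm_width = arm_width),
            class = "arena")
}

#' @export
print.arena <- function(x, ...) {
  if (x$kind == "open_field")
    cat(sprintf("<open-field arena: outer radius %g cm, inner radius %g cm>\n",
                x$outer_radius, x$inner_radius))
  else
    cat(sprintf("<EPM arena: arms %g x %g cm, open arms on the x axis>\n",
                x$arm_length, x$arm_width))
  invisible(x)
}

#' Classify positions into arena zones
#'
#' Open field: `"inner"` (inside the inner circle, boundary inclusive) or
#' `"outer"`.  EPM: `"centre"` (central square), `"open"` (x-axis arms) or
#' `"closed"` (y-axis arms); the animal position is the tracked centre
#' point.
#'
#' @param arena an [of_arena()] or [epm_arena()].
#' @param x,y coordinates in cm (vectors).
#' @return character vector of zone labels.
#' @export
arena_zone <- function(arena, x, y) {
  stopifnot(inherits(arena, "arena"))
  if (arena$kind == "open_field") {
    ifelse(sqrt(x^2 + y^2) <= arena$inner_radius, "inner", "outer")
  } else {
    h <- arena$arm_width / 2
    in_x <- abs(y) <= h
    in_y <- abs(x) <= h
    ifelse(in_x & in_y, "centre", ifelse(in_x, "open", "closed"))
  }
}

arena_contains <- function(arena, x, y, tol = 1e-9) {
  if (arena$kind == "open_field") {
    sqrt(x^2 + y^2) <= arena$outer_radius + tol
  } else {
    h <- arena$arm_width / 2 + tol
    reach <- arena$arm_width / 2 + arena$arm_length + tol
    (abs(y) <= h & abs(x) <= reach) | (abs(x) <= h & abs(y) <= reach)
  }
}
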