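#' Sucrose preference
#'
#' Two-bottle anhedonia index: `100 * sucrose / (sucrose + water)`, both
#' consumptions in grams over the timed test.
#'
#' @param sucrose_consumed g of 1% sucrose solution consumed (>= 0).
#' @param water_consumed g of water consumed (>= 0).
#' @return preference in percent, within [0, 100].
#' @export
#' @examples
#' sucrose_preference(3, 1)  # 75
sucrose_preference <- function(sucrose_consumed, water_consumed) {
  if (any(!is.finite(sucrose_consumed)) || any(!is.finite(water_consumed)) ||
      any(sucrose_consumed < 0) || any(water_consumed < 0))
    abort_validation("consumptions must be non-negative numbers of grams")
  tot <- sucrose_consumed + water_consumed
  if (any(tot == 0))
    stop(errorCondition("no intake: sucrose + water consumption is zero, preference undefined",
                        class = c("affectscales_no_intake", "affectscales_validation",
                                  "error", "condition")))
  # ratio first: s/tot <= 1 exactly, so the result can never exceed 100
  100 * (sucrose_consumed / tot)
}

#' Von Frey response series
#'
#' A sequence of filament applications: the forces applied (g) and the
#' parallel positive-withdrawal responses.  The manufacturer-recommended
#' filament set is `c(15, 10, 8, 6, 4, 2)` g.
#'
#' @param forces_applied numeric vector of forces in g.
#' @param responses logical vector, `TRUE` = positive withdrawal.
#' @param force_set allowed filament forces; applied forces must be drawn
#'   from it.
#' @return object of class `von_frey_series`.
#' @export
von_frey_series <- function(forces_applied, responses,
                            force_set = c(15, 10, 8, 6, 4, 2)) {
  if (length(forces_applied) != length(responses))
    abort_validation("forces and responses must have equal length")
  if (length(forces_applied) == 0L)
    abort_validation("a von Frey series cannot be empty")
  if (!all(forces_applied %in% force_set))
    abort_validation(sprintf("applied forces outside the configured force set {%s}",
                             paste(sort(force_set), collapse = ", ")))
  structure(list(forces_applied = as.numeric(forces_applied),
                 responses = as.logical(responses),
                 force_set = sort(as.numeric(force_set))),
            class = "von_frey_series")
}

#' @export
print.von_frey_series <- function(x, ...) {
  cat(sprintf("<von_frey_series: %d applications, %d positive>\n",
              length(x$forces_applied), sum(x$responses)))
  invisible(x)
}

#' 50% withdrawal threshold from a von Frey series
#'
#' The default `"ascending"` method returns the lowest force whose
#' empirical positive-response fraction is at least 0.5 (scanning the
#' applied forces in ascending order); it is reproducible from any response
#' table and is invariant to permuting applications of equal force.  The
#' alternative `"updown"` method is a Dixon-style estimator for staircase
#' protocols: the threshold is the geometric mean of the forces at which
#' the response sequence reversed direction.
#'
#' Boundary cases: if no force reaches a 0.5 response fraction the maximum
#' force of the force set is returned with flag `"ceiling"` (the animal
#' never responded enough); if every response is positive the minimum force
#' is returned with flag `"floor"`.
#'
#' @param series a [von_frey_series()].
#' @param method `"ascending"` (default) or `"updown"`.
#' @return numeric threshold in g, within the force set's range, with
#'   attribute `flag` (`NULL`, `"ceiling"` or `"floor"`).
#' @export
#' @examples
#' s <- von_frey_series(rep(c(15, 10, 8, 6, 4, 2), each = 2),
#'                      rep(c(15, 10, 8, 6, 4, 2), each = 2) >= 6)
#' fifty_percent_threshold(s)  # 6
fifty_percent_threshold <- function(series, method = c("ascending", "updown")) {
  stopifnot(inherits(series, "von_frey_series"))
  method <- match.arg(method)
  f_min <- min(series$force_set); f_max <- max(series$force_set)
  if (all(!series$responses))
    return(structure(f_max, flag = "ceiling"))
  if (all(series$responses))
    return(structure(f_min, flag = "floor"))
  if (method == "ascending") {
    frac <- tapply(series$responses, series$forces_applied, mean)
    forces <- as.numeric(names(frac))
    ord <- order(forces)
    hit <- which(frac[ord] >= 0.5)
    if (length(hit) == 0L) return(structure(f_max, flag = "ceiling"))
    structure(unname(forces[ord][hit[1L]]), flag = NULL)
  } else {
    # Dixon-style: reversals are consecutive applications whose outcome
    # changed; average the log-forces flanking each reversal.
    r <- series$responses
    ch <- which(diff(r) != 0)
    if (length(ch) == 0L) return(structure(f_max, flag = "ceiling"))
    lf <- log(series$forces_applied)
    est <- exp(mean((lf[ch] + lf[ch + 1L]) / 2))
    structure(min(max(est, f_min), f_max), flag = NULL)
  }
}

#' Weekly weight series for one rat
#'
#' Collects a rat's (day, weight) measurements, sorted by day.  Two weight
#' records for the same rat-day are a data-integrity error, not silently
#' averaged.
#'
#' @param records data.frame with at least `day` and `weight` columns
#'   (rows for one rat).
#' @return data.frame with columns `day`, `weight_g`, sorted by day.
#' @export
weekly_weight_series <- function(records) {
  if (!is.data.frame(records) || !all(c("day", "weight") %in% names(records)))
    abort_validation("records must be a data.frame with `day` and `weight` columns")
  records <- records[!is.na(records$weight), , drop = FALSE]
  if (nrow(records) == 0L)
    abort_validation("no weight measurements present")
  if (anyDuplicated(records$day))
    abort_validation(sprintf("duplicate weight measurements on day(s) %s",
                             paste(unique(records$day[duplicated(records$day)]), collapse = ", ")))
  out <- records[order(records$day), c("day", "weight")]
  names(out) <- c("day", "weight_g")
  rownames(out) <- NULL
  out
}
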