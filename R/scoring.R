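#' Item scorers for the depression and anxiety scales
#'
#' Each scorer maps one raw behavioural index to integer points via the
#' built-in interval tables (see [builtin_scales()]).  Fewer points mean
#' more depression- or anxiety-like behaviour.  The weight item is unimodal
#' (plateau at 330-360 g, the normal weight of a 9-10-week-old rat); all
#' other items are non-decreasing in their argument.  Values are scored at
#' full floating precision, never pre-rounded.
#'
#' @param weight body weight in g (> 0).
#' @param mode `"table"` follows the printed scale table (extremes score 1);
#'   `"prose"` follows the prose rule (weights < 300 g or >= 390 g score 0).
#'   The two disagree only at the extremes; see [validate_builtin_scales()].
#' @param scales scale-table set, defaulting to [builtin_scales()].
#' @return integer points.
#' @export
#' @examples
#' score_weight(345)   # 5: inside the normal-weight plateau
#' score_sucrose(97)   # 10: full score above 95% preference
#' score_distance(22)  # 5
#' score_rearing(25)   # 5
#' score_anxiety_pct(35, "ID")  # 7
#' score_oe(10)        # 1: the flat 1-20% band
score_weight <- function(weight, mode = c("table", "prose"), scales = builtin_scales()) {
  mode <- match.arg(mode)
  if (any(!is.finite(weight)) || any(weight <= 0))
    abort_validation("weight must be a positive number of grams")
  pts <- scale_points(scales$weight, weight)
  if (mode == "prose") pts[weight < 300 | weight >= 390] <- 0L
  pts
}

#' @rdname score_weight
#' @param pref sucrose preference in percent, within [0, 100].
#' @export
score_sucrose <- function(pref, scales = builtin_scales()) {
  if (any(!is.finite(pref)) || any(pref < 0) || any(pref > 100))
    abort_validation("sucrose preference must lie in [0, 100] percent")
  scale_points(scales$sucrose, pref)
}

#' @rdname score_weight
#' @param distance_m open-field travel distance in metres (>= 0).
#' @export
score_distance <- function(distance_m, scales = builtin_scales()) {
  if (any(!is.finite(distance_m)) || any(distance_m < 0))
    abort_validation("travel distance must be a non-negative number of metres")
  scale_points(scales$distance, distance_m)
}

#' @rdname score_weight
#' @param count rearing (exploration) count, a non-negative integer.
#' @export
score_rearing <- function(count, scales = builtin_scales()) {
  if (any(!is.finite(count)) || any(count < 0) || any(count != floor(count)))
    abort_validation("rearing count must be a non-negative integer")
  scale_points(scales$rearing, count)
}

#' @rdname score_weight
#' @param value percentage in [0, 100].
#' @param index which anxiety index the value is: `"ID"` (inner-zone
#'   distance %), `"IT"` (inner-zone time %) or `"OT"` (open-arm time %).
#'   All three share the same 0-7 bin structure.
#' @export
score_anxiety_pct <- function(value, index = c("ID", "IT", "OT"), scales = builtin_scales()) {
  index <- match.arg(index)
  if (any(!is.finite(value)) || any(value < 0) || any(value > 100))
    abort_validation(sprintf("%s%% must lie in [0, 100]", index))
  scale_points(scales[[tolower(index)]], value)
}

#' @rdname score_weight
#' @export
score_oe <- function(value, scales = builtin_scales()) {
  if (any(!is.finite(value)) || any(value < 0) || any(value > 100))
    abort_validation("OE% must lie in [0, 100]")
  scale_points(scales$oe, value)
}

#' Score one rat on both scales
#'
#' Applies the item scorers to a rat's eight indices and sums them into a
#' total depression score (weight + sucrose + distance + rearing, 0-25) and
#' a total anxiety score (ID + IT + OT + OE, 0-28).  `NA` indices are
#' treated as missing: excluded from the total and flagged — except OE%,
#' where the default policy scores an undefined OE% (a rat that never
#' entered any arm) as 0 points on the rationale that refusing every arm is
#' maximal avoidance, not missing data.
#'
#' @param indices named list or one-row data.frame with elements `weight`
#'   (g), `sucrose_pct`, `distance_m`, `rearing`, `id_pct`, `it_pct`,
#'   `ot_pct`, `oe_pct`.  `NA` marks a missing item.
#' @param rat_id identifier copied into the score card.
#' @param weight_conflict passed to [score_weight()] as `mode`.
#' @param oe_policy `"zero"` (default) scores a missing OE% as 0 with a
#'   flag; `"missing"` excludes it like any other missing item.
#' @param scales scale-table set.
#' @return one-row data.frame (a *score card*): `rat_id`, the eight item
#'   point columns (`weight_pts`, ..., `oe_pts`; `NA` when missing),
#'   `total_depression`, `total_anxiety`, and `flags` (`;`-separated).
#' @export
#' @examples
#' score_rat(list(weight = 345, sucrose_pct = 97, distance_m = 22, rearing = 25,
#'                id_pct = 35, it_pct = 35, ot_pct = 35, oe_pct = 50))
score_rat <- function(indices, rat_id = "rat",
                      weight_conflict = c("table", "prose"),
                      oe_policy = c("zero", "missing"),
                      scales = builtin_scales()) {
  weight_conflict <- match.arg(weight_conflict)
  oe_policy <- match.arg(oe_policy)
  needed <- c("weight", "sucrose_pct", "distance_m", "rearing",
              "id_pct", "it_pct", "ot_pct", "oe_pct")
  indices <- as.list(indices)
  missing_fields <- setdiff(needed, names(indices))
  if (length(missing_fields))
    abort_validation(paste("score_rat: missing indices:", paste(missing_fields, collapse = ", ")))
  vals <- lapply(indices[needed], function(v) if (is.null(v)) NA_real_ else as.numeric(v))
  if (all(is.na(unlist(vals))))
    abort_validation(sprintf("rat '%s': all indices missing, nothing to score", rat_id))

  flags <- character()
  item <- function(nm, f) {
    if (is.na(vals[[nm]])) {
      flags <<- c(flags, paste0("missing_", nm))
      NA_integer_
    } else f(vals[[nm]])
  }
  weight_pts  <- item("weight", function(v) score_weight(v, mode = weight_conflict, scales = scales))
  sucrose_pts <- item("sucrose_pct", function(v) score_sucrose(v, scales = scales))
  distance_pts <- item("distance_m", function(v) score_distance(v, scales = scales))
  rearing_pts <- item("rearing", function(v) score_rearing(v, scales = scales))
  id_pts <- item("id_pct", function(v) score_anxiety_pct(v, "ID", scales = scales))
  it_pts <- item("it_pct", function(v) score_anxiety_pct(v, "IT", scales = scales))
  ot_pts <- item("ot_pct", function(v) score_anxiety_pct(v, "OT", scales = scales))
  oe_pts <- if (is.na(vals$oe_pct)) {
    if (oe_policy == "zero") { flags <- c(flags, "oe_scored_zero_no_entries"); 0L }
    else { flags <- c(flags, "missing_oe_pct"); NA_integer_ }
  } else score_oe(vals$oe_pct, scales = scales)

  data.frame(
    rat_id = rat_id,
    weight_pts = weight_pts, sucrose_pts = sucrose_pts,
    distance_pts = distance_pts, rearing_pts = rearing_pts,
    id_pts = id_pts, it_pts = it_pts, ot_pts = ot_pts, oe_pts = oe_pts,
    total_depression = sum(c(weight_pts, sucrose_pts, distance_pts, rearing_pts), na.rm = TRUE),
    total_anxiety = sum(c(id_pts, it_pts, ot_pts, oe_pts), na.rm = TRUE),
    flags = paste(flags, collapse = ";"),
    stringsAsFactors = FALSE)
}
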