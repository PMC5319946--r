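#' Interval scoring tables
#'
#' A `scale_table` is an ordered list of scoring intervals mapping a raw
#' behavioural index (weight in g, sucrose preference in %, travel distance
#' in m, rearing count, or one of the four anxiety percentages) to integer
#' points.  Bins follow the tables' "a <= < b" convention: lower-closed,
#' upper-open, except the degenerate `[0, 0]` singleton that gives 0 points
#' for zero distance / zero rearing.  Bins must partition the declared
#' domain with no gaps or overlaps; [validate_scale()] checks this and, when
#' given an arithmetic rule, reports every place where table and rule
#' disagree.
#'
#' @param index name of the behavioural index (e.g. `"weight"`, `"oe"`).
#' @param bins data.frame with columns `lower`, `upper`, `lo_closed`,
#'   `hi_closed`, `points`.
#' @param max_points declared item maximum; defaults to `max(bins$points)`.
#' @return an object of class `scale_table` (a data.frame of bins with
#'   attributes `index` and `max_points`).
#' @export
scale_table <- function(index, bins, max_points = max(bins$points)) {
  needed <- c("lower", "upper", "lo_closed", "hi_closed", "points")
  if (!is.data.frame(bins) || !all(needed %in% names(bins)))
    abort_validation(sprintf("scale '%s': bins need columns %s", index,
                             paste(needed, collapse = ", ")))
  bins <- bins[order(bins$lower, bins$upper), needed, drop = FALSE]
  rownames(bins) <- NULL
  if (any(!is.finite(bins$lower)))
    abort_validation(sprintf("scale '%s': lower bounds must be finite", index))
  if (any(bins$upper < bins$lower))
    abort_validation(sprintf("scale '%s': upper < lower in some bin", index))
  if (any(bins$points < 0) || any(bins$points != floor(bins$points)))
    abort_validation(sprintf("scale '%s': points must be non-negative integers", index))
  deg <- bins$upper == bins$lower
  if (any(deg & !(bins$lo_closed & bins$hi_closed)))
    abort_validation(sprintf("scale '%s': degenerate bins must be closed on both sides", index))
  structure(bins, class = c("scale_table", "data.frame"),
            index = index, max_points = as.integer(max_points))
}

#' @export
print.scale_table <- function(x, ...) {
  cat(sprintf("<scale_table '%s'; %d bins; max %d points>\n",
              attr(x, "index"), nrow(x), attr(x, "max_points")))
  lo <- ifelse(x$lo_closed, "[", "(")
  hi <- ifelse(x$hi_closed, "]", ")")
  cat(sprintf("  %s%g, %g%s -> %d", lo, x$lower, x$upper, hi, x$points), sep = "\n")
  invisible(x)
}

#' Look up scale points for raw index values
#'
#' Pure interval lookup honouring each bin's closure flags.  Raw values are
#' **not** rounded before binning: a 94.999% sucrose preference scores 9,
#' not 10.
#'
#' @param table a [scale_table()].
#' @param x numeric vector of raw values.
#' @return integer vector of points.
#' @export
scale_points <- function(table, x) {
  stopifnot(inherits(table, "scale_table"))
  if (any(is.na(x)))
    abort_validation(sprintf("scale '%s': NA raw values cannot be scored", attr(table, "index")))
  out <- rep(NA_integer_, length(x))
  for (b in seq_len(nrow(table))) {
    lo_ok <- if (table$lo_closed[b]) x >= table$lower[b] else x > table$lower[b]
    hi_ok <- if (table$hi_closed[b]) x <= table$upper[b] else x < table$upper[b]
    sel <- lo_ok & hi_ok & is.na(out)
    out[sel] <- as.integer(table$points[b])
  }
  if (anyNA(out))
    abort_validation(sprintf("scale '%s': value(s) %s outside the scale domain",
                             attr(table, "index"),
                             paste(format(x[is.na(out)]), collapse = ", ")))
  out
}

scale_file_columns <- c("index", "lower", "upper", "lo_closed", "hi_closed", "points")

#' Read scale tables from a delimited text file
#'
#' Expects the exact header `index,lower,upper,lo_closed,hi_closed,points`;
#' `Inf` denotes an unbounded upper edge.  Every table read is structurally
#' validated with [validate_scale()]; a gap or overlap is surfaced at load
#' time as a validation error.
#'
#' @param path CSV file path.
#' @return named list of [scale_table()] objects.
#' @export
read_scale_tables <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("scale file '%s' does not exist", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), scale_file_columns))
    abort_io(sprintf("scale file '%s': header must be exactly '%s'",
                     path, paste(scale_file_columns, collapse = ",")))
  tables <- lapply(split(df, factor(df$index, levels = unique(df$index))),
                   function(d) scale_table(d$index[1], d[-1]))
  for (tb in tables) {
    v <- validate_scale(tb)
    if (!v$ok)
      abort_validation(sprintf("scale file '%s', index '%s': %s",
                               path, attr(tb, "index"),
                               paste(v$problems, collapse = "; ")))
  }
  tables
}

#' @rdname read_scale_tables
#' @param tables named list of scale tables.
#' @export
write_scale_tables <- function(tables, path) {
  rows <- do.call(rbind, lapply(tables, function(tb) {
    cbind(index = attr(tb, "index"), as.data.frame(tb))
  }))
  rownames(rows) <- NULL
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Built-in depression and anxiety scale tables
#'
#' Loads the scoring tables shipped with the package: the depression scale
#' (weight 0-5, sucrose preference 0-10, travel distance 0-5, rearing 0-5;
#' total 0-25) and the anxiety scale (ID%, IT%, OT%, OE%, each 0-7; total
#' 0-28).  The tables live as editable CSV files under
#' `system.file("extdata/scales", package = "affectscales")` so users can
#' run the validator on modified scales.
#'
#' @return named list of eight [scale_table()] objects
#'   (`weight`, `sucrose`, `distance`, `rearing`, `id`, `it`, `ot`, `oe`).
#' @export
builtin_scales <- function() {
  if (!is.null(the_cache$scales)) return(the_cache$scales)
  dir <- system.file("extdata", "scales", package = "affectscales")
  tabs <- c(read_scale_tables(file.path(dir, "depression_scale.csv")),
            read_scale_tables(file.path(dir, "anxiety_scale.csv")))
  maxima <- c(weight = 5L, sucrose = 10L, distance = 5L, rearing = 5L,
              id = 7L, it = 7L, ot = 7L, oe = 7L)
  for (nm in names(tabs)) attr(tabs[[nm]], "max_points") <- maxima[[nm]]
  the_cache$scales <- tabs
  tabs
}

#' Arithmetic restatements of the scale rules
#'
#' The scale prose also states each item as an arithmetic rule ("each 5%
#' increase was 1 point", and so on).  These closures are the normalised
#' rules (strict ">" at a full-score edge normalised to ">=", keeping the
#' partition gap-free) plus two *strict prose* variants that deliberately
#' preserve the prose where it contradicts the printed tables:
#' `weight_prose` assigns 0 (not 1) below 300 g and at/above 390 g, and
#' `oe_strict_increment` applies "+1 point per 5%" from the 1% floor,
#' which cannot generate the printed flat `[1, 20) -> 1` band.
#' [validate_scale()] uses them to report, not repair, the discrepancies.
#'
#' @return named list of vectorised functions raw value -> points.
#' @export
scale_rules <- function() {
  weight_table <- function(x) {
    ifelse(x < 300, 1,
    ifelse(x < 330, 2 + floor((x - 300) / 10),
    ifelse(x < 360, 5,
    ifelse(x < 390, 4 - floor((x - 360) / 10), 1))))
  }
  list(
    weight = weight_table,
    weight_prose = function(x) ifelse(x < 300 | x >= 390, 0, weight_table(x)),
    sucrose = function(x) ifelse(x < 50, 0, ifelse(x >= 95, 10, 1 + floor((x - 50) / 5))),
    distance = function(x) ifelse(x == 0, 0, ifelse(x >= 20, 5, 1 + floor(x / 5))),
    rearing = function(x) ifelse(x == 0, 0, ifelse(x >= 20, 5, 1 + floor(x / 5))),
    id = function(x) ifelse(x < 1, 0, ifelse(x >= 30, 7, pmax(1, 1 + floor(x / 5)))),
    it = function(x) ifelse(x < 1, 0, ifelse(x >= 30, 7, pmax(1, 1 + floor(x / 5)))),
    ot = function(x) ifelse(x < 1, 0, ifelse(x >= 30, 7, pmax(1, 1 + floor(x / 5)))),
    oe = function(x) ifelse(x < 1, 0, ifelse(x < 20, 1, ifelse(x >= 45, 7, 2 + floor((x - 20) / 5)))),
    oe_strict_increment = function(x) ifelse(x < 1, 0, pmin(7, 1 + floor((x - 1) / 5)))
  )
}

#' Validate a scale table's structure and, optionally, an arithmetic rule
#'
#' Structural checks: bins sorted, pairwise disjoint, covering the domain
#' with no gaps (consecutive bins must share an edge with exactly one side
#' closed), and the declared maximum attained by some bin.  If `rule` is
#' supplied, the table is additionally evaluated against the rule on a
#' dense grid and every disagreement region is reported.  Known
#' text-vs-table conflicts are *reported*, never silently fixed.
#'
#' @param table a [scale_table()].
#' @param rule optional vectorised function raw value -> points.
#' @param grid_step grid resolution for the rule comparison (default 0.01).
#' @param grid_max substitute upper edge when the top bin is unbounded.
#' @return an object of class `scale_validation`: list with elements `index`,
#'   `ok` (structure valid), `problems` (character), `max_attained`, and
#'   `discrepancies` (data.frame `from`, `to`, `table_points`, `rule_points`,
#'   one row per maximal disagreement region; empty if none or no rule).
#' @export
validate_scale <- function(table, rule = NULL, grid_step = 0.01, grid_max = NULL) {
  stopifnot(inherits(table, "scale_table"))
  problems <- character()
  n <- nrow(table)
  if (n == 0L) problems <- c(problems, "table has no bins")
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      hi <- table$upper[i]; lo <- table$lower[i + 1L]
      if (hi < lo) {
        problems <- c(problems, sprintf("gap between bins %d and %d: (%g, %g) uncovered", i, i + 1L, hi, lo))
      } else if (hi > lo) {
        problems <- c(problems, sprintf("bins %d and %d overlap on (%g, %g)", i, i + 1L, lo, min(hi, table$upper[i + 1L])))
      } else {
        ncl <- table$hi_closed[i] + table$lo_closed[i + 1L]
        if (ncl == 0L) problems <- c(problems, sprintf("gap at the single point %g (both bins open)", hi))
        if (ncl == 2L) problems <- c(problems, sprintf("bins %d and %d both claim the point %g", i, i + 1L, hi))
      }
    }
  }
  max_attained <- n > 0L && max(table$points) == attr(table, "max_points")
  if (!max_attained)
    problems <- c(problems, sprintf("declared maximum %d not attained (best bin gives %d)",
                                    attr(table, "max_points"), if (n) max(table$points) else NA_integer_))
  disc <- data.frame(from = numeric(), to = numeric(),
                     table_points = integer(), rule_points = integer())
  if (length(problems) == 0L && !is.null(rule)) {
    lo <- min(table$lower)
    hi <- max(table$upper[is.finite(table$upper)], table$lower)
    hi <- grid_max %||% (hi + 10)
    grid <- seq(lo, hi, by = grid_step)
    tp <- scale_points(table, grid)
    rp <- as.integer(rule(grid))
    differ <- tp != rp
    if (any(differ)) {
      r <- rle(differ)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        disc <- rbind(disc, data.frame(
          from = grid[starts[k]], to = grid[ends[k]],
          table_points = tp[starts[k]], rule_points = rp[starts[k]]))
      }
    }
  }
  structure(list(index = attr(table, "index"), ok = length(problems) == 0L,
                 problems = problems, max_attained = max_attained,
                 discrepancies = disc),
            class = "scale_validation")
}

#' @export
print.scale_validation <- function(x, ...) {
  cat(sprintf("Scale '%s': structure %s\n", x$index, if (x$ok) "OK" else "INVALID"))
  for (p in x$problems) cat("  problem:", p, "\n")
  if (nrow(x$discrepancies)) {
    cat("  table-vs-rule discrepancies:\n")
    with(x$discrepancies,
         cat(sprintf("    [%g, %g]: table %d vs rule %d", from, to, table_points, rule_points),
             sep = "\n"))
  } else if (x$ok) cat("  no rule discrepancies reported\n")
  invisible(x)
}

#' Validate every built-in scale and report the documented prose conflicts
#'
#' Runs [validate_scale()] on all eight built-in tables against their
#' normalised arithmetic rules (expected: full agreement), then against the
#' strict prose variants for the two documented conflicts: the weight item
#' (prose scores 0 below 300 g and at/above 390 g where the table prints 1)
#' and the OE% item (a literal "+1 point per 5%" increment contradicts the
#' printed flat 1-20% band).
#'
#' @return list with `structural` (per-index [validate_scale()] results
#'   against the normalised rules) and `conflicts` (data.frame of reported
#'   text-vs-table disagreement regions with an `item` column).
#' @export
validate_builtin_scales <- function() {
  tabs <- builtin_scales()
  rules <- scale_rules()
  structural <- lapply(names(tabs), function(nm)
    validate_scale(tabs[[nm]], rules[[nm]], grid_step = 0.05))
  names(structural) <- names(tabs)
  conflict_checks <- list(
    weight = validate_scale(tabs$weight, rules$weight_prose, grid_step = 0.05),
    oe = validate_scale(tabs$oe, rules$oe_strict_increment, grid_step = 0.05))
  conflicts <- do.call(rbind, lapply(names(conflict_checks), function(nm) {
    d <- conflict_checks[[nm]]$discrepancies
    if (nrow(d)) cbind(item = nm, d) else NULL
  }))
  list(structural = structural,
       conflicts = conflicts %||% data.frame(item = character(), from = numeric(),
                                             to = numeric(), table_points = integer(),
                                             rule_points = integer()))
}
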