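#' Run configuration
#'
#' Assembles and validates the options driving [run_pipeline()].  In
#' simulate mode the `design` block parameterises [cohort_design()]; in
#' files mode `paths$input_dir` must contain the layout written by
#' [write_cohort()].  All defaults are echoed into the output directory
#' for provenance.
#'
#' @param mode `"simulate"` or `"files"`.
#' @param seed master seed (simulate mode).
#' @param alpha significance level in (0, 1).
#' @param t_variant `"pooled"` or `"welch"` (reserved for two-group runs).
#' @param weight_conflict `"table"` or `"prose"` (see [score_weight()]).
#' @param oe_policy `"zero"` or `"missing"` (see [score_rat()]).
#' @param design list of [cohort_design()] arguments (simulate mode).
#' @param paths list with `input_dir` (files mode) and/or `output_dir`.
#' @param scales optional character vector of scale-table CSV paths
#'   replacing the built-in tables (validated at load).
#' @param debounce minimum arm dwell for EPM entry counting, s.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "files"), seed = 1, alpha = 0.05,
                       t_variant = c("pooled", "welch"),
                       weight_conflict = c("table", "prose"),
                       oe_policy = c("zero", "missing"),
                       design = list(), paths = list(), scales = NULL,
                       debounce = 0.5) {
  mode <- match.arg(mode)
  check_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  cfg <- list(mode = mode, seed = as.integer(seed), alpha = alpha,
              t_variant = match.arg(t_variant),
              weight_conflict = match.arg(weight_conflict),
              oe_policy = match.arg(oe_policy),
              design = design, paths = paths, scales = scales,
              debounce = debounce)
  if (mode == "files") {
    if (is.null(paths$input_dir)) abort_validation("files mode needs paths$input_dir")
    if (!dir.exists(paths$input_dir))
      abort_io(sprintf("input directory '%s' does not exist", paths$input_dir))
  }
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path JSON config file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("config file '%s' does not exist", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

#' Analyse a cohort: indices, metrics, scores, statistics
#'
#' The computational core of the pipeline, operating in memory.  For each
#' rat it computes the day-21 behavioural indices (weight, sucrose
#' preference from the drinking masses, the von Frey 50% threshold, and
#' the open-field / EPM trajectory metrics — or, on a trajectory-free
#' cohort, the generator's drawn endpoint targets), scores them into a
#' depression and an anxiety score card, runs per-endpoint one-way ANOVA
#' with SNK post-hoc comparisons across the groups, and computes the
#' Pearson correlation between the two totals.
#'
#' @param cohort a [simulate_cohort()] or [read_cohort()] result.
#' @param config a [run_config()].
#' @return list of class `run_report`: `indices` (per-rat day-21 index
#'   table), `scorecards`, `comparisons` (per-endpoint [compare_groups()]
#'   results), `comparison_table`, `snk_is_vs_con` (named logical),
#'   `correlation`, `provenance`.
#' @export
analyse_cohort <- function(cohort, config = run_config()) {
  stopifnot(inherits(cohort, "cohort"))
  rec <- cohort$records
  final_day <- max(rec$day)
  last <- rec[rec$day == final_day, ]

  idx <- lapply(seq_len(nrow(last)), function(i) {
    r <- last[i, ]
    pref <- tryCatch(sucrose_preference(r$sucrose_g, r$water_g),
                     affectscales_no_intake = function(e) NA_real_)
    vf <- cohort$von_frey[[paste(r$rat_id, final_day, sep = "|")]]
    thr <- if (is.null(vf)) NA_real_ else as.numeric(fifty_percent_threshold(vf))
    if (length(cohort$trajectories) && !is.na(r$of_ref)) {
      om <- of_metrics(cohort$trajectories[[r$of_ref]])
      em <- epm_metrics(cohort$trajectories[[r$epm_ref]], debounce = config$debounce)
      met <- c(distance_m = om$total_distance_m, id_pct = om$id_pct,
               it_pct = om$it_pct, ot_pct = em$ot_pct, oe_pct = em$oe_pct)
    } else {
      tg <- cohort$targets[cohort$targets$rat_id == r$rat_id, ]
      if (nrow(tg) == 0)
        abort_io(sprintf("rat '%s': no trajectory and no generator targets", r$rat_id))
      met <- c(distance_m = tg$distance_m, id_pct = tg$id_pct, it_pct = tg$it_pct,
               ot_pct = tg$ot_pct, oe_pct = tg$oe_pct)
    }
    data.frame(rat_id = r$rat_id, group = r$group, weight = r$weight_g,
               sucrose_pct = pref, distance_m = unname(met["distance_m"]),
               rearing = r$rearing_count, id_pct = unname(met["id_pct"]),
               it_pct = unname(met["it_pct"]), ot_pct = unname(met["ot_pct"]),
               oe_pct = unname(met["oe_pct"]), threshold_g = thr,
               stringsAsFactors = FALSE)
  })
  indices <- do.call(rbind, idx)

  tabs <- if (is.null(config$scales)) builtin_scales()
          else do.call(c, lapply(config$scales, read_scale_tables))
  cards <- do.call(rbind, lapply(seq_len(nrow(indices)), function(i) {
    r <- indices[i, ]
    card <- score_rat(r[c("weight", "sucrose_pct", "distance_m", "rearing",
                          "id_pct", "it_pct", "ot_pct", "oe_pct")],
                      rat_id = r$rat_id, weight_conflict = config$weight_conflict,
                      oe_policy = config$oe_policy, scales = tabs)
    card$group <- r$group
    card
  }))

  endpoints <- c("weight", "sucrose_pct", "distance_m", "rearing",
                 "id_pct", "it_pct", "ot_pct", "oe_pct", "threshold_g")
  comparisons <- lapply(endpoints, function(e)
    compare_groups(indices[[e]], indices$group, endpoint = e, alpha = config$alpha))
  names(comparisons) <- endpoints
  comparison_table <- do.call(rbind, lapply(comparisons, `[[`, "summary"))
  rownames(comparison_table) <- NULL

  snk_is_vs_con <- vapply(comparisons, function(cp) {
    dn <- dimnames(cp$snk$decisions)[[1]]
    if (all(c("IS", "CON") %in% dn)) cp$snk$decisions["IS", "CON"] else NA
  }, logical(1))

  structure(list(indices = indices, scorecards = cards,
                 comparisons = comparisons, comparison_table = comparison_table,
                 snk_is_vs_con = snk_is_vs_con,
                 correlation = depression_anxiety_correlation(cards),
                 provenance = list(config = unclass(config),
                                   package_version = as.character(utils::packageVersion("affectscales")))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Run report:", nrow(x$indices), "rats\n")
  ct <- x$comparison_table
  for (e in unique(ct$endpoint)) {
    d <- ct[ct$endpoint == e, ]
    cat(sprintf("  %-12s F = %6.2f, p = %.4g %s\n", e, d$F[1], d$p[1], d$stars[1]))
  }
  cat(sprintf("  depression-anxiety correlation: r = %.3f (n = %d, p = %.4g)\n",
              x$correlation$r, x$correlation$n, x$correlation$p))
  invisible(x)
}

#' Run the full pipeline
#'
#' simulate (or load) -> indices -> trajectory metrics -> score -> group
#' statistics -> report.  With an `output_dir` the per-rat indices table,
#' score cards, group comparison table, correlation, human-readable report
#' and the config echo (with an md5 hash covering the configuration) are
#' written as plain text; in simulate mode the raw cohort files are
#' written too.  Idempotent: identical inputs give identical outputs.
#'
#' @param config a [run_config()] or path to a JSON config file.
#' @return a `run_report` (see [analyse_cohort()]), invisibly when writing.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cohort <- if (config$mode == "simulate") {
    dargs <- config$design
    dargs$seed <- dargs$seed %||% config$seed
    simulate_cohort(do.call(cohort_design, dargs))
  } else {
    read_cohort(config$paths$input_dir)
  }
  report <- analyse_cohort(cohort, config)

  out <- config$paths$output_dir
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    if (config$mode == "simulate") write_cohort(cohort, file.path(out, "cohort"))
    write.csv(report$indices, file.path(out, "indices.csv"), row.names = FALSE, quote = FALSE)
    write_scorecards(report$scorecards, file.path(out, "scorecards.csv"))
    write.csv(report$comparison_table, file.path(out, "group_comparisons.csv"),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(report$correlation, file.path(out, "correlation.json"),
                         auto_unbox = TRUE, digits = NA)
    cfg_path <- file.path(out, "config_echo.json")
    jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
    hash <- unname(tools::md5sum(cfg_path))
    report$provenance$config_hash <- hash
    writeLines(format_report(report, hash), file.path(out, "report.txt"))
  }
  report
}

format_report <- function(report, hash = NA_character_) {
  ct <- report$comparison_table
  lines <- c("Group comparison report",
             sprintf("config hash: %s", hash),
             sprintf("rats: %d; alpha = %g", nrow(report$indices),
                     report$provenance$config$alpha),
             "NOTE: weekly endpoints are compared without cross-week multiplicity correction.",
             "")
  for (e in unique(ct$endpoint)) {
    d <- ct[ct$endpoint == e, ]
    lines <- c(lines, sprintf("%s: F(%d) = %.3f, p = %.4g %s",
                              e, nrow(d) - 1L, d$F[1], d$p[1], d$stars[1]))
    cmp <- report$comparisons[[e]]$snk$detail
    cmp <- cmp[!cmp$blocked & cmp$significant, , drop = FALSE]
    if (nrow(cmp))
      lines <- c(lines, sprintf("  SNK: %s vs %s, q = %.2f (crit %.2f) %s",
                                cmp$group1, cmp$group2, cmp$q, cmp$q_crit, p_stars(cmp$p)))
  }
  c(lines, "", sprintf("depression vs anxiety: r = %.3f, n = %d, p = %.4g %s",
                       report$correlation$r, report$correlation$n,
                       report$correlation$p, p_stars(report$correlation$p)))
}
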