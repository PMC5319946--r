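#' One-way analysis of variance
#'
#' Classical between/within sum-of-squares decomposition with the p value
#' from the F distribution.  Degenerate inputs are handled explicitly:
#' zero variance everywhere with equal means gives `F = 0, p = 1`; zero
#' within-group variance with unequal means gives `F = Inf, p = 0`.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `F`, `p`, `df_between`, `df_within`, `ms_within` and
#'   `group_stats` (data.frame `group`, `n`, `mean`, `se`).
#' @export
one_way_anova <- function(groups) {
  groups <- check_groups(groups)
  k <- length(groups)
  ns <- lengths(groups)
  means <- vapply(groups, mean, 0)
  grand <- sum(unlist(groups)) / sum(ns)
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum(vapply(seq_len(k), function(i) sum((groups[[i]] - means[i])^2), 0))
  df_b <- k - 1L
  df_w <- sum(ns) - k
  if (ss_w == 0) {
    if (ss_b == 0) { Fv <- 0; p <- 1 } else { Fv <- Inf; p <- 0 }
  } else {
    Fv <- (ss_b / df_b) / (ss_w / df_w)
    p <- pf(Fv, df_b, df_w, lower.tail = FALSE)
  }
  list(F = Fv, p = p, df_between = df_b, df_within = df_w,
       ms_within = ss_w / df_w,
       group_stats = data.frame(group = names(groups), n = as.integer(ns),
                                mean = unname(means),
                                se = vapply(groups, function(x) sd(x) / sqrt(length(x)), 0),
                                stringsAsFactors = FALSE))
}

check_groups <- function(groups, min_groups = 2L) {
  if (!is.list(groups) || length(groups) < min_groups)
    abort_validation(sprintf("need at least %d groups", min_groups))
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  for (nm in names(groups)) {
    x <- groups[[nm]]
    if (!is.numeric(x) || length(x) < 2L || any(!is.finite(x)))
      abort_validation(sprintf("group '%s' needs >= 2 finite numeric values", nm))
  }
  groups
}

#' Student-Newman-Keuls post-hoc test
#'
#' Step-down multiple comparisons on ranked group means using
#' studentized-range critical values: a pair spanning `p` ranks in the
#' ordered means is tested against `qtukey(1 - alpha, p, df_within)`, and
#' every pair inside a non-significant span is blocked (declared not
#' different without testing).  Unbalanced groups use the harmonic mean of
#' the two sample sizes in the standard error.  Tied means are ordered
#' stably by group name.  Quantiles come from R's `ptukey`/`qtukey`, not
#' printed tables.
#'
#' @param groups named list of numeric vectors.
#' @param alpha family significance level.
#' @return list with `decisions` (symmetric logical matrix, `TRUE` =
#'   significantly different), `detail` (one row per tested or blocked
#'   pair: `group1`, `group2`, `span`, `q`, `q_crit`, `p`, `significant`,
#'   `blocked`), `alpha`, and the underlying `anova` result.
#' @export
snk_posthoc <- function(groups, alpha = 0.05) {
  check_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  groups <- check_groups(groups)
  av <- one_way_anova(groups)
  k <- length(groups)
  ord <- order(vapply(groups, mean, 0), names(groups))
  means <- vapply(groups, mean, 0)[ord]
  ns <- lengths(groups)[ord]
  nm <- names(groups)[ord]
  msw <- av$ms_within
  decisions <- matrix(FALSE, k, k, dimnames = list(nm, nm))
  blocked <- matrix(FALSE, k, k)
  detail <- list()
  for (span in k:2) {
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      if (blocked[i, j]) next
      nh <- 2 / (1 / ns[i] + 1 / ns[j])
      se <- sqrt(msw / nh)
      qv <- if (se == 0) { if (means[j] - means[i] == 0) 0 else Inf } else (means[j] - means[i]) / se
      crit <- qtukey(1 - alpha, span, av$df_within)
      pv <- if (is.infinite(qv)) 0 else ptukey(qv, span, av$df_within, lower.tail = FALSE)
      sig <- qv > crit
      detail[[length(detail) + 1L]] <- data.frame(
        group1 = nm[i], group2 = nm[j], span = span, q = qv, q_crit = crit,
        p = pv, significant = sig, blocked = FALSE, stringsAsFactors = FALSE)
      if (sig) {
        decisions[i, j] <- decisions[j, i] <- TRUE
      } else {
        for (a in i:j) for (b in i:j) if (a < b && !(a == i && b == j)) {
          if (!blocked[a, b]) {
            blocked[a, b] <- TRUE
            detail[[length(detail) + 1L]] <- data.frame(
              group1 = nm[a], group2 = nm[b], span = b - a + 1L, q = NA_real_,
              q_crit = NA_real_, p = NA_real_, significant = FALSE,
              blocked = TRUE, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  detail <- do.call(rbind, detail)
  orig <- names(groups)
  list(decisions = decisions[orig, orig, drop = FALSE], detail = detail,
       alpha = alpha, anova = av)
}

#' Two-group Student's t-test
#'
#' Pooled-variance two-sided test by default (the era's convention when no
#' assumption is stated); `var_equal = FALSE` gives the Welch variant and
#' `paired = TRUE` the paired test.  Zero pooled variance with equal means
#' gives `t = 0, p = 1`.
#'
#' @param x,y numeric vectors (n >= 2 each).
#' @param paired paired test (requires equal lengths).
#' @param var_equal pool the variances (default `TRUE`).
#' @return list with `t`, `p`, `df`.
#' @export
two_group_t <- function(x, y, paired = FALSE, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L || any(!is.finite(c(x, y))))
    abort_validation("both samples need >= 2 finite values")
  if (paired) {
    if (length(x) != length(y)) abort_validation("paired test needs equal lengths")
    d <- x - y
    n <- length(d)
    sdd <- sd(d)
    if (sdd == 0) return(list(t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                              p = if (mean(d) == 0) 1 else 0, df = n - 1))
    tv <- mean(d) / (sdd / sqrt(n))
    return(list(t = tv, p = 2 * pt(abs(tv), n - 1, lower.tail = FALSE), df = n - 1))
  }
  nx <- length(x); ny <- length(y)
  if (var_equal) {
    sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
    df <- nx + ny - 2
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
  } else {
    vx <- stats::var(x) / nx; vy <- stats::var(y) / ny
    se <- sqrt(vx + vy)
    df <- if (vx + vy == 0) nx + ny - 2 else (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  }
  dm <- mean(x) - mean(y)
  if (se == 0) return(list(t = if (dm == 0) 0 else Inf * sign(dm),
                           p = if (dm == 0) 1 else 0, df = df))
  tv <- dm / se
  list(t = tv, p = 2 * pt(abs(tv), df, lower.tail = FALSE), df = df)
}

#' Correlation between total depression and total anxiety scores
#'
#' Pearson correlation over complete score cards, with the p value from
#' the t transform `t = r * sqrt((n - 2) / (1 - r^2))`.  Zero variance in
#' either total makes r undefined; it is returned as `NA` with a flag.
#'
#' @param scorecards data.frame with `total_depression` and
#'   `total_anxiety` columns (one row per rat; >= 3 complete rows).
#' @return list with `r`, `p`, `n`, `flags`.
#' @export
depression_anxiety_correlation <- function(scorecards) {
  if (!all(c("total_depression", "total_anxiety") %in% names(scorecards)))
    abort_validation("scorecards need total_depression and total_anxiety columns")
  ok <- complete.cases(scorecards[c("total_depression", "total_anxiety")])
  d <- scorecards[ok, ]
  n <- nrow(d)
  if (n < 3L) abort_validation("need >= 3 complete score cards for a correlation")
  if (sd(d$total_depression) == 0 || sd(d$total_anxiety) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, flags = "zero_variance"))
  r <- cor(d$total_depression, d$total_anxiety)
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n, flags = character()))
  tv <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(abs(tv), n - 2, lower.tail = FALSE), n = n, flags = character())
}

#' Group comparison table for one endpoint
#'
#' Convenience wrapper running [one_way_anova()] plus [snk_posthoc()] on a
#' per-rat endpoint column and formatting the figure-legend style output
#' (significance stars at 0.05 / 0.01 / 0.001).
#'
#' @param values numeric endpoint per rat.
#' @param group group label per rat.
#' @param endpoint endpoint name carried into the output.
#' @param alpha significance level for the SNK decisions.
#' @return list with `endpoint`, `anova`, `snk`, and `summary` (data.frame
#'   of per-group n / mean / se plus the ANOVA F, p and stars).
#' @export
compare_groups <- function(values, group, endpoint = "endpoint", alpha = 0.05) {
  ok <- is.finite(values)
  groups <- split(values[ok], group[ok])
  av <- one_way_anova(groups)
  snk <- snk_posthoc(groups, alpha = alpha)
  list(endpoint = endpoint, anova = av, snk = snk,
       summary = cbind(endpoint = endpoint, av$group_stats,
                       F = av$F, p = av$p, stars = p_stars(av$p)))
}
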