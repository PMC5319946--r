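test_that("one-way ANOVA matches hand arithmetic and handles degeneracies", {
  # hand-computed 3x3 example: means 2, 3, 5; SSB = 14 (df 2), SSW = 6 (df 6)
  # => F = 7 / 1 = 7
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(4, 5, 6))
  av <- one_way_anova(g)
  expect_equal(av$F, 7)
  expect_equal(av$p, pf(7, 2, 6, lower.tail = FALSE))
  # identical values everywhere
  same <- list(a = c(2, 2), b = c(2, 2))
  expect_equal(one_way_anova(same)$F, 0)
  expect_equal(one_way_anova(same)$p, 1)
  # zero within-variance, unequal means
  det <- list(a = c(1, 1), b = c(2, 2))
  expect_equal(one_way_anova(det)$F, Inf)
  expect_equal(one_way_anova(det)$p, 0)
  expect_error(one_way_anova(list(a = 1:3)), class = "affectscales_validation")
  expect_error(one_way_anova(list(a = 1, b = 1:3)), class = "affectscales_validation")
})

test_that("ANOVA agrees with the base-R oracle on random unbalanced data", {
  set.seed(8)
  for (i in 1:10) {
    g <- list(a = rnorm(sample(3:12, 1)), b = rnorm(sample(3:12, 1), 0.5),
              c = rnorm(sample(3:12, 1)))
    av <- one_way_anova(g)
    or <- stats::oneway.test(v ~ grp,
                             data.frame(v = unlist(g),
                                        grp = rep(names(g), lengths(g))),
                             var.equal = TRUE)
    expect_equal(av$F, unname(or$statistic), tolerance = 1e-10)
    expect_equal(av$p, unname(or$p.value), tolerance = 1e-10)
  }
  expect_equal(one_way_anova(g)$F, one_way_anova(rev(g))$F)
})

test_that("SNK declares nothing on identical groups and isolates a huge shift", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_false(any(snk_posthoc(same)$decisions))
  set.seed(2)
  g <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10), d = rnorm(10) + 10)
  dec <- snk_posthoc(g)$decisions
  expect_true(all(dec["d", c("a", "b", "c")]))
  expect_false(any(dec[c("a", "b", "c"), c("a", "b", "c")]))
  expect_identical(dec, t(dec))
})

test_that("numerical studentized-range quantiles match published tables", {
  published <- rbind(                   # q_{0.05}(k, df), standard tables
    c(k = 2, df = 10, q = 3.15), c(k = 3, df = 10, q = 3.88),
    c(k = 4, df = 10, q = 4.33), c(k = 6, df = 10, q = 4.91),
    c(k = 2, df = 20, q = 2.95), c(k = 4, df = 20, q = 3.96),
    c(k = 6, df = 20, q = 4.45), c(k = 3, df = 30, q = 3.49),
    c(k = 5, df = 30, q = 4.10), c(k = 6, df = 30, q = 4.30))
  for (r in seq_len(nrow(published)))
    expect_equal(qtukey(0.95, published[r, "k"], published[r, "df"]),
                 unname(published[r, "q"]), tolerance = 0.005)
})

test_that("SNK decisions equal a brute-force tabulated oracle on a fixed dataset", {
  # 4 groups, n = 4 each, df_within = 12; published q_{0.05}(p, 12)
  g <- list(CON = c(9.8, 10.4, 10.1, 9.9), IS = c(7.6, 8.1, 7.9, 8.4),
            IS_AMI = c(9.1, 9.6, 9.4, 8.9), AMI = c(10.0, 10.6, 9.7, 10.3))
  want <- snk_oracle(g, q_crit = c("2" = 3.08, "3" = 3.77, "4" = 4.20))
  got <- snk_posthoc(g)$decisions
  expect_identical(got, want)
  expect_true(got["IS", "CON"])        # sanity: the shifted group is isolated
})

test_that("step-down blocking never exceeds unprotected range-2 pairwise tests", {
  set.seed(13)
  for (i in 1:25) {
    g <- lapply(1:4, function(j) rnorm(6, mean = sample(0:2, 1)))
    names(g) <- letters[1:4]
    snk <- snk_posthoc(g)
    av <- one_way_anova(g)
    q2 <- qtukey(0.95, 2, av$df_within)
    for (a in names(g)) for (b in names(g)) {
      if (a >= b) next
      nh <- 2 / (1 / length(g[[a]]) + 1 / length(g[[b]]))
      q <- abs(mean(g[[a]]) - mean(g[[b]])) / sqrt(av$ms_within / nh)
      if (snk$decisions[a, b]) expect_gt(q, q2)
    }
  }
})

test_that("two-group t matches hand arithmetic and the base-R oracle", {
  # pooled variance 5/3, se = sqrt(5/6), t = -2 / se = -sqrt(4.8)
  out <- two_group_t(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(out$t, -sqrt(4.8))
  expect_equal(out$df, 6)
  eq <- two_group_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  set.seed(21)
  x <- rnorm(12); y <- rnorm(9, 0.4)
  for (ve in c(TRUE, FALSE)) {
    mine <- two_group_t(x, y, var_equal = ve)
    or <- t.test(x, y, var.equal = ve)
    expect_equal(mine$t, unname(or$statistic), tolerance = 1e-10)
    expect_equal(mine$p, unname(or$p.value), tolerance = 1e-10)
  }
  mp <- two_group_t(x[1:9], y, paired = TRUE)
  op <- t.test(x[1:9], y, paired = TRUE)
  expect_equal(mp$t, unname(op$statistic), tolerance = 1e-10)
})

test_that("depression-anxiety correlation handles exact and degenerate cases", {
  col <- data.frame(total_depression = c(5, 10, 15, 20),
                    total_anxiety = c(7, 14, 21, 28))
  expect_equal(depression_anxiety_correlation(col)$r, 1)
  anti <- data.frame(total_depression = c(5, 10, 15), total_anxiety = c(28, 14, 0))
  expect_equal(depression_anxiety_correlation(anti)$r, -1)
  flat <- data.frame(total_depression = c(5, 5, 5), total_anxiety = c(1, 2, 3))
  res <- depression_anxiety_correlation(flat)
  expect_true(is.na(res$r))
  expect_identical(res$flags, "zero_variance")
  expect_error(depression_anxiety_correlation(
    data.frame(total_depression = 1:2, total_anxiety = 1:2)),
    class = "affectscales_validation")
  # base-R oracle
  set.seed(5)
  d <- data.frame(total_depression = rnorm(30), total_anxiety = rnorm(30))
  mine <- depression_anxiety_correlation(d)
  or <- cor.test(d$total_depression, d$total_anxiety)
  expect_equal(mine$r, unname(or$estimate), tolerance = 1e-10)
  expect_equal(mine$p, unname(or$p.value), tolerance = 1e-10)
})

test_that("a shared latent affect factor yields the analytic correlation", {
  # dep = 0.8 z + sqrt(0.36) e1, anx = 0.8 z + sqrt(0.36) e2 => rho = 0.64
  set.seed(9)
  n <- 3000
  z <- rnorm(n)
  d <- data.frame(total_depression = 0.8 * z + sqrt(0.36) * rnorm(n),
                  total_anxiety = 0.8 * z + sqrt(0.36) * rnorm(n))
  res <- depression_anxiety_correlation(d)
  expect_gt(res$r, 0)
  expect_lt(abs(res$r - 0.64), 3 * (1 - 0.64^2) / sqrt(n))
})
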