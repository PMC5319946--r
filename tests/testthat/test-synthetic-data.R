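test_that("simulate_trajectory honours the sampling and containment contracts", {
  a <- of_arena()
  p <- locomotion_profile(8, 1, rearing_rate = 12, dt = 0.1, duration = 300)
  tr <- simulate_trajectory(a, p, seed = 1)
  expect_identical(nrow(tr$samples), 3001L)
  expect_true(all(arena_contains(a, tr$samples$x_cm, tr$samples$y_cm)))
  expect_true(is.numeric(attr(tr, "rearing_count")))
  # determinism
  tr2 <- simulate_trajectory(a, p, seed = 1)
  expect_identical(tr$samples, tr2$samples)
  # realised mean speed within 10% of the profile mean
  v <- path_length(tr) * 100 / 300
  expect_lt(abs(v - 8) / 8, 0.1)
  # EPM variant stays inside the maze
  e <- epm_arena()
  te <- simulate_trajectory(e, locomotion_profile(7, 1), seed = 2)
  expect_true(all(arena_contains(e, te$samples$x_cm, te$samples$y_cm)))
  expect_lt(abs(path_length(te) * 100 / 300 - 7) / 7, 0.1)
})

test_that("the large-bias limit parks the walk in the inner zone", {
  tr <- simulate_trajectory(of_arena(), locomotion_profile(8, 1e8), seed = 3)
  zfrac <- mean(arena_zone(of_arena(), tr$samples$x_cm, tr$samples$y_cm) == "inner")
  expect_gte(zfrac, 0.95)
})

test_that("zero mean speed keeps the animal at a fixed position", {
  tr <- simulate_trajectory(of_arena(), locomotion_profile(0, 1), seed = 4)
  expect_equal(path_length(tr), 0)
  expect_identical(length(unique(tr$samples$x_cm)), 1L)
})

test_that("an unbiased walk spends time near the inner/outer area ratio", {
  # 60/90 cm circles: inner area fraction = (60/90)^2 = 44.4%
  set.seed(10)
  its <- replicate(25, of_metrics(simulate_trajectory(
    of_arena(), locomotion_profile(8, 1)))$it_pct)
  expect_lt(abs(mean(its) - 44.4), 8)
})

test_that("simulate_drinking inverts the preference formula", {
  d <- simulate_drinking(0.5, 10, noise_sd = 0, seed = 1)
  expect_equal(d$sucrose_consumed, d$water_consumed)
  expect_false(d$clamped)
  # Monte-Carlo mean recovery at p = 0.9
  set.seed(2)
  prefs <- replicate(1000, {
    dd <- simulate_drinking(0.9, 15, noise_sd = 0.5)
    dd$sucrose_consumed / (dd$sucrose_consumed + dd$water_consumed)
  })
  expect_lt(abs(mean(prefs) - 0.9), 0.01)
  # clamping keeps masses non-negative and flags the event
  set.seed(3)
  out <- replicate(300, simulate_drinking(0.05, 1, noise_sd = 2), simplify = FALSE)
  expect_true(all(vapply(out, `[[`, 0, "sucrose_consumed") >= 0))
  expect_true(all(vapply(out, `[[`, 0, "water_consumed") >= 0))
  expect_true(any(vapply(out, `[[`, TRUE, "clamped")))
  expect_error(simulate_drinking(1.2, 10), class = "affectscales_validation")
})

test_that("simulate_von_frey implements the logistic responder", {
  # step limit: positive iff force >= threshold
  s <- simulate_von_frey(6, slope = Inf, seed = 1)
  expect_identical(s$responses, s$forces_applied >= 6)
  s2 <- simulate_von_frey(2, slope = Inf, seed = 1)
  expect_true(all(s2$responses))
  # response probability increases with force
  set.seed(4)
  big <- simulate_von_frey(6, n_applications_per_force = 200, slope = 8)
  fr <- tapply(big$responses, big$forces_applied, mean)
  expect_true(all(diff(fr[order(as.numeric(names(fr)))]) >= 0))
  expect_lt(abs(fr[["6"]] - 0.5), 0.12)  # p = 0.5 at the true threshold
})

test_that("composed OF trajectories realise their endpoint targets", {
  for (sd_case in list(c(25, 8, 12), c(12, 3, 12))) {
    tr <- compose_of_trajectory(sd_case[1], sd_case[2], sd_case[3], seed = 11)
    m <- of_metrics(tr)
    expect_lt(abs(m$total_distance_m - sd_case[1]) / sd_case[1], 0.05)
    expect_lt(abs(m$id_pct - sd_case[2]), 2.5)
    expect_lt(abs(m$it_pct - sd_case[3]), 2.5)
  }
  t1 <- compose_of_trajectory(20, 8, 12, seed = 3)
  t2 <- compose_of_trajectory(20, 8, 12, seed = 3)
  expect_identical(t1$samples, t2$samples)
})

test_that("composed EPM trajectories hit their entry and time targets", {
  tr <- compose_epm_trajectory(10, 5, 9, seed = 12)
  m <- epm_metrics(tr)
  expect_identical(m$open_entries, 5L)
  expect_identical(m$closed_entries, 9L)
  expect_lt(abs(m$ot_pct - 10), 1.5)
  none <- compose_epm_trajectory(0, 0, 0, seed = 1)
  expect_true(is.na(epm_metrics(none)$oe_pct))
})

test_that("cohort design validation rejects impossible worlds", {
  expect_error(cohort_design(groups = c(CON = 0)), class = "affectscales_validation")
  expect_error(cohort_design(groups = c(10, 10)), class = "affectscales_validation")
  expect_error(cohort_design(endpoints = list(distance = list(mean = c(CON = 25, IS = 12, IS_AMI = 22, AMI = 25), sd = -1))),
               class = "affectscales_validation")
})

test_that("cohorts are deterministic and substream-stable under design growth", {
  d <- cohort_design(groups = c(CON = 4, IS = 4, IS_AMI = 4, AMI = 4), seed = 5, dt = 0.5)
  c1 <- simulate_cohort(d)
  c2 <- simulate_cohort(d)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$targets, c2$targets)
  expect_identical(c1$trajectories[[1]]$samples, c2$trajectories[[1]]$samples)
  # adding a rat to one group must not perturb the others
  d2 <- cohort_design(groups = c(CON = 5, IS = 4, IS_AMI = 4, AMI = 4), seed = 5, dt = 0.5)
  c3 <- simulate_cohort(d2, trajectories = FALSE)
  shared <- intersect(c1$targets$rat_id, c3$targets$rat_id)
  a <- c1$targets[c1$targets$rat_id %in% shared, ]
  b <- c3$targets[c3$targets$rat_id %in% shared, ]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("zero-sd designs reproduce the group means exactly", {
  ep <- default_endpoints()
  ep$weight[c("base_sd", "gain_sd", "meas_sd")] <- list(0, 0, 0)
  ep$sucrose[c("sd", "intake_sd", "drink_noise_sd")] <- list(0, 0, 0)
  ep$von_frey$sd_log <- 0
  for (e in c("distance", "rearing", "id", "it", "ot", "oe", "entries")) ep[[e]]$sd <- 0
  d <- cohort_design(groups = c(CON = 3, IS = 3, IS_AMI = 3, AMI = 3),
                     seed = 1, endpoints = ep)
  co <- simulate_cohort(d, trajectories = FALSE)
  con <- co$targets[co$targets$group == "CON", ]
  expect_true(all(con$distance_m == 25))
  expect_true(all(con$id_pct == 8))
  expect_true(all(con$it_pct == 12))
  is_g <- co$targets[co$targets$group == "IS", ]
  expect_true(all(is_g$distance_m == 12))
  # weight day 21 = base + gain * 21 exactly
  w21 <- co$records$weight_g[co$records$day == 21]
  expect_true(all(w21 == 290 + 2.4 * 21))
  # recomputed preference equals the configured day-21 truth
  last <- co$records[co$records$day == 21, ]
  pref <- sucrose_preference(last$sucrose_g, last$water_g)
  expect_equal(pref[last$group == "CON"], rep(90, 3))
  expect_equal(pref[last$group == "IS"], rep(70, 3))
})

test_that("the dropout flag reproduces the single IS death", {
  d <- cohort_design(groups = c(CON = 3, IS = 3, IS_AMI = 3, AMI = 3),
                     seed = 2, dropout = TRUE)
  co <- simulate_cohort(d, trajectories = FALSE)
  expect_identical(sum(co$targets$group == "IS"), 2L)
  expect_identical(sum(co$targets$group == "CON"), 3L)
})

test_that("null designs are calibrated: two-group t-test rejects at about alpha", {
  d <- cohort_design(groups = c(CON = 10, IS = 10), days = 1, seed = 1,
                     endpoints = default_endpoints(group_names = c("CON", "IS"),
                                                   null = TRUE))
  rej <- logical(300)
  for (r in seq_len(300)) {
    d$seed <- r
    co <- simulate_cohort(d, trajectories = FALSE)
    last <- co$records[co$records$day == max(co$records$day), ]
    pref <- sucrose_preference(last$sucrose_g, last$water_g)
    rej[r] <- two_group_t(pref[last$group == "CON"], pref[last$group == "IS"])$p < 0.05
  }
  # 3-sigma binomial band around 0.05 at 300 replicates
  expect_gte(mean(rej), 0.05 - 3 * sqrt(0.05 * 0.95 / 300))
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("a fixed-seed default cohort propagates the configured effect pattern", {
  co <- simulate_cohort(cohort_design(seed = 7))
  rep <- analyse_cohort(co)
  flags <- rep$snk_is_vs_con
  expect_true(all(flags[c("sucrose_pct", "distance_m", "rearing", "id_pct", "oe_pct")]))
  expect_false(any(flags[c("weight", "it_pct", "ot_pct")]))
})
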