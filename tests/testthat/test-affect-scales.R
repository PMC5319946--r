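test_that("item scorers reproduce the printed worked values", {
  cases <- list(
    list(function(x) score_weight(x), 345, 5L),       # normal-weight plateau
    list(function(x) score_weight(x), 365, 4L),
    list(function(x) score_weight(x), 295, 1L),       # table value; prose says 0
    list(function(x) score_sucrose(x), 97, 10L),
    list(function(x) score_sucrose(x), 40, 0L),
    list(function(x) score_sucrose(x), 72, 5L),
    list(function(x) score_distance(x), 22, 5L),
    list(function(x) score_distance(x), 0, 0L),
    list(function(x) score_distance(x), 7, 2L),
    list(function(x) score_rearing(x), 25, 5L),
    list(function(x) score_rearing(x), 0, 0L),
    list(function(x) score_rearing(x), 12, 3L),
    list(function(x) score_anxiety_pct(x, "ID"), 35, 7L),
    list(function(x) score_anxiety_pct(x, "IT"), 0.5, 0L),
    list(function(x) score_anxiety_pct(x, "OT"), 12, 3L),
    list(function(x) score_oe(x), 10, 1L),
    list(function(x) score_oe(x), 50, 7L),
    list(function(x) score_oe(x), 42, 6L))
  for (cs in cases) expect_identical(cs[[1]](cs[[2]]), cs[[3]])
})

test_that("bin edges follow the lower-closed convention without pre-rounding", {
  expect_identical(score_sucrose(94.999), 9L)
  expect_identical(score_sucrose(95), 10L)
  expect_identical(score_weight(300), 2L)
  expect_identical(score_weight(329.999), 4L)
  expect_identical(score_weight(330), 5L)
  expect_identical(score_weight(360), 4L)
  expect_identical(score_weight(390), 1L)
  expect_identical(score_distance(0.001), 1L)  # the (0, 5) open-at-zero bin
  expect_identical(score_distance(5), 2L)
  expect_identical(score_oe(1), 1L)
  expect_identical(score_oe(0.999), 0L)
  expect_identical(score_oe(20), 2L)
  expect_identical(score_oe(45), 7L)
  expect_identical(score_anxiety_pct(30, "ID"), 7L)
  expect_identical(score_anxiety_pct(29.999, "ID"), 6L)
})

test_that("prose mode zeroes the weight extremes, table mode does not", {
  expect_identical(score_weight(295, mode = "prose"), 0L)
  expect_identical(score_weight(395, mode = "prose"), 0L)
  expect_identical(score_weight(390, mode = "prose"), 0L)
  expect_identical(score_weight(345, mode = "prose"), 5L)
  expect_identical(score_weight(295, mode = "table"), 1L)
  expect_identical(score_weight(395, mode = "table"), 1L)
})

test_that("scorers are monotone; the weight item is unimodal with a [330,360) plateau", {
  g <- seq(0, 100, by = 0.25)
  expect_true(all(diff(score_sucrose(g)) >= 0))
  expect_true(all(diff(score_anxiety_pct(g, "ID")) >= 0))
  expect_true(all(diff(score_oe(g)) >= 0))
  d <- seq(0, 40, by = 0.25)
  expect_true(all(diff(score_distance(d)) >= 0))
  expect_true(all(diff(score_rearing(0:40)) >= 0))
  w <- seq(200, 450, by = 0.5)
  pts <- score_weight(w)
  expect_true(all(diff(pts[w < 330]) >= 0))
  expect_true(all(diff(pts[w >= 330]) <= 0))
  expect_identical(unique(pts[w >= 330 & w < 360]), 5L)
  expect_true(all(pts[w < 330 | w >= 360] < 5L))
})

test_that("validate_scale accepts the built-ins and flags structural defects", {
  for (tb in builtin_scales()) {
    v <- validate_scale(tb)
    expect_true(v$ok, info = attr(tb, "index"))
    expect_true(v$max_attained, info = attr(tb, "index"))
  }
  overlap <- scale_table("bad", data.frame(
    lower = c(0, 4), upper = c(5, 10),
    lo_closed = TRUE, hi_closed = FALSE, points = c(0L, 1L)))
  expect_match(paste(validate_scale(overlap)$problems, collapse = " "), "overlap")
  gap <- scale_table("gappy", data.frame(
    lower = c(0, 6), upper = c(5, 10),
    lo_closed = TRUE, hi_closed = FALSE, points = c(0L, 1L)))
  expect_match(paste(validate_scale(gap)$problems, collapse = " "), "gap")
})

test_that("table scoring equals the normalised arithmetic rules; conflicts are reported not fixed", {
  rules <- scale_rules()
  tabs <- builtin_scales()
  for (nm in names(tabs)) {
    v <- validate_scale(tabs[[nm]], rules[[nm]], grid_step = 0.05)
    expect_identical(nrow(v$discrepancies), 0L, info = nm)
  }
  v <- validate_builtin_scales()
  w <- v$conflicts[v$conflicts$item == "weight", ]
  expect_identical(nrow(w), 2L)                       # both extremes
  expect_true(any(w$to < 300) && any(w$from >= 390))
  expect_true(all(w$table_points == 1L & w$rule_points == 0L))
  expect_true(any(v$conflicts$item == "oe"))          # strict +1/5% vs flat band
})

test_that("score_rat sums items into the 0-25 and 0-28 totals", {
  full <- score_rat(list(weight = 345, sucrose_pct = 97, distance_m = 22,
                         rearing = 25, id_pct = 35, it_pct = 35,
                         ot_pct = 35, oe_pct = 50))
  expect_identical(full$total_depression, 25L)
  expect_identical(full$total_anxiety, 28L)
  zero <- score_rat(list(weight = 295, sucrose_pct = 40, distance_m = 0,
                         rearing = 0, id_pct = 0.5, it_pct = 0.5,
                         ot_pct = 0.5, oe_pct = 0.5),
                    weight_conflict = "prose")
  expect_identical(zero$total_depression, 0L)
  expect_identical(zero$total_anxiety, 0L)
})

test_that("missing items are excluded from totals and flagged", {
  card <- score_rat(list(weight = NA, sucrose_pct = 97, distance_m = 22,
                         rearing = 25, id_pct = 35, it_pct = 35,
                         ot_pct = 35, oe_pct = 50))
  expect_true(is.na(card$weight_pts))
  expect_identical(card$total_depression, 20L)
  expect_match(card$flags, "missing_weight")

  oe0 <- score_rat(list(weight = 345, sucrose_pct = 97, distance_m = 22,
                        rearing = 25, id_pct = 35, it_pct = 35,
                        ot_pct = 35, oe_pct = NA))
  expect_identical(oe0$oe_pts, 0L)
  expect_match(oe0$flags, "oe_scored_zero_no_entries")
  oem <- score_rat(list(weight = 345, sucrose_pct = 97, distance_m = 22,
                        rearing = 25, id_pct = 35, it_pct = 35,
                        ot_pct = 35, oe_pct = NA), oe_policy = "missing")
  expect_true(is.na(oem$oe_pts))
  expect_identical(oem$total_anxiety, 21L)

  expect_error(score_rat(list(weight = NA, sucrose_pct = NA, distance_m = NA,
                              rearing = NA, id_pct = NA, it_pct = NA,
                              ot_pct = NA, oe_pct = NA)),
               class = "affectscales_validation")
})

test_that("out-of-range raw values are validation errors", {
  expect_error(score_weight(-1), class = "affectscales_validation")
  expect_error(score_sucrose(101), class = "affectscales_validation")
  expect_error(score_distance(-0.1), class = "affectscales_validation")
  expect_error(score_rearing(2.5), class = "affectscales_validation")
  expect_error(score_oe(-5), class = "affectscales_validation")
})

test_that("scale tables round-trip through their file format", {
  tabs <- builtin_scales()
  path <- withr::local_tempfile(fileext = ".csv")
  write_scale_tables(tabs, path)
  back <- read_scale_tables(path)
  expect_setequal(names(back), names(tabs))
  for (nm in names(tabs))
    expect_equal(as.data.frame(back[[nm]]), as.data.frame(tabs[[nm]]))
  grid <- seq(0, 100, by = 0.5)
  expect_identical(scale_points(back$oe, grid), scale_points(tabs$oe, grid))
})
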