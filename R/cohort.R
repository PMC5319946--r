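#' Cohort design for the synthetic generator
#'
#' Describes the four-group, 21-day chronic-migraine experiment the
#' generator emulates: group names and sizes, the day grid, and per-group
#' per-endpoint generative parameters (means, standard deviations, and
#' day trends where applicable).  [default_endpoints()] holds the stated
#' world: the inflammatory-soup (IS) group loses sucrose preference,
#' travel distance, rearing, ID% and OE% (all shifted by at least 1.5
#' within-group sd) and its withdrawal threshold falls to the 2-g floor;
#' weight, IT% and OT% are unaffected; co-administered amitriptyline
#' (IS_AMI) recovers locomotion, ID%, OE% and the threshold but not
#' sucrose preference.
#'
#' @param groups named integer vector of group sizes.
#' @param days length of the day grid (measurements on days `0..days`).
#' @param seed master seed; per-rat per-trial substreams are derived with
#'   [substream_seed()], so adding a rat never perturbs the others.
#' @param endpoints endpoint parameter list; entries override
#'   [default_endpoints()].
#' @param dropout reproduce the one IS-group death (removes the last IS
#'   rat); off by default.
#' @param dt trajectory sampling interval in s.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(groups = c(CON = 10, IS = 10, IS_AMI = 10, AMI = 10),
                          days = 21, seed = 1, endpoints = list(),
                          dropout = FALSE, dt = 0.1) {
  if (length(groups) < 1 || is.null(names(groups)) || any(!nzchar(names(groups))))
    abort_validation("groups must be a named vector of group sizes")
  if (any(groups < 1) || any(groups != floor(groups)))
    abort_validation("every group needs n >= 1 (integer)")
  check_number(days, "days", lower = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  ep <- modifyList(default_endpoints(group_names = names(groups)), endpoints)
  sds <- unlist(lapply(ep, function(e) unlist(e[grepl("sd", names(e))])))
  if (any(sds < 0)) abort_validation("all endpoint sds must be >= 0")
  structure(list(groups = groups, days = days, seed = as.integer(seed),
                 endpoints = ep, dropout = isTRUE(dropout), dt = dt),
            class = "cohort_design")
}

#' @rdname cohort_design
#' @param group_names group labels the per-group parameter vectors are
#'   expanded to (unknown labels fall back to the first / control column).
#' @param null if `TRUE`, every group gets the control parameters (used
#'   for type-I-error calibration).
#' @export
default_endpoints <- function(group_names = c("CON", "IS", "IS_AMI", "AMI"),
                              null = FALSE) {
  pg <- function(CON, IS, IS_AMI, AMI) {
    v <- c(CON = CON, IS = IS, IS_AMI = IS_AMI, AMI = AMI)
    if (null) v[] <- CON
    out <- v[group_names]
    out[is.na(out)] <- CON
    names(out) <- group_names
    out
  }
  list(
    weight = list(base_mean = pg(290, 290, 290, 290), base_sd = 10,
                  gain_mean = pg(2.4, 2.4, 2.4, 2.4), gain_sd = 0.25, meas_sd = 2),
    sucrose = list(day0 = 0.90, day21 = pg(0.90, 0.70, 0.72, 0.90), sd = 0.05,
                   intake_mean = 15, intake_sd = 2, drink_noise_sd = 0.5),
    von_frey = list(baseline = 12, floor = pg(12, 2, 2, 12),
                    recovered = pg(12, 2, 8, 12), sd_log = 0.12,
                    slope = 8, n_applications = 5),
    distance = list(mean = pg(25, 12, 22, 25), sd = 4),
    rearing = list(mean = pg(18, 8, 16, 18), sd = 3.5),
    id = list(mean = pg(8, 3, 8, 8), sd = 2.5),
    it = list(mean = pg(12, 12, 12, 12), sd = 4),
    ot = list(mean = pg(10, 10, 10, 10), sd = 4),
    oe = list(mean = pg(35, 18, 32, 35), sd = 8),
    entries = list(mean = pg(14, 8, 13, 14), sd = 3),
    epm_speed = 7
  )
}

group_param <- function(v, group) {
  if (length(v) == 1L) return(unname(v))
  unname(v[[group]])
}

# true threshold trend: decline to the floor over the first week, then
# (IS_AMI) gradual recovery from day 7 to day 21
threshold_truth <- function(day, baseline, floor_g, recovered, total_days = 21) {
  if (day <= 0) return(baseline)
  if (day <= 7) return(baseline + (floor_g - baseline) * day / 7)
  floor_g + (recovered - floor_g) * min((day - 7) / (total_days - 7), 1)
}

#' Simulate a cohort
#'
#' Generates the full raw-data bundle the analysis pipeline consumes:
#' weekly weights and two-bottle drinking observations, daily von Frey
#' response series, and (optionally) day-21 open-field and EPM
#' trajectories composed to hit per-rat endpoint targets drawn from the
#' design's means and sds.  Deterministic given `design$seed`.
#'
#' @param design a [cohort_design()].
#' @param trajectories if `FALSE`, skip trajectory synthesis; the drawn
#'   endpoint targets then stand in for the trajectory-derived metrics
#'   downstream (fast path for calibration studies).
#' @return object of class `cohort`: list with `records` (one row per rat
#'   x measurement day), `von_frey` (list keyed `"rat|day"`),
#'   `trajectories` (list keyed by trajectory ref), `targets` (one row per
#'   rat: the drawn day-21 endpoint truths) and `design`.
#' @export
simulate_cohort <- function(design, trajectories = TRUE) {
  stopifnot(inherits(design, "cohort_design"))
  ep <- design$endpoints
  weekly <- seq(0, design$days, by = 7)
  rec_rows <- list(); vf <- list(); trajs <- list(); tg_rows <- list()
  of_geom <- of_arena(); epm_geom <- epm_arena()

  for (g in names(design$groups)) {
    n_g <- design$groups[[g]]
    if (design$dropout && g == "IS") n_g <- n_g - 1L
    for (i in seq_len(n_g)) {
      rat <- sprintf("%s_%02d", g, i)
      base_w <- with_seed(substream_seed(design$seed, rat, "weight"), {
        c(rnorm(1, group_param(ep$weight$base_mean, g), ep$weight$base_sd),
          rnorm(1, group_param(ep$weight$gain_mean, g), ep$weight$gain_sd),
          rnorm(length(weekly), 0, ep$weight$meas_sd))
      })
      weights <- base_w[1] + base_w[2] * weekly + base_w[-(1:2)]

      p0 <- ep$sucrose$day0
      p21 <- group_param(ep$sucrose$day21, g)
      drink <- lapply(seq_along(weekly), function(k) {
        d <- weekly[k]
        s_seed <- substream_seed(design$seed, rat, "sucrose", d)
        with_seed(s_seed, {
          p <- p0 + (p21 - p0) * d / design$days + rnorm(1, 0, ep$sucrose$sd)
          p <- min(max(p, 0.02), 0.98)
          ti <- max(rnorm(1, ep$sucrose$intake_mean, ep$sucrose$intake_sd), 2)
          simulate_drinking(p, ti, ep$sucrose$drink_noise_sd)
        })
      })

      for (d in 0:design$days) {
        vf[[paste(rat, d, sep = "|")]] <- with_seed(
          substream_seed(design$seed, rat, "vf", d), {
            thr <- threshold_truth(d, ep$von_frey$baseline,
                                   group_param(ep$von_frey$floor, g),
                                   group_param(ep$von_frey$recovered, g),
                                   design$days)
            thr <- thr * exp(rnorm(1, 0, ep$von_frey$sd_log))
            simulate_von_frey(thr, n_applications_per_force = ep$von_frey$n_applications,
                              slope = ep$von_frey$slope)
          })
      }

      tg <- with_seed(substream_seed(design$seed, rat, "day21"), {
        draw <- function(e) rnorm(1, group_param(ep[[e]]$mean, g), ep[[e]]$sd)
        entries <- max(round(draw("entries")), 0)
        oe <- min(max(draw("oe"), 0), 100)
        n_open <- if (entries == 0) 0L else as.integer(round(oe / 100 * entries))
        data.frame(rat_id = rat, group = g,
                   distance_m = max(draw("distance"), 0.05),
                   rearing = max(round(draw("rearing")), 0),
                   id_pct = min(max(draw("id"), 0.3), 99),
                   it_pct = min(max(draw("it"), 1), 99),
                   ot_pct = min(max(draw("ot"), 0), 99),
                   open_entries = n_open,
                   closed_entries = as.integer(entries - n_open),
                   stringsAsFactors = FALSE)
      })
      tg$oe_pct <- if (tg$open_entries + tg$closed_entries == 0) NA_real_ else
        100 * tg$open_entries / (tg$open_entries + tg$closed_entries)
      if (tg$open_entries == 0) tg$ot_pct <- 0
      tg_rows[[rat]] <- tg

      of_ref <- paste0(rat, "_of21"); epm_ref <- paste0(rat, "_epm21")
      if (trajectories) {
        trajs[[of_ref]] <- compose_of_trajectory(
          tg$distance_m, tg$id_pct, tg$it_pct, of_geom, dt = design$dt,
          seed = substream_seed(design$seed, rat, "of_traj"))
        trajs[[epm_ref]] <- compose_epm_trajectory(
          tg$ot_pct, tg$open_entries, tg$closed_entries, epm_geom,
          mean_speed = ep$epm_speed, dt = design$dt,
          seed = substream_seed(design$seed, rat, "epm_traj"))
      }

      for (k in seq_along(weekly)) {
        d <- weekly[k]
        rec_rows[[paste(rat, d)]] <- data.frame(
          rat_id = rat, group = g, day = d,
          weight_g = weights[k],
          sucrose_g = drink[[k]]$sucrose_consumed,
          water_g = drink[[k]]$water_consumed,
          rearing_count = if (d == design$days) tg$rearing else NA_integer_,
          of_ref = if (d == design$days && trajectories) of_ref else NA_character_,
          epm_ref = if (d == design$days && trajectories) epm_ref else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, rec_rows)
  rownames(records) <- NULL
  targets <- do.call(rbind, tg_rows)
  rownames(targets) <- NULL
  structure(list(records = records, von_frey = vf, trajectories = trajs,
                 targets = targets, design = design),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d rats in %d groups, %d-day design, %d trajectories>\n",
              nrow(x$targets), length(x$design$groups), x$design$days,
              length(x$trajectories)))
  invisible(x)
}
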