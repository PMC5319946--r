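#' Compose an open-field trajectory realising target metrics
#'
#' Builds a 300-s trajectory whose recomputed metrics approximate given
#' targets for total distance, ID% and IT%.  The trial is laid out as
#' alternating inner-zone and outer-annulus bouts (the walk confined to the
#' respective region by reflection), joined by short radial bridges; within
#' each bout the animal moves as a correlated random walk at the constant
#' speed implied by its distance and time budget.  This is the generative
#' counterpart of [of_metrics()]: it lets a cohort design prescribe
#' endpoint-level means and standard deviations while the pipeline still
#' consumes raw trajectories.  Realisation error is a few percent (bridges
#' cross the zone boundary; reflections bend steps).
#'
#' @param total_m target total distance in m.
#' @param id_pct,it_pct target inner-zone distance and time percentages.
#' @param arena an [of_arena()].
#' @param dt sampling interval in s.
#' @param duration trial duration in s.
#' @param n_bouts number of inner (and outer) bouts.
#' @param seed integer seed or `NULL`.
#' @return a [trajectory()].
#' @export
compose_of_trajectory <- function(total_m, id_pct, it_pct, arena = of_arena(),
                                  dt = 0.1, duration = 300, n_bouts = 3, seed = NULL) {
  check_number(total_m, "total_m", lower = 0.01)
  check_number(id_pct, "id_pct", lower = 0, upper = 100)
  check_number(it_pct, "it_pct", lower = 0, upper = 100)
  with_seed(seed, {
    id_pct <- min(max(id_pct, 0.3), 99.7)
    it_pct <- min(max(it_pct, 1), 99)
    total_cm <- total_m * 100
    t_in <- duration * it_pct / 100
    t_out <- duration - t_in
    d_in <- total_cm * id_pct / 100
    d_out <- total_cm - d_in

    margin <- min(3, (arena$outer_radius - arena$inner_radius) / 4)
    zones <- list(inner = c(0, arena$inner_radius - margin),
                  outer = c(arena$inner_radius + margin, arena$outer_radius - 1))
    split_budget <- function(total, k) {
      w <- runif(k, 0.6, 1.4)
      total * w / sum(w)
    }
    plan <- data.frame(zone = rep(c("inner", "outer"), n_bouts),
                       time = as.vector(rbind(split_budget(t_in, n_bouts),
                                              split_budget(t_out, n_bouts))),
                       dist = as.vector(rbind(split_budget(d_in, n_bouts),
                                              split_budget(d_out, n_bouts))))

    total_steps <- round(duration / dt)
    xs <- numeric(total_steps + 1); ys <- numeric(total_steps + 1)
    xs[1] <- 0; ys[1] <- 0          # rat placed at the arena centre
    filled <- 0L                     # steps emitted so far
    heading <- runif(1, 0, 2 * pi)
    for (k in seq_len(nrow(plan))) {
      zone <- zones[[plan$zone[k]]]
      x0 <- xs[filled + 1L]; y0 <- ys[filled + 1L]
      r0 <- sqrt(x0^2 + y0^2)
      time_k <- plan$time[k]; dist_k <- plan$dist[k]
      # bridge radially into the target zone if outside it
      r_target <- if (r0 < zone[1]) zone[1] + 0.5 else if (r0 > zone[2]) zone[2] - 0.5 else r0
      gap <- abs(r_target - r0)
      if (gap > 1e-9) {
        v_next <- max(dist_k / max(time_k, dt), 0.5)
        nb <- max(1L, round(gap / (v_next * dt)))
        nb <- min(nb, total_steps - filled)
        if (nb > 0L) {
          ang <- if (r0 > 1e-9) atan2(y0, x0) else runif(1, 0, 2 * pi)
          rr <- r0 + (seq_len(nb) / nb) * (r_target - r0)
          xs[filled + 1L + seq_len(nb)] <- rr * cos(ang)
          ys[filled + 1L + seq_len(nb)] <- rr * sin(ang)
          filled <- filled + nb
          heading <- if (r_target > r0) ang else ang + pi
          time_k <- max(time_k - nb * dt, 0)
          dist_k <- max(dist_k - gap, 0)
        }
      }
      np <- if (k == nrow(plan)) total_steps - filled else min(round(time_k / dt), total_steps - filled)
      if (np <= 0L) next
      step <- rep(dist_k / np, np)
      pos <- crw_walk_cpp(np, xs[filled + 1L], ys[filled + 1L], heading, step,
                          turn_sd = 0.9 * sqrt(dt), bias_gain = 0,
                          r_min = zone[1], r_max = zone[2])
      xs[filled + 1L + seq_len(np)] <- pos[-1, 1]
      ys[filled + 1L + seq_len(np)] <- pos[-1, 2]
      if (np >= 2L) heading <- atan2(pos[np + 1, 2] - pos[np, 2], pos[np + 1, 1] - pos[np, 1])
      filled <- filled + np
    }
    times <- seq(0, by = dt, length.out = total_steps + 1)
    trajectory(times, xs, ys, arena, duration = duration)
  })
}

#' Compose an EPM trajectory realising target metrics
#'
#' Builds a 300-s trajectory with a prescribed number of open- and
#' closed-arm entries and a prescribed open-arm time.  Visits are scheduled
#' in shuffled order; each visit walks from the centre to a depth chosen so
#' that transit plus dwell consumes the visit's time share, then returns.
#' With zero entries of both kinds the animal stays at the centre for the
#' whole trial (OE% undefined downstream).
#'
#' @param ot_pct target open-arm time percentage (forced to 0 when
#'   `open_entries == 0`).
#' @param open_entries,closed_entries target entry counts.
#' @param arena an [epm_arena()].
#' @param mean_speed walking speed in cm/s.
#' @param dt sampling interval in s.
#' @param duration trial duration in s.
#' @param seed integer seed or `NULL`.
#' @return a [trajectory()].
#' @export
compose_epm_trajectory <- function(ot_pct, open_entries, closed_entries,
                                   arena = epm_arena(), mean_speed = 7,
                                   dt = 0.1, duration = 300, seed = NULL) {
  check_number(ot_pct, "ot_pct", lower = 0, upper = 100)
  check_number(open_entries, "open_entries", lower = 0, integer = TRUE)
  check_number(closed_entries, "closed_entries", lower = 0, integer = TRUE)
  check_number(mean_speed, "mean_speed", lower = 0.1)
  with_seed(seed, {
    n <- floor(duration / dt)
    times <- seq(0, by = dt, length.out = n + 1)
    n_o <- open_entries; n_c <- closed_entries
    if (n_o + n_c == 0L)
      return(trajectory(times, rep(0, n + 1), rep(0, n + 1), arena, duration = duration))
    h <- arena$arm_width / 2
    v <- mean_speed
    ot_s <- if (n_o == 0L) 0 else duration * ot_pct / 100
    centre_per_visit <- 2 * h / v
    closed_s <- max(duration - ot_s - (n_o + n_c) * centre_per_visit, n_c * 1)

    visit_time <- function(total_s, k) {
      if (k == 0L) return(numeric())
      w <- runif(k, 0.7, 1.3)
      total_s * w / sum(w)
    }
    kinds <- sample(c(rep("open", n_o), rep("closed", n_c)))
    shares <- numeric(length(kinds))
    shares[kinds == "open"] <- visit_time(ot_s, n_o)
    shares[kinds == "closed"] <- visit_time(closed_s, n_c)

    axes <- list(open = list(c(1, 0), c(-1, 0)), closed = list(c(0, 1), c(0, -1)))
    wt <- 0; wx <- 0; wy <- 0; t_now <- 0
    for (i in seq_along(kinds)) {
      share <- max(shares[i], 1.2)      # keep every visit above the debounce
      # choose depth so transit (in-arm) + dwell = share, dwell >= 0.6 s
      d_max <- h + 0.95 * arena$arm_length
      depth <- h + min((share - 0.6) * v / 2, d_max - h)
      depth <- max(depth, h + 1)
      transit <- 2 * (depth - h) / v
      dwell <- max(share - transit, 0.6)
      ax <- axes[[kinds[i]]][[sample.int(2, 1)]]
      leg <- depth / v
      wt <- c(wt, t_now + leg, t_now + leg + dwell, t_now + 2 * leg + dwell)
      wx <- c(wx, ax[1] * depth, ax[1] * depth, 0)
      wy <- c(wy, ax[2] * depth, ax[2] * depth, 0)
      t_now <- t_now + 2 * leg + dwell
    }
    if (t_now < duration) { wt <- c(wt, duration); wx <- c(wx, 0); wy <- c(wy, 0) }
    x <- stats::approx(wt, wx, xout = times, rule = 2)$y
    y <- stats::approx(wt, wy, xout = times, rule = 2)$y
    trajectory(times, x, y, arena, duration = duration)
  })
}
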