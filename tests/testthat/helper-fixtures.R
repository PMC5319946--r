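# Exact two-phase open-field trajectory (piecewise linear):
#   phase A (0-150 s): straight chord from (-30, 0) to (30, 0), entirely
#     inside the 30-cm inner circle, 60 cm of distance;
#   phase B (150-300 s): radial oscillation 30 -> 42 cm along the x axis,
#     5 legs of 12 cm = 60 cm, entirely in the annulus (the shared x = 30
#     endpoints have zero measure).
# So IT% = 50 and ID% = 50 exactly.
two_phase_of_trajectory <- function() {
  t <- c(0, 150, 180, 210, 240, 270, 300)
  x <- c(-30, 30, 42, 30, 42, 30, 42)
  trajectory(t, x, rep(0, length(t)), of_arena())
}

# EPM trajectory alternating open and closed visits with dwell >> debounce
epm_visits_trajectory <- function(n_open = 3, n_closed = 3, dwell = 20) {
  wt <- 0; wx <- 0; wy <- 0; t_now <- 0
  kinds <- rep(c("open", "closed"), length.out = n_open + n_closed)
  for (k in kinds) {
    ax <- if (k == "open") c(1, 0) else c(0, 1)
    wt <- c(wt, t_now + 5, t_now + 5 + dwell, t_now + 10 + dwell)
    wx <- c(wx, ax[1] * 30, ax[1] * 30, 0)
    wy <- c(wy, ax[2] * 30, ax[2] * 30, 0)
    t_now <- t_now + 10 + dwell
  }
  stopifnot(t_now <= 300)
  trajectory(wt, wx, wy, epm_arena(), duration = 300)
}

# independent oracle: OF inner distance/time by brute-force fine subdivision
# of every segment (no analytic intersection)
of_metrics_oracle <- function(traj, n_sub = 400) {
  s <- traj$samples
  ri <- traj$arena$inner_radius
  inner_d <- 0; inner_t <- 0; total_d <- 0
  for (i in seq_len(nrow(s) - 1)) {
    dx <- s$x_cm[i + 1] - s$x_cm[i]; dy <- s$y_cm[i + 1] - s$y_cm[i]
    dt <- s$time_s[i + 1] - s$time_s[i]
    L <- sqrt(dx^2 + dy^2)
    total_d <- total_d + L
    tm <- (seq_len(n_sub) - 0.5) / n_sub
    ins <- (s$x_cm[i] + tm * dx)^2 + (s$y_cm[i] + tm * dy)^2 <= ri^2
    inner_d <- inner_d + L * mean(ins)
    inner_t <- inner_t + dt * mean(ins)
  }
  lead <- s$time_s[1]; trail <- traj$duration - s$time_s[nrow(s)]
  if (s$x_cm[1]^2 + s$y_cm[1]^2 <= ri^2) inner_t <- inner_t + lead
  if (s$x_cm[nrow(s)]^2 + s$y_cm[nrow(s)]^2 <= ri^2) inner_t <- inner_t + trail
  list(total_m = total_d / 100, inner_m = inner_d / 100, inner_time = inner_t)
}

# naive transition counter (count_entries oracle at debounce 0)
naive_entries <- function(zones) {
  r <- rle(as.character(zones))
  v <- r$values[-1]
  table(factor(v, levels = sort(unique(r$values))))
}

# independent SNK implementation against a supplied critical-value table
# q_crit: named vector, names = span ("2".."k")
snk_oracle <- function(groups, q_crit) {
  k <- length(groups)
  means <- sapply(groups, mean)
  ord <- order(means, names(groups))
  m <- means[ord]; ns <- lengths(groups)[ord]; nm <- names(groups)[ord]
  msw <- sum(sapply(groups, function(x) sum((x - mean(x))^2))) /
    (sum(lengths(groups)) - k)
  sig <- matrix(FALSE, k, k, dimnames = list(nm, nm))
  blocked <- matrix(FALSE, k, k)
  for (span in k:2) {
    for (i in 1:(k - span + 1)) {
      j <- i + span - 1
      if (blocked[i, j]) next
      nh <- 2 / (1 / ns[i] + 1 / ns[j])
      q <- (m[j] - m[i]) / sqrt(msw / nh)
      if (q > q_crit[[as.character(span)]]) {
        sig[i, j] <- sig[j, i] <- TRUE
      } else {
        for (a in i:j) for (b in i:j) if (a < b) blocked[a, b] <- TRUE
      }
    }
  }
  sig[names(groups), names(groups)]
}

# three-rat record fixture used by the IO tests
make_record_fixture <- function() {
  data.frame(
    rat_id = rep(c("CON_01", "CON_02", "IS_01"), each = 2),
    group = rep(c("CON", "CON", "IS"), each = 2),
    day = rep(c(0, 21), 3),
    weight_g = c(290, 345, 285, 338, 288, 332),
    sucrose_g = c(13.1, 13.5, 12.8, 13.0, 13.2, 9.1),
    water_g = c(1.4, 0.5, 1.5, 1.1, 1.2, 4.3),
    rearing_count = c(NA, 22, NA, 18, NA, 7),
    of_ref = NA_character_, epm_ref = NA_character_,
    stringsAsFactors = FALSE)
}
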