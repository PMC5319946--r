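#' Open-field metrics
#'
#' Computes total distance, inner-zone distance, inner-zone time and the
#' two percentages ID% (inner distance / total distance x 100) and IT%
#' (inner time / 300 s x 100) from a raw trajectory.  A segment crossing
#' the inner-circle boundary is split at the exact geometric intersection
#' and its time and distance apportioned by sub-segment (assuming constant
#' speed along the segment), which removes sampling-rate dependence.  Time
#' before the first and after the last sample is attributed to the zone of
#' that sample.
#'
#' The IT% denominator is the trial duration verbatim (default 300 s) even
#' if the trace is shorter; `strict = TRUE` errors on a truncated trace
#' instead.  A stationary trial (zero total distance) gets `id_pct = 0`
#' with flag `"stationary"` rather than an error, so scoring can proceed:
#' a motionless rat is maximally scorable as depressed, not missing.
#'
#' @param traj a [trajectory()] recorded in an open-field arena.
#' @param strict error when the trace does not span the full trial.
#' @return object of class `of_metrics`: list with `total_distance_m`,
#'   `inner_distance_m`, `inner_time_s`, `id_pct`, `it_pct`, `flags`.
#' @export
of_metrics <- function(traj, strict = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$arena$kind != "open_field")
    abort_validation("of_metrics needs a trajectory recorded in an open-field arena")
  s <- traj$samples
  n <- nrow(s)
  if (strict && (s$time_s[1] > 1e-6 || s$time_s[n] < traj$duration - 1e-6))
    abort_validation("strict mode: trace does not span the full trial duration")
  ri <- traj$arena$inner_radius
  flags <- character()

  inner_time <- 0; inner_dist <- 0; total_dist <- 0
  # time outside the sampled span goes to the zone of the nearest sample
  lead <- s$time_s[1]; trail <- traj$duration - s$time_s[n]
  if (lead > 0 && s$x_cm[1]^2 + s$y_cm[1]^2 <= ri^2) inner_time <- inner_time + lead
  if (trail > 0 && s$x_cm[n]^2 + s$y_cm[n]^2 <= ri^2) inner_time <- inner_time + trail

  if (n >= 2L) {
    x1 <- s$x_cm[-n]; y1 <- s$y_cm[-n]
    dx <- diff(s$x_cm); dy <- diff(s$y_cm)
    dt <- diff(s$time_s)
    L <- sqrt(dx^2 + dy^2)
    total_dist <- sum(L)
    # segment-circle intersections: |p1 + t d|^2 = ri^2, t in (0, 1)
    a <- dx^2 + dy^2
    b <- 2 * (x1 * dx + y1 * dy)
    cc <- x1^2 + y1^2 - ri^2
    disc <- b^2 - 4 * a * cc
    ok <- a > 0 & disc > 0
    sq <- sqrt(pmax(disc, 0))
    t1 <- ifelse(ok, (-b - sq) / (2 * a), 1)
    t2 <- ifelse(ok, (-b + sq) / (2 * a), 1)
    t1[!(t1 > 0 & t1 < 1)] <- 1
    t2[!(t2 > 0 & t2 < 1)] <- 1
    r1 <- pmin(t1, t2); r2 <- pmax(t1, t2)
    brk <- cbind(0, r1, r2, 1)
    for (j in 1:3) {
      f <- brk[, j + 1L] - brk[, j]
      tm <- (brk[, j + 1L] + brk[, j]) / 2
      mx <- x1 + tm * dx; my <- y1 + tm * dy
      ins <- (mx^2 + my^2 <= ri^2) & f > 0
      inner_dist <- inner_dist + sum(L[ins] * f[ins])
      inner_time <- inner_time + sum(dt[ins] * f[ins])
    }
  }

  total_m <- total_dist / 100
  inner_m <- inner_dist / 100
  if (total_m == 0) {
    id_pct <- 0
    flags <- c(flags, "stationary")
  } else {
    id_pct <- 100 * inner_m / total_m
  }
  structure(list(total_distance_m = total_m,
                 inner_distance_m = inner_m,
                 inner_time_s = inner_time,
                 id_pct = min(max(id_pct, 0), 100),
                 it_pct = min(max(100 * inner_time / traj$duration, 0), 100),
                 flags = flags),
            class = "of_metrics")
}

#' Zone label sequence of a trajectory
#'
#' @param traj a [trajectory()].
#' @return data.frame with columns `time_s`, `zone`.
#' @export
zone_sequence <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  data.frame(time_s = traj$samples$time_s,
             zone = arena_zone(traj$arena, traj$samples$x_cm, traj$samples$y_cm),
             stringsAsFactors = FALSE)
}

#' Count arm entries from a zone label sequence
#'
#' An entry is a transition from a different effective zone into an arm.
#' A minimum-dwell debounce (default 0.5 s) suppresses tracking jitter:
#' a zone visit shorter than the debounce window neither counts as an
#' entry nor changes the effective zone.  With `debounce = 0` this reduces
#' to a naive transition count.  The first run is the placement position,
#' not an entry.
#'
#' @param zones character vector of labels from
#'   `{"open", "closed", "centre"}` (or `{"inner", "outer"}`).
#' @param time_s sample times parallel to `zones`.
#' @param duration trial duration used to close the last visit; defaults
#'   to the last sample time.
#' @param debounce minimum dwell in s for a visit to register.
#' @return named integer vector of entry counts, one element per distinct
#'   zone label (arms and centre alike; [epm_metrics()] uses the arm
#'   counts).
#' @export
count_entries <- function(zones, time_s, duration = NULL, debounce = 0.5) {
  if (length(zones) != length(time_s))
    abort_validation("zones and time_s must have equal length")
  duration <- duration %||% time_s[length(time_s)]
  r <- rle(as.character(zones))
  starts <- time_s[cumsum(c(1L, r$lengths[-length(r$lengths)]))]
  durs <- diff(c(starts, duration))
  counts <- setNames(integer(length(unique(r$values))), sort(unique(r$values)))
  eff <- r$values[1L]
  if (length(r$values) > 1L) {
    for (k in 2:length(r$values)) {
      if (durs[k] >= debounce && !identical(r$values[k], eff)) {
        counts[r$values[k]] <- counts[r$values[k]] + 1L
        eff <- r$values[k]
      }
    }
  }
  counts
}

#' Elevated-plus-maze metrics
#'
#' Computes open/closed/centre times, arm entry counts, OT% (open-arm time
#' / 300 s x 100) and OE% (open entries / total arm entries x 100) from a
#' raw trajectory.  Each inter-sample interval is attributed to the zone of
#' its left sample; entries are counted by [count_entries()] with the given
#' debounce.  A trial with zero arm entries has an undefined OE%, returned
#' as `NA` with flag `"no_entries"`; the scoring stage decides its points
#' (see [score_rat()]).
#'
#' @param traj a [trajectory()] recorded in an EPM arena.
#' @param debounce minimum arm dwell in s for an entry to count.
#' @param strict error when the trace does not span the full trial.
#' @return object of class `epm_metrics`: list with `open_time_s`,
#'   `closed_time_s`, `centre_time_s`, `open_entries`, `closed_entries`,
#'   `ot_pct`, `oe_pct`, `flags`.
#' @export
epm_metrics <- function(traj, debounce = 0.5, strict = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$arena$kind != "epm")
    abort_validation("epm_metrics needs a trajectory recorded in an EPM arena")
  s <- traj$samples
  n <- nrow(s)
  if (strict && (s$time_s[1] > 1e-6 || s$time_s[n] < traj$duration - 1e-6))
    abort_validation("strict mode: trace does not span the full trial duration")
  zs <- arena_zone(traj$arena, s$x_cm, s$y_cm)
  # interval [t_i, t_{i+1}) belongs to the zone of sample i; leading and
  # trailing slack to the first/last sample's zone
  w <- if (n >= 2L) c(diff(s$time_s), traj$duration - s$time_s[n]) else traj$duration - s$time_s
  w[1L] <- w[1L] + s$time_s[1L]
  tm <- tapply(w, zs, sum)
  zt <- function(z) if (z %in% names(tm)) unname(tm[[z]]) else 0
  ent <- count_entries(zs, s$time_s, duration = traj$duration, debounce = debounce)
  ec <- function(z) if (z %in% names(ent)) unname(ent[[z]]) else 0L
  open_entries <- ec("open"); closed_entries <- ec("closed")
  flags <- character()
  if (open_entries + closed_entries == 0L) {
    oe_pct <- NA_real_
    flags <- c(flags, "no_entries")
  } else {
    oe_pct <- 100 * open_entries / (open_entries + closed_entries)
  }
  structure(list(open_time_s = zt("open"), closed_time_s = zt("closed"),
                 centre_time_s = zt("centre"),
                 open_entries = open_entries, closed_entries = closed_entries,
                 ot_pct = min(max(100 * zt("open") / traj$duration, 0), 100),
                 oe_pct = oe_pct, flags = flags),
            class = "epm_metrics")
}
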