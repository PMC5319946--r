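#' Trajectory objects
#'
#' A trajectory is the tracking system's output for one trial: time-stamped
#' planar positions of the animal's tracked centre point, together with the
#' arena it was recorded in.  Times must be strictly increasing, start at
#' or after 0 and end at or before the trial duration (default 300 s).
#'
#' @param time_s,x_cm,y_cm numeric vectors of equal length.
#' @param arena an [of_arena()] or [epm_arena()].
#' @param duration trial duration in s (the fixed denominator of the IT%
#'   and OT% formulas).
#' @return object of class `trajectory`: list with `samples` (data.frame
#'   `time_s`, `x_cm`, `y_cm`), `arena`, `duration`.
#' @export
trajectory <- function(time_s, x_cm, y_cm, arena, duration = 300) {
  stopifnot(inherits(arena, "arena"))
  n <- length(time_s)
  if (length(x_cm) != n || length(y_cm) != n)
    abort_validation("time_s, x_cm, y_cm must have equal length")
  if (n == 0L) abort_validation("a trajectory needs at least one sample")
  if (any(!is.finite(time_s)) || any(!is.finite(x_cm)) || any(!is.finite(y_cm)))
    abort_validation("trajectory samples must be finite")
  if (any(diff(time_s) <= 0))
    abort_validation("trajectory times must be strictly increasing")
  if (time_s[1] < 0 || time_s[n] > duration + 1e-9)
    abort_validation(sprintf("trajectory times must lie in [0, %g]", duration))
  structure(list(samples = data.frame(time_s = as.numeric(time_s),
                                      x_cm = as.numeric(x_cm),
                                      y_cm = as.numeric(y_cm)),
                 arena = arena, duration = duration),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d samples over %g s in a %s arena>\n",
              nrow(x$samples), x$duration, x$arena$kind))
  invisible(x)
}

#' Read or write a single-trial trajectory file
#'
#' Plain delimited text with the exact header `time_s,x_cm,y_cm`, one file
#' per trial.
#'
#' @param path file path.
#' @param arena arena geometry the trial was recorded in.
#' @param duration trial duration in s.
#' @return [trajectory()] for `read_trajectory`; the path, invisibly, for
#'   `write_trajectory`.
#' @export
read_trajectory <- function(path, arena, duration = 300) {
  if (!file.exists(path)) abort_io(sprintf("trajectory file '%s' does not exist", path))
  df <- read.csv(path)
  if (!identical(names(df), c("time_s", "x_cm", "y_cm")))
    abort_io(sprintf("trajectory file '%s': header must be exactly 'time_s,x_cm,y_cm'", path))
  trajectory(df$time_s, df$x_cm, df$y_cm, arena, duration)
}

#' @rdname read_trajectory
#' @param traj a [trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  write.csv(traj$samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Path length of a trajectory
#'
#' Sum of consecutive Euclidean segment lengths, converted cm to m.
#'
#' @param traj a [trajectory()].
#' @return distance in metres.
#' @export
path_length <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  s <- traj$samples
  if (nrow(s) < 2L) {
    warning("trajectory has fewer than 2 samples; path length is 0")
    return(0)
  }
  sum(sqrt(diff(s$x_cm)^2 + diff(s$y_cm)^2)) / 100
}
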