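#' @useDynLib affectscales, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate complete.cases cor pf plogis pt ptukey qtukey
#'   rbinom rgamma rnorm rpois runif sd setNames
#' @importFrom utils modifyList read.csv write.csv
NULL

the_cache <- new.env(parent = emptyenv())

abort_validation <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("affectscales_validation", "error", "condition")))
}

abort_io <- function(msg) {
  stop(errorCondition(msg, class = c("affectscales_io", "error", "condition")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    abort_validation(sprintf("`%s` must be a single non-missing number", name))
  if (x < lower || x > upper)
    abort_validation(sprintf("`%s` = %s is outside [%s, %s]", name, format(x), lower, upper))
  if (integer && x != floor(x))
    abort_validation(sprintf("`%s` must be an integer, got %s", name, format(x)))
  invisible(x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so callers see no RNG side effects.
#' With `seed = NULL` the expression runs under the current RNG stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a deterministic substream seed
#'
#' Maps a master seed plus any number of string/number identifiers to an
#' integer in `[0, 2^31 - 2]` via a polynomial rolling hash.  Each
#' (rat, day, stream) combination gets its own reproducible substream, so
#' adding a rat to a design never perturbs the draws of the others.
#'
#' @param master integer master seed.
#' @param ... identifiers (coerced to character) naming the substream.
#' @return integer seed.
#' @export
#' @examples
#' substream_seed(1, "rat01", 21, "of")
substream_seed <- function(master, ...) {
  key <- paste(c(format(master), vapply(list(...), function(x) paste(format(x), collapse = ","), "")),
               collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# significance stars matching the usual figure-legend convention
p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}
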