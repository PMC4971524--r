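## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cdc <- function(fmt, ..., class = "cdcseq_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "cdcseq_error")))
}

warn_cdc <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop_cdc("'%s' must be a single number in [%s, %s]", name, lower, upper,
             class = "cdcseq_invalid_config")
  invisible(x)
}

#' Percentage of a count out of a total, as printed in reports
#'
#' Convenience for reporting fractions the way clinical and genomics papers
#' print them, e.g. 308 of 18417 genes is 1.7 (percent).
#'
#' @param k numerator count(s).
#' @param n denominator total(s), positive.
#' @param digits decimal places to round to (default 1).
#' @return numeric percentage(s).
#' @export
percent_of <- function(k, n, digits = 1) {
  if (any(n <= 0)) stop_cdc("'n' must be positive")
  round(100 * k / n, digits)
}

## evaluate expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## derive a stream-specific 32-bit seed from a master seed
derive_seed <- function(seed, stream) {
  offsets <- c(simulate = 11L, atlas = 23L, til = 37L, de = 53L,
               cluster = 71L, origin = 97L, enrich = 113L, perm = 131L)
  off <- if (stream %in% names(offsets)) offsets[[stream]] else
    sum(utf8ToInt(stream))
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}
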