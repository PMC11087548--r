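#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions do not disturb the global stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert an information value from bits per sample to bits per second
#'
#' MI and co-information are reported per time sample; at a sampling rate of
#' `fs` Hz a value of `x` bits/sample corresponds to `x * fs` bits/second
#' (e.g. 0.01 bits/sample at 500 Hz is 5 bits/second).
#'
#' @param bits_per_sample information in bits per sample.
#' @param fs sampling rate in Hz.
#' @return Information rate in bits per second.
#' @examples
#' bits_per_second(0.01, 500)  # 5
#' @export
bits_per_second <- function(bits_per_sample, fs) {
  stopifnot(is.numeric(bits_per_sample), is.numeric(fs), fs > 0)
  bits_per_sample * fs
}
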