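#' Round half away from zero
#'
#' Printed coverage percentages and fall rates use commercial (half-up)
#' rounding, not the IEC 60559 half-to-even rule of [base::round()]:
#' 47/98 is reported as 48.0, not 47.9.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Derive a child seed from a run seed
#'
#' A single run seed fans out to independent per-stream seeds (cohort
#' structure, fall draws, series noise, resampling) so that components stay
#' reproducible and independent of each other. The derived value stays within
#' the 32-bit integer range `set.seed()` accepts.
#'
#' @param seed integer run seed.
#' @param stream small integer identifying the consuming stream.
#' @return an integer seed.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((abs(seed) * 48271 + stream * 16807) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# split a ";"-separated cell into a character vector (empty cell -> character(0))
split_semi <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1]]
}
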