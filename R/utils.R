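# Internal helpers: classed error conditions and display rounding.

apogee_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "apogee_error"),
                      call = call))
}

format_error     <- function(msg) apogee_error(msg, "apogee_format_error")
validation_error <- function(msg) apogee_error(msg, "apogee_validation_error")
curation_error   <- function(msg) apogee_error(msg, "apogee_curation_error")

#' Round half away from zero
#'
#' Display rounding used in evaluation reports. `base::round()` rounds
#' half to even; published performance tables conventionally round half
#' up (away from zero), so 0.125 becomes 0.13 rather than 0.12.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# deterministic stream of sub-seeds derived from one master seed;
# values stay below 2^31 so they are valid R integer seeds
spawn_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}
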