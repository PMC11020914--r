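`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

#' Derive a reproducible child seed from a global seed
#'
#' Stage seeds are deterministic functions of the global seed so pipeline
#' stages can be rerun in isolation yet reproducibly. Kept below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage integer stage offset.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 7919) %% 2147483647L)
}

## population standard deviation (1/n denominator)
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

is_binary_01 <- function(x) all(x %in% c(0, 1) | is.na(x))

years_between <- function(from, to) as.numeric(difftime(to, from, units = "days")) / 365.25
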