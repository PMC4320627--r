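# Shared helpers: rounding, seeds, validation.

#' Round half away from zero
#'
#' Displayed expected counts round halves away from zero (2.5 -> 3, -2.5 -> -3),
#' unlike [base::round()], which rounds halves to even.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
#' @examples
#' round_half_away(c(2.5, 3.5, -2.5))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive a stage seed from a top-level seed
#'
#' All randomness in a pipeline run flows from one user seed; each stage uses a
#' deterministic derived seed so stages stay reproducible independently.
#' Result always fits in a 32-bit integer.
#'
#' @param seed integer top-level seed.
#' @param stage character stage label.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 131071 + h * 2654435) %% .Machine$integer.max)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

# Text digest used by the run manifest: numbers-stable, no external deps.
digest_lines <- function(lines) {
  x <- paste(lines, collapse = "\n")
  bytes <- utf8ToInt(x)
  h1 <- 5381; h2 <- 52711
  for (b in bytes) {
    h1 <- (h1 * 33 + b) %% 4294967291
    h2 <- (h2 * 31 + b) %% 4294967279
  }
  sprintf("%010.0f%010.0f", h1, h2)
}

digest_file <- function(path) {
  digest_lines(readLines(path, warn = FALSE))
}
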