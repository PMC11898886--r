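#' @keywords internal
"_PACKAGE"

#' @import methods
#' @importFrom stats rnorm rlnorm var pf pt sd setNames
#' @importFrom utils read.csv write.csv head
NULL

CLASS_LEVELS <- c("healthy", "localized", "metastatic")

#' Derive a reproducible sub-stream seed
#'
#' One root integer seed drives the whole pipeline; every stage that consumes
#' randomness (cohort draw, plate noise, dataset split, model initialisation)
#' derives its own seed from the root seed and a stream label, so stages can
#' be re-run in isolation without perturbing each other.
#'
#' @param seed integer root seed.
#' @param stream character stream label, e.g. `"cohort"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' deriveSeed(1L, "cohort")
deriveSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stream), length(stream) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime; arithmetic stays exact in doubles
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% m
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807 + 1) %% m)
}

## Row-wise softmax that is safe against overflow.
softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

## Truncate (floor) a positive percentage to `digits` decimals. Truncation,
## not rounding: reported percentages never over-state performance.
truncateDecimals <- function(x, digits = 2L) {
  f <- 10^digits
  floor(x * f) / f
}

## Cheap deterministic content hash (FNV-1a over the deparsed object),
## used to stamp config provenance into report files.
hashObject <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (ch in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2147483647), ch)
    h <- (as.numeric(h) * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

## Column name used in CSV headers for a protease ("ADAM10/12" -> "ADAM10_12").
proteaseColumn <- function(x) gsub("/", "_", x, fixed = TRUE)
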