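## Well-coordinate helpers. Convention: letter row A-P, two-digit column
## 01-24 ("A01".."P24"); well index is row-major, A01 = 1 .. P24 = 384.

#' All 384 well identifiers in row-major order
#' @return Character vector "A01".."P24".
#' @export
plateWells384 <- function() {
  as.vector(t(outer(LETTERS[1:16], sprintf("%02d", 1:24), paste0)))
}

#' Validate 384-format well identifiers
#' @param wells character vector of well ids.
#' @return Logical vector; TRUE where the id is a valid A01..P24 well.
#' @export
isValidWell384 <- function(wells) {
  grepl("^[A-P](0[1-9]|1[0-9]|2[0-4])$", wells)
}

#' Row-major index of a 384-format well (A01 = 1 .. P24 = 384)
#' @param wells character vector of valid well ids.
#' @return Integer vector of indices.
#' @export
wellIndex384 <- function(wells) {
  stopifnot(all(isValidWell384(wells)))
  row <- match(substr(wells, 1, 1), LETTERS[1:16])
  col <- as.integer(substr(wells, 2, 3))
  as.integer((row - 1L) * 24L + col)
}

## Per-well substream seed: plate seed plus the row-major well index, an
## offset-counter scheme that keeps every well independently reproducible.
## Kept inside 32-bit integer range.
wellSeed <- function(seed, index) {
  as.integer((as.numeric(seed) + as.numeric(index)) %% 2147483647)
}

## Non-negative Gaussian draws by resampling (fluorescence cannot be
## negative). Resampling rather than clipping keeps the moments close to
## nominal for means a few SDs above zero; after `maxIter` rounds any
## remaining negatives are floored with a warning (pathological specs).
rnormTrunc0 <- function(n, mean, sd, maxIter = 100L) {
  x <- stats::rnorm(n, mean, sd)
  it <- 0L
  repeat {
    neg <- which(x < 0)
    if (!length(neg)) return(x)
    it <- it + 1L
    if (it > maxIter) {
      warning("truncation resampling did not terminate; flooring at 0")
      x[neg] <- 0
      return(x)
    }
    x[neg] <- stats::rnorm(length(neg), mean, sd)
  }
}

## 32-bit polynomial rolling hash of a string, as 8 hex digits; used to
## stamp output files with a short configuration fingerprint (audit trail,
## not cryptographic). Arithmetic in doubles: 31 * 2^32 < 2^53 is exact.
configHash <- function(s) {
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## aggregation helper shared by the screen statistics
aggFun <- function(aggregation = c("median", "mean")) {
  aggregation <- match.arg(aggregation)
  if (aggregation == "median") stats::median else mean
}
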