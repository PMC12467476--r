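## Shared null-model machinery: composition-preserving scrambles and the
## NullSummary computation (z, add-one empirical p, direction call).

#' Composition-preserving scramble of a sequence
#'
#' Returns a uniformly random permutation of the input residues. Uses the
#' current R random number generator state (`set.seed()` for
#' reproducibility).
#'
#' @param x a single sequence (character scalar, optionally named, or
#'   `AAString`/length-1 `AAStringSet`).
#' @return a named character scalar; the name carries a `_scramble` tag.
#' @examples
#' set.seed(1)
#' scrambleSequence(c(toy = "MKVQQQ"))
#' @export
scrambleSequence <- function(x) {
  s <- .asSequence(x)
  ch <- strsplit(s$residues, "", fixed = TRUE)[[1L]]
  out <- paste(ch[sample.int(length(ch))], collapse = "")
  names(out) <- paste0(s$id, "_scramble")
  out
}

#' Summarize an observed statistic against a null sample
#'
#' Computes the z-score, both one-sided add-one empirical p-values, and the
#' direction call. The add-one (pseudo-count) convention
#' `p_high = (1 + #\{null >= observed\}) / (n + 1)` keeps p strictly
#' positive: n null samples cannot support p below 1/(n+1). When the null
#' sample is constant (sd = 0) the z-score is flagged undefined; the call is
#' still derived from the empirical p-values, so a constant null equal to
#' the observed value yields `call = "none"`.
#'
#' @param observed observed value of the statistic.
#' @param nullValues numeric vector of the statistic on null samples.
#' @param alpha significance level for the direction call (default 0.05).
#' @return a [NullSummary-class] object.
#' @examples
#' summarizeNull(5, rep(0, 1000))   # p_high = 1/1001, call "high"
#' @export
summarizeNull <- function(observed, nullValues, alpha = 0.05) {
  stopifnot(length(observed) == 1L, is.finite(observed),
            length(nullValues) >= 1L, all(is.finite(nullValues)),
            alpha > 0, alpha < 1)
  n <- length(nullValues)
  mu <- mean(nullValues)
  sdev <- stats::sd(nullValues)
  if (n == 1L) sdev <- 0
  defined <- sdev > 0
  z <- if (defined) (observed - mu) / sdev else NA_real_
  pHigh <- (1 + sum(nullValues >= observed)) / (n + 1)
  pLow <- (1 + sum(nullValues <= observed)) / (n + 1)
  call <- if (pHigh < alpha) "high" else if (pLow < alpha) "low" else "none"
  new("NullSummary", observed = observed, nullMean = mu, nullSd = sdev,
      z = z, pHigh = pHigh, pLow = pLow, nSamples = as.integer(n),
      alpha = alpha, call = call, defined = defined)
}

## Deterministic per-sequence sub-seed from (global seed, sequence id), so
## batch results are independent of processing order. Plain polynomial hash
## over the id bytes, folded into [0, 2^31 - 2].
.sequenceSeed <- function(seed, id) {
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.numeric(seed)) %% 2147483647)
}
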