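#' Additivity index
#'
#' Ratio of the bimodal response to the sum of the two unimodal responses,
#' `M / (V + A)`. Values above 1 indicate super-additive integration, below 1
#' sub-additive integration; exactly 1 means the bimodal response equals the
#' linear sum of the unimodal responses.
#'
#' @param M Bimodal response (>= 0).
#' @param V,A Unimodal visual and auditory responses (>= 0).
#' @return The index, or `NA` (undefined) where `V + A` is numerically zero.
#' @export
#' @examples
#' additivity_index(0.8, 0.3, 0.3) # 1.333...
additivity_index <- function(M, V, A) {
  check_nonneg_rates(M, V, A)
  denom <- V + A
  ifelse(denom < 1e-9, NA_real_, M / denom)
}

#' Cross-modal response enhancement
#'
#' `(M - max(V, A)) / (M + max(V, A))`: positive values indicate cross-modal
#' enhancement (the bimodal response exceeds the best unimodal response),
#' negative values cross-modal suppression.
#'
#' @inheritParams additivity_index
#' @return Signed ratio in `[-1, 1]`, `NA` where the denominator is zero.
#' @export
response_enhancement <- function(M, V, A) {
  check_nonneg_rates(M, V, A)
  best <- pmax(V, A)
  denom <- M + best
  ifelse(denom < 1e-9, NA_real_, (M - best) / denom)
}

#' Response additivity (percent)
#'
#' `(M - (V + A)) / (M + (V + A)) * 100`: positive values indicate
#' super-additivity, negative values sub-additivity. Sign-equivalent to the
#' additivity index being above/below 1.
#'
#' @inheritParams additivity_index
#' @return Signed percentage, `NA` where the denominator is zero.
#' @export
response_additivity <- function(M, V, A) {
  check_nonneg_rates(M, V, A)
  s <- V + A
  denom <- M + s
  ifelse(denom < 1e-9, NA_real_, (M - s) / denom * 100)
}

check_nonneg_rates <- function(M, V, A) {
  if (any(c(M, V, A) < 0, na.rm = TRUE)) {
    stop("responses M, V, A must be nonnegative", call. = FALSE)
  }
  invisible(NULL)
}

#' Find response peaks in a population rate profile
#'
#' Local maxima of the rate vector that exceed `rel_threshold` times the
#' global maximum; maxima closer than `min_separation` channels are merged,
#' keeping the larger one. A profile whose maximum is below `1e-6` is treated
#' as silent (no peaks). Plateaus count once, at their first channel.
#'
#' @param rates Nonnegative numeric vector over channels.
#' @param rel_threshold Fraction of the global maximum a local maximum must
#'   reach, in (0, 1). Default 0.1.
#' @param min_separation Minimum distance in channels between reported peaks
#'   (>= 1). Default 2.
#' @return Integer vector of peak locations in 0-based channel coordinates
#'   (possibly empty), sorted increasing.
#' @export
find_peaks <- function(rates, rel_threshold = 0.1, min_separation = 2L) {
  stopifnot(rel_threshold > 0, rel_threshold < 1, min_separation >= 1)
  n <- length(rates)
  top <- max(rates)
  if (top < 1e-6) return(integer(0))
  left <- c(-Inf, rates[-n])
  right <- c(rates[-1L], -Inf)
  is_max <- rates > left & rates >= right # plateau start counts, rest of plateau not
  cand <- which(is_max & rates >= rel_threshold * top)
  if (length(cand) == 0L) return(integer(0))
  # greedy merge: keep highest first, drop candidates within min_separation
  ord <- cand[order(rates[cand], cand, decreasing = c(TRUE, FALSE), method = "radix")]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(i - kept) > min_separation)) kept <- c(kept, i)
  }
  sort(kept) - 1L
}

#' Classify a response pattern as fused, separate or silent
#'
#' One response peak means the two stimuli were fused into a single perceived
#' event; two or more peaks mean separate events; no peak means no response.
#'
#' @param peaks Integer vector of peak locations (from [find_peaks()]).
#' @return One of `"fused"`, `"separate"`, `"none"`.
#' @export
classify_fusion <- function(peaks) {
  n <- length(peaks)
  if (n == 0L) "none" else if (n == 1L) "fused" else "separate"
}

#' Maximum-likelihood location readout
#'
#' The location estimate of the population response: the 0-based channel index
#' of the maximum rate. Ties are broken toward the lower index.
#'
#' @param rates Nonnegative numeric vector over channels.
#' @return Integer location in `0 .. length(rates) - 1`.
#' @export
ml_location <- function(rates) {
  if (max(rates) <= 0) stop("no response: all rates are zero", call. = FALSE)
  which.max(rates) - 1L
}

# Build one metric record row from the three condition responses.
metric_record <- function(M, V, A, condition, intensity, offset = 0, lam = NA_real_) {
  data.frame(
    condition = condition, intensity = intensity, offset = offset, lam = lam,
    M = M, V = V, A = A,
    additivity_index = additivity_index(M, V, A),
    enhancement = response_enhancement(M, V, A),
    response_additivity = response_additivity(M, V, A),
    stringsAsFactors = FALSE
  )
}
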