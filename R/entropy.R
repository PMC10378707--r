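#' Sample and approximate entropy
#'
#' Template-matching regularity measures under the Chebyshev (maximum)
#' distance. Sample entropy is -ln(A/B), where B and A count ordered
#' template pairs (i != j, both template start points within the first
#' N - m positions) matching at length m and m+1 respectively,
#' self-matches excluded. Approximate entropy is Phi_m - Phi_{m+1},
#' where Phi_m averages log of the self-match-inclusive match frequency
#' of each length-m template. When no (m+1)-matches exist the sample
#' entropy is returned at its maximum attainable value
#' ln((N-m)(N-m-1)) - ln 2 (flagged via attribute `capped`) rather than
#' infinity.
#'
#' @param x numeric sample vector, length > m + 1.
#' @param m embedding (template) length, default 2.
#' @param r match tolerance in the units of `x` (a common choice is
#'   0.2 * sd(x), which [extractFeatures()] applies).
#' @return named numeric vector `c(se = ..., ae = ...)` with attribute
#'   `capped` (TRUE if the sample-entropy cap was hit).
#' @examples
#' x <- sin(seq(0, 8 * pi, length.out = 200))
#' entropyFeatures(x, m = 2, r = 0.2 * sd(x))
#' @export
entropyFeatures <- function(x, m = 2, r) {
  n <- length(x)
  if (n <= m + 1) stop("need more than m + 1 samples")
  if (r < 0) stop("tolerance r must be non-negative")
  if (!all(is.finite(x))) stop("non-finite samples in input")

  d0 <- abs(outer(x, x, "-"))

  chebMatch <- function(mm) {
    k <- n - mm + 1L
    D <- d0[seq_len(k), seq_len(k)]
    if (mm > 1) for (l in seq_len(mm - 1L))
      D <- pmax(D, d0[(1L + l):(k + l), (1L + l):(k + l)])
    D <= r
  }

  Mm <- chebMatch(m)
  Mm1 <- chebMatch(m + 1L)

  # SampEn: restrict both template lengths to the first n - m positions
  idx <- seq_len(n - m)
  B <- sum(Mm[idx, idx]) - length(idx)          # exclude self-matches
  A <- sum(Mm1) - (n - m)
  capped <- FALSE
  if (A == 0 || B == 0) {
    se <- log((n - m) * (n - m - 1)) - log(2)
    capped <- TRUE
  } else {
    se <- -log(A / B)
  }

  # ApEn: self-matches included, all templates of each length
  phi <- function(M) mean(log(rowSums(M) / nrow(M)))
  ae <- phi(Mm) - phi(Mm1)

  structure(c(se = se, ae = ae), capped = capped)
}
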