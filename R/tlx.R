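#' @importFrom stats aov t.test
NULL

tlxSubscales <- c("mental", "physical", "temporal", "effort",
                  "frustration", "performance")

#' Default NASA-TLX phase-by-subscale rating means (0-100)
#'
#' Phase-wise subscale means of the simulated-flight survey: landing is
#' the most demanding phase on every demand-related subscale, cruise the
#' least, and perceived performance runs in the opposite direction.
#'
#' @return numeric matrix, phases x subscales.
#' @export
defaultTLXMeans <- function() {
  m <- rbind(
    "landing"  = c(74, 43, 64, 52, 36, 64),
    "take-off" = c(64, 42, 68, 50, 32, 70),
    "cruise"   = c(46, 41, 51, 45, 25, 78))
  colnames(m) <- tlxSubscales
  m
}

#' Default NASA-TLX phase-by-subscale dispersions
#'
#' Dispersions of the phase-wise subscale ratings, given as standard
#' errors of a 21-participant mean; [tlxConfig()] converts them to
#' per-participant standard deviations when `dispersionIs = "se"`.
#'
#' @return numeric matrix, phases x subscales (same layout as
#'   [defaultTLXMeans()]).
#' @export
defaultTLXSE <- function() {
  m <- rbind(
    "landing"  = c(1.14, 1.69, 1.50, 0.91, 1.48, 1.79),
    "take-off" = c(1.29, 1.56, 1.31, 1.33, 1.40, 1.32),
    "cruise"   = c(1.53, 1.36, 1.56, 1.46, 1.26, 1.48))
  colnames(m) <- tlxSubscales
  m
}

#' Default pairwise-comparison subscale weights
#'
#' Fixed tallies over the 15 pairwise comparisons of the six subscales,
#' emphasising the demand-related subscales; tallies sum to 15.
#'
#' @return named numeric vector over the six subscales.
#' @export
defaultTLXWeights <- function() {
  c(mental = 5, physical = 1, temporal = 2, effort = 4,
    frustration = 2, performance = 1)
}

#' NASA-TLX simulation configuration
#'
#' @param means phases x subscales matrix of rating means on 0-100.
#' @param dispersion phases x subscales matrix of dispersions.
#' @param dispersionIs either "se" (dispersion is the standard error of
#'   an `nRef`-participant mean; per-participant SD = dispersion *
#'   sqrt(nRef)) or "sd" (dispersion is the per-participant SD directly).
#'   The survey's printed plus/minus values do not state which; both are
#'   supported.
#' @param nRef reference sample size for the "se" interpretation.
#' @param weights named tallies over 15 pairwise comparisons (sum 15).
#' @param seed integer RNG seed.
#' @return a validated list of class `TLXConfig`.
#' @export
tlxConfig <- function(means = defaultTLXMeans(),
                      dispersion = defaultTLXSE(),
                      dispersionIs = c("se", "sd"),
                      nRef = 21,
                      weights = defaultTLXWeights(),
                      seed = 1L) {
  dispersionIs <- match.arg(dispersionIs)
  if (any(means < 0 | means > 100))
    stop("TLX rating means must lie in [0, 100]")
  if (any(dispersion < 0)) stop("dispersions must be non-negative")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 15) > 1e-9)
    stop("pairwise weight tallies must sum to 15")
  if (!identical(dim(means), dim(dispersion)))
    stop("means and dispersion must have the same layout")
  structure(list(means = means, dispersion = dispersion,
                 dispersionIs = dispersionIs, nRef = nRef,
                 weights = weights, seed = as.integer(seed)),
            class = "TLXConfig")
}

#' Simulate NASA-TLX survey records
#'
#' Draws one record per participant and phase: six subscale ratings from
#' truncated normal distributions at the configured means, the pairwise
#' weights, and the weighted workload score.
#'
#' @param config a `TLXConfig` from [tlxConfig()].
#' @param nParticipants number of participants (>= 1).
#' @param aggregator passed to [tlxWeightedScore()].
#' @return data.frame with columns `participant`, `phase`, the six
#'   subscale ratings, and `weighted_score`; the weights are attached as
#'   attribute `"weights"`.
#' @export
simulateTLX <- function(config, nParticipants,
                        aggregator = c("standard", "sum")) {
  stopifnot(inherits(config, "TLXConfig"), nParticipants >= 1)
  aggregator <- match.arg(aggregator)
  sdMat <- config$dispersion
  if (config$dispersionIs == "se") sdMat <- sdMat * sqrt(config$nRef)
  phases <- rownames(config$means)
  withSeed(config$seed, {
    out <- expand.grid(participant = seq_len(nParticipants),
                       phase = phases, stringsAsFactors = FALSE)
    for (s in tlxSubscales) out[[s]] <- NA_real_
    for (p in phases) {
      rows <- out$phase == p
      for (s in tlxSubscales) {
        x <- rnorm(sum(rows), config$means[p, s], sdMat[p, s])
        out[[s]][rows] <- pmin(100, pmax(0, x))
      }
    }
    out$weighted_score <- apply(out[, tlxSubscales], 1, function(r)
      tlxWeightedScore(r, config$weights, aggregator))
    attr(out, "weights") <- config$weights
    out
  })
}

#' Simulate phase-level NASA-TLX weighted scores directly
#'
#' Some survey summaries are reported only at the weighted-score level
#' (and on a scale exceeding 0-100, so not reachable by the standard
#' aggregator); this generator draws the per-participant weighted scores
#' directly at given phase means, for use with
#' [testPhaseDifferences()] and [assignLabels()].
#'
#' @param means named numeric vector of phase score means (default: the
#'   study's phase means 145.53 / 105.6 / 65.6 for landing / take-off /
#'   cruise).
#' @param se named standard errors of the phase means at `nRef`
#'   participants.
#' @param nRef reference sample size behind `se`.
#' @param n participants to draw.
#' @param seed integer RNG seed.
#' @return data.frame `participant`, `phase`, `weighted_score`.
#' @export
simulateTLXScores <- function(means = c("landing" = 145.53,
                                        "take-off" = 105.6,
                                        "cruise" = 65.6),
                              se = c("landing" = 1.13,
                                     "take-off" = 1.29,
                                     "cruise" = 1.37),
                              nRef = 21, n = 21, seed = 1L) {
  stopifnot(n >= 1, all(names(means) %in% names(se)) || is.null(names(se)))
  withSeed(seed, {
    out <- expand.grid(participant = seq_len(n), phase = names(means),
                       stringsAsFactors = FALSE)
    sds <- se[names(means)] * sqrt(nRef)
    out$weighted_score <- rnorm(nrow(out),
                                mean = means[out$phase],
                                sd = sds[out$phase])
    out
  })
}

#' NASA-TLX weighted workload score
#'
#' The standard aggregation divides the weighted sum of the six subscale
#' ratings by the 15 pairwise comparisons, keeping the score on 0-100.
#' An alternative plain weighted sum (no division) is provided because
#' some phase-level summaries are reported on a scale exceeding 100.
#'
#' @param ratings named numeric vector over the six subscales (0-100).
#' @param weights named tallies summing to 15.
#' @param aggregator "standard" (sum(r*w)/15) or "sum" (sum(r*w)).
#' @return the weighted score.
#' @examples
#' tlxWeightedScore(c(mental = 74, physical = 43, temporal = 64,
#'                    effort = 52, frustration = 36, performance = 64),
#'                  rep(2.5, 6))
#' @export
tlxWeightedScore <- function(ratings, weights = defaultTLXWeights(),
                             aggregator = c("standard", "sum")) {
  aggregator <- match.arg(aggregator)
  ratings <- unlist(ratings)
  if (!is.null(names(ratings))) {
    miss <- setdiff(tlxSubscales, names(ratings))
    if (length(miss))
      stop("missing subscale rating(s): ", paste(miss, collapse = ", "))
    ratings <- ratings[tlxSubscales]
    if (!is.null(names(weights))) weights <- weights[tlxSubscales]
  }
  if (length(ratings) != 6 || anyNA(ratings))
    stop("six complete subscale ratings are required")
  s <- sum(ratings * weights)
  if (aggregator == "standard") s / 15 else s
}
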