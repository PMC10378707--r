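#' @importFrom stats fft rnorm runif rpois
NULL

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default scalp montage of the 5-channel headset
#'
#' AF3/AF4 over the frontal lobe, T7/T8 over the temporal lobes and Pz,
#' the single posterior midline electrode, standing in for the occipital
#' region (10-20 system).
#'
#' @return named character vector mapping channel -> region.
#' @export
defaultChannelRegions <- function() {
  c(AF3 = "frontal", AF4 = "frontal",
    T7 = "temporal", T8 = "temporal",
    Pz = "occipital")
}

#' Default per-level oscillation amplitudes (uV RMS)
#'
#' A 3 x 3 x 6 array (MWL level x region x band) of band-limited
#' oscillation RMS amplitudes. Every cell carries a 2 uV baseline rhythm;
#' each workload level additionally expresses a distinctive pattern at
#' 20 uV RMS (twice the default 10 uV background RMS, the contrast at
#' which the class structure is recoverable downstream): strong occipital
#' alpha when demand is low (relaxed wakefulness), frontal theta plus
#' temporal low-beta at intermediate demand (working-memory engagement),
#' and frontal delta plus temporal high-beta under high demand
#' (effortful processing).
#'
#' @param baseline baseline rhythm RMS in uV for every cell.
#' @param boost RMS in uV of the level-specific rhythms.
#' @return numeric array with dimnames level (low/middle/high), region
#'   (frontal/temporal/occipital) and band (delta...gamma).
#' @export
defaultBandGain <- function(baseline = 2, boost = 20) {
  bands <- c("delta", "theta", "alpha", "beta1", "beta2", "gamma")
  g <- array(baseline,
             dim = c(3, 3, 6),
             dimnames = list(level = c("low", "middle", "high"),
                             region = c("frontal", "temporal", "occipital"),
                             band = bands))
  g["low", "occipital", "alpha"] <- boost
  g["middle", "frontal", "theta"] <- boost
  g["middle", "temporal", "beta1"] <- boost
  g["high", "frontal", "delta"] <- boost
  g["high", "temporal", "beta2"] <- boost
  g
}

#' Simulation configuration for synthetic EEG recordings
#'
#' Bundles everything [simulateRecording()] needs: montage, sampling
#' rate, per-phase durations and workload levels, the oscillation
#' amplitude table, background-noise parameters and artifact rate.
#'
#' @param channelRegions named character vector channel -> region
#'   (frontal/temporal/occipital).
#' @param fs sampling rate, Hz. Must exceed twice the highest band edge.
#' @param phaseDurations named numeric vector, seconds per phase; each
#'   must be at least one analysis window (2 s).
#' @param phaseLevels named character vector phase -> MWL level
#'   (low/middle/high); defaults to the study design (cruise low,
#'   take-off middle, landing high).
#' @param bandGain 3-d array as from [defaultBandGain()].
#' @param noiseAmp RMS of the 1/f background, uV.
#' @param noiseExponent spectral slope of the background (power ~
#'   1/f^noiseExponent).
#' @param artifactRate ocular-artifact transients per minute (frontal
#'   channels only).
#' @param artifactAmp artifact peak amplitude, uV.
#' @param seed integer RNG seed; identical configs give bit-identical
#'   recordings.
#' @return a validated list of class `SimConfig`.
#' @export
simConfig <- function(channelRegions = defaultChannelRegions(),
                      fs = 128,
                      phaseDurations = c("take-off" = 60, "cruise" = 60,
                                         "landing" = 60),
                      phaseLevels = c("take-off" = "middle",
                                      "cruise" = "low",
                                      "landing" = "high"),
                      bandGain = defaultBandGain(),
                      noiseAmp = 10,
                      noiseExponent = 1,
                      artifactRate = 4,
                      artifactAmp = 150,
                      seed = 1L) {
  cfg <- structure(list(channelRegions = channelRegions, fs = fs,
                        phaseDurations = phaseDurations,
                        phaseLevels = phaseLevels, bandGain = bandGain,
                        noiseAmp = noiseAmp, noiseExponent = noiseExponent,
                        artifactRate = artifactRate,
                        artifactAmp = artifactAmp, seed = as.integer(seed)),
                   class = "SimConfig")
  errs <- validateSimConfig(cfg)
  if (length(errs)) stop("invalid SimConfig: ", paste(errs, collapse = "; "))
  cfg
}

validateSimConfig <- function(cfg) {
  errs <- character()
  bands <- defaultBands()
  if (cfg$fs <= 2 * max(bands$high_hz))
    errs <- c(errs, sprintf("fs must exceed 2 x %g Hz", max(bands$high_hz)))
  if (any(cfg$phaseDurations < 2))
    errs <- c(errs, "phaseDurations must each be at least 2 s (one window)")
  if (any(cfg$bandGain < 0) || cfg$noiseAmp < 0 || cfg$artifactAmp < 0)
    errs <- c(errs, "amplitudes must be non-negative")
  if (cfg$artifactRate < 0)
    errs <- c(errs, "artifactRate must be non-negative")
  if (!all(names(cfg$phaseDurations) %in% names(cfg$phaseLevels)))
    errs <- c(errs, "every phase needs an entry in phaseLevels")
  if (!all(cfg$phaseLevels %in% dimnames(cfg$bandGain)$level))
    errs <- c(errs, "phaseLevels must name rows of bandGain")
  if (!all(cfg$channelRegions %in% dimnames(cfg$bandGain)$region))
    errs <- c(errs, "channelRegions must name regions of bandGain")
  errs
}

# Gaussian 1/f^a background of n samples, scaled to target RMS.
# Synthesised in the frequency domain: amplitude ~ f^(-a/2), random phase.
pinkNoise <- function(n, fs, rms, exponent) {
  if (rms <= 0 || n < 2) return(numeric(n))
  freqs <- seq_len(floor(n / 2)) * fs / n
  amp <- freqs^(-exponent / 2)
  co <- amp * complex(real = rnorm(length(amp)),
                      imaginary = rnorm(length(amp)))
  spec <- complex(real = numeric(n))
  spec[2:(length(amp) + 1)] <- co
  spec[n:(n - length(amp) + 1)] <- Conj(co)[seq_along(amp)]
  if (n %% 2 == 0) spec[n / 2 + 1] <- complex(real = rnorm(1) * amp[n / 2])
  x <- Re(fft(spec, inverse = TRUE)) / n
  s <- sqrt(mean(x^2))
  if (s == 0) return(numeric(n))
  x * (rms / s)
}

# Band-limited Gaussian oscillation: random Gaussian spectrum restricted
# to [low, high] Hz, scaled to target RMS. Random per-bin amplitudes give
# periodogram estimates realistic variance (unlike a pure tone).
bandNoise <- function(n, fs, rms, low, high) {
  if (rms <= 0 || n < 2) return(numeric(n))
  freqs <- seq_len(floor(n / 2)) * fs / n
  sel <- which(freqs >= low & freqs <= high)
  if (!length(sel)) return(numeric(n))
  co <- complex(real = rnorm(length(sel)), imaginary = rnorm(length(sel)))
  spec <- complex(real = numeric(n))
  spec[sel + 1] <- co
  spec[n - sel + 1] <- Conj(co)
  x <- Re(fft(spec, inverse = TRUE)) / n
  s <- sqrt(mean(x^2))
  if (s == 0) return(numeric(n))
  x * (rms / s)
}

# Half-second raised-cosine ocular transient, peak `amp` uV.
eogPulse <- function(fs, amp, durS = 0.5) {
  n <- round(durS * fs)
  amp * 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
}

#' Generate a synthetic annotated EEG recording
#'
#' Produces one contiguous multichannel recording whose phases carry the
#' band-power structure encoded in the configuration: per phase and
#' channel, a 1/f Gaussian background plus one band-limited Gaussian
#' oscillation per frequency band at the RMS given by
#' `bandGain[level, region, band]`, plus occasional high-amplitude
#' low-frequency ocular transients on frontal channels. Deterministic
#' under the config seed.
#'
#' @param config a `SimConfig` from [simConfig()].
#' @return an [EEGRecording-class] with one annotation per phase.
#' @examples
#' rec <- simulateRecording(simConfig(phaseDurations = c(
#'   "take-off" = 10, "cruise" = 10, "landing" = 10)))
#' rec
#' @export
simulateRecording <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  errs <- validateSimConfig(config)
  if (length(errs)) stop("invalid SimConfig: ", paste(errs, collapse = "; "))
  fs <- config$fs
  bands <- defaultBands()
  chans <- names(config$channelRegions)
  phases <- names(config$phaseDurations)
  withSeed(config$seed, {
    pieces <- vector("list", length(phases))
    ann <- data.frame(phase = phases, start_s = NA_real_, end_s = NA_real_,
                      stringsAsFactors = FALSE)
    t0 <- 0
    for (p in seq_along(phases)) {
      dur <- config$phaseDurations[[p]]
      n <- round(dur * fs)
      level <- config$phaseLevels[[phases[p]]]
      mat <- matrix(0, nrow = length(chans), ncol = n,
                    dimnames = list(chans, NULL))
      for (ci in seq_along(chans)) {
        region <- config$channelRegions[[ci]]
        x <- pinkNoise(n, fs, config$noiseAmp, config$noiseExponent)
        for (b in seq_len(nrow(bands))) {
          x <- x + bandNoise(n, fs,
                             config$bandGain[level, region, bands$name[b]],
                             bands$low_hz[b], bands$high_hz[b])
        }
        if (region == "frontal" && config$artifactRate > 0 &&
            config$artifactAmp > 0) {
          k <- rpois(1, config$artifactRate * dur / 60)
          if (k > 0) {
            pulse <- eogPulse(fs, config$artifactAmp)
            starts <- floor(runif(k, 1, max(2, n - length(pulse))))
            for (s in starts) {
              idx <- s:(s + length(pulse) - 1)
              idx <- idx[idx <= n]
              x[idx] <- x[idx] + pulse[seq_along(idx)]
            }
          }
        }
        mat[ci, ] <- x
      }
      pieces[[p]] <- mat
      ann$start_s[p] <- t0
      ann$end_s[p] <- t0 + n / fs
      t0 <- t0 + n / fs
    }
    new("EEGRecording",
        samples = do.call(cbind, pieces),
        fs = fs, channelNames = chans, annotations = ann,
        provenance = list(simulated = TRUE, seed = config$seed))
  })
}
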