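# Small fixture builders used across the suite. Everything is generated
# in code; no data files.

# A recording holding an arbitrary channels x time matrix.
makeRecording <- function(x, fs = 128, channels = NULL, phases = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(x)))
  rownames(x) <- channels
  dur <- ncol(x) / fs
  if (is.null(phases))
    phases <- data.frame(phase = "task", start_s = 0, end_s = dur,
                         stringsAsFactors = FALSE)
  new("EEGRecording", samples = x, fs = fs, channelNames = channels,
      annotations = phases, provenance = list())
}

# Single-phase all-zero recording of n seconds (windowing-law checks).
silentRecording <- function(nSeconds, fs = 128, channels = 1) {
  makeRecording(matrix(0, channels, round(nSeconds * fs)), fs = fs)
}

# Sinusoid at a given frequency, 1 channel.
toneRecording <- function(freq, durS = 10, fs = 128, amp = 1) {
  t <- (seq_len(round(durS * fs)) - 1) / fs
  makeRecording(amp * sin(2 * pi * freq * t), fs = fs)
}

# EpochSet wrapping a channels x time x epochs array directly.
makeEpochSet <- function(arr, fs = 128, phases = NULL) {
  stopifnot(length(dim(arr)) == 3)
  chans <- dimnames(arr)[[1]]
  if (is.null(chans)) {
    chans <- paste0("ch", seq_len(dim(arr)[1]))
    dimnames(arr)[[1]] <- chans
  }
  n <- dim(arr)[3]
  if (is.null(phases)) phases <- rep("task", n)
  info <- data.frame(epoch_id = seq_len(n), phase = phases,
                     start_s = (seq_len(n) - 1) * dim(arr)[2] / fs,
                     quality = "pass", reason = "",
                     stringsAsFactors = FALSE)
  new("EpochSet", samples = arr, fs = fs, channelNames = chans,
      info = info, provenance = list())
}

# Gaussian 3-class feature matrix with `nInf` informative columns
# (class-shifted means) and `nNoise` pure-noise columns.
makeClassData <- function(n = 150, nInf = 2, nNoise = 4, sep = 2,
                          seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("low", "middle", "high"), length.out = n),
              levels = c("low", "middle", "high"))
  shift <- (as.integer(y) - 2) * sep
  x <- cbind(
    matrix(rnorm(n * nInf) + shift, n, nInf),
    if (nNoise > 0) matrix(rnorm(n * nNoise), n, nNoise))
  colnames(x) <- c(paste0("inf", seq_len(nInf)),
                   if (nNoise > 0) paste0("noise", seq_len(nNoise)))
  list(x = x, y = y)
}

# Literal O(n^2) nested-loop sample/approximate entropy (oracle).
bruteEntropy <- function(x, m, r) {
  n <- length(x)
  maxdist <- function(i, j, mm) {
    d <- 0
    for (l in 0:(mm - 1)) d <- max(d, abs(x[i + l] - x[j + l]))
    d
  }
  # SampEn: ordered pairs i != j over the first n - m template starts
  B <- 0; A <- 0
  for (i in seq_len(n - m)) for (j in seq_len(n - m)) {
    if (i == j) next
    if (maxdist(i, j, m) <= r) B <- B + 1
    if (maxdist(i, j, m + 1) <= r) A <- A + 1
  }
  se <- if (A == 0 || B == 0) log((n - m) * (n - m - 1)) - log(2)
        else -log(A / B)
  # ApEn: self-matches included, all templates of each length
  phi <- function(mm) {
    k <- n - mm + 1
    tot <- 0
    for (i in seq_len(k)) {
      c_i <- 0
      for (j in seq_len(k)) if (maxdist(i, j, mm) <= r) c_i <- c_i + 1
      tot <- tot + log(c_i / k)
    }
    tot / k
  }
  ae <- phi(m) - phi(m + 1)
  c(se = se, ae = ae)
}

# Hand-computed Kruskal-Wallis H with tie correction (oracle).
handKW <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, 0L))
  N <- length(x)
  rk <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(rk, g, function(r) length(r) * (mean(r) - (N + 1) / 2)^2))
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / corr
}
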