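test_that("DFT of simple signals matches closed forms", {
  # constant vector: DC bin N*c, all others zero
  sp <- fftSpectrum(rep(3, 64), fs = 128)
  expect_equal(Mod(sp$coefficients[1]), 64 * 3)
  expect_lt(max(Mod(sp$coefficients[-1])), 1e-9)

  # on-bin 8 Hz cosine, N = 256 at 128 Hz: peak exactly at k = 16
  t <- (0:255) / 128
  sp <- fftSpectrum(cos(2 * pi * 8 * t), fs = 128)
  mags <- Mod(sp$coefficients)
  peaks <- which(mags > 1e-6)
  expect_equal(sort(peaks), c(17L, 241L))   # k = 16 and its mirror
  expect_equal(mags[17], 256 / 2)
  expect_equal(sp$freqs[17], 8)

  # Parseval on random vectors
  set.seed(1)
  for (i in 1:5) {
    x <- rnorm(200)
    sp <- fftSpectrum(x, fs = 128)
    expect_equal(sum(x^2), sum(Mod(sp$coefficients)^2) / 200)
  }

  expect_error(fftSpectrum(c(1, NA, 3), 128), "non-finite")
})

test_that("band powers follow the periodogram convention", {
  expect_true(all(bandPowers(fftSpectrum(rep(0, 256), 128)) == 0))

  # on-bin 10 Hz cosine: alpha carries >= 95% of total power
  t <- (0:255) / 128
  bp <- bandPowers(fftSpectrum(cos(2 * pi * 10 * t), 128))
  expect_gt(bp["alpha"] / sum(bp), 0.95)
  expect_true(all(bp[names(bp) != "alpha"] <= 0.05 * sum(bp)))

  # white noise: band powers proportional to band widths
  set.seed(2)
  acc <- 0
  for (i in 1:10000)
    acc <- acc + bandPowers(fftSpectrum(rnorm(256), 128))
  bands <- defaultBands()
  nbins <- vapply(seq_len(nrow(bands)), function(b)
    sum(seq(0, 64, by = 0.5) >= bands$low_hz[b] &
        seq(0, 64, by = 0.5) <= bands$high_hz[b]), 0)
  ratio <- (acc / nbins) / mean(acc / nbins)
  expect_true(all(abs(ratio - 1) < 0.05))
})

test_that("band power integration conserves total power (Parseval)", {
  set.seed(3)
  x <- rnorm(255)            # odd length: every bin lies below Nyquist
  sp <- fftSpectrum(x, 128)
  # total integrated one-sided PSD equals the mean square of the signal
  allBand <- data.frame(name = "all", low_hz = 0, high_hz = 63.99)
  expect_equal(unname(bandPowers(sp, allBand)), mean(x^2),
               tolerance = 1e-9)
})

test_that("time-domain features match analytic values", {
  # constant vector
  td <- timeDomainFeatures(rep(-4, 100))
  expect_equal(unname(td[c("mean", "vari", "std", "ptp", "rms", "zc")]),
               c(-4, 0, 0, 0, 4, 0))
  expect_true(attr(td, "degenerate"))

  # 20-cycle unit sine over the window: rms = 1/sqrt(2), zc = 40
  t <- (0:255) / 128
  td <- timeDomainFeatures(sin(2 * pi * 10 * t))
  expect_equal(unname(td["rms"]), 1 / sqrt(2), tolerance = 0.01)
  expect_true(abs(td["zc"] - 40) <= 1)

  # alternating +1/-1: zc = n - 1 and maximal Hjorth mobility among
  # all +/-1 sequences (brute force over length-10 sign sequences)
  alt <- rep(c(1, -1), 10)
  tdAlt <- timeDomainFeatures(alt)
  expect_equal(unname(tdAlt["zc"]), length(alt) - 1)
  hmAlt <- unname(timeDomainFeatures(rep(c(1, -1), 5))["hm"])
  grid <- expand.grid(rep(list(c(-1, 1)), 10))
  hms <- apply(grid, 1, function(s)
    if (var(s) < 1e-12) 0 else sqrt(var(diff(s)) / var(s)))
  expect_equal(hmAlt, max(hms), tolerance = 1e-9)
})

test_that("features transform correctly under amplitude scaling", {
  set.seed(4)
  x <- rnorm(256)
  c0 <- 3.7
  a <- timeDomainFeatures(x)
  b <- timeDomainFeatures(c0 * x)
  expect_equal(unname(b[c("mean", "std", "ptp", "rms")]),
               unname(c0 * a[c("mean", "std", "ptp", "rms")]))
  expect_equal(unname(b["vari"]), unname(c0^2 * a["vari"]))
  inv <- c("skewness", "kurtosis", "zc", "hm", "hc")
  expect_equal(unname(b[inv]), unname(a[inv]), tolerance = 1e-9)
  # band powers scale with c^2
  bp1 <- bandPowers(fftSpectrum(x, 128))
  bp2 <- bandPowers(fftSpectrum(c0 * x, 128))
  expect_equal(unname(bp2), unname(c0^2 * bp1), tolerance = 1e-9)
  # entropies invariant when r scales with the signal
  e1 <- entropyFeatures(x, 2, 0.2 * sd(x))
  e2 <- entropyFeatures(c0 * x, 2, 0.2 * sd(c0 * x))
  expect_equal(unname(e1), unname(e2), tolerance = 1e-9)
})

test_that("entropies equal the brute-force definitions", {
  # constant vector: everything matches, both entropies zero
  e <- entropyFeatures(rep(1, 50), 2, 0.2)
  expect_equal(unname(e["se"]), 0)
  expect_equal(unname(e["ae"]), 0, tolerance = 1e-9)

  set.seed(5)
  for (i in 1:8) {
    n <- sample(30:120, 1)
    x <- rnorm(n)
    r <- 0.2 * sd(x)
    expect_equal(as.numeric(entropyFeatures(x, 2, r)),
                 as.numeric(bruteEntropy(x, 2, r)), tolerance = 1e-12)
  }
  # also at m = 3
  x <- rnorm(80)
  expect_equal(as.numeric(entropyFeatures(x, 3, 0.3)),
               as.numeric(bruteEntropy(x, 3, 0.3)), tolerance = 1e-12)
})

test_that("periodic signals are more regular than their shuffles", {
  set.seed(6)
  wins <- 0
  for (s in 1:100) {
    motif <- rnorm(5)
    x <- rep(motif, 40)
    y <- sample(x)
    r <- 0.2 * sd(x)
    seP <- entropyFeatures(x, 2, r)["se"]
    seS <- entropyFeatures(y, 2, r)["se"]
    if (seP < seS) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("feature table layout matches the 18-per-channel schema", {
  set.seed(7)
  arr5 <- array(rnorm(5 * 256 * 4, sd = 10), c(5, 256, 4),
                dimnames = list(c("AF3", "AF4", "T7", "T8", "Pz"),
                                NULL, NULL))
  fe <- extractFeatures(makeEpochSet(arr5))
  expect_equal(nrow(fe), 90)
  expect_equal(ncol(fe), 4)
  expect_equal(ncol(featureMatrix(fe, "psd")), 30)
  expect_equal(ncol(featureMatrix(fe, "calculative")), 60)
  expect_true("AF4-delta" %in% rownames(fe))
  expect_true("Pz-se" %in% rownames(fe))
  expect_true("T7-rms" %in% rownames(fe))

  arr1 <- array(rnorm(256 * 3), c(1, 256, 3))
  fe1 <- extractFeatures(makeEpochSet(arr1))
  expect_equal(nrow(fe1), 18)
})

test_that("a 60 s phase produces a 59-row feature table", {
  set.seed(8)
  rec <- makeRecording(matrix(rnorm(2 * 60 * 128, sd = 5), 2))
  fe <- extractFeatures(segmentEpochs(rec))
  expect_equal(ncol(fe), 59)
})
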