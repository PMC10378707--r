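test_that("metrics are exact on constructed confusion counts", {
  # perfect predictions
  y <- factor(rep(c("low", "middle", "high"), 10))
  m <- computeMetrics(y, y)
  expect_equal(c(m$accuracy, m$precision, m$recall, m$f1),
               c(1, 1, 1, 1))

  # one-vs-rest cell counts TP=50 FP=10 FN=20 TN=120 for class A
  truth <- c(rep("A", 70), rep("B", 130))
  pred <- c(rep("A", 50), rep("B", 20),      # 50 TP, 20 FN
            rep("A", 10), rep("B", 120))     # 10 FP, 120 TN
  m2 <- computeMetrics(pred, truth)
  rowA <- m2$perClass[m2$perClass$class == "A", ]
  expect_equal(rowA$precision, 50 / 60)
  expect_equal(rowA$recall, 50 / 70)
  expect_equal(m2$accuracy, 170 / 200)
})

test_that("metrics match a brute-force confusion computation", {
  set.seed(1)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    n <- sample(10:50, 1)
    classes <- LETTERS[1:k]
    truth <- sample(classes, n, TRUE)
    pred <- sample(classes, n, TRUE)
    m <- computeMetrics(pred, truth)
    # oracle: explicit per-class confusion cells
    precs <- recs <- f1s <- numeric(0)
    for (cl in sort(unique(c(truth, pred)))) {
      tp <- sum(pred == cl & truth == cl)
      fp <- sum(pred == cl & truth != cl)
      fn <- sum(pred != cl & truth == cl)
      p <- if (tp + fp > 0) tp / (tp + fp) else 0
      r <- if (tp + fn > 0) tp / (tp + fn) else 0
      precs <- c(precs, p); recs <- c(recs, r)
      f1s <- c(f1s, if (p + r > 0) 2 * p * r / (p + r) else 0)
    }
    expect_equal(m$accuracy, mean(pred == truth))
    expect_equal(m$precision, mean(precs))
    expect_equal(m$recall, mean(recs))
    expect_equal(m$f1, mean(f1s))
  }
})

test_that("random predictions sit at the 3-class chance level", {
  set.seed(2)
  truth <- rep(c("low", "middle", "high"), length.out = 10000)
  pred <- sample(c("low", "middle", "high"), 10000, TRUE)
  m <- computeMetrics(pred, truth)
  expect_lt(abs(m$accuracy - 1 / 3), 0.02)
})

test_that("the accuracy-based F1 variant is exposed behind a flag", {
  truth <- c(rep("A", 70), rep("B", 130))
  pred <- c(rep("A", 50), rep("B", 20), rep("A", 10), rep("B", 120))
  std <- computeMetrics(pred, truth, f1 = "standard")
  alt <- computeMetrics(pred, truth, f1 = "accuracy")
  acc <- 170 / 200
  rowA <- alt$perClass[alt$perClass$class == "A", ]
  expect_equal(rowA$f1, 2 * acc * (50 / 70) / (acc + 50 / 70))
  expect_false(isTRUE(all.equal(std$f1, alt$f1)))
})

test_that("cross-validation separates well-separated classes", {
  set.seed(3)
  n <- 300
  y <- factor(rep(c("low", "middle", "high"), each = n / 3),
              levels = c("low", "middle", "high"))
  x <- cbind(rnorm(n) + (as.integer(y) - 2) * 6, rnorm(n))
  colnames(x) <- c("f1", "f2")
  cv <- crossValidate(x, y, classifierSpec("knn", k = 1), folds = 10,
                      seed = 1)
  expect_gte(cv$mean[["accuracy"]], 0.99)
})

test_that("permuted labels drop every classifier to chance", {
  set.seed(4)
  d <- makeClassData(n = 120, nInf = 2, nNoise = 2, sep = 3, seed = 5)
  yPerm <- sample(d$y)
  for (kind in c("knn", "rf", "svm-l")) {
    cv <- crossValidate(d$x, yPerm, classifierSpec(kind), folds = 5,
                        seed = 2)
    expect_lt(abs(cv$mean[["accuracy"]] - 1 / 3),
              max(3 * cv$sd[["accuracy"]], 0.12),
              label = paste(kind, "permuted accuracy"))
  }
})

test_that("cross-validation is deterministic under a fixed seed", {
  d <- makeClassData(n = 90, seed = 6)
  cv1 <- crossValidate(d$x, d$y, folds = 5, seed = 7)
  cv2 <- crossValidate(d$x, d$y, folds = 5, seed = 7)
  expect_identical(cv1$mean, cv2$mean)
  expect_identical(cv1$folds, cv2$folds)
})

test_that("all six classifier kinds train and predict", {
  d <- makeClassData(n = 60, nInf = 2, nNoise = 1, sep = 4, seed = 8)
  for (kind in c("knn", "rf", "svm-l", "svm-r", "svm-p")) {
    cv <- crossValidate(d$x, d$y, classifierSpec(kind), folds = 3,
                        seed = 3)
    expect_gte(cv$mean[["accuracy"]], 0.5, label = kind)
  }
  spec <- classifierSpec("bnn", bnn = list(hidden = c(20, 20),
                                           epochs = 150))
  cv <- crossValidate(d$x, d$y, spec, folds = 3, seed = 3)
  expect_gte(cv$mean[["accuracy"]], 0.5, label = "bnn")
})

test_that("the Bayesian network fits separable classes", {
  d <- makeClassData(n = 150, nInf = 3, nNoise = 0, sep = 4, seed = 9)
  x <- zscoreFeatures(d$x)
  fit <- trainBNN(x, d$y, hidden = c(50, 50), epochs = 500, seed = 1)
  pred <- predictBNN(fit, x, mcSamples = 50)$class
  expect_gte(mean(pred == d$y), 0.95)
  # loss decreases over training
  n0 <- mean(head(fit$lossTrace, 20))
  n1 <- mean(tail(fit$lossTrace, 20))
  expect_lt(n1, n0)
})

test_that("more MC samples stabilize the predictive distribution", {
  d <- makeClassData(n = 90, nInf = 2, nNoise = 1, sep = 1, seed = 10)
  x <- zscoreFeatures(d$x)
  fit <- trainBNN(x, d$y, hidden = c(30, 30), epochs = 200, seed = 2)
  # repeated prediction of one sample: probability spread shrinks with
  # the number of stochastic passes averaged
  spread <- function(mc) {
    p <- vapply(1:30, function(s)
      predictBNN(fit, x[1, , drop = FALSE], mcSamples = mc,
                 seed = s)$probs[1, 1], 0)
    sd(p)
  }
  expect_lt(spread(50), spread(2))
})

test_that("region-band harness selects the right columns", {
  set.seed(11)
  arr <- array(rnorm(5 * 256 * 30, sd = 10), c(5, 256, 30),
               dimnames = list(c("AF3", "AF4", "T7", "T8", "Pz"),
                               NULL, NULL))
  fe <- extractFeatures(makeEpochSet(arr, phases = rep(
    c("take-off", "cruise", "landing"), each = 10)))
  fe <- assignLabels(c("landing" = "high", "take-off" = "middle",
                       "cruise" = "low"), fe)
  tab <- regionBandHarness(fe, folds = 3, seed = 1)
  occMix <- tab[tab$region == "occipital" & tab$band == "mix", ]
  expect_equal(occMix$nFeatures, 6)         # 1 channel x 6 bands
  froDelta <- tab[tab$region == "frontal" & tab$band == "delta", ]
  expect_equal(froDelta$nFeatures, 2)       # AF3-delta, AF4-delta
  allMix <- tab[tab$region == "all" & tab$band == "mix", ]
  expect_equal(allMix$nFeatures, 30)
})

test_that("planted temporal contrasts make the temporal region win", {
  wins <- 0
  for (s in 1:3) {
    g <- defaultBandGain(2, 2)
    g["low", "temporal", "alpha"] <- 20
    g["middle", "temporal", "beta1"] <- 20
    g["high", "temporal", "beta2"] <- 20
    cfg <- simConfig(bandGain = g, artifactRate = 0,
                     phaseDurations = c("take-off" = 30, "cruise" = 30,
                                        "landing" = 30), seed = 100 + s)
    ep <- segmentEpochs(lowpassFilter(simulateRecording(cfg)))
    fe <- extractFeatures(ep)
    fe <- assignLabels(c("landing" = "high", "take-off" = "middle",
                         "cruise" = "low"), fe)
    tab <- regionBandHarness(fe, folds = 5, seed = s)
    tmp <- tab$accuracy[tab$region == "temporal" & tab$band == "mix"]
    occ <- tab$accuracy[tab$region == "occipital" & tab$band == "mix"]
    if (tmp > occ) wins <- wins + 1
  }
  expect_equal(wins, 3)
})
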