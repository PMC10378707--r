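test_that("normality screen is calibrated under Gaussian draws", {
  set.seed(1)
  rej <- 0
  for (s in 1:200) {
    m <- matrix(rnorm(500), ncol = 1, dimnames = list(NULL, "f"))
    if (!normalityScreen(m)$normal[1]) rej <- rej + 1
  }
  expect_gte(rej / 200, 0.02)
  expect_lte(rej / 200, 0.09)
  # strong power against exponential draws
  rejE <- 0
  for (s in 1:50) {
    m <- matrix(rexp(500), ncol = 1, dimnames = list(NULL, "f"))
    if (!normalityScreen(m)$normal[1]) rejE <- rejE + 1
  }
  expect_equal(rejE, 50)
  # constant column: degenerate, treated as non-normal
  res <- normalityScreen(matrix(1, 50, 1, dimnames = list(NULL, "c")))
  expect_true(res$degenerate[1])
  expect_false(res$normal[1])
})

test_that("Kruskal-Wallis H matches the hand rank formula", {
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), ncol = 1,
              dimnames = list(NULL, "f"))
  lab <- factor(rep(c("low", "middle", "high"), each = 3))
  sc <- kwScreen(m, lab)
  expect_equal(sc$table$H, 7.2)
  # random grouped data with ties, against the tie-corrected oracle
  set.seed(2)
  for (i in 1:10) {
    g <- list(sample(1:8, 7, TRUE), sample(1:8, 9, TRUE),
              sample(1:8, 8, TRUE))
    mm <- matrix(unlist(g), ncol = 1, dimnames = list(NULL, "f"))
    ll <- factor(rep(c("a", "b", "c"), times = c(7, 9, 8)))
    expect_equal(kwScreen(mm, ll)$table$H, handKW(g), tolerance = 1e-12)
  }
  # identical constant groups: H = 0
  mc <- matrix(5, 12, 1, dimnames = list(NULL, "f"))
  lc <- factor(rep(c("a", "b", "c"), each = 4))
  expect_equal(kwScreen(mc, lc)$table$H, 0)
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(3)
  x <- rnorm(60)
  lab <- factor(rep(c("a", "b", "c"), 20))
  h1 <- kwScreen(matrix(x, dimnames = list(NULL, "f")), lab)$table$H
  h2 <- kwScreen(matrix(exp(x), dimnames = list(NULL, "f")), lab)$table$H
  h3 <- kwScreen(matrix(x^3, dimnames = list(NULL, "f")), lab)$table$H
  expect_equal(h1, h2)
  expect_equal(h1, h3)
})

test_that("selected sets nest across significance levels", {
  d <- makeClassData(n = 120, nInf = 3, nNoise = 5, sep = 1, seed = 4)
  sc <- kwScreen(d$x, d$y)
  expect_true(all(sc$selected$alpha0.01 %in% sc$selected$alpha0.05))
  expect_true(all(sc$table$p >= 0 & sc$table$p <= 1))
  # planted informative features are caught, at least at 0.05
  expect_true(all(paste0("inf", 1:3) %in% sc$selected$alpha0.05))
})

test_that("null type-I rate of the screen is near alpha", {
  set.seed(5)
  hits <- 0
  for (i in 1:300) {
    m <- matrix(rnorm(60), ncol = 1, dimnames = list(NULL, "f"))
    lab <- factor(rep(c("a", "b", "c"), 20))
    if (kwScreen(m, lab)$table$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 300, 0.02)
  expect_lte(hits / 300, 0.08)
})

test_that("z-scoring standardizes on the fitted rows only", {
  set.seed(6)
  m <- matrix(rnorm(200, 10, 3), 50, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  z <- zscoreFeatures(m)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-9)
  # affine-transformed copy standardizes identically
  m2 <- m; m2[, 2] <- 5 * m[, 1] - 7
  z2 <- zscoreFeatures(m2)
  expect_equal(z2[, 1], z2[, 2], ignore_attr = TRUE)
  # fit on train rows: test rows need not be (0, 1)
  zt <- zscoreFeatures(m, fitRows = 1:30)
  expect_lt(max(abs(colMeans(zt[1:30, ]))), 1e-9)
  expect_gt(max(abs(colMeans(zt[31:50, ]))), 1e-3)
  # zero-variance feature flagged and mapped to 0
  m3 <- cbind(m, const = 2)
  z3 <- zscoreFeatures(m3)
  expect_true("const" %in% attr(z3, "degenerate"))
  expect_true(all(z3[, "const"] == 0))
})

test_that("SFFS with one feature is a forced choice", {
  d <- makeClassData(n = 60, nInf = 1, nNoise = 0, sep = 2, seed = 7)
  tr <- sffs(d$x, d$y, folds = 5, seed = 1)
  expect_equal(tr$best$features, "inf1")
  cv <- crossValidate(d$x, d$y, folds = 5, seed = 1)
  expect_equal(tr$best$criterion, unname(cv$mean["accuracy"]))
})

test_that("SFFS matches exhaustive search on a 6-feature problem", {
  d <- makeClassData(n = 90, nInf = 2, nNoise = 4, sep = 2.5, seed = 8)
  folds <- 5; seed <- 3
  tr <- sffs(d$x, d$y, folds = folds, seed = seed)
  # exhaustive oracle with the identical estimator/folds/seed
  for (k in 1:6) {
    subs <- utils::combn(6, k)
    vals <- apply(subs, 2, function(cols)
      unname(crossValidate(d$x[, cols, drop = FALSE], d$y,
                           folds = folds, seed = seed)$mean["accuracy"]))
    best <- max(vals)
    got <- tr$bestBySize$criterion[tr$bestBySize$size == k]
    expect_equal(got, best, tolerance = 1e-12,
                 label = paste("criterion at size", k))
  }
})

test_that("inclusion order follows a strictly nested structure", {
  # f1 alone separates classes; f2 adds the remaining separation
  set.seed(9)
  n <- 90
  y <- factor(rep(c("low", "middle", "high"), each = n / 3),
              levels = c("low", "middle", "high"))
  f1 <- as.integer(y) * 4 + rnorm(n)            # separates all classes
  f2 <- (y == "middle") * 4 + rnorm(n)          # refines
  x <- cbind(f1 = f1, f2 = f2, n1 = rnorm(n), n2 = rnorm(n))
  tr <- sffs(x, y, folds = 5, seed = 2)
  inc <- tr$steps$feature[tr$steps$action == "include"]
  expect_identical(inc[1:2], c("f1", "f2"))
})

test_that("floating selection never trails plain forward selection", {
  d <- makeClassData(n = 90, nInf = 2, nNoise = 4, sep = 1, seed = 10)
  tr <- sffs(d$x, d$y, folds = 5, seed = 4)
  fw <- sfs(d$x, d$y, folds = 5, seed = 4)
  for (k in fw$size) {
    got <- tr$bestBySize$criterion[tr$bestBySize$size == k]
    expect_gte(got, fw$criterion[fw$size == k])
  }
})
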