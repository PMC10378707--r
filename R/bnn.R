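#' Train a Monte-Carlo-dropout Bayesian neural network
#'
#' A fully connected 3-layer network (inputs -> 200 -> 200 -> classes,
#' ReLU activations, dropout after each hidden activation) trained with
#' full-batch Adam on a variational objective: cross-entropy plus
#' `klWeight` times the Kullback-Leibler penalty of the weights against
#' a zero-mean Gaussian prior (sd `priorSd`), the standard dropout-based
#' variational approximation in which the KL term reduces to scaled
#' weight decay. Prediction averages the class probabilities of
#' `mcSamples` stochastic (dropout-active) forward passes. A plateau
#' scheduler halves the learning rate when the loss stalls.
#'
#' Features should be standardized before training (see
#' [zscoreFeatures()]); [crossValidate()] does this per fold.
#'
#' @param x numeric matrix, samples x features (standardized).
#' @param y class labels (factor or character).
#' @param hidden hidden layer sizes (default c(200, 200)).
#' @param dropout dropout probability after each hidden activation.
#' @param priorSd standard deviation of the Gaussian weight prior.
#' @param klWeight weight of the KL penalty (default 0.05; 0 reduces the
#'   model to an ordinary dropout MLP).
#' @param lr initial Adam learning rate (default 1e-3).
#' @param epochs training epochs (default 500; larger values trade time
#'   for a tighter fit).
#' @param mcSamples default number of stochastic forward passes at
#'   prediction time.
#' @param seed RNG seed for initialization and dropout masks.
#' @return object of class `bnnModel` with the weights, the per-epoch
#'   loss trace and the training configuration.
#' @export
trainBNN <- function(x, y, hidden = c(200, 200), dropout = 0.2,
                     priorSd = 0.1, klWeight = 0.05, lr = 1e-3,
                     epochs = 500, mcSamples = 50, seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y)
  classes <- levels(y)
  if (length(classes) < 2) stop("need at least 2 classes")
  n <- nrow(x)
  p <- ncol(x)
  sizes <- c(p, hidden, length(classes))
  L <- length(sizes) - 1L
  yIdx <- as.integer(y)
  Y <- matrix(0, n, length(classes))
  Y[cbind(seq_len(n), yIdx)] <- 1

  withSeed(seed, {
    W <- lapply(seq_len(L), function(l)
      matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0,
                          sqrt(2 / sizes[l])), sizes[l], sizes[l + 1]))
    b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mB <- lapply(b, function(bb) bb * 0); vB <- mB
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    lossTrace <- numeric(epochs)
    bestLoss <- Inf; sinceBest <- 0L
    curLr <- lr

    for (ep in seq_len(epochs)) {
      # forward with dropout on hidden activations
      acts <- list(x)
      masks <- list()
      for (l in seq_len(L - 1L)) {
        z <- acts[[l]] %*% W[[l]] + matrix(b[[l]], n, sizes[l + 1],
                                           byrow = TRUE)
        a <- pmax(z, 0)
        msk <- matrix(stats::runif(length(a)) >= dropout, nrow(a), ncol(a))
        a <- a * msk / (1 - dropout)
        masks[[l]] <- msk
        acts[[l + 1L]] <- a
      }
      logits <- acts[[L]] %*% W[[L]] + matrix(b[[L]], n, sizes[L + 1],
                                              byrow = TRUE)
      mx <- apply(logits, 1, max)
      ez <- exp(logits - mx)
      probs <- ez / rowSums(ez)
      ce <- -mean(log(pmax(probs[cbind(seq_len(n), yIdx)], 1e-12)))
      kl <- sum(vapply(W, function(w) sum(w^2), 0)) / (2 * priorSd^2)
      loss <- ce + klWeight * kl / n
      if (!is.finite(loss))
        stop("BNN training diverged (non-finite loss); config: lr=", lr,
             " klWeight=", klWeight, " dropout=", dropout)
      lossTrace[ep] <- loss

      # backward
      grad <- (probs - Y) / n
      gW <- vector("list", L); gB <- vector("list", L)
      for (l in rev(seq_len(L))) {
        gW[[l]] <- t(acts[[l]]) %*% grad + klWeight * W[[l]] / (priorSd^2 * n)
        gB[[l]] <- colSums(grad)
        if (l > 1) {
          grad <- grad %*% t(W[[l]])
          grad <- grad * masks[[l - 1L]] / (1 - dropout)
          grad <- grad * (acts[[l]] > 0)
        }
      }
      for (l in seq_len(L)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
        mB[[l]] <- beta1 * mB[[l]] + (1 - beta1) * gB[[l]]
        vB[[l]] <- beta2 * vB[[l]] + (1 - beta2) * gB[[l]]^2
        mhW <- mW[[l]] / (1 - beta1^ep); vhW <- vW[[l]] / (1 - beta2^ep)
        mhB <- mB[[l]] / (1 - beta1^ep); vhB <- vB[[l]] / (1 - beta2^ep)
        W[[l]] <- W[[l]] - curLr * mhW / (sqrt(vhW) + eps)
        b[[l]] <- b[[l]] - curLr * mhB / (sqrt(vhB) + eps)
      }

      # plateau scheduler
      if (loss < bestLoss - 1e-4) { bestLoss <- loss; sinceBest <- 0L }
      else sinceBest <- sinceBest + 1L
      if (sinceBest >= 50L) { curLr <- curLr / 2; sinceBest <- 0L }
    }

    structure(list(W = W, b = b, classes = classes, dropout = dropout,
                   priorSd = priorSd, klWeight = klWeight,
                   mcSamples = mcSamples, lossTrace = lossTrace,
                   seed = seed),
              class = "bnnModel")
  })
}

#' Predict from a Monte-Carlo-dropout network
#'
#' Averages the softmax outputs of `mcSamples` dropout-active forward
#' passes (the Monte Carlo approximation of the posterior predictive)
#' and returns the averaged probabilities and their argmax classes.
#'
#' @param model a `bnnModel` from [trainBNN()].
#' @param x samples x features matrix (same standardization as training).
#' @param mcSamples stochastic passes (default: the model's setting;
#'   1 disables averaging).
#' @param seed RNG seed for the dropout masks.
#' @return list with `probs` (samples x classes) and `class` (factor).
#' @export
predictBNN <- function(model, x, mcSamples = model$mcSamples, seed = 1L) {
  x <- as.matrix(x)
  L <- length(model$W)
  n <- nrow(x)
  acc <- matrix(0, n, length(model$classes))
  withSeed(seed, {
    for (s in seq_len(mcSamples)) {
      a <- x
      for (l in seq_len(L - 1L)) {
        z <- a %*% model$W[[l]] + matrix(model$b[[l]], n,
                                         ncol(model$W[[l]]), byrow = TRUE)
        a <- pmax(z, 0)
        if (mcSamples > 1) {
          msk <- matrix(stats::runif(length(a)) >= model$dropout,
                        nrow(a), ncol(a))
          a <- a * msk / (1 - model$dropout)
        }
      }
      logits <- a %*% model$W[[L]] + matrix(model$b[[L]], n,
                                            ncol(model$W[[L]]),
                                            byrow = TRUE)
      mx <- apply(logits, 1, max)
      ez <- exp(logits - mx)
      acc <- acc + ez / rowSums(ez)
    }
  })
  probs <- acc / mcSamples
  colnames(probs) <- model$classes
  list(probs = probs,
       class = factor(model$classes[max.col(probs)],
                      levels = model$classes))
}
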