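#' @include utils.R
NULL

# Conditional probabilities with per-point precision tuned by binary search
# to match the target perplexity.
.tsne_p <- function(D, perplexity, tol = 1e-5) {
  n <- nrow(D)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    Di <- D[i, -i]
    for (iter in 1:50) {
      Pi <- exp(-Di * beta)
      sP <- sum(Pi)
      if (sP == 0) { H <- 0; Pi[] <- 0 }
      else {
        H <- log(sP) + beta * sum(Di * Pi) / sP
        Pi <- Pi / sP
      }
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- Pi
  }
  P
}

#' t-SNE embedding of feature vectors
#'
#' Exact (quadratic-time) t-distributed stochastic neighbor embedding of
#' high-dimensional feature vectors into 2-D, with the standard early
#' exaggeration, momentum switch and adaptive gains schedule.  Deterministic
#' for a fixed seed.
#'
#' @param features n x d numeric matrix (e.g. penultimate-layer activations).
#' @param perplexity neighborhood size parameter; requires
#'   `n > 3 * perplexity`.
#' @param iterations gradient iterations (reference setting: 2000).
#' @param seed seed for the random initialization.
#' @param learningRate gradient step size.
#' @return n x 2 coordinate matrix.
#' @export
tsneEmbed <- function(features, perplexity = 64, iterations = 2000L,
                      seed = 1L, learningRate = 200) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n <= 3 * perplexity)
    .stopf("need n > 3 * perplexity (n = %d, perplexity = %g)", n, perplexity)
  sq <- rowSums(features^2)
  D <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(features), 0)
  P <- .tsne_p(D, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  .with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    iY <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    exaggeration <- 12
    momentum <- 0.5
    for (it in seq_len(iterations)) {
      if (it == 251L) { exaggeration <- 1; momentum <- 0.8 }
      sqy <- rowSums(Y^2)
      num <- 1 / (1 + outer(sqy, sqy, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      PQ <- (P * exaggeration - Q) * num
      dY <- 4 * (diag(rowSums(PQ)) - PQ) %*% Y
      gains <- ifelse(sign(dY) != sign(iY), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      iY <- momentum * iY - learningRate * gains * dY
      Y <- Y + iY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}
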