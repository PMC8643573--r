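# Extended-infomax independent component analysis.
# Natural-gradient block updates with per-component sub/super-Gaussian
# switching (the kurtosis-sign "extended" rule) and learning-rate annealing.

#' Extended-infomax ICA
#'
#' Decomposes a channels x samples matrix into independent components by
#' natural-gradient infomax with the extended (sub/super-Gaussian) rule:
#' each component carries a sign k (+1 super-Gaussian, -1 sub-Gaussian),
#' re-estimated from the sample kurtosis every few steps, and the unmixing
#' matrix is updated per data block as
#' W <- W + lr (I - K tanh(u) u' - u u') W on sphered data. The learning
#' rate is annealed on weight blow-up and the iteration stops when the
#' update norm falls below \code{tol}.
#'
#' @param x numeric matrix channels x samples (centered internally).
#' @param maxIter maximum passes over the data.
#' @param tol convergence tolerance on the relative weight change.
#' @param lrate initial learning rate.
#' @param blockSize samples per update block (default
#'   \code{ceiling(sqrt(nSamples / 3))}).
#' @param seed RNG seed for the block permutations.
#' @return list with \code{unmixing} (components x channels, includes
#'   sphering), \code{mixing} (its inverse), \code{sources} (components x
#'   samples), \code{converged}, \code{iterations}.
#' @export
extendedInfomax <- function(x, maxIter = 200, tol = 1e-6, lrate = NULL,
                            blockSize = NULL, seed = 1) {
  nCh <- nrow(x); n <- ncol(x)
  set.seed(seed)
  ctr <- rowMeans(x)
  xc <- x - ctr
  cv <- tcrossprod(xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  sphere <- eg$vectors %*% diag(1 / sqrt(pmax(eg$values, 1e-12))) %*%
    t(eg$vectors)
  xs <- sphere %*% xc

  if (is.null(blockSize)) blockSize <- ceiling(sqrt(n / 3))
  if (is.null(lrate)) lrate <- 0.00065 / log(nCh)
  W <- diag(nCh)
  I <- diag(nCh)
  signs <- rep(1, nCh)           # +1 super-Gaussian
  converged <- FALSE
  iter <- 0
  oldW <- W
  oldChange <- Inf
  while (iter < maxIter) {
    iter <- iter + 1
    perm <- sample.int(n)
    blown <- FALSE
    for (b in seq(1, n - blockSize + 1, by = blockSize)) {
      u <- W %*% xs[, perm[b:(b + blockSize - 1)], drop = FALSE]
      y <- tanh(u)
      W <- W + lrate * (blockSize * I - (y * signs) %*% t(u) -
                          u %*% t(u)) %*% W
      if (max(abs(W)) > 1e8) { blown <- TRUE; break }
    }
    if (blown) {
      lrate <- lrate / 2
      W <- diag(nCh)
      oldW <- W
      oldChange <- Inf
      next
    }
    # re-estimate sub/super-Gaussian signs from source kurtosis
    if (iter %% 3 == 0) {
      src <- W %*% xs
      kurt <- apply(src, 1, function(s) mean(s^4) / mean(s^2)^2 - 3)
      signs <- ifelse(kurt >= 0, 1, -1)
    }
    change <- sum((W - oldW)^2) / sum(W^2)
    if (change > oldChange) lrate <- lrate * 0.9   # anneal on oscillation
    oldChange <- change
    oldW <- W
    if (change < tol) { converged <- TRUE; break }
  }
  unmix <- W %*% sphere
  list(unmixing = unmix, mixing = solve(unmix),
       sources = unmix %*% xc, converged = converged, iterations = iter)
}
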