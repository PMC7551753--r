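# Independent oracles. These deliberately avoid the package's own code
# paths: the AUC oracle enumerates all (positive, negative) pairs; the
# logistic oracle scans a lattice of weight vectors and evaluates the
# penalized log-likelihood directly.

auc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

penalized_ll_oracle <- function(w, x, y, lambda) {
  eta <- drop(cbind(1, x) %*% w)
  sum(y * eta - log1p(exp(eta))) - lambda / 2 * sum(w[-1]^2)
}

# two-stage lattice search: coarse step 0.1 on [-3,3]^3, then step 0.01 on
# a +/-0.12 cube around the coarse optimum; both stages are exhaustive
# enumerations of the penalized likelihood surface
lattice_logistic_oracle <- function(x, y, lambda) {
  stopifnot(ncol(x) == 2L)
  X1 <- cbind(1, x)
  eval_grid <- function(g0, g1, g2) {
    W <- as.matrix(expand.grid(w0 = g0, w1 = g1, w2 = g2))
    eta <- X1 %*% t(W)                      # n x n_grid
    ll <- colSums(y * eta - log1p(exp(eta))) -
      lambda / 2 * (W[, 2]^2 + W[, 3]^2)
    W[which.max(ll), ]
  }
  g <- seq(-3, 3, by = 0.1)
  w_c <- eval_grid(g, g, g)
  f <- function(c0) seq(c0 - 0.12, c0 + 0.12, by = 0.01)
  eval_grid(f(w_c[1]), f(w_c[2]), f(w_c[3]))
}
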