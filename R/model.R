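# penalized log-likelihood: sum_i [y_i eta_i - log(1 + exp(eta_i))]
#                           - lambda/2 * ||w_noint||^2
.binom_ll <- function(eta, y) sum(y * eta - log1p(exp(pmin(eta, 700))))

#' Fit a binary logistic regression by penalized maximum likelihood
#'
#' Maximizes the Bernoulli log-likelihood
#' `L(w) = sum_i [y_i (w . x_i) - log(1 + exp(w . x_i))]` minus a ridge
#' penalty `lambda/2 ||w||^2` (the intercept is unpenalized) by Newton's
#' method with step halving. The penalized objective is strictly concave
#' for `lambda > 0`, so the optimum is unique and the solver is
#' deterministic from its zero-vector initialization; `w_init` exists only
#' for warm starts, which reach the same optimum.
#'
#' @param x numeric feature matrix (no intercept column; one is added
#'   internally). Should be standardized so one `lambda` is meaningful
#'   across columns.
#' @param y 0/1 labels; both classes must be present.
#' @param l2_lambda ridge penalty, `>= 0`. The default 1 guarantees finite
#'   weights under separation.
#' @param tol convergence tolerance on the gradient max-norm.
#' @param max_iter Newton iteration cap.
#' @param w_init optional warm-start weights (intercept first), length
#'   `ncol(x) + 1`.
#' @return Object of class `pvr_logit`: `weights` (named, intercept
#'   first), `l2_lambda`, `converged`, `final_gradient_norm`, `n_iter`.
#' @export
fit_logistic <- function(x, y, l2_lambda = 1, tol = 1e-8, max_iter = 200L,
                         w_init = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite values in x", call. = FALSE)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) stop("degenerate labels: y is single-class",
                                   call. = FALSE)
  if (l2_lambda < 0) stop("l2_lambda must be >= 0", call. = FALSE)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("length(y) != nrow(x)", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, x)
  pen <- c(0, rep(l2_lambda, p))
  w <- if (is.null(w_init)) numeric(p + 1L) else {
    stopifnot(length(w_init) == p + 1L)
    as.numeric(w_init)
  }
  obj <- function(w, eta) .binom_ll(eta, y) - sum(pen * w^2) / 2
  eta <- drop(X %*% w)
  f <- obj(w, eta)
  converged <- FALSE
  gnorm <- Inf
  iter <- 0L
  while (iter < max_iter) {
    mu <- plogis(eta)
    g <- drop(crossprod(X, y - mu)) - pen * w
    gnorm <- max(abs(g))
    if (gnorm <= tol) { converged <- TRUE; break }
    iter <- iter + 1L
    wt <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * sqrt(wt))
    diag(H) <- diag(H) + pen + 1e-12
    delta <- solve(H, g)
    step <- 1
    repeat {
      w_new <- w + step * delta
      eta_new <- drop(X %*% w_new)
      f_new <- obj(w_new, eta_new)
      if (f_new >= f - 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    w <- w_new; eta <- eta_new; f <- f_new
  }
  if (!converged) {           # re-check after the last update
    mu <- plogis(eta)
    g <- drop(crossprod(X, y - mu)) - pen * w
    gnorm <- max(abs(g))
    converged <- gnorm <= tol
  }
  structure(list(weights = stats::setNames(w, colnames(X)),
                 l2_lambda = l2_lambda, converged = converged,
                 final_gradient_norm = gnorm, n_iter = iter),
            class = "pvr_logit")
}

#' Fit a multinomial (softmax) logistic regression
#'
#' The K-class model `P(Y = k | x) = exp(w_k . x) / (1 + sum_j exp(w_j . x))`
#' for `k < K`, with class K as the reference; fitted by penalized maximum
#' likelihood with a full Newton step on the stacked weight vector. With
#' `K = 2` this reduces exactly to [fit_logistic()]. Intended for
#' single-label inputs and small feature counts; the pipeline's operative
#' model for co-occurring diseases is one-vs-rest [fit_logistic()].
#'
#' @inheritParams fit_logistic
#' @param y a factor (or coercible) with K levels; the last level is the
#'   reference class.
#' @return Object of class `pvr_mlogit`: `weights` (matrix, K-1 rows),
#'   `classes`, `l2_lambda`, `converged`, `final_gradient_norm`, `n_iter`.
#' @export
fit_multinomial <- function(x, y, l2_lambda = 1, tol = 1e-8,
                            max_iter = 200L) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite values in x", call. = FALSE)
  y <- factor(y)
  K <- nlevels(y)
  if (K < 2L) stop("degenerate labels: y is single-class", call. = FALSE)
  n <- nrow(x); p <- ncol(x) + 1L
  X <- cbind(`(Intercept)` = 1, x)
  Y <- matrix(0, n, K - 1L)
  yi <- as.integer(y)
  for (k in seq_len(K - 1L)) Y[, k] <- as.numeric(yi == k)
  pen <- rep(c(0, rep(l2_lambda, p - 1L)), K - 1L)
  w <- numeric(p * (K - 1L))
  probs <- function(w) {
    W <- matrix(w, p, K - 1L)
    E <- exp(pmin(X %*% W, 700))
    P <- E / (1 + rowSums(E))
    P
  }
  obj <- function(w) {
    W <- matrix(w, p, K - 1L)
    eta <- X %*% W
    lse <- log1p(rowSums(exp(pmin(eta, 700))))
    sum(rowSums(Y * eta)) - sum(lse) - sum(pen * w^2) / 2
  }
  f <- obj(w)
  converged <- FALSE; gnorm <- Inf; iter <- 0L
  while (iter < max_iter) {
    P <- probs(w)
    G <- crossprod(X, Y - P)            # p x (K-1)
    g <- as.vector(G) - pen * w
    gnorm <- max(abs(g))
    if (gnorm <= tol) { converged <- TRUE; break }
    iter <- iter + 1L
    H <- matrix(0, p * (K - 1L), p * (K - 1L))
    for (k in seq_len(K - 1L)) for (l in seq_len(K - 1L)) {
      wkl <- P[, k] * ((k == l) - P[, l])
      H[(k - 1L) * p + seq_len(p), (l - 1L) * p + seq_len(p)] <-
        crossprod(X, X * wkl)
    }
    diag(H) <- diag(H) + pen + 1e-10
    delta <- solve(H, g)
    step <- 1
    repeat {
      w_new <- w + step * delta
      f_new <- obj(w_new)
      if (f_new >= f - 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    w <- w_new; f <- f_new
  }
  if (!converged) {
    P <- probs(w)
    g <- as.vector(crossprod(X, Y - P)) - pen * w
    gnorm <- max(abs(g))
    converged <- gnorm <= tol
  }
  W <- matrix(w, p, K - 1L, dimnames = list(colnames(X),
                                            levels(y)[seq_len(K - 1L)]))
  structure(list(weights = t(W), classes = levels(y),
                 l2_lambda = l2_lambda, converged = converged,
                 final_gradient_norm = gnorm, n_iter = iter),
            class = "pvr_mlogit")
}

#' Predicted class probabilities
#'
#' Binary fits return `plogis(w . x)`; multinomial fits return a matrix of
#' K per-class probabilities summing to 1. Values are clamped to the open
#' interval (0, 1) at machine precision.
#'
#' @param fit a `pvr_logit` or `pvr_mlogit`.
#' @param x feature matrix with the same columns the fit was trained on.
#' @return Numeric vector (binary) or matrix (multinomial).
#' @export
predict_proba <- function(fit, x) UseMethod("predict_proba")

#' @export
predict_proba.pvr_logit <- function(fit, x) {
  x <- as.matrix(x)
  if (ncol(x) + 1L != length(fit$weights))
    stop(sprintf("dimension mismatch: fit has %d features, x has %d",
                 length(fit$weights) - 1L, ncol(x)), call. = FALSE)
  p <- plogis(drop(cbind(1, x) %*% fit$weights))
  pmin(pmax(p, .Machine$double.eps), 1 - .Machine$double.eps)
}

#' @export
predict_proba.pvr_mlogit <- function(fit, x) {
  x <- as.matrix(x)
  W <- t(fit$weights)                   # p x (K-1)
  if (ncol(x) + 1L != nrow(W))
    stop(sprintf("dimension mismatch: fit has %d features, x has %d",
                 nrow(W) - 1L, ncol(x)), call. = FALSE)
  E <- exp(pmin(cbind(1, x) %*% W, 700))
  denom <- 1 + rowSums(E)
  P <- cbind(E / denom, 1 / denom)
  colnames(P) <- fit$classes
  P <- pmin(pmax(P, .Machine$double.eps), 1 - .Machine$double.eps)
  P / rowSums(P)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random positive outscores a random negative,
#' with half credit for ties: computed from midranks, which is exactly the
#' mean over all (positive, negative) pairs of
#' `[s_pos > s_neg] + 0.5 [s_pos == s_neg]`. Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("labels must be binary 0/1", call. = FALSE)
  m <- sum(labels == 1); n <- sum(labels == 0)
  if (m == 0L || n == 0L)
    stop("labels are single-class; AUC undefined", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n)
}

#' Deterministic train/test split of stays
#'
#' @param n number of stays (rows).
#' @param train_frac fraction assigned to training.
#' @param seed RNG seed; the caller's RNG state is untouched.
#' @return list with integer `train` and `test` row indices.
#' @export
split_stays <- function(n, train_frac = 0.7, seed = 1L) {
  stopifnot(n >= 2, train_frac > 0, train_frac < 1)
  n_train <- max(1L, min(n - 1L, round(train_frac * n)))
  local_seed(seed, {
    train <- sort(sample.int(n, n_train))
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Train and evaluate one experiment (one PV set)
#'
#' Fits one binary one-vs-rest classifier per disease on the training rows
#' of a single seeded stay-level split, scores the held-out rows and
#' returns per-disease AUROC. Imputation and standardization parameters
#' are fitted on the training rows only. Diseases with a single class on
#' either side of the split are reported with a `reason` instead of being
#' silently dropped.
#'
#' @param features an *unstandardized* `pvr_features` for the PV set.
#' @param labels disease label table (`stay_id` + one 0/1 column per
#'   disease), row-matched to the feature matrix via `stay_id`.
#' @param diseases disease codes to evaluate (default: all label columns).
#' @param train_frac,seed the stay-level split; reuse one seed across PV
#'   sets so AUC differences reflect the PV set, not the split.
#' @param l2_lambda ridge penalty passed to [fit_logistic()].
#' @param w_init_list optional named list (by disease) of warm-start
#'   weights aligned to `features`' columns.
#' @param return_fits keep the fitted models (for warm starts downstream).
#' @return data.frame with columns `pv_set_id`, `disease`, `auc`, `n_pos`,
#'   `n_neg`, `reason` (NA when evaluated); attribute `"fits"` when
#'   requested.
#' @export
evaluate_experiment <- function(features, labels, diseases = NULL,
                                train_frac = 0.7, seed = 1L, l2_lambda = 1,
                                w_init_list = NULL, return_fits = FALSE) {
  stopifnot(inherits(features, "pvr_features"))
  labels <- as.data.table(labels)
  if (is.null(diseases))
    diseases <- setdiff(names(labels), "stay_id")
  ri <- match(features$stay_id, labels$stay_id)
  if (anyNA(ri)) stop("labels table lacks rows for some stays",
                      call. = FALSE)
  n <- nrow(features$x)
  sp <- split_stays(n, train_frac, seed)
  if (!length(sp$train) || !length(sp$test))
    stop("empty split side", call. = FALSE)
  fm <- impute_and_standardize(features, sp$train)
  Xtr <- fm$x[sp$train, , drop = FALSE]
  Xte <- fm$x[sp$test, , drop = FALSE]
  fits <- list()
  rows <- lapply(diseases, function(d) {
    y <- as.numeric(labels[[d]])[ri]
    ytr <- y[sp$train]; yte <- y[sp$test]
    if (length(unique(ytr)) < 2L)
      return(data.frame(pv_set_id = features$pv_set_id, disease = d,
                        auc = NA_real_, n_pos = sum(yte == 1),
                        n_neg = sum(yte == 0),
                        reason = "single_class_train"))
    if (length(unique(yte)) < 2L)
      return(data.frame(pv_set_id = features$pv_set_id, disease = d,
                        auc = NA_real_, n_pos = sum(yte == 1),
                        n_neg = sum(yte == 0),
                        reason = "single_class_test"))
    fit <- fit_logistic(Xtr, ytr, l2_lambda = l2_lambda,
                        w_init = w_init_list[[d]])
    if (return_fits) fits[[d]] <<- fit
    s <- predict_proba(fit, Xte)
    data.frame(pv_set_id = features$pv_set_id, disease = d,
               auc = roc_auc(s, yte), n_pos = sum(yte == 1),
               n_neg = sum(yte == 0), reason = NA_character_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (return_fits) attr(out, "fits") <- fits
  out
}
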