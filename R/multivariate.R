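#' @importFrom stats quantile complete.cases runif rnorm
NULL

#' Range scaling
#'
#' Centers each feature at its training mean and divides by the training
#' range (`max - min`), the van den Berg convention. Parameters are learned
#' on `train` only and applied unchanged to `apply_to`, so no test-set
#' statistics leak into the scaling. Features with zero training range are
#' scaled to 0.
#'
#' @param train samples-by-features numeric matrix (>= 2 samples).
#' @param apply_to optional matrix with the same features, scaled with the
#'   training parameters.
#' @return list with `train` (scaled), `applied` (scaled `apply_to` or
#'   NULL) and the learned `center`, `min`, `max`.
#' @export
rangeScale <- function(train, apply_to = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2) stop("range scaling needs >= 2 training samples")
  ctr <- colMeans(train)
  mn <- apply(train, 2, min)
  mx <- apply(train, 2, max)
  params <- list(center = ctr, min = mn, max = mx)
  list(train = .applyRangeScale(train, params),
       applied = if (is.null(apply_to)) NULL
                 else .applyRangeScale(as.matrix(apply_to), params),
       center = ctr, min = mn, max = mx)
}

.applyRangeScale <- function(X, params) {
  rng <- params$max - params$min
  Xs <- sweep(X, 2, params$center, "-")
  nz <- rng > 0
  Xs[, nz] <- sweep(Xs[, nz, drop = FALSE], 2, rng[nz], "/")
  Xs[, !nz] <- 0
  Xs
}

# ---------------------------------------------------------------------------

#' Multivariate model (PCA or PLS-DA)
#'
#' Holds scores, loadings/weights, per-component and cumulative explained
#' variance of the predictor block (R2X) and, for PLS-DA, of the one-hot
#' response block (R2Y), cross-validated goodness-of-prediction (Q2), the
#' range-scaling parameters learned on the training data, and the class
#' encoding.
#'
#' @aliases MVAModel-class
#' @export
setClass("MVAModel", representation(
  kind = "character", n_components = "integer", scores = "matrix",
  loadings = "matrix", weights = "matrix", y_loadings = "matrix",
  coefficients = "matrix", y_means = "numeric", r2x_comp = "numeric",
  r2y_comp = "numeric", q2 = "numeric", scaling = "list",
  class_levels = "character"))

setValidity("MVAModel", function(object) {
  msg <- character()
  if (any(diff(cumsum(object@r2x_comp)) < -1e-8))
    msg <- c(msg, "cumulative R2X must be nondecreasing")
  if (sum(object@r2x_comp) > 1 + 1e-8) msg <- c(msg, "R2X exceeds 1")
  if (object@kind == "plsda" && sum(object@r2y_comp) > 1 + 1e-8)
    msg <- c(msg, "R2Y exceeds 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MVAModel", function(object) {
  cat(sprintf("MVAModel (%s): %d component(s), %d sample(s) x %d feature(s)\n",
              object@kind, object@n_components, nrow(object@scores),
              nrow(object@loadings)))
  cat(sprintf("  R2X(cum) = %.3f", sum(object@r2x_comp)))
  if (object@kind == "plsda")
    cat(sprintf(", R2Y(cum) = %.3f", sum(object@r2y_comp)))
  if (length(object@q2) && !all(is.na(object@q2)))
    cat(sprintf(", Q2(%d) = %.3f", length(object@q2),
                object@q2[length(object@q2)]))
  cat("\n")
})

#' @describeIn MVAModel score matrix accessor.
#' @param x an `MVAModel`.
#' @export
mvaScores <- function(x) x@scores

#' @describeIn MVAModel loading matrix accessor.
#' @export
mvaLoadings <- function(x) x@loadings

#' @describeIn MVAModel per-component and cumulative explained variance.
#' @export
mvaR2 <- function(x)
  data.frame(component = seq_along(x@r2x_comp), r2x_comp = x@r2x_comp,
             r2x_cum = cumsum(x@r2x_comp),
             r2y_comp = if (x@kind == "plsda") x@r2y_comp else NA_real_,
             r2y_cum = if (x@kind == "plsda") cumsum(x@r2y_comp)
                       else NA_real_)

.fixSign <- function(v) if (v[which.max(abs(v))] < 0) -1 else 1

.oneHot <- function(labels) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  Y <- matrix(0, length(labels), length(lev),
              dimnames = list(NULL, lev))
  Y[cbind(seq_along(labels), match(labels, lev))] <- 1
  Y
}

#' Principal component analysis with cross-validated Q2X
#'
#' Singular-value decomposition of the (scaled, complete) predictor matrix,
#' components ordered by explained variance, with Q2X estimated by k-fold
#' cross-validated reconstruction error: held-out samples are projected on
#' loadings learned without them and `Q2X = 1 - PRESS/TSS`. The sign
#' convention makes the largest-magnitude loading of each component
#' positive.
#'
#' @param X samples-by-features matrix, scaled and complete.
#' @param n_components number of components to retain.
#' @param n_folds folds for Q2X estimation (set 0 to skip).
#' @param seed RNG seed for the fold assignment.
#' @return an [MVAModel-class] with `kind = "pca"`.
#' @export
fitPCA <- function(X, n_components = 2, n_folds = 7, seed = 1L) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must be complete (impute first)")
  A <- min(n_components, nrow(X) - 1, ncol(X))
  sv <- svd(X, nu = A, nv = A)
  signs <- vapply(seq_len(A), function(a) .fixSign(sv$v[, a]), numeric(1))
  P <- sweep(sv$v[, seq_len(A), drop = FALSE], 2, signs, "*")
  Tm <- sweep(sv$u[, seq_len(A), drop = FALSE] %*% diag(sv$d[seq_len(A)],
                                                        A), 2, signs, "*")
  ssx <- sum(X^2)
  r2x <- sv$d[seq_len(A)]^2 / ssx
  q2 <- rep(NA_real_, A)
  if (n_folds >= 2) {
    set.seed(seed)
    folds <- sample(rep_len(seq_len(min(n_folds, nrow(X))), nrow(X)))
    press <- numeric(A)
    tss <- 0
    for (fo in unique(folds)) {
      te <- folds == fo
      sv_tr <- svd(X[!te, , drop = FALSE], nu = 0, nv = A)
      tss <- tss + sum(X[te, ]^2)
      for (k in seq_len(A)) {
        Pk <- sv_tr$v[, seq_len(k), drop = FALSE]
        rec <- X[te, , drop = FALSE] %*% Pk %*% t(Pk)
        press[k] <- press[k] + sum((X[te, , drop = FALSE] - rec)^2)
      }
    }
    q2 <- 1 - press / tss
  }
  dimnames(P) <- list(colnames(X), paste0("PC", seq_len(A)))
  dimnames(Tm) <- list(rownames(X), paste0("PC", seq_len(A)))
  new("MVAModel", kind = "pca", n_components = as.integer(A), scores = Tm,
      loadings = P, weights = matrix(numeric(0), 0, 0),
      y_loadings = matrix(numeric(0), 0, 0),
      coefficients = matrix(numeric(0), 0, 0), y_means = numeric(0),
      r2x_comp = r2x, r2y_comp = numeric(0), q2 = q2, scaling = list(),
      class_levels = character(0))
}

# core NIPALS PLS2 on centered response; deflation on X only
.nipals <- function(X, Yc, A, tol = 1e-10, max_iter = 500) {
  n <- nrow(X); p <- ncol(X); K <- ncol(Yc)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  C <- matrix(0, K, A); Tm <- matrix(0, n, A)
  Xa <- X
  for (a in seq_len(A)) {
    u <- Yc[, which.max(colSums(Yc^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xa, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) return(list(W = W[, seq_len(a - 1), drop = FALSE],
                                  P = P[, seq_len(a - 1), drop = FALSE],
                                  C = C[, seq_len(a - 1), drop = FALSE],
                                  T = Tm[, seq_len(a - 1), drop = FALSE]))
      w <- w / nw
      tt <- Xa %*% w
      cc <- crossprod(Yc, tt) / sum(tt^2)
      u <- Yc %*% cc / sum(cc^2)
      if (sum((tt - t_old)^2) / max(sum(tt^2), 1e-300) < tol^2) break
      t_old <- tt
    }
    s <- .fixSign(w)
    w <- s * w; tt <- s * tt; cc <- s * cc
    pp <- crossprod(Xa, tt) / sum(tt^2)
    Xa <- Xa - tcrossprod(tt, pp)
    W[, a] <- w; P[, a] <- pp; C[, a] <- cc; Tm[, a] <- tt
  }
  list(W = W, P = P, C = C, T = Tm)
}

.plsCoefficients <- function(fit, k) {
  W <- fit$W[, seq_len(k), drop = FALSE]
  P <- fit$P[, seq_len(k), drop = FALSE]
  C <- fit$C[, seq_len(k), drop = FALSE]
  W %*% solve(crossprod(P, W)) %*% t(C)
}

#' Multi-class PLS-DA
#'
#' NIPALS PLS2 regression of the one-hot class matrix on the scaled
#' predictor block, deflating X only. The predicted class of a sample is
#' the argmax of its predicted responses. Per-component R2X and R2Y report
#' the explained predictor and response variance; the sign convention makes
#' the largest-magnitude weight of each component positive.
#'
#' @param X samples-by-features matrix, scaled and complete.
#' @param labels class label per sample (>= 2 classes).
#' @param n_components number of latent variables.
#' @return an [MVAModel-class] with `kind = "plsda"`.
#' @export
fitPLSDA <- function(X, labels, n_components = 2) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must be complete (impute first)")
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("PLS-DA needs >= 2 classes")
  stopifnot(length(labels) == nrow(X))
  Y <- .oneHot(labels)
  y_means <- colMeans(Y)
  Yc <- sweep(Y, 2, y_means)
  A <- min(n_components, nrow(X) - 1, ncol(X))
  fit <- .nipals(X, Yc, A)
  A <- ncol(fit$T)
  ssx <- sum(X^2)
  ssy <- sum(Yc^2)
  r2x <- vapply(seq_len(A), function(a)
    sum(fit$T[, a]^2) * sum(fit$P[, a]^2) / ssx, numeric(1))
  r2y_cum <- vapply(seq_len(A), function(k) {
    B <- .plsCoefficients(fit, k)
    1 - sum((Yc - X %*% B)^2) / ssy
  }, numeric(1))
  r2y <- diff(c(0, r2y_cum))
  B <- .plsCoefficients(fit, A)
  dimnames(fit$T) <- list(rownames(X), paste0("LV", seq_len(A)))
  dimnames(fit$P) <- list(colnames(X), paste0("LV", seq_len(A)))
  dimnames(fit$W) <- dimnames(fit$P)
  dimnames(B) <- list(colnames(X), colnames(Y))
  new("MVAModel", kind = "plsda", n_components = as.integer(A),
      scores = fit$T, loadings = fit$P, weights = fit$W,
      y_loadings = fit$C, coefficients = B, y_means = y_means,
      r2x_comp = r2x, r2y_comp = r2y, q2 = rep(NA_real_, A),
      scaling = list(), class_levels = colnames(Y))
}

#' Predict classes and responses from a PLS-DA model
#'
#' @param object a fitted plsda [MVAModel-class].
#' @param newdata samples-by-features matrix on the same scale as the
#'   training matrix (apply the training range scaling first), or raw if
#'   the model carries `scaling` parameters.
#' @param ... unused.
#' @return list with `response` (predicted one-hot responses) and `class`.
#' @export
setMethod("predict", "MVAModel", function(object, newdata, ...) {
  stopifnot(object@kind == "plsda")
  X <- as.matrix(newdata)
  if (length(object@scaling)) X <- .applyRangeScale(X, object@scaling)
  Yhat <- sweep(X %*% object@coefficients, 2, object@y_means, "+")
  list(response = Yhat,
       class = object@class_levels[max.col(Yhat, ties.method = "first")])
})

# ---------------------------------------------------------------------------

.stratifiedFolds <- function(labels, n_folds, seed) {
  set.seed(seed)
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Stratified double k-fold cross-validation of PLS-DA
#'
#' The outer stratified k-fold split estimates prediction performance; on
#' each outer training set an inner stratified k-fold tunes the number of
#' latent variables via [selectComponents()]. Range-scaling parameters are
#' learned on training folds only, so no test-fold statistics leak into the
#' model. `Q2Y(k) = 1 - PRESS/TSS` pools squared prediction errors of the
#' held-out one-hot responses (centered at the training class frequencies)
#' over the outer folds.
#'
#' @param X samples-by-features matrix, raw (unscaled) and complete.
#' @param labels class label per sample; every class needs >= 2 samples,
#'   and folds are reduced with a warning if a class has fewer samples than
#'   `n_folds`.
#' @param max_components largest number of latent variables examined.
#' @param n_folds folds for both loops (default 7).
#' @param q2_rel_increase relative Q2 gain threshold for component
#'   selection.
#' @param exclude_classes classes to drop before modelling (an explicit
#'   analyst decision, e.g. to remove an outlier condition; never applied
#'   automatically).
#' @param seed RNG seed for the fold assignments.
#' @return list with `q2y` (per-component outer Q2Y), `accuracy_per_component`,
#'   `n_components` (tuned, majority over outer folds), `accuracy` (outer
#'   accuracy at the per-fold tuned component counts), `per_fold_ncomp`,
#'   `n_folds` actually used and `folds` (the outer fold assignment).
#' @export
doubleCV <- function(X, labels, max_components = 3, n_folds = 7,
                     q2_rel_increase = 0.05, exclude_classes = NULL,
                     seed = 1L) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (!is.null(exclude_classes)) {
    keep <- !labels %in% exclude_classes
    X <- X[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  tab <- table(labels)
  if (any(tab < 2)) stop("every class needs >= 2 samples for stratified CV")
  if (min(tab) < n_folds) {
    n_folds <- max(2, min(tab))
    warning("folds reduced to ", n_folds, " (smallest class size)")
  }
  outer <- .stratifiedFolds(labels, n_folds, seed)
  A <- max_components
  press <- numeric(A)
  tss <- 0
  correct <- integer(A)
  tuned_correct <- 0
  per_fold_ncomp <- integer(0)
  for (fo in seq_len(n_folds)) {
    te <- outer == fo
    Xtr <- X[!te, , drop = FALSE]
    ytr <- labels[!te]
    # inner loop tunes the component count on the outer-training set only
    inner_q2 <- .innerQ2(Xtr, ytr, A, n_folds, q2_rel_increase,
                         seed + 1000L + fo)
    k_f <- selectComponents(inner_q2, q2_rel_increase)
    per_fold_ncomp <- c(per_fold_ncomp, k_f)
    sc <- rangeScale(Xtr, X[te, , drop = FALSE])
    model <- fitPLSDA(sc$train, ytr, A)
    Yte <- .oneHot(c(labels))[te, sort(unique(labels)), drop = FALSE]
    Ytec <- sweep(Yte, 2, model@y_means)
    tss <- tss + sum(Ytec^2)
    fit <- list(W = model@weights, P = model@loadings, C = model@y_loadings)
    for (k in seq_len(model@n_components)) {
      B <- .plsCoefficients(fit, k)
      Yhat_c <- sc$applied %*% B
      press[k] <- press[k] + sum((Ytec - Yhat_c)^2)
      pred <- model@class_levels[max.col(
        sweep(Yhat_c, 2, model@y_means, "+"), ties.method = "first")]
      correct[k] <- correct[k] + sum(pred == labels[te])
      if (k == min(k_f, model@n_components))
        tuned_correct <- tuned_correct + sum(pred == labels[te])
    }
    if (model@n_components < A)
      for (k in seq(model@n_components + 1, A))
        press[k] <- press[k] + sum((Ytec - sc$applied %*%
          .plsCoefficients(fit, model@n_components))^2)
  }
  q2y <- 1 - press / tss
  list(q2y = q2y, accuracy_per_component = correct / nrow(X),
       n_components = as.integer(stats::median(per_fold_ncomp)),
       accuracy = tuned_correct / nrow(X),
       per_fold_ncomp = per_fold_ncomp, n_folds = n_folds, folds = outer)
}

.innerQ2 <- function(X, labels, A, n_folds, q2_rel_increase, seed) {
  tab <- table(labels)
  nf <- min(n_folds, max(2, min(tab)))
  folds <- .stratifiedFolds(labels, nf, seed)
  press <- numeric(A)
  tss <- 0
  for (fo in seq_len(nf)) {
    te <- folds == fo
    sc <- rangeScale(X[!te, , drop = FALSE], X[te, , drop = FALSE])
    model <- fitPLSDA(sc$train, labels[!te], A)
    Yte <- .oneHot(labels)[te, sort(unique(labels)), drop = FALSE]
    Ytec <- sweep(Yte, 2, model@y_means)
    tss <- tss + sum(Ytec^2)
    fit <- list(W = model@weights, P = model@loadings, C = model@y_loadings)
    for (k in seq_len(A)) {
      kk <- min(k, model@n_components)
      press[k] <- press[k] +
        sum((Ytec - sc$applied %*% .plsCoefficients(fit, kk))^2)
    }
  }
  1 - press / tss
}

#' Select the number of components from a Q2 series
#'
#' Returns the smallest `k` for which adding component `k + 1` improves the
#' goodness-of-prediction by less than `rel_threshold` relative to `|Q2(k)|`
#' (default 5%); if every step improves more than that, the last index is
#' returned.
#'
#' @param q2_series numeric vector of Q2 values by component count.
#' @param rel_threshold relative-increase threshold.
#' @return integer component count.
#' @export
selectComponents <- function(q2_series, rel_threshold = 0.05) {
  stopifnot(length(q2_series) >= 1)
  if (length(q2_series) == 1) return(1L)
  for (k in seq_len(length(q2_series) - 1)) {
    rel <- (q2_series[k + 1] - q2_series[k]) / abs(q2_series[k])
    if (is.nan(rel) || rel < rel_threshold) return(k)
  }
  length(q2_series)
}

# class-specific VIP: weights weighted by the response variance of each
# class column explained per component; normalized so mean(VIP^2) = 1
.classVIP <- function(W, C, Tm) {
  p <- nrow(W)
  A <- ncol(W)
  K <- nrow(C)
  t2 <- colSums(Tm^2)
  vip <- matrix(NA_real_, p, K)
  for (k in seq_len(K)) {
    ssy <- C[k, seq_len(A)]^2 * t2                      # SSY_{k,a}
    denom <- sum(ssy)
    if (denom == 0) { vip[, k] <- 0; next }
    vip[, k] <- sqrt(p * as.vector(W^2 %*% ssy) / denom)
  }
  vip
}

#' Bootstrap confidence intervals for beta and class-specific VIP
#'
#' Draws `r` stratified bootstrap resamples (with replacement, class
#' proportions preserved), refits range scaling and PLS-DA on each, and
#' collects per-feature, per-class PLS regression coefficients (beta) and
#' class-specific VIP scores. Percentile 2.5/97.5% confidence intervals are
#' reported. The class-specific VIP weights each component's squared
#' weights by the share of that class's response variance it explains,
#' normalized so the mean squared VIP over features is 1.
#'
#' @param X samples-by-features matrix, raw and complete.
#' @param labels class label per sample.
#' @param n_components latent variables per refit.
#' @param r number of bootstrap resamples (default 100).
#' @param seed RNG seed.
#' @return data.frame (one row per feature x class) with `feature_id`,
#'   `class`, `beta_lo`, `beta_median`, `beta_hi`, `vip_lo`, `vip_median`,
#'   `vip_hi`.
#' @export
bootstrapSelection <- function(X, labels, n_components = 2, r = 100,
                               seed = 1L) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (r < 1) stop("r must be >= 1")
  lev <- sort(unique(labels))
  p <- ncol(X)
  K <- length(lev)
  beta <- array(NA_real_, c(p, K, r))
  vip <- array(NA_real_, c(p, K, r))
  set.seed(seed)
  for (b in seq_len(r)) {
    idx <- unlist(lapply(lev, function(cl) {
      w <- which(labels == cl)
      sample(w, length(w), replace = TRUE)
    }))
    sc <- rangeScale(X[idx, , drop = FALSE])
    model <- fitPLSDA(sc$train, labels[idx], n_components)
    beta[, , b] <- model@coefficients[, lev]
    vip[, , b] <- .classVIP(model@weights, model@y_loadings, model@scores)
  }
  qs <- function(a, pr) apply(a, c(1, 2), quantile, probs = pr, na.rm = TRUE)
  out <- expand.grid(feature_id = colnames(X) %||% paste0("x", seq_len(p)),
                     class = lev, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out$beta_lo <- as.vector(qs(beta, 0.025))
  out$beta_median <- as.vector(qs(beta, 0.5))
  out$beta_hi <- as.vector(qs(beta, 0.975))
  out$vip_lo <- as.vector(qs(vip, 0.025))
  out$vip_median <- as.vector(qs(vip, 0.5))
  out$vip_hi <- as.vector(qs(vip, 0.975))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select discriminating variables from bootstrap CIs
#'
#' A feature is selected for a class when its class-specific VIP lower
#' confidence bound exceeds `vip_threshold` and its beta confidence
#' interval excludes 0.
#'
#' @param sel result of [bootstrapSelection()].
#' @param vip_threshold VIP threshold (default 1).
#' @return list with `table` (`sel` plus a `selected` flag), `per_class`
#'   (named list of selected feature vectors) and `union`.
#' @export
selectVariables <- function(sel, vip_threshold = 1.0) {
  sel$selected <- sel$vip_lo > vip_threshold &
    (sel$beta_lo > 0 | sel$beta_hi < 0)
  per_class <- lapply(split(sel, sel$class),
                      function(d) d$feature_id[d$selected])
  list(table = sel, per_class = per_class,
       union = sort(unique(unlist(per_class))))
}
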