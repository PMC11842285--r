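test_that("range scaling centers by the mean and divides by the range", {
  sc <- rangeScale(matrix(c(0, 1, 2), 3, 1))
  expect_equal(as.vector(sc$train), c(-0.5, 0, 0.5))
  # constant feature maps to zero
  sc2 <- rangeScale(matrix(5, 3, 1))
  expect_equal(as.vector(sc2$train), c(0, 0, 0))
  # test data scaled with training parameters only: no leakage
  sc3 <- rangeScale(matrix(c(0, 2), 2, 1), matrix(4, 1, 1))
  expect_equal(as.vector(sc3$applied), 1.5)
  expect_error(rangeScale(matrix(1, 1, 2)), "2 training samples")
})

test_that("scaling parameters inside CV never come from test folds", {
  # instrument the training matrix: if the scaler saw the test rows, the
  # learned min/max would include the planted extreme values
  X <- matrix(rnorm(40), 10, 4)
  X[1, ] <- 1e6   # extreme row used only as "test"
  sc <- rangeScale(X[-1, , drop = FALSE], X[1, , drop = FALSE])
  expect_true(all(sc$max < 1e6))
  expect_true(all(abs(sc$applied) > 1))  # test row lies far outside [min,max]
})

test_that("PCA explains a rank-1 matrix with a single component", {
  t_true <- rnorm(12)
  p_true <- c(1, -2, 0.5)
  X <- outer(t_true, p_true)
  m <- fitPCA(X, n_components = 3, n_folds = 0)
  expect_equal(m@r2x_comp[1], 1)
  expect_equal(sum(m@r2x_comp[-1]), 0, tolerance = 1e-12)
})

test_that("PCA scores are orthogonal and sign-fixed", {
  set.seed(5)
  X <- scale(matrix(rnorm(20 * 6), 20, 6), scale = FALSE)
  m <- fitPCA(X, 4, n_folds = 0)
  g <- crossprod(mvaScores(m))
  expect_lt(max(abs(g - diag(diag(g)))), 1e-8)
  # the largest-magnitude loading of each component is positive
  for (a in seq_len(4)) {
    l <- mvaLoadings(m)[, a]
    expect_gt(l[which.max(abs(l))], 0)
  }
  # deterministic: identical call, identical scores
  expect_identical(mvaScores(fitPCA(X, 4, n_folds = 0)), mvaScores(m))
})

test_that("PC1 separates two well-separated classes", {
  d <- separable_xy(n_per_class = 10, p = 12, n_informative = 6,
                    effect = 6, seed = 8)
  sc <- rangeScale(d$X)
  m <- fitPCA(sc$train, 2, seed = 3)
  pc1 <- mvaScores(m)[, 1]
  # silhouette of the two classes on PC1
  sil <- vapply(seq_along(pc1), function(i) {
    own <- mean(abs(pc1[i] - pc1[d$y == d$y[i]][-match(i, which(d$y == d$y[i]))]))
    oth <- mean(abs(pc1[i] - pc1[d$y != d$y[i]]))
    (oth - own) / max(own, oth)
  }, numeric(1))
  expect_gt(mean(sil), 0)
  expect_true(all(m@q2 <= 1))
})

test_that("PLS-DA separates classes and reports R2", {
  d <- separable_xy(seed = 2)
  sc <- rangeScale(d$X)
  m <- fitPLSDA(sc$train, d$y, 2)
  pred <- predict(m, sc$train)
  expect_equal(pred$class, d$y)               # training accuracy 1.0
  expect_true(all(diff(cumsum(m@r2y_comp)) >= -1e-12))
  expect_lte(sum(m@r2y_comp), 1 + 1e-8)
  expect_error(fitPLSDA(sc$train, rep("A", nrow(d$X)), 2), "2 classes")
})

test_that("single-feature PLS-DA R2Y equals the squared correlation", {
  set.seed(4)
  y <- rep(c("A", "B"), each = 8)
  x <- rnorm(16) + (y == "B") * 2
  X <- matrix(scale(x, scale = FALSE), ncol = 1)
  m <- fitPLSDA(X, y, 1)
  r2_direct <- cor(x, as.numeric(y == "B"))^2
  expect_equal(sum(m@r2y_comp), r2_direct, tolerance = 1e-10)
})

test_that("duplicated feature columns receive identical loadings", {
  d <- separable_xy(n_per_class = 8, p = 5, seed = 6)
  X <- cbind(d$X, dup = d$X[, 1])
  sc <- rangeScale(X)
  m <- fitPLSDA(sc$train, d$y, 2)
  expect_equal(unname(mvaLoadings(m)[1, ]), unname(mvaLoadings(m)[6, ]),
               tolerance = 1e-8)
  expect_equal(unname(m@weights[1, ]), unname(m@weights[6, ]),
               tolerance = 1e-8)
})

test_that("double CV PRESS matches a hand-computed oracle", {
  d <- separable_xy(n_per_class = 6, p = 4, n_informative = 2, effect = 3,
                    seed = 9)
  cv <- doubleCV(d$X, d$y, max_components = 1, n_folds = 6, seed = 13)
  # recompute Q2Y(1) from scratch over the same outer partition with an
  # independent 1-component PLS (direct power-iteration formulas)
  press <- 0; tss <- 0
  for (fo in seq_len(cv$n_folds)) {
    te <- cv$folds == fo
    Xtr <- d$X[!te, , drop = FALSE]
    ctr <- colMeans(Xtr); rng <- apply(Xtr, 2, max) - apply(Xtr, 2, min)
    scl <- function(M) sweep(sweep(M, 2, ctr), 2, ifelse(rng > 0, rng, 1), "/")
    Xs <- scl(Xtr); Xs_te <- scl(d$X[te, , drop = FALSE])
    Y <- cbind(A = as.numeric(d$y[!te] == "A"),
               B = as.numeric(d$y[!te] == "B"))
    ym <- colMeans(Y); Yc <- sweep(Y, 2, ym)
    u <- Yc[, which.max(colSums(Yc^2))]
    for (it in 1:200) {
      w <- drop(crossprod(Xs, u)); w <- w / sqrt(sum(w^2))
      tt <- drop(Xs %*% w)
      cc <- drop(crossprod(Yc, tt)) / sum(tt^2)
      u <- drop(Yc %*% cc) / sum(cc^2)
    }
    b <- outer(w, cc)            # 1-component coefficients W (P'W)^-1 C'
    p1 <- drop(crossprod(Xs, tt)) / sum(tt^2)
    b <- w %*% solve(crossprod(p1, w)) %*% t(cc)
    Yte <- cbind(A = as.numeric(d$y[te] == "A"),
                 B = as.numeric(d$y[te] == "B"))
    Ytec <- sweep(Yte, 2, ym)
    press <- press + sum((Ytec - Xs_te %*% b)^2)
    tss <- tss + sum(Ytec^2)
  }
  expect_equal(cv$q2y[1], 1 - press / tss, tolerance = 1e-8)
})

test_that("double CV achieves perfect accuracy on separable classes", {
  d <- separable_xy(n_per_class = 14, p = 20, n_informative = 4,
                    effect = 5, seed = 3)
  cv <- doubleCV(d$X, d$y, max_components = 2, n_folds = 7, seed = 17)
  expect_equal(cv$accuracy, 1.0)
  expect_gt(cv$q2y[cv$n_components], 0.5)
})

test_that("stratified CV errors on singleton classes and reduces folds", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(doubleCV(X, c(rep("A", 9), "B"), 1), "2 samples")
  expect_warning(cv <- doubleCV(X, rep(c("A", "B"), each = 5), 1,
                                n_folds = 7, seed = 1), "folds reduced")
  expect_equal(cv$n_folds, 5)
})

test_that("the component-selection rule follows the 5% relative gain", {
  expect_equal(selectComponents(c(0.50, 0.52, 0.53), 0.05), 1L)
  expect_equal(selectComponents(c(0.40, 0.60, 0.61), 0.05), 2L)
  expect_equal(selectComponents(c(0.9), 0.05), 1L)
  expect_equal(selectComponents(c(0.2, 0.4, 0.8, 0.81), 0.05), 3L)
  # a drop in Q2 always stops
  expect_equal(selectComponents(c(0.8, 0.7, 0.9), 0.05), 1L)
})

test_that("a single-feature model has VIP identically 1", {
  set.seed(10)
  y <- rep(c("A", "B"), each = 6)
  X <- matrix(rnorm(12) + (y == "B"), ncol = 1,
              dimnames = list(NULL, "only"))
  sel <- bootstrapSelection(X, y, n_components = 1, r = 20, seed = 5)
  expect_equal(sel$vip_lo, rep(1, nrow(sel)), tolerance = 1e-10)
  expect_equal(sel$vip_hi, rep(1, nrow(sel)), tolerance = 1e-10)
})

test_that("mean squared class-specific VIP equals 1 in every fit", {
  d <- separable_xy(n_per_class = 8, p = 7, seed = 20)
  sc <- rangeScale(d$X)
  m <- fitPLSDA(sc$train, d$y, 2)
  vip <- footprintMS:::.classVIP(m@weights, m@y_loadings, m@scores)
  expect_equal(unname(colMeans(vip^2)), c(1, 1), tolerance = 1e-8)
})

test_that("bootstrap CIs contain zero for pure-noise features", {
  covered <- 0
  total <- 0
  for (s in seq_len(10)) {
    d <- separable_xy(n_per_class = 10, p = 6, n_informative = 2,
                      effect = 5, seed = 100 + s)
    sel <- bootstrapSelection(d$X, d$y, n_components = 1, r = 100,
                              seed = 200 + s)
    noise_rows <- sel$feature_id %in% sprintf("x%02d", 3:6)
    covered <- covered + sum(sel$beta_lo[noise_rows] <= 0 &
                             sel$beta_hi[noise_rows] >= 0)
    total <- total + sum(noise_rows)
  }
  expect_gte(covered / total, 0.9)
})

test_that("variable selection requires both the VIP and beta rules", {
  sel <- data.frame(
    feature_id = c("a", "b", "c"), class = "A",
    beta_lo = c(0.1, 0.1, -0.1), beta_hi = c(0.3, 0.3, 0.2),
    vip_lo = c(1.2, 0.8, 1.2), vip_median = 1, vip_hi = c(1.8, 1.4, 1.8),
    beta_median = 0.2)
  v <- selectVariables(sel, vip_threshold = 1)
  expect_equal(v$per_class$A, "a")   # b fails VIP, c's beta CI spans 0
  expect_equal(v$union, "a")
})

test_that("planted features dominate the VIP ranking", {
  d <- separable_xy(n_per_class = 12, p = 15, n_informative = 3,
                    effect = 4, seed = 31)
  sel <- bootstrapSelection(d$X, d$y, n_components = 1, r = 100, seed = 32)
  med <- tapply(sel$vip_median, sel$feature_id, mean)
  planted <- sprintf("x%02d", 1:3)
  expect_true(all(med[planted] > 1))
  expect_gt(min(med[planted]), max(med[setdiff(names(med), planted)]))
})

test_that("the NIPALS implementation agrees with an independent PLS", {
  skip_if_not_installed("mixOmics")
  d <- separable_xy(n_per_class = 8, p = 6, seed = 14)
  sc <- rangeScale(d$X)
  m <- fitPLSDA(sc$train, d$y, 2)
  Y <- cbind(A = as.numeric(d$y == "A"), B = as.numeric(d$y == "B"))
  ref <- mixOmics::pls(sc$train, scale(Y, scale = FALSE), ncomp = 2,
                       scale = FALSE, mode = "regression")
  # first-component scores must agree up to sign
  expect_gt(abs(cor(mvaScores(m)[, 1], ref$variates$X[, 1])), 1 - 1e-8)
})

test_that("class exclusion in double CV is explicit, never automatic", {
  set.seed(44)
  X <- matrix(rnorm(60), 20, 3)
  y <- rep(c("A", "B", "outlier"), length.out = 20)
  X[y == "A", 1] <- X[y == "A", 1] + 5
  cv <- doubleCV(X, y, 1, n_folds = 3, exclude_classes = "outlier",
                 seed = 2)
  expect_equal(cv$accuracy, 1.0)
  expect_length(cv$folds, sum(y != "outlier"))
})
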