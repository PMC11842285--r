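#' @importFrom stats kruskal.test t.test p.adjust cor as.dist hclust
NULL

#' Kruskal-Wallis omnibus test
#'
#' Rank-based one-way omnibus test with tie correction; the p-value uses
#' the chi-square approximation with `groups - 1` degrees of freedom. The
#' degenerate all-identical input (every rank tied) is defined as
#' `H = 0, p = 1`.
#'
#' @param values numeric observations.
#' @param groups group label per observation (>= 2 groups, >= 3 values).
#' @return list with `statistic` (H), `p_value` and `df`.
#' @export
kruskalWallis <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(droplevels(groups)) < 2) stop("need >= 2 groups")
  if (length(values) < 3) stop("need >= 3 observations")
  if (length(unique(values)) == 1)
    return(list(statistic = 0, p_value = 1,
                df = nlevels(droplevels(groups)) - 1))
  kt <- kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Pairwise post-hoc tests with FDR correction
#'
#' All pairwise two-sample comparisons following an omnibus test: Welch's
#' t-test for independent samples or the paired t-test for dependent
#' samples (`paired = TRUE` requires equal group sizes in consistent
#' order). Dunn's rank-based z-test is available as an alternative.
#' p-values are Benjamini-Hochberg corrected across the pair set. Groups
#' with identical constant values compare at p = 1.
#'
#' @param values numeric observations.
#' @param groups group label per observation.
#' @param paired compare groups as dependent samples.
#' @param method `"welch"` (parametric, default) or `"dunn"`.
#' @return list of symmetric matrices `p` and `q` with unit diagonal.
#' @export
posthocPairwise <- function(values, groups, paired = FALSE,
                            method = c("welch", "dunn")) {
  method <- match.arg(method)
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) < 2) stop("need >= 2 groups")
  pairs <- utils::combn(lev, 2)
  if (method == "dunn") {
    rk <- rank(values)
    n <- length(values)
    ties <- table(values)
    tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  }
  pv <- apply(pairs, 2, function(pr) {
    a <- values[groups == pr[1]]
    b <- values[groups == pr[2]]
    if (method == "dunn") {
      ra <- rk[groups == pr[1]]; rb <- rk[groups == pr[2]]
      se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                   (1 / length(ra) + 1 / length(rb)))
      if (se == 0) return(1)
      z <- (mean(ra) - mean(rb)) / se
      return(2 * stats::pnorm(-abs(z)))
    }
    if (length(unique(c(a, b))) == 1) return(1)
    tryCatch(t.test(a, b, paired = paired)$p.value,
             error = function(e) 1)
  })
  qv <- p.adjust(pv, method = "BH")
  mk <- function(v) {
    m <- diag(1, length(lev))
    dimnames(m) <- list(lev, lev)
    m[t(pairs)] <- v
    m[t(pairs)[, 2:1, drop = FALSE]] <- v
    m
  }
  list(p = mk(pv), q = mk(qv))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return monotone step-up adjusted q-values, capped at 1.
#' @export
benjaminiHochberg <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  p.adjust(pvalues, method = "BH")
}

#' Per-feature univariate statistics
#'
#' Kruskal-Wallis omnibus across classes for every feature with BH
#' correction over features, plus pairwise post-hoc comparisons for
#' features passing `alpha`.
#'
#' @param fe a preprocessed [FootprintExperiment-class] (complete sample
#'   cells).
#' @param alpha significance level for the post-hoc stage.
#' @param paired passed to [posthocPairwise()].
#' @return list with `omnibus` data.frame (`feature_id`, `H`, `p`, `q`,
#'   `significant`) and `posthoc` (named list of p/q matrix pairs for
#'   significant features).
#' @export
runUnivariate <- function(fe, alpha = 0.05, paired = FALSE) {
  is_s <- sampleRoles(fe) == "sample"
  x <- intensities(fe)[, is_s, drop = FALSE]
  cls <- classLabels(fe)[is_s]
  res <- t(vapply(seq_len(nrow(x)), function(i) {
    kw <- kruskalWallis(x[i, ], cls)
    c(kw$statistic, kw$p_value)
  }, numeric(2)))
  q <- benjaminiHochberg(res[, 2])
  omnibus <- data.frame(feature_id = rownames(x), H = res[, 1],
                        p = res[, 2], q = q, significant = q < alpha,
                        row.names = NULL)
  posthoc <- lapply(which(omnibus$significant), function(i)
    posthocPairwise(x[i, ], cls, paired = paired))
  names(posthoc) <- omnibus$feature_id[omnibus$significant]
  list(omnibus = omnibus, posthoc = posthoc)
}

# ---------------------------------------------------------------------------

#' Correlation distance matrix
#'
#' `d = 1 - Pearson r` between observations along the chosen axis.
#' Constant observations have undefined correlation; their distance to
#' everything else is defined as 1 (and 0 to themselves).
#'
#' @param m numeric matrix.
#' @param axis `"rows"` (observations are rows, features are coordinates)
#'   or `"cols"`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
correlationDistance <- function(m, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  if (axis == "rows") m <- t(m)
  const <- apply(m, 2, function(v) max(v) == min(v))
  r <- suppressWarnings(cor(m))
  d <- 1 - r
  d[const, ] <- 1
  d[, const] <- 1
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering where the distance between clusters is the
#' mean of all pairwise member distances; merge heights are nondecreasing
#' and ties break deterministically by lowest index.
#'
#' @param D symmetric distance matrix with zero diagonal (or a `dist`).
#' @return an [stats::hclust] dendrogram.
#' @export
hcaAverageLinkage <- function(D) {
  if (!inherits(D, "dist")) {
    D <- as.matrix(D)
    if (any(abs(D - t(D)) > 1e-12) || any(diag(D) != 0))
      stop("D must be symmetric with zero diagonal")
    D <- as.dist(D)
  }
  hclust(D, method = "average")
}

#' Per-feature heatmap normalization to [0, 1]
#'
#' For every feature (row) the minimum is subtracted and the result is
#' divided by its maximum, mapping each non-constant feature onto `[0, 1]`
#' with minimum 0; constant features map to all 0.
#'
#' @param m features-by-samples numeric matrix.
#' @return matrix of the same shape with entries in `[0, 1]`.
#' @export
heatmapNormalize <- function(m) {
  t(apply(m, 1, function(v) {
    v <- v - min(v)
    mx <- max(v)
    if (mx == 0) rep(0, length(v)) else v / mx
  }))
}

#' Hierarchical clustering of samples and features
#'
#' Builds the sample and feature dendrograms with the correlation distance
#' and average linkage, together with the per-feature normalized heatmap
#' matrix.
#'
#' @param fe a preprocessed [FootprintExperiment-class].
#' @param features optional feature subset (e.g. the VIP selection union).
#' @return list with `sample_dendrogram`, `feature_dendrogram` and
#'   `heatmap` (normalized matrix).
#' @export
runHCA <- function(fe, features = NULL) {
  is_s <- sampleRoles(fe) == "sample"
  x <- intensities(fe)[, is_s, drop = FALSE]
  if (!is.null(features)) x <- x[features, , drop = FALSE]
  list(sample_dendrogram = hcaAverageLinkage(correlationDistance(t(x),
                                                                 "rows")),
       feature_dendrogram = hcaAverageLinkage(correlationDistance(x,
                                                                  "rows")),
       heatmap = heatmapNormalize(x))
}
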