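#' @import ggplot2
NULL

# 95% Hotelling's T2 ellipse path from a 2-column score matrix
.hotellingEllipse <- function(scores2, level = 0.95, n_points = 200) {
  n <- nrow(scores2)
  ctr <- colMeans(scores2)
  S <- stats::cov(scores2)
  r <- sqrt(2 * (n - 1) / (n - 2) * stats::qf(level, 2, n - 2))
  theta <- seq(0, 2 * pi, length.out = n_points)
  circ <- cbind(cos(theta), sin(theta)) * r
  ell <- circ %*% chol(S)
  data.frame(x = ell[, 1] + ctr[1], y = ell[, 2] + ctr[2])
}

#' Score plot with Hotelling's T2 ellipse
#'
#' Scatter of two model components colored by class, annotated with the
#' 95% Hotelling's T2 confidence ellipse computed from the score
#' covariance (an annotation, not a test decision).
#'
#' @param model an [MVAModel-class].
#' @param classes class label per sample (QCs may be labelled "QC").
#' @param components which two components to draw.
#' @return a ggplot object.
#' @export
plotScores <- function(model, classes, components = c(1, 2)) {
  sc <- mvaScores(model)[, components, drop = FALSE]
  df <- data.frame(x = sc[, 1], y = sc[, 2], class = as.character(classes))
  lab <- if (model@kind == "pca") "PC" else "LV"
  r2 <- model@r2x_comp[components]
  ell <- if (nrow(sc) > 3) .hotellingEllipse(sc) else NULL
  p <- ggplot(df, aes(x = .data$x, y = .data$y, color = .data$class)) +
    geom_point(size = 2) +
    labs(x = sprintf("%s%d (R2X = %.1f%%)", lab, components[1], 100 * r2[1]),
         y = sprintf("%s%d (R2X = %.1f%%)", lab, components[2], 100 * r2[2]),
         color = "class") +
    theme_bw()
  if (!is.null(ell))
    p <- p + geom_path(data = ell, aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE, linetype = 2, color = "grey40")
  p
}

#' Enrichment bubble plot
#'
#' Pathway impact against -log10 adjusted p, bubble size by hit count —
#' the usual joint ORA/PTA display.
#'
#' @param enrichment result of [runORA()].
#' @param alpha significance level drawn as a dashed line.
#' @return a ggplot object.
#' @export
plotEnrichment <- function(enrichment, alpha = 0.05) {
  ggplot(enrichment,
         aes(x = .data$impact, y = -log10(.data$q), size = .data$k,
             color = .data$significant)) +
    geom_point(alpha = 0.8) +
    geom_hline(yintercept = -log10(alpha), linetype = 2,
               color = "grey40") +
    labs(x = "pathway impact", y = expression(-log[10] ~ q),
         size = "hits") +
    theme_bw()
}
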