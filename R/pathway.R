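#' @importFrom stats phyper
#' @importFrom igraph graph_from_data_frame betweenness make_empty_graph
#'   vertices
NULL

.pathwayGraph <- function(pw) {
  if (length(pw$edges)) {
    el <- do.call(rbind, pw$edges)
    g <- graph_from_data_frame(data.frame(from = el[, 1], to = el[, 2]),
                               directed = TRUE,
                               vertices = data.frame(name = pw$nodes))
  } else {
    g <- make_empty_graph(directed = TRUE) + vertices(pw$nodes)
  }
  g
}

#' Betweenness centrality of a directed compound graph
#'
#' Raw (unnormalized) betweenness: for each node, the sum over ordered
#' source/target pairs of the fraction of shortest directed paths passing
#' through it; unreachable pairs contribute nothing.
#'
#' @param pw a single pathway entry (list with `nodes` and `edges`) from a
#'   [PathwaySet-class], or a 2-column from/to edge matrix.
#' @param nodes node set when `pw` is an edge matrix.
#' @return named numeric vector of centralities.
#' @export
betweennessCentrality <- function(pw, nodes = NULL) {
  if (is.matrix(pw))
    pw <- list(nodes = if (is.null(nodes)) unique(as.vector(pw)) else nodes,
               edges = lapply(seq_len(nrow(pw)), function(i) pw[i, ]))
  g <- .pathwayGraph(pw)
  b <- betweenness(g, directed = TRUE, normalized = FALSE)
  b[pw$nodes]
}

#' Topology-weighted pathway impact
#'
#' The normalized betweenness-centrality ratio: the sum of centralities of
#' the hit compounds divided by the total centrality of all pathway
#' compounds. A pathway whose total centrality is 0 (e.g. edgeless) has
#' impact 0 by definition. Lies in `[0, 1]` and is monotone in the hit set.
#'
#' @param hits character vector of hit compound identifiers (must be
#'   pathway members).
#' @param pw a single pathway entry from a [PathwaySet-class].
#' @param normalization denominator of the ratio: `"total"` (sum of all
#'   node centralities, default) or `"max"` (largest node centrality; the
#'   result may then exceed 1 for multi-hit sets and is capped).
#' @return impact in `[0, 1]`.
#' @export
pathwayImpact <- function(hits, pw, normalization = c("total", "max")) {
  normalization <- match.arg(normalization)
  bad <- setdiff(hits, pw$nodes)
  if (length(bad))
    stop("hit compound(s) not in pathway: ", paste(bad, collapse = ", "))
  b <- betweennessCentrality(pw)
  denom <- if (normalization == "total") sum(b) else max(b)
  if (denom == 0) return(0)
  min(sum(b[hits]) / denom, 1)
}

#' Over-representation and pathway topology analysis
#'
#' For each pathway, the one-sided hypergeometric over-representation
#' p-value of the selected compound set against the background
#' (`p = P(X >= k)` with `k` selected pathway members, `K` pathway members,
#' `n` selected compounds, `M` background compounds), Benjamini-Hochberg
#' corrected across pathways, together with the betweenness-centrality
#' pathway impact of the selected members.
#'
#' @param selected character vector of selected compound identifiers; must
#'   all be in the background.
#' @param pathways a [PathwaySet-class].
#' @param alpha significance level on the FDR-adjusted q-values.
#' @return data.frame with one row per pathway: `pathway_id`, `name`, `k`,
#'   `K`, `n`, `M`, `p`, `q`, `significant`, `impact`.
#' @export
runORA <- function(selected, pathways, alpha = 0.05) {
  stopifnot(is(pathways, "PathwaySet"))
  selected <- unique(as.character(selected))
  bg <- pathwayBackground(pathways)
  bad <- setdiff(selected, bg)
  if (length(bad))
    stop("selected compound(s) not in background: ",
         paste(bad, collapse = ", "))
  M <- length(bg)
  n <- length(selected)
  rows <- lapply(pathwayList(pathways), function(pw) {
    members <- intersect(pw$nodes, bg)
    K <- length(members)
    hits <- intersect(selected, members)
    k <- length(hits)
    p <- phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    data.frame(pathway_id = pw$id, name = pw$name, k = k, K = K, n = n,
               M = M, p = p,
               impact = pathwayImpact(hits, pw))
  })
  out <- do.call(rbind, rows)
  out$q <- benjaminiHochberg(out$p)
  out$significant <- out$q < alpha
  out[c("pathway_id", "name", "k", "K", "n", "M", "p", "q", "significant",
        "impact")]
}
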