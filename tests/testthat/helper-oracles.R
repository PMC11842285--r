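# Independent brute-force oracles used to verify the package's statistics.
# These are deliberately naive implementations straight from definitions;
# they never share code with the functions they check.

# Kruskal-Wallis H from the rank-sum formula with tie correction
oracle_kw_h <- function(values, groups) {
  groups <- as.factor(groups)
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / corr
}

# two-sided Mann-Whitney normal approximation (no continuity correction,
# tie-corrected variance)
oracle_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(c(a, b))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (w - mu) / sqrt(sigma2)
  2 * pnorm(-abs(z))
}

# hypergeometric over-representation P(X >= k) by exhaustive enumeration of
# all C(M, n) draws of the selected set
oracle_ora_p <- function(M, K, n, k) {
  draws <- combn(M, n)
  in_pathway <- seq_len(K)                # wlog the first K compounds
  hits <- apply(draws, 2, function(d) sum(d %in% in_pathway))
  mean(hits >= k)
}

# betweenness centrality by BFS shortest-path counting over all ordered
# pairs (directed, unweighted)
oracle_betweenness <- function(nodes, edges) {
  adj <- setNames(lapply(nodes, function(v)
    unlist(lapply(edges, function(e) if (e[1] == v) e[2]))), nodes)
  # BFS from s: distances and number of shortest paths
  bfs <- function(s) {
    dist <- setNames(rep(Inf, length(nodes)), nodes)
    nsp <- setNames(rep(0, length(nodes)), nodes)
    dist[s] <- 0; nsp[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- character()
      for (v in frontier) for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- union(nxt, w)
        }
        if (dist[w] == dist[v] + 1) nsp[w] <- nsp[w] + nsp[v]
      }
      frontier <- nxt
    }
    list(dist = dist, nsp = nsp)
  }
  fw <- lapply(setNames(nodes, nodes), bfs)
  cb <- setNames(rep(0, length(nodes)), nodes)
  for (s in nodes) for (t in nodes) {
    if (s == t || is.infinite(fw[[s]]$dist[t])) next
    for (v in setdiff(nodes, c(s, t))) {
      d_sv <- fw[[s]]$dist[v]
      if (is.infinite(d_sv) || is.infinite(fw[[v]]$dist[t])) next
      if (d_sv + fw[[v]]$dist[t] == fw[[s]]$dist[t])
        cb[v] <- cb[v] +
          fw[[s]]$nsp[v] * fw[[v]]$nsp[t] / fw[[s]]$nsp[t]
    }
  }
  cb
}

# UPGMA straight from the definition: cluster distance is the mean of all
# pairwise original distances; merge the closest pair (lowest index on
# ties); returns sorted merge heights and the cophenetic matrix
oracle_upgma <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < best[1]) best <- c(d, i, j)
    }
    i <- best[2]; j <- best[3]
    coph[clusters[[i]], clusters[[j]]] <- best[1]
    coph[clusters[[j]], clusters[[i]]] <- best[1]
    heights <- c(heights, best[1])
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  list(heights = heights, cophenetic = coph)
}

# random weakly structured DAG edge list on labelled nodes (acyclic by
# construction: edges only go forward in a random topological order)
random_dag <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  nodes <- LETTERS[seq_len(n_nodes)]
  ord <- sample(nodes)
  edges <- list()
  for (i in seq_len(n_nodes - 1)) for (j in seq(i + 1, n_nodes))
    if (runif(1) < p_edge) edges <- c(edges, list(c(ord[i], ord[j])))
  list(nodes = nodes, edges = edges)
}
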