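# Independent oracles and fixture builders, deliberately naive.

# mean shortest-path distance by plain BFS over an edge list
bfs_mean_spd <- function(edges, nodes) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]
    b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  total <- 0
  npair <- 0
  for (s in nodes) {
    dist <- setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    total <- total + sum(dist[nodes > s])
    npair <- npair + sum(nodes > s)
  }
  total / npair
}

# two-pass covariance/variance Pearson correlation
naive_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# exhaustive single-split SSE minimiser over a (gamma, kin) profile;
# returns the midpoint between the adjacent gammas of the best split
best_single_split <- function(gamma, kin) {
  n <- length(kin)
  best <- Inf
  at <- NA_real_
  for (s in 1:(n - 1)) {
    sse <- sum((kin[1:s] - mean(kin[1:s]))^2) +
      sum((kin[(s + 1):n] - mean(kin[(s + 1):n]))^2)
    if (sse < best - 1e-12) {
      best <- sse
      at <- (gamma[s] + gamma[s + 1]) / 2
    }
  }
  at
}

# wrap a symmetric matrix as the package's similarity container
make_sim <- function(m, mode = "correlation") {
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- sprintf("c%02d", seq_len(nrow(m)))
  }
  msclust:::new_similarity(m, mode)
}

# cell graph made of disjoint cliques (optionally bridged), unit-ish weights
clique_graph <- function(sizes, bridges = NULL, weight = 0.9,
                         stage = "final", mode = "correlation") {
  nodes <- sprintf("c%02d", seq_len(sum(sizes)))
  block <- rep(seq_along(sizes), times = sizes)
  edges <- NULL
  for (b in seq_along(sizes)) {
    members <- nodes[block == b]
    if (length(members) >= 2) {
      pr <- t(combn(members, 2))
      edges <- rbind(edges, pr)
    }
  }
  if (!is.null(bridges)) edges <- rbind(edges, bridges)
  cell_graph(data.frame(from = edges[, 1], to = edges[, 2], weight = weight),
             nodes = nodes, stage = stage, mode = mode)
}

# gamma_scan object with a prescribed kin profile (for breakpoint tests)
fake_scan <- function(gamma, kin) {
  structure(list(table = data.frame(gamma = gamma,
                                    n_clusters = seq_along(gamma),
                                    kin = kin),
                 memberships = NULL),
            class = "gamma_scan")
}

# random Erdos-Renyi style edge list on n nodes
random_graph_edges <- function(n, p) {
  pr <- t(combn(sprintf("c%02d", seq_len(n)), 2))
  pr[runif(nrow(pr)) < p, , drop = FALSE]
}
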