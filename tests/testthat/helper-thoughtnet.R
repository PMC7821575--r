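# shared helpers and independent oracles for the test suite

# subject-major (subject, day, run) vector of true occasion scores,
# aligned with a generated connectivity stack
scores_vector <- function(truth, component = 1) {
  as.vector(t(truth$true_scores[, , component]))
}

# per-scan partial factor scores aligned with a subject-major stack
partial_scores_vector <- function(fit, component = 1) {
  n <- fit$n_subjects
  out <- numeric(n * 4L)
  k <- 0L
  for (i in seq_len(n)) {
    for (b in 1:4) {
      k <- k + 1L
      out[k] <- fit$partial_scores[[b]][i, component]
    }
  }
  out
}

# independent connected-components oracle: breadth-first search over an
# adjacency list (deliberately different from both igraph and the
# package's union-find)
bfs_components <- function(pairs) {
  if (NROW(pairs) == 0) return(list())
  nodes <- sort(unique(as.integer(pairs)))
  adj <- lapply(nodes, function(v) integer(0))
  names(adj) <- nodes
  for (e in seq_len(nrow(pairs))) {
    a <- as.character(pairs[e, 1]); b <- as.character(pairs[e, 2])
    adj[[a]] <- c(adj[[a]], pairs[e, 2])
    adj[[b]] <- c(adj[[b]], pairs[e, 1])
  }
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (v in nodes) {
    if (seen[as.character(v)]) next
    queue <- v
    members <- integer(0)
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (seen[as.character(u)]) next
      seen[as.character(u)] <- TRUE
      members <- c(members, u)
      queue <- c(queue, adj[[as.character(u)]])
    }
    members <- sort(members)
    in_comp <- pairs[, 1] %in% members
    comps[[length(comps) + 1L]] <- list(
      nodes = members,
      edges = pairs[in_comp, , drop = FALSE],
      extent = sum(in_comp))
  }
  comps
}

# brute-force OLS t statistic for the last column of M (normal
# equations, no QR)
brute_t <- function(M, y) {
  XtX <- t(M) %*% M
  beta <- solve(XtX, t(M) %*% y)
  res <- y - M %*% beta
  df <- nrow(M) - ncol(M)
  sigma2 <- sum(res^2) / df
  k <- ncol(M)
  beta[k] / sqrt(sigma2 * solve(XtX)[k, k])
}

# independent Benjamini-Hochberg step-up implementation
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# load the packaged example sensorimotor network (26 region-pair
# connections over 19 parcels) as canonical node-index pairs
example_network <- function() {
  nodes <- read_node_table(system.file("extdata",
                                       "example_network_nodes.csv",
                                       package = "thoughtnet"))
  edges <- utils::read.csv(system.file("extdata",
                                       "example_network_edges.csv",
                                       package = "thoughtnet"),
                           stringsAsFactors = FALSE)
  key <- paste(nodes$hemisphere, nodes$label)
  i <- match(paste(edges$hemisphere_i, edges$label_i), key)
  j <- match(paste(edges$hemisphere_j, edges$label_j), key)
  stopifnot(!anyNA(i), !anyNA(j))
  pairs <- cbind(pmin(i, j), pmax(i, j))
  list(nodes = nodes, pairs = pairs[order(pairs[, 1], pairs[, 2]), ])
}

# minimal hand-built design object (bypasses nbs_design validation)
manual_design <- function(predictor, nuisance, blocks) {
  structure(list(predictor = predictor,
                 nuisance = as.matrix(nuisance),
                 nuisance_type = "indicators",
                 exchange_blocks = as.factor(blocks)),
            class = "nbs_design")
}

# minimal hand-built stack for GLM/permutation tests
manual_stack <- function(edges, subject_ids, n_nodes) {
  n <- length(subject_ids)
  connectivity_stack(
    edges = edges,
    meta = data.frame(subject_id = subject_ids,
                      day = rep_len(c(1, 1, 2, 2), n),
                      run = rep_len(c(1, 2, 1, 2), n)),
    nodes = data.frame(label = sprintf("Region %03d", seq_len(n_nodes)),
                       hemisphere = rep_len(c("L", "R"), n_nodes),
                       x = seq_len(n_nodes), y = 0, z = 0),
    n_nodes = n_nodes)
}
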