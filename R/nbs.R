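#' Design matrix for the repeated-measures network GLM
#'
#' The predictor is typically a per-scan partial factor score from the
#' questionnaire MFA.  Subject identity enters as nuisance indicator
#' columns (equivalent to within-subject centering of every edge), so
#' the GLM tests within-subject covariation of connectivity with the
#' predictor; permutation is constrained to each subject's own scans.
#' As an alternative nuisance coding, each subject's mean connectivity
#' of the edge under test can be used as a single covariate
#' (`nuisance = "mean_fc"`).
#'
#' @param stack a `conn_stack`.
#' @param predictor numeric vector, one value per scan.
#' @param nuisance `"indicators"` (default: one column per subject) or
#'   `"mean_fc"` (per-edge subject-mean covariate plus intercept).
#' @return object of class `nbs_design`.
#' @export
nbs_design <- function(stack, predictor, nuisance = c("indicators",
                                                      "mean_fc")) {
  stopifnot(inherits(stack, "conn_stack"))
  nuisance <- match.arg(nuisance)
  n <- nrow(stack$edges)
  predictor <- as.numeric(predictor)
  if (length(predictor) != n) {
    stop("predictor must have one value per scan", call. = FALSE)
  }
  blocks <- factor(stack$meta$subject_id,
                   levels = unique(stack$meta$subject_id))
  sizes <- table(blocks)
  if (any(sizes < 2)) {
    stop("every exchangeability block needs at least 2 scans",
         call. = FALSE)
  }
  within_var <- tapply(predictor, blocks, stats::var)
  if (all(within_var < 1e-14)) {
    stop("predictor is constant within every subject; ",
         "no within-subject effect is estimable", call. = FALSE)
  }
  nuis <- if (nuisance == "indicators") {
    stats::model.matrix(~ 0 + blocks)
  } else {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  structure(list(predictor = predictor,
                 nuisance = nuis,
                 nuisance_type = nuisance,
                 exchange_blocks = blocks),
            class = "nbs_design")
}

# closed-form OLS t for the last column of M against many responses
.glm_tstats <- function(M, Y) {
  n <- nrow(M)
  k <- ncol(M)
  qrM <- qr(M)
  if (qrM$rank < k) stop("rank-deficient design matrix", call. = FALSE)
  coefs <- qr.coef(qrM, Y)
  res <- qr.resid(qrM, Y)
  rss <- colSums(res^2)
  df <- n - k
  ckk <- solve(crossprod(M))[k, k]
  se <- sqrt(pmax(rss, 0) / df * ckk)
  t <- as.numeric(coefs[k, ]) / se
  list(t = t, beta_hat = as.numeric(coefs[k, ]), df = df)
}

#' Edge-wise general linear model
#'
#' Ordinary least squares of every edge's connectivity values on the
#' nuisance columns plus the predictor; returns the predictor's t
#' statistic and coefficient per edge.  Results are invariant to any
#' (full-rank) rescaling of the nuisance columns.
#'
#' @param stack a `conn_stack` (or a scans x E numeric matrix).
#' @param design an [nbs_design()].
#' @return object of class `edge_glm`: `t`, `beta_hat`, `df`.
#' @export
fit_edge_glm <- function(stack, design) {
  stopifnot(inherits(design, "nbs_design"))
  Y <- if (inherits(stack, "conn_stack")) stack$edges else as.matrix(stack)
  n <- nrow(Y)
  if (length(design$predictor) != n) {
    stop("design rows must align with stack scans", call. = FALSE)
  }
  if (design$nuisance_type == "mean_fc") {
    blocks <- design$exchange_blocks
    E <- ncol(Y)
    t <- beta <- numeric(E)
    df <- NA_integer_
    for (e in seq_len(E)) {
      m_e <- stats::ave(Y[, e], blocks)
      M <- cbind(design$nuisance, mean_fc = m_e, x = design$predictor)
      fit <- .glm_tstats(M, Y[, e, drop = FALSE])
      t[e] <- fit$t; beta[e] <- fit$beta_hat; df <- fit$df
    }
    return(structure(list(t = t, beta_hat = beta, df = df),
                     class = "edge_glm"))
  }
  M <- cbind(design$nuisance, x = design$predictor)
  structure(.glm_tstats(M, Y), class = "edge_glm")
}

#' Random permutation within exchangeability blocks
#'
#' Shuffles scan indices independently and uniformly inside each block
#' (each subject's own scans), leaving the block structure intact.
#' Uses the current RNG state.
#'
#' @param exchange_blocks factor (or vector) assigning each scan to a
#'   block.
#' @return integer permutation of `seq_along(exchange_blocks)`.
#' @export
permute_within_blocks <- function(exchange_blocks) {
  blocks <- as.factor(exchange_blocks)
  if (all(table(blocks) == 1L)) {
    warning("all exchangeability blocks have size 1; ",
            "only the identity permutation exists")
  }
  perm <- seq_along(blocks)
  for (b in levels(blocks)) {
    idx <- which(blocks == b)
    if (length(idx) > 1L) perm[idx] <- idx[sample.int(length(idx))]
  }
  perm
}

#' Enumerate all within-block permutations
#'
#' Lists every permutation that shuffles only within blocks; there are
#' `prod(n_b!)` of them.  Intended for exact inference on small
#' designs.
#'
#' @param exchange_blocks block assignment per scan.
#' @param max_perms safety cap on the number of permutations (default
#'   100000).
#' @return integer matrix, one permutation per row.
#' @export
enumerate_block_permutations <- function(exchange_blocks,
                                         max_perms = 1e5) {
  blocks <- as.factor(exchange_blocks)
  idx_by_block <- split(seq_along(blocks), blocks)
  all_perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  per_block <- lapply(idx_by_block, all_perms)
  total <- prod(vapply(per_block, length, 0))
  if (total > max_perms) {
    stop("design has ", total, " within-block permutations, ",
         "exceeding max_perms = ", max_perms, call. = FALSE)
  }
  grid <- do.call(expand.grid, lapply(per_block, seq_along))
  out <- matrix(NA_integer_, nrow(grid), length(blocks))
  for (r in seq_len(nrow(grid))) {
    perm <- integer(length(blocks))
    for (b in seq_along(per_block)) {
      perm[idx_by_block[[b]]] <- per_block[[b]][[grid[r, b]]]
    }
    out[r, ] <- perm
  }
  out
}

#' Select supra-threshold edges
#'
#' @param stats an `edge_glm` (or numeric vector of t values).
#' @param threshold positive primary threshold on the t statistic.
#' @param tail `"positive"` (t > threshold), `"negative"`
#'   (t < -threshold) or `"two_sided"` (|t| > threshold).
#' @return integer vector of edge positions in canonical order.
#' @export
threshold_edges <- function(stats, threshold,
                            tail = c("positive", "negative", "two_sided")) {
  tail <- match.arg(tail)
  t <- if (inherits(stats, "edge_glm")) stats$t else as.numeric(stats)
  if (threshold <= 0) stop("'threshold' must be positive", call. = FALSE)
  switch(tail,
         positive = which(t > threshold),
         negative = which(t < -threshold),
         two_sided = which(abs(t) > threshold))
}

# connected-component labels per edge for a k x 2 pair matrix
.edge_components <- function(pairs) {
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  memb <- igraph::components(g)$membership
  memb[pairs[, 1]]
}

# union-find over the edges of a small graph: returns the root label of
# each edge's component.  Used in the permutation loop, where the
# igraph construction overhead would dominate; [find_components()]
# (igraph-based) is the reference the tests compare against.
.uf_edge_labels <- function(pairs) {
  nodes <- unique(as.integer(pairs))
  parent <- seq_along(nodes)
  id <- match(pairs, nodes)
  dim(id) <- dim(pairs)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (e in seq_len(nrow(id))) {
    ra <- find(id[e, 1]); rb <- find(id[e, 2])
    if (ra != rb) parent[rb] <- ra
  }
  vapply(id[, 1], find, 0L)
}

#' Connected components of a supra-threshold edge set
#'
#' Components of the undirected graph formed by the selected edges,
#' sorted by extent (edge count) in decreasing order, ties broken by
#' smallest node index.
#'
#' @param pairs integer matrix (k x 2) of node pairs, `i < j`.
#' @return list of `nbs_component` objects, each with `edges` (pair
#'   matrix), `nodes`, `size_extent`.
#' @export
find_components <- function(pairs) {
  if (is.null(pairs) || NROW(pairs) == 0) return(list())
  pairs <- matrix(as.integer(pairs), ncol = 2)
  labels <- .edge_components(pairs)
  comps <- lapply(unique(labels), function(l) {
    e <- pairs[labels == l, , drop = FALSE]
    ord <- order(e[, 1], e[, 2])
    e <- e[ord, , drop = FALSE]
    structure(list(edges = e,
                   nodes = sort(unique(as.integer(e))),
                   size_extent = nrow(e)),
              class = "nbs_component")
  })
  ord <- order(-vapply(comps, function(c) c$size_extent, 0L),
               vapply(comps, function(c) min(c$nodes), 0L))
  comps[ord]
}

# size of the largest component under a chosen statistic
.max_component_size <- function(pairs, tvals = NULL, threshold = 0,
                                statistic = "extent") {
  if (NROW(pairs) == 0) return(0)
  labels <- .uf_edge_labels(pairs)
  if (statistic == "extent") {
    max(tabulate(labels))
  } else {
    w <- abs(tvals) - threshold
    max(tapply(w, labels, sum))
  }
}

#' Freedman-Lane permutation null of maximal component size
#'
#' For each permutation, the nuisance-only model is fitted per edge,
#' its residuals are permuted within exchangeability blocks and added
#' back to the nuisance fit, the full model is refitted on the
#' permuted data, the resulting t field is thresholded, and the size of
#' the largest connected component is recorded.  The refit is carried
#' out through the Frisch-Waugh-Lovell identity (residualized predictor
#' against residualized permuted responses), which is algebraically
#' identical to refitting the full model and avoids re-decomposing the
#' design.
#'
#' @param stack a `conn_stack`.
#' @param design an [nbs_design()] (indicator nuisance coding).
#' @param threshold primary t threshold.
#' @param tail test tail (see [threshold_edges()]).
#' @param n_perm number of permutations (>= 100 unless `exhaustive`).
#' @param seed RNG seed for the permutation stream.
#' @param exhaustive enumerate all within-block permutations instead of
#'   sampling (small designs only).
#' @param statistic component statistic: `"extent"` (edge count,
#'   default) or `"intensity"` (sum of |t| - threshold).
#' @return numeric vector of maximal component sizes, one per
#'   permutation, with attributes `n_perm` and `exhaustive`.
#' @export
freedman_lane_null <- function(stack, design, threshold,
                               tail = c("positive", "negative",
                                        "two_sided"),
                               n_perm = 5000, seed = 1,
                               exhaustive = FALSE,
                               statistic = c("extent", "intensity")) {
  tail <- match.arg(tail)
  statistic <- match.arg(statistic)
  null <- .fl_null_multi(stack, design, threshold, tails = tail,
                         n_perm = n_perm, seed = seed,
                         exhaustive = exhaustive, statistic = statistic)
  out <- null$max_sizes[, 1]
  attr(out, "n_perm") <- null$n_perm
  attr(out, "exhaustive") <- exhaustive
  out
}

# shared engine: one permutation stream, one or more tails scored
# against the same permuted t fields
.fl_null_multi <- function(stack, design, threshold, tails,
                           n_perm, seed, exhaustive = FALSE,
                           statistic = "extent") {
  stopifnot(inherits(design, "nbs_design"))
  if (design$nuisance_type != "indicators") {
    stop("the permutation null requires indicator nuisance coding",
         call. = FALSE)
  }
  Y <- stack$edges
  n <- nrow(Y)
  idx <- stack$edge_index
  qrN <- qr(design$nuisance)
  x <- design$predictor
  xr <- qr.resid(qrN, x)
  xss <- sum(xr^2)
  if (xss < 1e-14) {
    stop("predictor has no within-block variance", call. = FALSE)
  }
  df <- n - ncol(design$nuisance) - 1L
  R <- qr.resid(qrN, Y)
  # Within-block permutation maps every exchangeability block onto
  # itself, so the permuted residuals remain block-centered: the
  # nuisance re-projection of the Freedman-Lane refit is the identity
  # here, and the residual sum of squares per edge is unchanged by the
  # row shuffle.  Each permutation therefore reduces to one mat-vec
  # product with the (inverse-)permuted residualized predictor.
  den <- colSums(R^2)
  sdf <- sqrt(df)
  idx_list <- split(seq_len(n), design$exchange_blocks)
  perms <- if (exhaustive) {
    enumerate_block_permutations(design$exchange_blocks)
  } else {
    if (n_perm < 100) warning("n_perm < 100 gives coarse p-values")
    NULL
  }
  np <- if (exhaustive) nrow(perms) else n_perm
  max_sizes <- matrix(0, np, length(tails),
                      dimnames = list(NULL, tails))
  nonempty <- 0L
  run_one <- function(perm, p_row) {
    xp <- xr
    xp[perm] <- xr
    num <- as.numeric(crossprod(R, xp))
    disc <- pmax(xss * den - num^2, 0)
    # disc == 0 with num != 0 gives a perfect fit: t = +/-Inf; with
    # num == 0 the NaN is dropped by which() below
    t <- num * sdf / sqrt(disc)
    any_edges <- FALSE
    for (ti in seq_along(tails)) {
      keep <- switch(tails[ti],
                     positive = which(t > threshold),
                     negative = which(t < -threshold),
                     two_sided = which(abs(t) > threshold))
      if (length(keep)) {
        any_edges <- TRUE
        max_sizes[p_row, ti] <<- .max_component_size(
          idx[keep, , drop = FALSE], t[keep], threshold, statistic)
      }
    }
    any_edges
  }
  if (exhaustive) {
    for (p in seq_len(np)) {
      if (run_one(perms[p, ], p)) nonempty <- nonempty + 1L
    }
  } else {
    with_seed(seed, {
      for (p in seq_len(np)) {
        perm <- seq_len(n)
        for (ib in idx_list) {
          if (length(ib) > 1L) perm[ib] <- ib[sample.int(length(ib))]
        }
        if (run_one(perm, p)) nonempty <- nonempty + 1L
      }
    })
  }
  # a threshold so low that nearly every permutation yields one big
  # supra-threshold graph cannot rank the observed network
  if (statistic == "extent") {
    E <- ncol(Y)
    whole <- mean(max_sizes[, 1] >= 0.9 * E)
    if (whole > 0.5) {
      warning("threshold appears uninformative: the supra-threshold ",
              "graph spans nearly all edges in most permutations")
    }
  }
  list(max_sizes = max_sizes, n_perm = np, nonempty = nonempty)
}

#' Family-wise-error p-value of an observed component
#'
#' Position of the observed component size in the permutation null of
#' maximal sizes: `p = (1 + #\{null >= observed\}) / (1 + n_perm)` for
#' sampled permutations, or the exact proportion when the null was
#' enumerated exhaustively.
#'
#' @param observed observed component size (extent or intensity).
#' @param null_max_sizes vector from [freedman_lane_null()].
#' @param exhaustive was the null enumerated exhaustively?  Defaults to
#'   the attribute carried by `null_max_sizes`.
#' @return p-value in (0, 1].
#' @export
component_pvalue <- function(observed, null_max_sizes,
                             exhaustive = isTRUE(attr(null_max_sizes,
                                                      "exhaustive"))) {
  if (!length(null_max_sizes)) stop("empty null distribution",
                                    call. = FALSE)
  if (observed <= 0) return(1)
  hits <- sum(null_max_sizes >= observed)
  if (exhaustive) {
    hits / length(null_max_sizes)
  } else {
    (1 + hits) / (1 + length(null_max_sizes))
  }
}

#' Benjamini-Hochberg adjustment across a contrast family
#'
#' Standard step-up false-discovery-rate adjustment (with monotonicity
#' enforcement) applied to the family of network tests, e.g. 3
#' components x 2 one-sided tails.
#'
#' @param p vector of p-values.
#' @return adjusted p-values.
#' @export
adjust_fdr <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Standardized effect size of a network component
#'
#' Converts each component edge's t statistic to a per-edge Cohen's d
#' (`d = 2 t / sqrt(df)`, the paired/repeated-measures convention) and
#' averages the absolute values over the component's edges.
#'
#' @param stats an `edge_glm`.
#' @param edge_positions canonical edge positions of the component's
#'   edges.
#' @return list with `cohens_d` (mean |d|) and `mean_abs_t`.
#' @export
network_cohens_d <- function(stats, edge_positions) {
  stopifnot(inherits(stats, "edge_glm"))
  if (!length(edge_positions)) stop("component has no edges",
                                    call. = FALSE)
  if (stats$df <= 0) stop("non-positive residual degrees of freedom",
                          call. = FALSE)
  t <- stats$t[edge_positions]
  d <- 2 * t / sqrt(stats$df)
  list(cohens_d = mean(abs(d)), mean_abs_t = mean(abs(t)))
}

#' Run the full network-based statistic
#'
#' For each predictor column (typically the per-scan partial factor
#' scores of each retained MFA component) and each tail in the family,
#' fits the edge-wise GLM, extracts supra-threshold components, builds
#' the Freedman-Lane within-subject permutation null of maximal
#' component size, and assigns each observed component a family-wise
#' error p-value.  Benjamini-Hochberg FDR adjustment is then applied
#' across the contrast family (default: components x tails).
#'
#' @param stack a `conn_stack`.
#' @param scores numeric matrix (scans x components) or vector of
#'   per-scan predictor values, aligned with the stack.
#' @param threshold primary t threshold (default 4.7).
#' @param tails tails tested per predictor (default both one-sided
#'   tails).
#' @param n_perm permutations per contrast (default 5000).
#' @param seed seed for the permutation streams (required).
#' @param alpha FWE level used to label components significant
#'   (default 0.05).
#' @param statistic component statistic, `"extent"` or `"intensity"`.
#' @return object of class `nbs_run`: per-contrast results
#'   (`contrasts`), family FDR table (`family`), and provenance.
#' @export
run_nbs <- function(stack, scores, threshold = 4.7,
                    tails = c("positive", "negative"),
                    n_perm = 5000, seed, alpha = 0.05,
                    statistic = c("extent", "intensity")) {
  statistic <- match.arg(statistic)
  if (missing(seed)) stop("'seed' is required for reproducibility",
                          call. = FALSE)
  tails <- match.arg(tails, c("positive", "negative", "two_sided"),
                     several.ok = TRUE)
  scores <- as.matrix(scores)
  if (nrow(scores) != nrow(stack$edges)) {
    stop("scores must align with stack scans", call. = FALSE)
  }
  n_pred <- ncol(scores)
  base_seed <- derive_seed(seed, "nbs")
  contrasts <- list()
  for (c_i in seq_len(n_pred)) {
    design <- nbs_design(stack, scores[, c_i])
    stats <- fit_edge_glm(stack, design)
    null <- .fl_null_multi(stack, design, threshold, tails,
                           n_perm = n_perm,
                           seed = (base_seed + c_i) %% (2^31 - 1),
                           statistic = statistic)
    for (t_i in seq_along(tails)) {
      tail <- tails[t_i]
      keep <- threshold_edges(stats, threshold, tail)
      comps <- find_components(stack$edge_index[keep, , drop = FALSE])
      null_sizes <- null$max_sizes[, t_i]
      comps <- lapply(comps, function(cmp) {
        pos <- match_edge_rows(cmp$edges, stack$n_nodes)
        cmp$edge_positions <- pos
        cmp$statistic_value <- if (statistic == "extent") {
          cmp$size_extent
        } else {
          sum(abs(stats$t[pos]) - threshold)
        }
        cmp$p_fwe <- component_pvalue(cmp$statistic_value, null_sizes,
                                      exhaustive = FALSE)
        es <- network_cohens_d(stats, pos)
        cmp$cohens_d <- es$cohens_d
        cmp$mean_abs_t <- es$mean_abs_t
        cmp
      })
      contrasts[[length(contrasts) + 1L]] <- list(
        predictor = c_i, tail = tail,
        stats = stats, components = comps,
        null_max_sizes = null_sizes,
        p_min = if (length(comps)) {
          min(vapply(comps, function(cm) cm$p_fwe, 0))
        } else 1
      )
    }
  }
  p_family <- vapply(contrasts, function(cn) cn$p_min, 0)
  p_fdr <- adjust_fdr(p_family)
  family <- data.frame(
    predictor = vapply(contrasts, function(cn) cn$predictor, 0L),
    tail = vapply(contrasts, function(cn) cn$tail, ""),
    n_components = vapply(contrasts, function(cn)
      length(cn$components), 0L),
    p_fwe = p_family,
    p_fdr = p_fdr,
    significant = p_fdr <= alpha
  )
  structure(list(contrasts = contrasts, family = family,
                 threshold = threshold, tails = tails,
                 n_perm = n_perm, seed = seed, alpha = alpha,
                 statistic = statistic,
                 n_nodes = stack$n_nodes),
            class = "nbs_run")
}

#' @export
print.nbs_run <- function(x, ...) {
  cat(sprintf("Network-based statistic: threshold %.3g, %d permutations, %s\n",
              x$threshold, x$n_perm, x$statistic))
  print(x$family, digits = 4, row.names = FALSE)
  for (cn in x$contrasts) {
    for (cmp in cn$components) {
      cat(sprintf(
        "  predictor %d, %s tail: %d edges / %d nodes, p_fwe = %.4f, d = %.2f\n",
        cn$predictor, cn$tail, cmp$size_extent, length(cmp$nodes),
        cmp$p_fwe, cmp$cohens_d))
    }
  }
  invisible(x)
}

#' @export
print.nbs_component <- function(x, ...) {
  cat(sprintf("Network component: %d edges over %d nodes\n",
              x$size_extent, length(x$nodes)))
  if (!is.null(x$p_fwe)) {
    cat(sprintf("  p_fwe = %.4f, Cohen's d = %.3f\n", x$p_fwe, x$cohens_d))
  }
  invisible(x)
}
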