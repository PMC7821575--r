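#' Canonical edge index for an N-node undirected graph
#'
#' Edges are the upper triangle in row-major order:
#' (1,2), (1,3), ..., (1,N), (2,3), ..., (N-1,N).  All vectorized edge
#' representations in the package use this ordering; node indices are
#' 1-based (files written for external viewers keep the same 1-based
#' convention).
#'
#' @param n_nodes number of nodes.
#' @return integer matrix with `n_nodes * (n_nodes - 1) / 2` rows and
#'   columns `i`, `j` (`i < j`).
#' @export
edge_index <- function(n_nodes) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 2L)
  i <- rep.int(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  j <- unlist(lapply(seq_len(n_nodes - 1L),
                     function(k) (k + 1L):n_nodes), use.names = FALSE)
  cbind(i = i, j = as.integer(j))
}

# map rows of an (i, j) pair matrix (i < j) to positions in the
# canonical edge ordering
match_edge_rows <- function(pairs, n_nodes) {
  i <- as.numeric(pairs[, 1]); j <- as.numeric(pairs[, 2])
  if (any(i >= j) || any(i < 1) || any(j > n_nodes)) {
    stop("edge pairs must satisfy 1 <= i < j <= n_nodes", call. = FALSE)
  }
  # edges before row block i: (i-1) * n - i * (i - 1) / 2
  as.integer((i - 1) * n_nodes - i * (i - 1) / 2 + (j - i))
}

#' Pairwise Pearson correlation matrix of ROI time series
#'
#' @param ts numeric matrix, volumes x regions (>= 3 volumes).
#' @return symmetric regions x regions correlation matrix with unit
#'   diagonal.
#' @export
pearson_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("need at least 3 volumes", call. = FALSE)
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0] %||% which(sds == 0)
    stop("constant time series for region(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(ts)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Vectorize a symmetric matrix into the canonical edge order
#'
#' @param m square symmetric numeric matrix.
#' @return numeric vector of length `N (N - 1) / 2` in the
#'   [edge_index()] ordering.
#' @export
vectorize_edges <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (ncol(m) != n) stop("matrix must be square", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8) {
    stop("matrix must be symmetric", call. = FALSE)
  }
  idx <- edge_index(n)
  m[idx]
}

#' Rebuild a symmetric matrix from a canonical edge vector
#'
#' Inverse of [vectorize_edges()]; the diagonal is restored as 1
#' (self-connectivity).
#'
#' @param v edge vector of triangular length.
#' @param n_nodes number of nodes; inferred from `length(v)` if missing.
#' @param diag_value value for the diagonal (default 1).
#' @return symmetric `n_nodes x n_nodes` matrix.
#' @export
devectorize_edges <- function(v, n_nodes = NULL, diag_value = 1) {
  e <- length(v)
  if (is.null(n_nodes)) {
    n_nodes <- (1 + sqrt(1 + 8 * e)) / 2
    if (n_nodes != round(n_nodes)) {
      stop("length ", e, " is not a triangular number N(N-1)/2",
           call. = FALSE)
    }
    n_nodes <- as.integer(round(n_nodes))
  } else if (e != n_nodes * (n_nodes - 1) / 2) {
    stop("edge vector length does not match n_nodes", call. = FALSE)
  }
  m <- matrix(0, n_nodes, n_nodes)
  idx <- edge_index(n_nodes)
  m[idx] <- v
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Fisher z transform of correlation values
#'
#' Optional variance-stabilizing transform (`atanh`); the default
#' analysis operates on raw Pearson R.  Values at exactly +/-1 are
#' clipped inward by 1e-7 with a warning.
#'
#' @param r numeric vector of correlations in \[-1, 1\].
#' @return transformed values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1)) stop("correlations must lie in [-1, 1]",
                            call. = FALSE)
  if (any(abs(r) == 1)) {
    warning("|r| = 1 clipped to 1 - 1e-7 before atanh")
    r <- pmin(1 - 1e-7, pmax(-1 + 1e-7, r))
  }
  atanh(r)
}

#' Construct a connectivity stack
#'
#' Low-level constructor used by the generator and by [build_stack()].
#'
#' @param edges scans x E numeric matrix of edge values in canonical
#'   order.
#' @param meta data frame with columns `subject_id`, `day`, `run`, one
#'   row per scan, aligned with `edges`.
#' @param nodes node metadata data frame: `label`, `hemisphere`, `x`,
#'   `y`, `z` (MNI millimeters).
#' @param n_nodes number of nodes.
#' @return object of class `conn_stack`.
#' @export
connectivity_stack <- function(edges, meta, nodes, n_nodes) {
  edges <- as.matrix(edges)
  n_nodes <- check_count(n_nodes, "n_nodes", min = 2L)
  E <- n_nodes * (n_nodes - 1L) / 2
  if (ncol(edges) != E) {
    stop("edges must have N(N-1)/2 = ", E, " columns", call. = FALSE)
  }
  if (nrow(meta) != nrow(edges)) {
    stop("metadata rows must match scans", call. = FALSE)
  }
  need <- c("subject_id", "day", "run")
  if (!all(need %in% names(meta))) {
    stop("meta must contain columns subject_id, day, run", call. = FALSE)
  }
  if (nrow(nodes) != n_nodes) {
    stop("node table must have one row per node", call. = FALSE)
  }
  structure(list(edges = edges,
                 meta = as.data.frame(meta)[need],
                 nodes = as.data.frame(nodes),
                 n_nodes = n_nodes,
                 edge_index = edge_index(n_nodes)),
            class = "conn_stack")
}

#' Build an aligned connectivity stack from matrices or time series
#'
#' Accepts per-scan square connectivity matrices or ROI time series
#' (converted with [pearson_matrix()]).  Only subjects with all four
#' usable scans (2 days x 2 runs) are retained -- the within-subject
#' permutation scheme of the network GLM requires complete cases; any
#' incomplete subject is dropped with a warning naming it.  When a
#' questionnaire table is supplied, scans are additionally required to
#' match its blocks one-to-one on (subject, day, run), and the stack is
#' ordered subject-major to align with it.
#'
#' @param x list of square symmetric matrices, or list of volumes x
#'   regions time-series matrices (detected by `type`).
#' @param meta data frame (`subject_id`, `day`, `run`), one row per
#'   element of `x`.
#' @param nodes node metadata table.
#' @param questionnaire optional [multiblock_table()] to align with.
#' @param type `"matrix"` or `"timeseries"`.
#' @return a `conn_stack`.
#' @export
build_stack <- function(x, meta, nodes, questionnaire = NULL,
                        type = c("matrix", "timeseries")) {
  type <- match.arg(type)
  if (length(x) == 0) stop("no scans supplied", call. = FALSE)
  if (nrow(meta) != length(x)) {
    stop("meta must have one row per scan", call. = FALSE)
  }
  mats <- lapply(x, function(m) {
    if (type == "timeseries") pearson_matrix(m) else {
      m <- as.matrix(m)
      if (nrow(m) != ncol(m)) stop("connectivity matrix must be square",
                                   call. = FALSE)
      m
    }
  })
  N <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, 0L) != N)) {
    stop("all scans must share the same region count", call. = FALSE)
  }
  key <- interaction(meta$subject_id, meta$day, meta$run, drop = TRUE)
  if (anyDuplicated(key)) {
    stop("duplicate (subject, day, run) scan", call. = FALSE)
  }
  counts <- table(meta$subject_id)
  complete <- names(counts)[counts == 4L]
  dropped <- setdiff(unique(meta$subject_id), complete)
  if (length(dropped)) {
    warning("dropping subject(s) without all 4 usable scans: ",
            paste(dropped, collapse = ", "))
  }
  if (!is.null(questionnaire)) {
    qsub <- questionnaire$subject_ids
    extra <- setdiff(complete, qsub)
    if (length(extra)) {
      warning("dropping scan subject(s) absent from questionnaire: ",
              paste(extra, collapse = ", "))
    }
    complete <- intersect(complete, qsub)
  }
  if (!length(complete)) stop("no complete subjects remain", call. = FALSE)
  keep_meta <- meta[meta$subject_id %in% complete, , drop = FALSE]
  ord <- order(match(keep_meta$subject_id, complete),
               keep_meta$day, keep_meta$run)
  rows <- which(meta$subject_id %in% complete)[ord]
  edges <- t(vapply(mats[rows], vectorize_edges,
                    numeric(N * (N - 1L) / 2)))
  connectivity_stack(edges = edges,
                     meta = meta[rows, , drop = FALSE],
                     nodes = nodes, n_nodes = N)
}

#' @export
print.conn_stack <- function(x, ...) {
  cat(sprintf("Connectivity stack: %d scans x %d edges (%d nodes)\n",
              nrow(x$edges), ncol(x$edges), x$n_nodes))
  cat(sprintf("  %d subjects, edge range [%.3f, %.3f]\n",
              length(unique(x$meta$subject_id)),
              min(x$edges), max(x$edges)))
  invisible(x)
}
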