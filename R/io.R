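# File formats: comma-separated tables with a header row, "." decimal,
# UTF-8; square matrices are whitespace-delimited for compatibility
# with surface/graph viewers; structured results are JSON.

#' Read a long-format questionnaire file
#'
#' Expects a CSV with columns `subject_id`, `day`, `run` and the item
#' columns (`item_01` ... `item_12`), one row per subject x occasion.
#' Duplicate (subject, day, run) rows are a hard error; subjects
#' without the complete 2 days x 2 runs design are dropped with a
#' warning, since the within-subject permutation scheme downstream
#' requires all four scans.
#'
#' @param path CSV file path.
#' @return a [multiblock_table()].
#' @export
read_questionnaire <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  need <- c("subject_id", "day", "run")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("questionnaire file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  item_cols <- grep("^item_", names(df), value = TRUE)
  if (length(item_cols) < 2) {
    stop("no item_* columns found in ", path, call. = FALSE)
  }
  for (col in item_cols) {
    if (!is.numeric(df[[col]])) {
      stop("non-numeric values in item column '", col, "'",
           call. = FALSE)
    }
  }
  if (anyNA(df[item_cols])) {
    stop("missing item values are not supported", call. = FALSE)
  }
  key <- paste(df$subject_id, df$day, df$run, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (subject, day, run) row(s): ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "),
         call. = FALSE)
  }
  des <- block_design()
  complete <- vapply(split(df, df$subject_id), function(d) {
    nrow(d) == 4L &&
      all(paste(des$day, des$run) %in% paste(d$day, d$run))
  }, TRUE)
  keep <- names(complete)[complete]
  dropped <- names(complete)[!complete]
  if (length(dropped)) {
    warning("dropping subject(s) without all 4 occasions: ",
            paste(dropped, collapse = ", "))
  }
  if (!length(keep)) stop("no subject has the complete design",
                          call. = FALSE)
  keep <- unique(df$subject_id)[unique(df$subject_id) %in% keep]
  blocks <- lapply(seq_len(4L), function(b) {
    sub <- df[df$day == des$day[b] & df$run == des$run[b] &
                df$subject_id %in% keep, , drop = FALSE]
    sub <- sub[match(keep, sub$subject_id), , drop = FALSE]
    as.matrix(sub[item_cols])
  })
  multiblock_table(values = do.call(cbind, blocks),
                   subject_ids = keep, items = item_cols,
                   blocks = des)
}

#' Write a questionnaire table in long format
#'
#' @param table a [multiblock_table()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_questionnaire <- function(table, path) {
  stopifnot(inherits(table, "mb_table"))
  rows <- lapply(seq_len(4L), function(b) {
    vals <- table$values[, table$col_block == b, drop = FALSE]
    colnames(vals) <- table$items
    data.frame(subject_id = table$subject_ids,
               day = table$blocks$day[b],
               run = table$blocks$run[b],
               vals, check.names = FALSE)
  })
  long <- do.call(rbind, rows)
  long <- long[order(match(long$subject_id, table$subject_ids),
                     long$day, long$run), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a node metadata table
#'
#' CSV with columns `label`, `hemisphere`, `x`, `y`, `z` (MNI
#' millimeters).
#'
#' @param path CSV file path.
#' @return data frame.
#' @export
read_node_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "hemisphere", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("node table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df[need]
}

#' Write a connectivity stack as per-scan matrix files
#'
#' Each scan's square symmetric matrix goes to a whitespace-delimited
#' file; a `scans.csv` manifest records (subject, day, run, file) and
#' `nodes.csv` the node table.
#'
#' @param stack a `conn_stack`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "conn_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(nrow(stack$edges))
  for (s in seq_len(nrow(stack$edges))) {
    m <- devectorize_edges(stack$edges[s, ], stack$n_nodes)
    files[s] <- sprintf("conn_%s_d%dr%d.txt", stack$meta$subject_id[s],
                        stack$meta$day[s], stack$meta$run[s])
    utils::write.table(format(m, digits = 10, trim = TRUE),
                       file.path(dir, files[s]),
                       row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  manifest <- cbind(stack$meta, file = files)
  utils::write.csv(manifest, file.path(dir, "scans.csv"),
                   row.names = FALSE)
  utils::write.csv(stack$nodes, file.path(dir, "nodes.csv"),
                   row.names = FALSE)
  invisible(file.path(dir, "scans.csv"))
}

#' Read a connectivity stack written by [write_stack()]
#'
#' @param dir directory containing `scans.csv`, `nodes.csv` and the
#'   per-scan matrix files.
#' @param questionnaire optional [multiblock_table()] to align with.
#' @return a `conn_stack`.
#' @export
read_stack <- function(dir, questionnaire = NULL) {
  manifest <- utils::read.csv(file.path(dir, "scans.csv"),
                              stringsAsFactors = FALSE)
  nodes <- read_node_table(file.path(dir, "nodes.csv"))
  mats <- lapply(manifest$file, function(f) {
    as.matrix(utils::read.table(file.path(dir, f)))
  })
  build_stack(mats, manifest[c("subject_id", "day", "run")], nodes,
              questionnaire = questionnaire, type = "matrix")
}

#' Write network component tables and viewer files
#'
#' For each reported component: a node table (atlas label, hemisphere,
#' MNI coordinates), an edge-pair table listing the direct region
#' connections, and graph-viewer files -- a `.node` file
#' (`x y z color size label`, whitespace-delimited) and a `.edge` file
#' (square symmetric 0/1 adjacency over the component's nodes).  Node
#' indices in files are 1-based.  With no components, empty tables
#' with headers are still written.
#'
#' @param run an `nbs_run`.
#' @param node_table node metadata for all nodes of the analysis.
#' @param dir output directory.
#' @param alpha only components with `p_fwe <= alpha` are written
#'   (default: the run's alpha).
#' @return data frame listing the files written, invisibly.
#' @export
write_network_tables <- function(run, node_table, dir,
                                 alpha = run$alpha) {
  stopifnot(inherits(run, "nbs_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(node_table) < run$n_nodes) {
    stop("node table does not cover all analysis nodes", call. = FALSE)
  }
  node_header <- data.frame(node = integer(), label = character(),
                            hemisphere = character(), x = numeric(),
                            y = numeric(), z = numeric())
  edge_header <- data.frame(node_i = integer(), node_j = integer(),
                            label_i = character(), label_j = character())
  written <- list()
  k <- 0L
  for (cn in run$contrasts) {
    for (cmp in cn$components) {
      if (is.null(cmp$p_fwe) || cmp$p_fwe > alpha) next
      k <- k + 1L
      if (any(cmp$nodes > nrow(node_table))) {
        stop("component references node absent from node table",
             call. = FALSE)
      }
      stem <- sprintf("network_%02d", k)
      nt <- data.frame(node = cmp$nodes,
                       node_table[cmp$nodes, , drop = FALSE])
      nt$x <- round(nt$x, 2); nt$y <- round(nt$y, 2)
      nt$z <- round(nt$z, 2)
      utils::write.csv(nt, file.path(dir, paste0(stem, "_nodes.csv")),
                       row.names = FALSE)
      et <- data.frame(node_i = cmp$edges[, 1], node_j = cmp$edges[, 2],
                       label_i = node_table$label[cmp$edges[, 1]],
                       label_j = node_table$label[cmp$edges[, 2]])
      utils::write.csv(et, file.path(dir, paste0(stem, "_edges.csv")),
                       row.names = FALSE)
      # viewer files over the component's nodes only
      degree <- tabulate(match(as.integer(cmp$edges), cmp$nodes),
                         nbins = length(cmp$nodes))
      bn <- data.frame(x = round(node_table$x[cmp$nodes], 2),
                       y = round(node_table$y[cmp$nodes], 2),
                       z = round(node_table$z[cmp$nodes], 2),
                       color = k, size = degree,
                       label = gsub("[[:space:]]+", "_",
                                    node_table$label[cmp$nodes]))
      utils::write.table(bn, file.path(dir, paste0(stem, ".node")),
                         row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
      m <- length(cmp$nodes)
      adj <- matrix(0L, m, m)
      ei <- match(cmp$edges[, 1], cmp$nodes)
      ej <- match(cmp$edges[, 2], cmp$nodes)
      adj[cbind(ei, ej)] <- 1L
      adj[cbind(ej, ei)] <- 1L
      utils::write.table(adj, file.path(dir, paste0(stem, ".edge")),
                         row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
      written[[k]] <- data.frame(component = k,
                                 predictor = cn$predictor,
                                 tail = cn$tail,
                                 extent = cmp$size_extent,
                                 p_fwe = cmp$p_fwe,
                                 cohens_d = cmp$cohens_d,
                                 stem = stem)
    }
  }
  if (k == 0L) {
    utils::write.csv(node_header, file.path(dir, "network_00_nodes.csv"),
                     row.names = FALSE)
    utils::write.csv(edge_header, file.path(dir, "network_00_edges.csv"),
                     row.names = FALSE)
    out <- data.frame()
  } else {
    out <- do.call(rbind, written)
    utils::write.csv(out, file.path(dir, "networks_summary.csv"),
                     row.names = FALSE)
  }
  invisible(out)
}

#' Read an edge-pair table back into a canonical pair matrix
#'
#' @param path CSV written by [write_network_tables()] (columns
#'   `node_i`, `node_j`).
#' @return integer matrix of canonical node pairs (i < j, sorted).
#' @export
read_edge_pairs <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("node_i", "node_j") %in% names(df))) {
    stop("edge table needs columns node_i, node_j", call. = FALSE)
  }
  if (!nrow(df)) return(matrix(integer(), 0, 2))
  pairs <- cbind(pmin(df$node_i, df$node_j),
                 pmax(df$node_i, df$node_j))
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  storage.mode(pairs) <- "integer"
  pairs
}

#' Save simulation ground truth as JSON
#'
#' @param truth a `ground_truth` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  payload <- list(
    true_scores = truth$true_scores,
    dim = dim(truth$true_scores),
    planted_edges = truth$planted_edges,
    beta = truth$beta
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' JSON summary of an NBS run
#'
#' Null-distribution summary, per-contrast results and full provenance
#' (seed, threshold, permutation count).
#'
#' @param run an `nbs_run`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_nbs_report <- function(run, path) {
  stopifnot(inherits(run, "nbs_run"))
  contrasts <- lapply(run$contrasts, function(cn) {
    list(predictor = cn$predictor, tail = cn$tail,
         p_min = cn$p_min,
         null_max_size = list(mean = mean(cn$null_max_sizes),
                              q95 = as.numeric(
                                stats::quantile(cn$null_max_sizes, 0.95)),
                              max = max(cn$null_max_sizes)),
         components = lapply(cn$components, function(cmp) {
           list(extent = cmp$size_extent,
                n_nodes = length(cmp$nodes),
                p_fwe = cmp$p_fwe,
                cohens_d = cmp$cohens_d,
                mean_abs_t = cmp$mean_abs_t)
         }))
  })
  payload <- list(
    threshold = run$threshold, tails = run$tails,
    n_perm = run$n_perm, seed = run$seed, alpha = run$alpha,
    statistic = run$statistic,
    family = run$family,
    contrasts = contrasts
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(path)
}
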