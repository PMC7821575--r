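#' Construct a multi-block questionnaire table
#'
#' Holds the subjects x (items x blocks) response matrix for a
#' repeated-measures questionnaire with four occasions crossed as
#' 2 days x 2 runs.  Columns are block-major: all items of block 1,
#' then all items of block 2, and so on.
#'
#' @param values numeric matrix, subjects x (items * 4), no missing
#'   values.
#' @param subject_ids character vector of subject identifiers.
#' @param items character vector of item names.
#' @param blocks data frame with columns `block`, `day`, `run` (one row
#'   per occasion, exactly 4).
#' @return object of class `mb_table`.
#' @export
multiblock_table <- function(values, subject_ids, items,
                             blocks = block_design()) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("questionnaire values must not contain NA",
                          call. = FALSE)
  if (nrow(blocks) != 4L) stop("exactly 4 blocks are required",
                               call. = FALSE)
  n_items <- length(items)
  if (ncol(values) != n_items * 4L) {
    stop("values must have items x 4 columns", call. = FALSE)
  }
  if (nrow(values) != length(subject_ids)) {
    stop("one row per subject required", call. = FALSE)
  }
  colnames(values) <- paste0(rep(items, 4), ".d",
                             rep(blocks$day, each = n_items), "r",
                             rep(blocks$run, each = n_items))
  rownames(values) <- subject_ids
  structure(list(values = values,
                 subject_ids = as.character(subject_ids),
                 items = as.character(items),
                 blocks = as.data.frame(blocks),
                 col_block = rep(seq_len(4L), each = n_items)),
            class = "mb_table")
}

#' @export
print.mb_table <- function(x, ...) {
  cat(sprintf("Multi-block questionnaire: %d subjects x %d items x 4 blocks\n",
              length(x$subject_ids), length(x$items)))
  cat("  blocks:", paste(sprintf("(day %d, run %d)", x$blocks$day,
                                 x$blocks$run), collapse = " "), "\n")
  invisible(x)
}

#' Center (and scale) each questionnaire block independently
#'
#' Each occasion is treated as a separate data block and standardized
#' on its own: columns are centered within block and, by default,
#' scaled to unit variance so items with different usage ranges
#' contribute comparably.
#'
#' @param table a [multiblock_table()].
#' @param scale scale columns to unit variance (default TRUE).
#' @return list of 4 standardized subjects x items matrices.
#' @export
preprocess_blocks <- function(table, scale = TRUE) {
  stopifnot(inherits(table, "mb_table"))
  n <- length(table$subject_ids)
  if (n < 3) stop("at least 3 subjects are required", call. = FALSE)
  lapply(seq_len(4L), function(b) {
    X <- table$values[, table$col_block == b, drop = FALSE]
    ctr <- colMeans(X)
    X <- sweep(X, 2, ctr)
    if (scale) {
      s <- apply(X, 2, stats::sd)
      if (any(s == 0)) {
        stop("zero-variance column(s) in block ", b, ": ",
             paste(colnames(X)[s == 0], collapse = ", "),
             " (disable scaling or drop the item)", call. = FALSE)
      }
      X <- sweep(X, 2, s, "/")
    }
    X
  })
}

#' Block weights for multiple factor analysis
#'
#' Every block receives the standard MFA weight 1 / (first singular
#' value)^2, which makes each block's leading dimension contribute unit
#' inertia to the grand analysis.  With `nested = TRUE` the crossed
#' day/run structure is normalized as well: the base-weighted blocks of
#' each day (blocks 1&2, 3&4) and of each run ("time point": blocks
#' 1&3, 2&4) are concatenated, and each block's weight is further
#' divided by the squared first singular value of its day group and of
#' its run group.
#'
#' @param blocks list of standardized block matrices from
#'   [preprocess_blocks()].
#' @param block_labels data frame with `day` and `run` per block
#'   (default the 2 x 2 crossed design).
#' @param nested apply the two-level day/run normalization (default
#'   TRUE).
#' @return object of class `mfa_weights`: `block_weight`, `block_sv1`,
#'   `day_factor`, `time_factor`, `nested`.
#' @export
compute_block_weights <- function(blocks, block_labels = block_design(),
                                  nested = TRUE) {
  stopifnot(is.list(blocks), length(blocks) == nrow(block_labels))
  sv1 <- vapply(blocks, function(X) {
    d1 <- svd(X, nu = 0, nv = 0)$d[1]
    if (!is.finite(d1) || d1 < 1e-12) {
      stop("degenerate (all-zero) block", call. = FALSE)
    }
    d1
  }, 0)
  base_w <- 1 / sv1^2
  K <- length(blocks)
  day_factor <- rep(1, K)
  time_factor <- rep(1, K)
  if (nested) {
    group_factor <- function(labels) {
      fac <- rep(1, K)
      for (g in unique(labels)) {
        members <- which(labels == g)
        Zg <- do.call(cbind, lapply(members, function(b) {
          sqrt(base_w[b]) * blocks[[b]]
        }))
        fac[members] <- svd(Zg, nu = 0, nv = 0)$d[1]^2
      }
      fac
    }
    day_factor <- group_factor(block_labels$day)
    time_factor <- group_factor(block_labels$run)
  }
  structure(list(block_weight = base_w / (day_factor * time_factor),
                 block_sv1 = sv1,
                 day_factor = day_factor,
                 time_factor = time_factor,
                 nested = nested),
            class = "mfa_weights")
}

#' Fit the multi-block factor analysis
#'
#' Performs the grand eigendecomposition of the column-weighted
#' concatenated table (a generalized PCA): with block weights `w_b`,
#' the SVD of `Z = [sqrt(w_b) X_b]` yields eigenvalues (squared
#' singular values), factor loadings, compromise factor scores for each
#' subject, and partial factor scores for each subject at each
#' occasion.  The compromise score is the barycenter (mean) of the four
#' partial scores.  Component signs are fixed so the loading of largest
#' magnitude is positive.
#'
#' @param blocks standardized blocks from [preprocess_blocks()].
#' @param weights an `mfa_weights` object.
#' @param n_components number of components to retain (must not exceed
#'   `min(subjects - 1, total columns)`).
#' @param items,subject_ids optional names carried into the result.
#' @return object of class `mfa_fit` with elements `eigenvalues`,
#'   `eigenvalues_all`, `variance_explained`, `loadings`,
#'   `compromise_scores`, `partial_scores` (list of 4 matrices),
#'   `contributions` (items x 4 x L array), `weights`, `col_block`.
#' @export
fit_mfa <- function(blocks, weights, n_components = 3,
                    items = NULL, subject_ids = NULL) {
  stopifnot(is.list(blocks), inherits(weights, "mfa_weights"))
  K <- length(blocks)
  n <- nrow(blocks[[1]])
  J <- ncol(blocks[[1]])
  w <- weights$block_weight
  if (length(w) != K) stop("weights do not match block count",
                           call. = FALSE)
  n_components <- check_count(n_components, "n_components")
  max_comp <- min(n - 1L, K * J)
  if (n_components > max_comp) {
    stop("'n_components' may not exceed min(subjects - 1, columns) = ",
         max_comp, call. = FALSE)
  }
  col_block <- rep(seq_len(K), each = J)
  w_col <- w[col_block]
  Z <- do.call(cbind, lapply(seq_len(K), function(b) sqrt(w[b]) * blocks[[b]]))
  sv <- svd(Z)
  lambda_all <- sv$d^2
  L <- n_components
  d <- sv$d[seq_len(L)]
  if (any(d^2 < 1e-12)) {
    stop("requested component with (near) zero eigenvalue", call. = FALSE)
  }
  U <- sv$u[, seq_len(L), drop = FALSE]
  V <- sv$v[, seq_len(L), drop = FALSE]
  # generalized loadings (unit norm in the block-weight metric)
  Qg <- V / sqrt(w_col)
  # reported loadings: scaled by the singular value, analogous to
  # variable factor scores in PCA
  q <- sweep(Qg, 2, d, "*")
  # orient each component so its largest-magnitude loading is positive
  flip <- vapply(seq_len(L), function(l) {
    sign(q[which.max(abs(q[, l])), l])
  }, 0)
  flip[flip == 0] <- 1
  q <- sweep(q, 2, flip, "*")
  Qg <- sweep(Qg, 2, flip, "*")
  U <- sweep(U, 2, flip, "*")
  compromise <- sweep(U, 2, d, "*")
  partial <- lapply(seq_len(K), function(b) {
    Fb <- K * w[b] * blocks[[b]] %*% Qg[col_block == b, , drop = FALSE]
    dimnames(Fb) <- list(subject_ids, paste0("PC", seq_len(L)))
    Fb
  })
  names(partial) <- paste0("block", seq_len(K))
  item_names <- items %||% sprintf("var_%02d", seq_len(J))
  rownames(q) <- paste0(rep(item_names, K), ".block", col_block)
  colnames(q) <- paste0("PC", seq_len(L))
  dimnames(compromise) <- list(subject_ids, paste0("PC", seq_len(L)))
  out <- structure(list(
    eigenvalues = lambda_all[seq_len(L)],
    eigenvalues_all = lambda_all,
    variance_explained = lambda_all[seq_len(L)] / sum(lambda_all),
    loadings = q,
    generalized_loadings = Qg,
    compromise_scores = compromise,
    partial_scores = partial,
    weights = weights,
    col_block = col_block,
    items = item_names,
    n_blocks = K,
    n_subjects = n
  ), class = "mfa_fit")
  out$contributions <- compute_contributions(out, weights)
  out
}

#' Factor contributions of each item at each occasion
#'
#' The squared factor loading, multiplied by its block weight and
#' normalized by the component eigenvalue: the fraction of a
#' component's variance attributable to one item at one occasion.
#' Within each component the contributions over all item x block cells
#' sum to 1.
#'
#' @param result an `mfa_fit`.
#' @param weights the `mfa_weights` used in the fit (defaults to those
#'   stored in `result`).
#' @return array items x 4 x components of contributions.
#' @export
compute_contributions <- function(result, weights = result$weights) {
  stopifnot(inherits(result, "mfa_fit"))
  q <- result$loadings
  lambda <- result$eigenvalues
  if (any(lambda <= 1e-12)) {
    stop("contribution undefined for zero-eigenvalue component",
         call. = FALSE)
  }
  w_col <- weights$block_weight[result$col_block]
  ctr_flat <- sweep(w_col * q^2, 2, lambda, "/")
  J <- length(result$items)
  K <- result$n_blocks
  L <- length(lambda)
  ctr <- array(NA_real_, dim = c(J, K, L),
               dimnames = list(item = result$items,
                               block = paste0("block", seq_len(K)),
                               component = paste0("PC", seq_len(L))))
  for (b in seq_len(K)) {
    ctr[, b, ] <- ctr_flat[result$col_block == b, , drop = FALSE]
  }
  ctr
}

#' Fit MFA to a questionnaire table
#'
#' Convenience wrapper: standardizes the blocks, computes (nested)
#' block weights, and fits the grand decomposition.
#'
#' @param table a [multiblock_table()].
#' @param scale standardize item variances within block (default TRUE).
#' @param nested use the nested day/run normalization (default TRUE).
#' @param n_components components to retain (default 3).
#' @return an `mfa_fit`.
#' @export
mfa <- function(table, scale = TRUE, nested = TRUE, n_components = 3) {
  blocks <- preprocess_blocks(table, scale = scale)
  weights <- compute_block_weights(blocks, table$blocks, nested = nested)
  fit_mfa(blocks, weights, n_components = n_components,
          items = table$items, subject_ids = table$subject_ids)
}

#' Bootstrap significance of summed item contributions
#'
#' For each item, the four per-occasion contributions to one component
#' are resampled with replacement (4 draws per replicate) and summed;
#' the percentile interval of the resampled sums forms the confidence
#' interval.  Under equal contribution of all items, the expected
#' summed contribution is `1 / n_items` (1/12 = 0.083 for the standard
#' 12-item questionnaire); an item is flagged as a reliable contributor
#' when the lower confidence bound exceeds that expected value, i.e.
#' when it is consistently influential across all four occasions.
#'
#' @param result an `mfa_fit` (or an items x 4 contribution matrix).
#' @param component which component to assess (default 1).
#' @param n_boot bootstrap replicates (default 10000; fewer than 100
#'   triggers a warning, fewer than 2 an error).
#' @param alpha nominal significance level (default 0.05).
#' @param bonferroni divide `alpha` by the number of items (default
#'   TRUE).
#' @param seed RNG seed for the resampling.
#' @return a `contribution_summary` data frame with per-item observed
#'   summed contribution, bootstrap median, corrected and uncorrected
#'   percentile bounds, and significance flags.
#' @export
bootstrap_contributions <- function(result, component = 1, n_boot = 10000,
                                    alpha = 0.05, bonferroni = TRUE,
                                    seed = 1) {
  if (inherits(result, "mfa_fit")) {
    ctr <- result$contributions[, , component]
  } else {
    ctr <- as.matrix(result)
  }
  if (ncol(ctr) != 4L) {
    stop("need the 4 per-occasion contributions per item", call. = FALSE)
  }
  n_boot <- check_count(n_boot, "n_boot")
  if (n_boot < 2) stop("'n_boot' must be at least 2", call. = FALSE)
  if (n_boot < 100) warning("n_boot < 100: confidence bounds are crude")
  n_items <- nrow(ctr)
  alpha_eff <- if (bonferroni) alpha / n_items else alpha
  expected <- 1 / n_items
  with_seed(derive_seed(seed, "bootstrap"), {
    rows <- lapply(seq_len(n_items), function(j) {
      draws <- matrix(sample(ctr[j, ], 4L * n_boot, replace = TRUE),
                      n_boot, 4L)
      sums <- rowSums(draws)
      ci <- stats::quantile(sums, c(alpha_eff / 2, 1 - alpha_eff / 2),
                            names = FALSE)
      ci_raw <- stats::quantile(sums, c(alpha / 2, 1 - alpha / 2),
                                names = FALSE)
      data.frame(item = rownames(ctr)[j] %||% paste0("item_", j),
                 observed = sum(ctr[j, ]),
                 boot_median = stats::median(sums),
                 ci_lower = ci[1], ci_upper = ci[2],
                 significant = ci[1] > expected,
                 ci_lower_unadj = ci_raw[1], ci_upper_unadj = ci_raw[2],
                 significant_unadj = ci_raw[1] > expected)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "expected_null") <- expected
    attr(out, "n_boot") <- n_boot
    attr(out, "alpha") <- alpha
    attr(out, "alpha_eff") <- alpha_eff
    attr(out, "bonferroni") <- isTRUE(bonferroni)
    attr(out, "component") <- component
    class(out) <- c("contribution_summary", "data.frame")
    out
  })
}

#' Eigenvalue / variance-explained table
#'
#' Ordered table of eigenvalues with the proportion and cumulative
#' proportion of total inertia, over the full spectrum of the fit.
#' Component retention (e.g. at a scree elbow) is left to the caller.
#'
#' @param result an `mfa_fit`.
#' @return data frame with `component`, `eigenvalue`, `proportion`,
#'   `cumulative`.
#' @export
variance_table <- function(result) {
  stopifnot(inherits(result, "mfa_fit"))
  lambda <- result$eigenvalues_all
  prop <- lambda / sum(lambda)
  data.frame(component = seq_along(lambda),
             eigenvalue = lambda,
             proportion = prop,
             cumulative = cumsum(prop))
}

#' @export
print.mfa_fit <- function(x, ...) {
  L <- length(x$eigenvalues)
  cat(sprintf("Multi-block factor analysis: %d subjects, %d items x %d blocks\n",
              x$n_subjects, length(x$items), x$n_blocks))
  cat(sprintf("  %d retained component(s); variance explained: %s\n", L,
              paste(sprintf("%.1f%%", 100 * x$variance_explained),
                    collapse = ", ")))
  cat(sprintf("  nested normalization: %s\n", x$weights$nested))
  invisible(x)
}

#' @export
print.contribution_summary <- function(x, ...) {
  if (!is.null(attr(x, "n_boot"))) {
    cat(sprintf(
      "Summed contributions, component %s (expected under equal loading: %.4f)\n",
      attr(x, "component"), attr(x, "expected_null")))
    cat(sprintf("  %d bootstrap replicates, alpha = %.4g%s\n",
                attr(x, "n_boot"), attr(x, "alpha_eff"),
                if (isTRUE(attr(x, "bonferroni")))
                  " (Bonferroni-corrected)" else ""))
  }
  print.data.frame(x, digits = 4)
  invisible(x)
}
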