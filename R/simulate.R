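#' Simulation parameters for a repeated-measures thought-probe study
#'
#' Bundles every knob of the synthetic-data generator.  The defaults
#' emulate a two-day, two-runs-per-day resting-state protocol in which
#' each scan is followed by a 12-item retrospective thought
#' questionnaire: 19 subjects with 4 usable scans each, items driven by
#' three latent thought dimensions, and a connectivity stack over a
#' scaled-down parcellation (60 nodes by default; up to 470 supported).
#'
#' @param n_subjects number of subjects (default 19).
#' @param n_blocks number of questionnaire/scan occasions per subject;
#'   fixed at 4, crossed as 2 days x 2 runs.
#' @param n_items number of questionnaire items (default 12).
#' @param n_nodes number of parcellation regions (default 60, max 470).
#' @param n_volumes volumes per simulated ROI time-series scan
#'   (default 300, i.e. 15 min at TR = 3 s).
#' @param latent_loadings `n_items x 3` matrix mapping the three latent
#'   thought factors to items.  Default: a block-structured matrix in
#'   which items 1-4, 5-8 and 9-12 each load on one factor.
#' @param subject_score_sd,block_score_sd standard deviations of the
#'   subject-level and occasion-level components of the latent factor
#'   scores; scalars are recycled over the three factors.  The default
#'   subject-level SDs decrease across factors (1.2, 0.9, 0.6) so the
#'   three thought dimensions carry distinct shares of variance and the
#'   recovered components are identifiable and ordered, as in any
#'   eigendecomposition-based factor structure; the occasion-level SD
#'   defaults to 0.5 for all factors.
#' @param item_noise_sd standard deviation of item-level Gaussian noise
#'   on the latent scale (default 0.3).
#' @param item_center,item_scale affine map from the latent scale to the
#'   0-100 visual-analog response scale: `value = center + scale * raw`,
#'   clipped to `[0, 100]` (defaults 50 and 15).
#' @param round_items round responses to whole numbers (default FALSE;
#'   the continuous scale keeps the factor-analysis assumptions clean).
#' @param planted_edges integer matrix with two columns giving node
#'   pairs (i < j) whose connectivity tracks a latent factor score, or
#'   NULL for no planted subnetwork.
#' @param beta effect per unit factor score on planted edges
#'   (correlation units).
#' @param edge_noise_sd scan-level edge noise SD (default 0.1).
#' @param base_edge_mean,base_edge_sd mean and SD of the per-edge
#'   population baseline connectivity (defaults 0.25, 0.08).
#' @param subject_edge_sd SD of stable subject-specific edge offsets
#'   (default 0.1); these are what the subject nuisance regressors in
#'   the network GLM absorb.
#' @param ts_rho,ts_n_communities,ts_coupling_base time-series generator
#'   settings: within-community signal share, number of communities, and
#'   baseline coupling of planted node pairs.
#' @param seed integer seed; expanded internally into independent
#'   per-stage child seeds.
#'
#' @return an object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_subjects = 19, n_blocks = 4, n_items = 12,
                       n_nodes = 60, n_volumes = 300,
                       latent_loadings = default_latent_loadings(n_items),
                       subject_score_sd = c(1.2, 0.9, 0.6),
                       block_score_sd = 0.5,
                       item_noise_sd = 0.3,
                       item_center = 50, item_scale = 15,
                       round_items = FALSE,
                       planted_edges = NULL, beta = 0,
                       edge_noise_sd = 0.1,
                       base_edge_mean = 0.25, base_edge_sd = 0.08,
                       subject_edge_sd = 0.1,
                       ts_rho = 0.3, ts_n_communities = 4,
                       ts_coupling_base = 0.2,
                       seed = 1) {
  n_subjects <- check_count(n_subjects, "n_subjects", min = 2L)
  n_blocks <- check_count(n_blocks, "n_blocks")
  if (n_blocks != 4L) {
    stop("'n_blocks' is fixed at 4 (2 days x 2 runs)", call. = FALSE)
  }
  n_items <- check_count(n_items, "n_items", min = 2L)
  n_nodes <- check_count(n_nodes, "n_nodes", min = 2L)
  if (n_nodes > 470L) stop("'n_nodes' may not exceed 470", call. = FALSE)
  n_volumes <- check_count(n_volumes, "n_volumes", min = 10L)

  latent_loadings <- as.matrix(latent_loadings)
  if (nrow(latent_loadings) != n_items || ncol(latent_loadings) != 3L) {
    stop("'latent_loadings' must be an n_items x 3 matrix", call. = FALSE)
  }
  for (nm in c("item_noise_sd", "edge_noise_sd", "base_edge_sd",
               "subject_edge_sd")) {
    assign(nm, check_nonneg(get(nm), nm))
  }
  for (nm in c("subject_score_sd", "block_score_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || !length(v) %in% c(1L, 3L) || anyNA(v) ||
        any(v < 0)) {
      stop("'", nm, "' must be 1 or 3 non-negative numbers",
           call. = FALSE)
    }
    assign(nm, rep_len(as.numeric(v), 3L))
  }
  if (!is.null(planted_edges)) {
    planted_edges <- as.matrix(planted_edges)
    storage.mode(planted_edges) <- "integer"
    if (ncol(planted_edges) != 2L) {
      stop("'planted_edges' must have two columns (i, j)", call. = FALSE)
    }
    if (any(planted_edges < 1L) || any(planted_edges > n_nodes)) {
      stop("planted edge outside node range 1..", n_nodes, call. = FALSE)
    }
    if (any(planted_edges[, 1] >= planted_edges[, 2])) {
      stop("'planted_edges' must satisfy i < j (upper triangle)",
           call. = FALSE)
    }
  }
  if (ts_rho < 0 || ts_rho > 1) stop("'ts_rho' must lie in [0, 1]",
                                     call. = FALSE)
  out <- list(
    n_subjects = n_subjects, n_blocks = n_blocks, n_items = n_items,
    n_nodes = n_nodes, n_volumes = n_volumes,
    latent_loadings = latent_loadings,
    subject_score_sd = subject_score_sd, block_score_sd = block_score_sd,
    item_noise_sd = item_noise_sd,
    item_center = item_center, item_scale = item_scale,
    round_items = isTRUE(round_items),
    planted_edges = planted_edges, beta = as.numeric(beta),
    edge_noise_sd = edge_noise_sd,
    base_edge_mean = as.numeric(base_edge_mean),
    base_edge_sd = base_edge_sd, subject_edge_sd = subject_edge_sd,
    ts_rho = as.numeric(ts_rho),
    ts_n_communities = check_count(ts_n_communities, "ts_n_communities"),
    ts_coupling_base = as.numeric(ts_coupling_base),
    seed = check_count(seed, "seed", min = 0L)
  )
  class(out) <- "sim_params"
  out
}

#' Default latent loading pattern
#'
#' A block-structured loading matrix with unequal group sizes (5:4:3
#' for 12 items): the largest item group loads on factor 1, the next on
#' factor 2, the smallest on factor 3, all with unit loading.  Mirrors
#' the qualitative structure of retrospective thought probes, where
#' dimensions of experience (e.g. self-referential content, affective
#' tone, modality of thought) recruit different numbers of items; the
#' unequal sizes also keep the component spectrum separated after
#' items are standardized to unit variance, so the recovered
#' components are identifiable.
#'
#' @param n_items number of items (split in proportion 5:4:3).
#' @return `n_items x 3` numeric matrix.
#' @export
default_latent_loadings <- function(n_items = 12) {
  n_items <- check_count(n_items, "n_items", min = 3L)
  cuts <- round(cumsum(c(5, 4, 3) / 12 * n_items))
  cuts[3] <- n_items
  groups <- rep(1:3, times = diff(c(0, cuts)))
  L <- matrix(0, n_items, 3)
  L[cbind(seq_len(n_items), groups)] <- 1
  rownames(L) <- sprintf("item_%02d", seq_len(n_items))
  colnames(L) <- paste0("factor_", 1:3)
  L
}

# Day/run labels for the four occasions: block b -> (day, run)
block_design <- function() {
  data.frame(block = 1:4,
             day = c(1L, 1L, 2L, 2L),
             run = c(1L, 2L, 1L, 2L))
}

#' Draw latent thought-factor scores
#'
#' Each subject has a stable subject-level score per factor plus an
#' independent occasion-level deviation per scan, so scores vary both
#' between and within subjects.  Both components are zero-mean
#' Gaussian.
#'
#' @param params a [sim_params()] object.
#' @return an object of class `ground_truth`: list with `true_scores`
#'   (array `n_subjects x 4 x 3`), `planted_edges` and `beta` copied
#'   from `params`.
#' @export
generate_factor_scores <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_subjects
  with_seed(derive_seed(params$seed, "scores"), {
    subj <- matrix(stats::rnorm(n * 3,
                                sd = rep(params$subject_score_sd,
                                         each = n)), n, 3)
    scores <- array(stats::rnorm(n * 4 * 3,
                                 sd = rep(params$block_score_sd,
                                          each = n * 4)),
                    dim = c(n, 4, 3))
    for (b in 1:4) scores[, b, ] <- scores[, b, ] + subj
    dimnames(scores) <- list(
      subject = sprintf("sub%02d", seq_len(n)),
      block = paste0("block", 1:4),
      factor = paste0("factor_", 1:3)
    )
    structure(list(true_scores = scores,
                   planted_edges = params$planted_edges,
                   beta = params$beta),
              class = "ground_truth")
  })
}

#' Simulate questionnaire responses from latent factor scores
#'
#' Item responses are linear in the latent scores
#' (`latent_loadings %*% score`) plus Gaussian item noise, then mapped
#' affinely onto the 0-100 visual-analog scale and clipped.
#'
#' @param truth a `ground_truth` object from [generate_factor_scores()].
#' @param params the matching [sim_params()] object.
#' @return a [multiblock_table()] with one block per scan occasion.
#' @export
generate_questionnaire <- function(truth, params) {
  stopifnot(inherits(truth, "ground_truth"), inherits(params, "sim_params"))
  L <- params$latent_loadings
  n <- dim(truth$true_scores)[1]
  if (nrow(L) != params$n_items || ncol(L) != 3L) {
    stop("'latent_loadings' must be n_items x 3", call. = FALSE)
  }
  items <- sprintf("item_%02d", seq_len(params$n_items))
  with_seed(derive_seed(params$seed, "questionnaire"), {
    blocks <- lapply(1:4, function(b) {
      raw <- truth$true_scores[, b, ] %*% t(L) +
        matrix(stats::rnorm(n * params$n_items, sd = params$item_noise_sd),
               n, params$n_items)
      val <- params$item_center + params$item_scale * raw
      val <- pmin(pmax(val, 0), 100)
      if (params$round_items) val <- round(val)
      colnames(val) <- items
      val
    })
    multiblock_table(values = do.call(cbind, blocks),
                     subject_ids = dimnames(truth$true_scores)[[1]],
                     items = items,
                     blocks = block_design())
  })
}

# default node metadata: labels, alternating hemispheres, MNI-like
# millimeter coordinates inside a brain-sized bounding box
default_node_table <- function(n_nodes, seed) {
  with_seed(seed, {
    hemi <- rep(c("L", "R"), length.out = n_nodes)
    data.frame(
      label = sprintf("Region %03d", seq_len(n_nodes)),
      hemisphere = hemi,
      x = round(ifelse(hemi == "L", -1, 1) * stats::runif(n_nodes, 5, 65), 2),
      y = round(stats::runif(n_nodes, -100, 65), 2),
      z = round(stats::runif(n_nodes, -60, 75), 2),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a connectivity stack with a planted subnetwork
#'
#' Each scan's edge vector is built as population baseline +
#' subject-specific offset + planted effect + scan noise, where the
#' planted effect is `beta * score` on the edges listed in
#' `params$planted_edges` and `score` is that subject's occasion-level
#' factor score for `score_component`.  Values are clipped to the open
#' interval (-1, 1) so they remain valid correlation values.  Planted
#' effects enter edge-wise; positive semi-definiteness of the implied
#' matrix is not enforced (use [generate_roi_timeseries()] when exact
#' correlation matrices are required).
#'
#' @param truth a `ground_truth` object.
#' @param params the matching [sim_params()].
#' @param score_component which latent factor (1-3) drives the planted
#'   edges.
#' @return a [connectivity_stack()] whose scan metadata rows align with
#'   the questionnaire blocks (subject-major, then day, then run).
#' @export
generate_connectivity <- function(truth, params, score_component = 1) {
  stopifnot(inherits(truth, "ground_truth"), inherits(params, "sim_params"))
  if (!score_component %in% 1:3) {
    stop("'score_component' must be 1, 2 or 3", call. = FALSE)
  }
  N <- params$n_nodes
  idx <- edge_index(N)
  E <- nrow(idx)
  n <- dim(truth$true_scores)[1]
  planted <- integer(0)
  if (!is.null(truth$planted_edges)) {
    pe <- truth$planted_edges
    if (any(pe > N)) stop("planted edge outside node range", call. = FALSE)
    planted <- match_edge_rows(pe, N)
  }
  des <- block_design()
  seed <- derive_seed(params$seed, "connectivity")
  with_seed(seed, {
    base <- stats::rnorm(E, mean = params$base_edge_mean,
                         sd = params$base_edge_sd)
    subj_off <- matrix(stats::rnorm(n * E, sd = params$subject_edge_sd), n, E)
    meta <- data.frame(
      subject_id = rep(dimnames(truth$true_scores)[[1]], each = 4),
      day = rep(des$day, n),
      run = rep(des$run, n),
      stringsAsFactors = FALSE
    )
    edges <- matrix(NA_real_, n * 4, E)
    row <- 0L
    for (i in seq_len(n)) {
      for (b in 1:4) {
        row <- row + 1L
        val <- base + subj_off[i, ] +
          stats::rnorm(E, sd = params$edge_noise_sd)
        if (length(planted)) {
          val[planted] <- val[planted] +
            truth$beta * truth$true_scores[i, b, score_component]
        }
        edges[row, ] <- val
      }
    }
    eps <- 1e-6
    edges <- pmin(pmax(edges, -1 + eps), 1 - eps)
    connectivity_stack(edges = edges, meta = meta,
                       nodes = default_node_table(N, seed + 7L),
                       n_nodes = N)
  })
}

#' Simulate ROI time series whose correlations carry the planted effect
#'
#' Regions are assigned to contiguous communities sharing a common
#' signal (`ts_rho` of the variance); the rest is region-private noise.
#' Each planted node pair additionally shares a pair-specific signal
#' whose strength is `ts_coupling_base + beta * score`, truncated to
#' the range 0 to 0.95, so the pair's Pearson correlation increases
#' with the driving factor score.
#'
#' @inheritParams generate_connectivity
#' @return list with `scans` (list of `n_volumes x n_nodes` matrices),
#'   `meta` (subject/day/run per scan) and `nodes`.
#' @export
generate_roi_timeseries <- function(truth, params, score_component = 1) {
  stopifnot(inherits(truth, "ground_truth"), inherits(params, "sim_params"))
  if (params$n_volumes < 10) stop("'n_volumes' must be >= 10", call. = FALSE)
  N <- params$n_nodes
  Tn <- params$n_volumes
  n <- dim(truth$true_scores)[1]
  K <- min(params$ts_n_communities, N)
  membership <- sort(rep_len(seq_len(K), N))
  pe <- truth$planted_edges
  des <- block_design()
  seed <- derive_seed(params$seed, "timeseries")
  with_seed(seed, {
    meta <- data.frame(
      subject_id = rep(dimnames(truth$true_scores)[[1]], each = 4),
      day = rep(des$day, n),
      run = rep(des$run, n),
      stringsAsFactors = FALSE
    )
    a <- sqrt(params$ts_rho)
    b <- sqrt(1 - params$ts_rho)
    scans <- vector("list", n * 4L)
    s <- 0L
    for (i in seq_len(n)) {
      for (blk in 1:4) {
        s <- s + 1L
        shared <- matrix(stats::rnorm(Tn * K), Tn, K)
        ts <- a * shared[, membership, drop = FALSE] +
          b * matrix(stats::rnorm(Tn * N), Tn, N)
        if (!is.null(pe) && nrow(pe) > 0) {
          cpl <- params$ts_coupling_base +
            truth$beta * truth$true_scores[i, blk, score_component]
          cpl <- min(0.95, max(0, cpl))
          if (cpl > 0) {
            w <- sqrt(cpl)
            for (p in seq_len(nrow(pe))) {
              u <- stats::rnorm(Tn)
              ts[, pe[p, 1]] <- ts[, pe[p, 1]] + w * u
              ts[, pe[p, 2]] <- ts[, pe[p, 2]] + w * u
            }
          }
        }
        colnames(ts) <- sprintf("Region %03d", seq_len(N))
        scans[[s]] <- ts
      }
    }
    list(scans = scans, meta = meta,
         nodes = default_node_table(N, seed + 7L))
  })
}

#' Calibrate the planted edge effect to a target per-edge Cohen's d
#'
#' Solves for the `beta` that makes the expected edge-wise t statistic
#' in the within-subject network GLM correspond to a population
#' standardized effect `d = 2 t / sqrt(df)`, given the design implied
#' by `params` (4 scans per subject, subject-indicator nuisance).
#'
#' @param d target per-edge Cohen's d.
#' @param params a [sim_params()] object.
#' @param component which latent factor drives the planted edges.
#' @return the calibrated `beta` (correlation units per unit score).
#' @export
calibrate_effect <- function(d, params, component = 1) {
  stopifnot(inherits(params, "sim_params"))
  n_scans <- params$n_subjects * 4L
  df <- n_scans - params$n_subjects - 1L
  # expected within-subject sum of squares of the predictor
  ess <- params$n_subjects * 3 * params$block_score_sd[component]^2
  (d / 2) * sqrt(df) * params$edge_noise_sd / sqrt(ess)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters:\n")
  cat(sprintf("  %d subjects x 4 scans (2 days x 2 runs), %d items\n",
              x$n_subjects, x$n_items))
  cat(sprintf("  %d nodes, %d volumes/scan\n", x$n_nodes, x$n_volumes))
  cat(sprintf("  score SDs: subject (%s), occasion (%s); item noise %.3g\n",
              paste(signif(x$subject_score_sd, 3), collapse = ", "),
              paste(signif(x$block_score_sd, 3), collapse = ", "),
              x$item_noise_sd))
  if (!is.null(x$planted_edges)) {
    cat(sprintf("  planted subnetwork: %d edges, beta = %.4g\n",
                nrow(x$planted_edges), x$beta))
  }
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
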