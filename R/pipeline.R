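#' Default pipeline configuration
#'
#' Nested list of options for [run_pipeline()]: simulation parameters
#' (see [sim_params()]), MFA options, NBS options and the output
#' directory.  Any subset can be overridden through the `config`
#' argument or a YAML file on the command line.
#'
#' @return nested list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    out_dir = "thoughtnet_out",
    sim = list(n_subjects = 19, n_items = 12, n_nodes = 60,
               planted_edges = NULL, beta = 0,
               score_component = 1),
    mfa = list(scale = TRUE, nested = TRUE, n_components = 3,
               n_boot = 10000, alpha = 0.05, bonferroni = TRUE),
    nbs = list(threshold = 4.7, tails = c("positive", "negative"),
               n_perm = 5000, alpha = 0.05, statistic = "extent"),
    write_scans = FALSE
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

validate_config <- function(config) {
  if (config$nbs$threshold <= 0) {
    stop("invalid config: nbs threshold must be positive", call. = FALSE)
  }
  if (config$nbs$n_perm < 2) {
    stop("invalid config: nbs n_perm must be >= 2", call. = FALSE)
  }
  if (config$mfa$n_components < 1) {
    stop("invalid config: mfa n_components must be >= 1", call. = FALSE)
  }
  invisible(config)
}

# per-scan predictor matrix from MFA partial scores, aligned with a
# subject-major (subject, day, run) stack
partial_score_matrix <- function(fit, subject_ids) {
  L <- length(fit$eigenvalues)
  n <- fit$n_subjects
  out <- matrix(NA_real_, n * 4L, L)
  row <- 0L
  for (i in seq_len(n)) {
    for (b in 1:4) {
      row <- row + 1L
      out[row, ] <- fit$partial_scores[[b]][i, ]
    }
  }
  colnames(out) <- paste0("PC", seq_len(L))
  out
}

#' Run the full simulate -> MFA -> NBS pipeline
#'
#' Generates (or loads) a questionnaire and connectivity stack, fits
#' the multi-block factor analysis with bootstrap contribution
#' intervals, uses the partial factor scores of each retained
#' component as predictors in the network-based statistic, and writes
#' every result table plus a machine-readable run report.
#'
#' @param config nested option list; missing entries fall back to
#'   [default_config()].  Set `config$questionnaire_path` /
#'   `config$stack_dir` to analyze existing files instead of
#'   simulating.
#' @return invisible list with `table`, `fit`, `boot`, `stack`, `run`,
#'   `report`.
#' @export
run_pipeline <- function(config = list()) {
  config <- validate_config(merge_config(default_config(), config))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package_version = as.character(
    utils::packageVersion("thoughtnet")),
    config = config, stages = list())
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    report$stages[[name]] <<- list(seconds = round(
      proc.time()[["elapsed"]] - t0, 3))
    val
  }

  # --- stage 1: data ---------------------------------------------------
  truth <- NULL
  if (!is.null(config$questionnaire_path)) {
    table <- timed("load_questionnaire",
                   read_questionnaire(config$questionnaire_path))
    stack <- if (!is.null(config$stack_dir)) {
      timed("load_stack", read_stack(config$stack_dir, table))
    } else NULL
  } else {
    sim_args <- config$sim
    sim_args$score_component <- NULL
    sim_args$seed <- config$seed
    params <- do.call(sim_params, sim_args)
    truth <- generate_factor_scores(params)
    table <- timed("simulate_questionnaire",
                   generate_questionnaire(truth, params))
    stack <- timed("simulate_connectivity",
                   generate_connectivity(truth, params,
                                         config$sim$score_component))
    write_questionnaire(table, file.path(out_dir, "questionnaire.csv"))
    write_ground_truth(truth, file.path(out_dir, "ground_truth.json"))
    if (isTRUE(config$write_scans)) {
      write_stack(stack, file.path(out_dir, "scans"))
    }
  }

  # --- stage 2: MFA ----------------------------------------------------
  fit <- timed("mfa", mfa(table, scale = config$mfa$scale,
                          nested = config$mfa$nested,
                          n_components = config$mfa$n_components))
  utils::write.csv(variance_table(fit),
                   file.path(out_dir, "variance_table.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(variable = rownames(fit$loadings),
                              fit$loadings),
                   file.path(out_dir, "loadings.csv"), row.names = FALSE)
  utils::write.csv(data.frame(subject_id = rownames(fit$compromise_scores),
                              fit$compromise_scores),
                   file.path(out_dir, "compromise_scores.csv"),
                   row.names = FALSE)
  ctr_flat <- do.call(rbind, lapply(1:4, function(b) {
    data.frame(item = fit$items, block = b,
               fit$contributions[, b, , drop = TRUE])
  }))
  utils::write.csv(ctr_flat, file.path(out_dir, "contributions.csv"),
                   row.names = FALSE)
  boot <- timed("bootstrap", lapply(
    seq_len(config$mfa$n_components), function(l) {
      bootstrap_contributions(fit, component = l,
                              n_boot = config$mfa$n_boot,
                              alpha = config$mfa$alpha,
                              bonferroni = config$mfa$bonferroni,
                              seed = config$seed + l)
    }))
  boot_all <- do.call(rbind, lapply(seq_along(boot), function(l) {
    data.frame(component = l, boot[[l]])
  }))
  utils::write.csv(boot_all, file.path(out_dir, "bootstrap_ci.csv"),
                   row.names = FALSE)

  # --- stage 3: NBS ----------------------------------------------------
  run <- NULL
  if (!is.null(stack)) {
    scores <- partial_score_matrix(fit, table$subject_ids)
    run <- timed("nbs", run_nbs(
      stack, scores,
      threshold = config$nbs$threshold,
      tails = config$nbs$tails,
      n_perm = config$nbs$n_perm,
      seed = config$seed,
      alpha = config$nbs$alpha,
      statistic = config$nbs$statistic))
    write_network_tables(run, stack$nodes, out_dir)
    write_nbs_report(run, file.path(out_dir, "nbs_report.json"))
  }

  # --- run report ------------------------------------------------------
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("run_report\\.json$", files)]
  report$checksums <- as.list(tools::md5sum(files))
  names(report$checksums) <- basename(files)
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(table = table, truth = truth, fit = fit, boot = boot,
                 stack = stack, run = run, report = report))
}
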