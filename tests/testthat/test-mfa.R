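make_table <- function(n = 10, seed = 1, n_items = 12) {
  p <- sim_params(n_subjects = n, n_items = n_items, seed = seed)
  generate_questionnaire(generate_factor_scores(p), p)
}

test_that("block preprocessing centers and scales within block", {
  tab <- make_table(12, seed = 2)
  blocks <- preprocess_blocks(tab, scale = TRUE)
  for (X in blocks) {
    expect_lt(max(abs(colMeans(X))), 1e-12)
    expect_equal(unname(apply(X, 2, sd)), rep(1, ncol(X)))
  }
  # centered input with scale = FALSE passes through unchanged
  centered <- do.call(cbind, preprocess_blocks(tab, scale = FALSE))
  tab2 <- multiblock_table(centered, tab$subject_ids, tab$items)
  blocks2 <- preprocess_blocks(tab2, scale = FALSE)
  expect_equal(unname(do.call(cbind, blocks2)), unname(centered))
  # constant column: zeros without scaling, named error with scaling
  vals <- tab$values
  vals[, 5] <- 7
  tab3 <- multiblock_table(vals, tab$subject_ids, tab$items)
  expect_equal(unname(preprocess_blocks(tab3, scale = FALSE)[[1]][, 5]),
               rep(0, 12))
  expect_error(preprocess_blocks(tab3, scale = TRUE), "item_05")
  tiny <- multiblock_table(tab$values[1:2, ], tab$subject_ids[1:2],
                           tab$items)
  expect_error(preprocess_blocks(tiny), "3 subjects")
})

test_that("block weights equalize first singular values", {
  tab <- make_table(15, seed = 4)
  blocks <- preprocess_blocks(tab)
  w <- compute_block_weights(blocks, tab$blocks, nested = FALSE)
  # oracle: first singular value via eigendecomposition of X'X
  sv1 <- vapply(blocks, function(X) sqrt(max(eigen(crossprod(X),
                                                   symmetric = TRUE)$values)),
                0)
  expect_equal(w$block_weight, 1 / sv1^2, tolerance = 1e-10)
  expect_equal(w$day_factor, rep(1, 4))
  # a block pre-scaled to first singular value 1 gets base weight 1
  b1 <- blocks[[1]] / sv1[1]
  wb <- compute_block_weights(list(b1, b1, b1, b1), tab$blocks,
                              nested = FALSE)
  expect_equal(wb$block_weight, rep(1, 4), tolerance = 1e-10)
  # duplicated identical blocks receive equal weights (nested too)
  wd <- compute_block_weights(rep(blocks[1], 4), tab$blocks, nested = TRUE)
  expect_equal(max(wd$block_weight) - min(wd$block_weight), 0,
               tolerance = 1e-12)
  # after base weighting every block's first singular value is 1
  for (b in 1:4) {
    expect_equal(svd(sqrt(1 / sv1[b]^2) * blocks[[b]])$d[1], 1,
                 tolerance = 1e-10)
  }
  expect_error(compute_block_weights(list(blocks[[1]] * 0, blocks[[2]],
                                          blocks[[3]], blocks[[4]]),
                                     tab$blocks), "degenerate")
})

test_that("single-block unit-weight fit reproduces plain PCA", {
  set.seed(31)
  X <- scale(matrix(rnorm(20 * 6), 20, 6), scale = FALSE)
  w <- structure(list(block_weight = 1, block_sv1 = 1,
                      day_factor = 1, time_factor = 1, nested = FALSE),
                 class = "mfa_weights")
  fit <- fit_mfa(list(X), w, n_components = 3)
  sv <- svd(X)
  pca_scores <- sv$u[, 1:3] %*% diag(sv$d[1:3])
  pca_load <- sv$v[, 1:3] %*% diag(sv$d[1:3])
  expect_equal(abs(unname(fit$compromise_scores)), abs(pca_scores),
               tolerance = 1e-8)
  expect_equal(abs(unname(fit$loadings)), abs(pca_load),
               tolerance = 1e-8)
  expect_equal(fit$eigenvalues, sv$d[1:3]^2, tolerance = 1e-8)
  # with one block the partial score equals the compromise score
  expect_equal(fit$partial_scores[[1]], fit$compromise_scores)
})

test_that("compromise scores are the barycenter of the partial scores", {
  tab <- make_table(19, seed = 6)
  for (nested in c(TRUE, FALSE)) {
    fit <- mfa(tab, nested = nested)
    bary <- Reduce(`+`, fit$partial_scores) / 4
    expect_lt(max(abs(bary - fit$compromise_scores)), 1e-10)
  }
  # four identical blocks: every partial score equals the compromise
  X <- preprocess_blocks(tab)[[1]]
  tab4 <- multiblock_table(cbind(X, X, X, X), tab$subject_ids, tab$items)
  fit4 <- mfa(tab4, scale = FALSE)
  for (b in 1:4) {
    expect_equal(fit4$partial_scores[[b]], fit4$compromise_scores,
                 tolerance = 1e-10)
  }
})

test_that("contribution identities hold and match a hand computation", {
  tab <- make_table(19, seed = 7)
  fit <- mfa(tab)
  ctr <- fit$contributions
  for (l in 1:3) {
    expect_equal(sum(ctr[, , l]), 1, tolerance = 1e-10)
    expect_equal(mean(rowSums(ctr[, , l])), 1 / 12, tolerance = 1e-10)
  }
  # 2-items-per-block toy, 2 blocks: contributions recomputed from an
  # independent eigendecomposition of the weighted concatenated table
  set.seed(41)
  B1 <- scale(matrix(rnorm(8), 4, 2), scale = FALSE)
  B2 <- scale(matrix(rnorm(8), 4, 2), scale = FALSE)
  labels <- data.frame(block = 1:2, day = c(1, 2), run = c(1, 1))
  sv1 <- c(sqrt(max(eigen(crossprod(B1))$values)),
           sqrt(max(eigen(crossprod(B2))$values)))
  w <- 1 / sv1^2
  Z <- cbind(sqrt(w[1]) * B1, sqrt(w[2]) * B2)
  eg <- eigen(crossprod(Z), symmetric = TRUE)
  ctr_oracle <- eg$vectors[, 1]^2  # contributions = squared right vectors
  wgt <- compute_block_weights(list(B1, B2), labels, nested = FALSE)
  fit2 <- fit_mfa(list(B1, B2), wgt, n_components = 2)
  expect_equal(unname(thoughtnet::compute_contributions(fit2)[, , 1]),
               matrix(ctr_oracle, 2, 2), tolerance = 1e-8)
})

test_that("variance table is a normalized, monotone spectrum", {
  tab <- make_table(19, seed = 8)
  fit <- mfa(tab)
  vt <- variance_table(fit)
  expect_equal(sum(vt$proportion), 1, tolerance = 1e-10)
  expect_true(all(diff(vt$cumulative) >= -1e-12))
  expect_true(all(diff(vt$eigenvalue) <= 1e-12))
  # noiseless 3-factor data with occasion-constant scores: the
  # concatenated table has rank 3, so three components carry everything
  p <- sim_params(n_subjects = 20, item_noise_sd = 0,
                  subject_score_sd = c(0.6, 0.5, 0.4),
                  block_score_sd = 0, seed = 9)
  q0 <- generate_questionnaire(generate_factor_scores(p), p)
  fit0 <- mfa(q0, scale = FALSE)
  vt0 <- variance_table(fit0)
  expect_equal(vt0$cumulative[3], 1, tolerance = 1e-8)
})

test_that("bootstrap of summed contributions follows the resampling law", {
  # zero-variance resamples: point mass CIs, strict significance rule
  ctr <- rbind(rep(1 / 48, 4), rep(0.25, 4))
  rownames(ctr) <- c("flat", "dominant")
  bs <- bootstrap_contributions(ctr, n_boot = 500, seed = 2)
  expect_equal(bs$ci_lower[1], 1 / 12)
  expect_equal(bs$ci_upper[1], 1 / 12)
  expect_false(bs$significant[1])  # CI collapses onto the null value
  expect_equal(bs$ci_lower[2], 1)
  expect_true(bs$significant[2])

  # two-valued case against exhaustive enumeration of all 4^4 resamples
  vals <- c(0.02, 0.02, 0.05, 0.05)
  ctr2 <- matrix(vals, 1, 4, dimnames = list("it", NULL))
  grid <- as.matrix(expand.grid(vals, vals, vals, vals))
  sums <- rowSums(grid)  # 256 equally likely outcomes
  bs2 <- bootstrap_contributions(ctr2, n_boot = 20000, alpha = 0.05,
                                 bonferroni = FALSE, seed = 3)
  expect_equal(bs2$ci_lower, quantile(sums, 0.025, names = FALSE))
  expect_equal(bs2$ci_upper, quantile(sums, 0.975, names = FALSE))
  expect_equal(bs2$boot_median, median(sums))

  expect_error(bootstrap_contributions(ctr2, n_boot = 1), "at least 2")
  expect_warning(bootstrap_contributions(ctr2, n_boot = 50, seed = 1),
                 "crude")
})

test_that("planted three-factor structure is recovered", {
  p <- sim_params(n_subjects = 60, item_noise_sd = 0.3, seed = 10)
  tr <- generate_factor_scores(p)
  fit <- mfa(generate_questionnaire(tr, p))
  # Tucker congruence between |mean loadings| and the planted pattern
  load_by_item <- sapply(1:3, function(l) {
    rowMeans(matrix(abs(fit$loadings[, l]), 12, 4))
  })
  planted <- p$latent_loadings
  used <- integer(0)
  for (f in 1:3) {
    cong <- apply(load_by_item, 2, function(v) {
      sum(v * planted[, f]) / sqrt(sum(v^2) * sum(planted[, f]^2))
    })
    cong[used] <- -Inf
    best <- which.max(cong)
    expect_gt(cong[best], 0.9)
    used <- c(used, best)
  }
  expect_setequal(used, 1:3)
})
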