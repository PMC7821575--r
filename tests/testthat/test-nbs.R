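sim_stack <- function(n_subjects = 6, n_nodes = 10, seed = 61, beta = 0,
                      planted = NULL) {
  p <- sim_params(n_subjects = n_subjects, n_nodes = n_nodes,
                  planted_edges = planted, beta = beta, seed = seed)
  tr <- generate_factor_scores(p)
  list(stack = generate_connectivity(tr, p, 1), truth = tr, params = p)
}

test_that("design construction validates the repeated-measures layout", {
  s <- sim_stack()
  x <- scores_vector(s$truth)
  des <- nbs_design(s$stack, x)
  expect_equal(ncol(des$nuisance), 6)
  expect_equal(as.character(unique(des$exchange_blocks)),
               unique(s$stack$meta$subject_id))
  expect_error(nbs_design(s$stack, x[-1]), "one value per scan")
  expect_error(nbs_design(s$stack, rep(1:6, each = 4)),
               "constant within every subject")
})

test_that("edge GLM t-statistics match a brute-force solver", {
  s <- sim_stack(n_subjects = 8, n_nodes = 15, seed = 62)
  x <- scores_vector(s$truth)
  des <- nbs_design(s$stack, x)
  fit <- fit_edge_glm(s$stack, des)
  M <- cbind(des$nuisance, x)
  n_check <- min(100, ncol(s$stack$edges))
  for (e in seq_len(n_check)) {
    expect_equal(fit$t[e], unname(brute_t(M, s$stack$edges[, e])),
                 tolerance = 1e-8)
  }
  expect_equal(fit$df, 32 - 8 - 1)
  # invariance under rescaling of nuisance columns
  des2 <- des
  des2$nuisance <- des$nuisance %*% diag(c(2, 0.1, 7, 1, 0.5, 30, 4, 11))
  expect_equal(fit_edge_glm(s$stack, des2)$t, fit$t, tolerance = 1e-10)
  # subject-constant shifts are absorbed by the subject nuisance
  shifted <- s$stack$edges
  shifted[s$stack$meta$subject_id == "sub03", ] <-
    shifted[s$stack$meta$subject_id == "sub03", ] + 5
  expect_equal(fit_edge_glm(shifted, des)$t, fit$t, tolerance = 1e-8)
})

test_that("edge GLM reduces to the closed-form correlation t-test", {
  set.seed(63)
  n <- 24
  x <- rnorm(n)
  y <- matrix(rnorm(n * 5), n, 5)
  des <- manual_design(x, matrix(1, n, 1), rep(c("a", "b"), each = n / 2))
  fit <- fit_edge_glm(y, des)
  r <- as.numeric(cor(x, y))
  t_closed <- r * sqrt(n - 2) / sqrt(1 - r^2)
  expect_equal(fit$t, t_closed, tolerance = 1e-10)
  # orthogonality: a response orthogonal to the centered predictor
  xc <- x - mean(x)
  y_orth <- rnorm(n)
  y_orth <- y_orth - mean(y_orth)
  y_orth <- y_orth - xc * sum(y_orth * xc) / sum(xc^2)
  expect_lt(abs(fit_edge_glm(cbind(y_orth), des)$t), 1e-10)
})

test_that("within-block permutations are bijections of each block", {
  blocks <- rep(c("a", "b", "c"), times = c(4, 4, 2))
  set.seed(64)
  for (i in 1:20) {
    perm <- permute_within_blocks(blocks)
    expect_setequal(perm[1:4], 1:4)
    expect_setequal(perm[5:8], 5:8)
    expect_setequal(perm[9:10], 9:10)
  }
  expect_warning(permute_within_blocks(c("a", "b", "c")), "size 1")
  # exhaustive enumeration: 2! = 2 and (3!)^2 = 36, all distinct
  e2 <- enumerate_block_permutations(c("a", "a"))
  expect_equal(nrow(e2), 2)
  e36 <- enumerate_block_permutations(rep(c("a", "b"), each = 3))
  expect_equal(nrow(e36), 36)
  expect_equal(nrow(unique(e36)), 36)
  expect_error(enumerate_block_permutations(rep("a", 9), max_perms = 100),
               "exceeding")
})

test_that("thresholding respects the tail convention", {
  t <- c(-6, -3, 0, 2, 4.8, 5)
  expect_equal(threshold_edges(t, 4.7, "positive"), c(5L, 6L))
  expect_equal(threshold_edges(t, 4.7, "negative"), 1L)
  expect_equal(threshold_edges(t, 4.7, "two_sided"), c(1L, 5L, 6L))
  expect_equal(threshold_edges(t, 10, "two_sided"), integer(0))
  # element-wise comparison oracle
  expect_equal(threshold_edges(t, 2.5, "two_sided"),
               which(abs(t) > 2.5))
  # negating the predictor swaps the one-sided supra-threshold sets
  s <- sim_stack(seed = 65)
  x <- scores_vector(s$truth)
  f1 <- fit_edge_glm(s$stack, nbs_design(s$stack, x))
  f2 <- fit_edge_glm(s$stack, nbs_design(s$stack, -x))
  expect_equal(threshold_edges(f1, 1.5, "positive"),
               threshold_edges(f2, 1.5, "negative"))
})

test_that("component extraction agrees with an independent BFS oracle", {
  # two disjoint triangles
  tri <- rbind(c(1, 2), c(1, 3), c(2, 3), c(5, 6), c(5, 7), c(6, 7))
  comps <- find_components(tri)
  expect_length(comps, 2)
  expect_equal(vapply(comps, function(c) c$size_extent, 0L), c(3L, 3L))
  expect_equal(comps[[1]]$nodes, c(1L, 2L, 3L))
  expect_length(find_components(matrix(integer(), 0, 2)), 0)
  # random graphs vs BFS
  set.seed(66)
  for (i in 1:100) {
    a <- matrix(runif(900) < 0.1, 30, 30)
    pairs <- which(a & upper.tri(a), arr.ind = TRUE)
    if (!nrow(pairs)) next
    got <- find_components(pairs)
    want <- bfs_components(pairs)
    expect_equal(length(got), length(want))
    key <- function(nodes) paste(nodes, collapse = ",")
    expect_setequal(vapply(got, function(c) key(c$nodes), ""),
                    vapply(want, function(c) key(c$nodes), ""))
    expect_setequal(vapply(got, function(c) c$size_extent, 0L),
                    vapply(want, function(c) c$extent, 0L))
    # internal union-find (used in the permutation loop) agrees too
    expect_equal(thoughtnet:::.max_component_size(pairs),
                 max(vapply(want, function(c) c$extent, 0L)))
  }
})

test_that("the example sensorimotor network forms one 19-node component", {
  net <- example_network()
  expect_equal(nrow(net$pairs), 26)
  comps <- find_components(net$pairs)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$size_extent, 26)
  expect_length(comps[[1]]$nodes, 19)
  oracle <- bfs_components(net$pairs)
  expect_length(oracle, 1)
  expect_equal(comps[[1]]$nodes, oracle[[1]]$nodes)
})

test_that("component p-values follow the permutation-counting formula", {
  expect_equal(component_pvalue(5, rep(1, 99)), 0.01)
  expect_equal(component_pvalue(0, rep(10, 99)), 1)
  expect_equal(component_pvalue(3, c(1, 2, 3, 4)), 0.6)  # (1+2)/5
  expect_equal(component_pvalue(3, c(1, 2, 3, 4), exhaustive = TRUE),
               0.5)  # 2/4
})

test_that("FDR adjustment reproduces the step-up oracle", {
  expect_equal(adjust_fdr(0.03), 0.03)
  p6 <- c(0.0081, 0.4, 0.3, 0.9, 0.62, 0.55)
  expect_equal(adjust_fdr(p6)[1], 0.0486, tolerance = 5e-4)
  set.seed(67)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    expect_equal(adjust_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("network effect size converts t to Cohen's d per edge", {
  st <- structure(list(t = c(0, 3, -3, 6), df = 36), class = "edge_glm")
  expect_equal(network_cohens_d(st, 1)$cohens_d, 0)
  expect_equal(network_cohens_d(st, 2)$cohens_d, 1)
  expect_equal(network_cohens_d(st, 2:4)$cohens_d, mean(c(1, 1, 2)))
  expect_equal(network_cohens_d(st, 2:4)$mean_abs_t, 4)
  expect_error(network_cohens_d(st, integer(0)), "no edges")
  st$df <- 0
  expect_error(network_cohens_d(st, 1), "degrees of freedom")
})

test_that("permutation null is deterministic and threshold-monotone", {
  s <- sim_stack(n_subjects = 8, n_nodes = 14, seed = 68)
  x <- scores_vector(s$truth)
  des <- nbs_design(s$stack, x)
  n1 <- freedman_lane_null(s$stack, des, 2.5, "two_sided",
                           n_perm = 300, seed = 5)
  n2 <- freedman_lane_null(s$stack, des, 2.5, "two_sided",
                           n_perm = 300, seed = 5)
  expect_identical(n1, n2)
  n3 <- freedman_lane_null(s$stack, des, 2.5, "two_sided",
                           n_perm = 300, seed = 6)
  expect_false(identical(as.numeric(n1), as.numeric(n3)))
  # supra-threshold mass shrinks as the threshold rises
  sizes <- vapply(c(2, 2.5, 3), function(thr) {
    mean(freedman_lane_null(s$stack, des, thr, "two_sided",
                            n_perm = 300, seed = 7))
  }, 0)
  expect_true(all(diff(sizes) < 0))
})

test_that("with intercept-only nuisance the null equals raw permutation", {
  set.seed(69)
  n <- 6
  edges <- matrix(rnorm(n * 15), n, 15)  # 6 nodes -> 15 edges
  subj <- rep(c("a", "b"), each = 3)
  x <- rnorm(n)
  des <- manual_design(x, matrix(1, n, 1), subj)
  st <- manual_stack(edges, subj, 6)
  thr <- 1.0
  null_fl <- freedman_lane_null(st, des, thr, "two_sided",
                                exhaustive = TRUE, seed = 1)
  # oracle: permute the raw edge rows within blocks, refit [1, x]
  perms <- enumerate_block_permutations(subj)
  oracle <- numeric(nrow(perms))
  M <- cbind(1, x)
  for (p in seq_len(nrow(perms))) {
    Yp <- edges[perms[p, ], ]
    t <- vapply(seq_len(15), function(e) brute_t(M, Yp[, e]), 0)
    keep <- which(abs(t) > thr)
    oracle[p] <- if (length(keep)) {
      max(vapply(bfs_components(st$edge_index[keep, , drop = FALSE]),
                 function(c) c$extent, 0L))
    } else 0
  }
  expect_equal(sort(as.numeric(null_fl)), sort(oracle))
})

test_that("full NBS run is reproducible and reports a coherent family", {
  pe <- t(combn(1:5, 2))
  s <- sim_stack(n_subjects = 8, n_nodes = 12, seed = 70, beta = 0.3,
                 planted = pe)
  x <- scores_vector(s$truth)
  r1 <- run_nbs(s$stack, cbind(x, rev(x)), threshold = 3,
                n_perm = 200, seed = 9)
  r2 <- run_nbs(s$stack, cbind(x, rev(x)), threshold = 3,
                n_perm = 200, seed = 9)
  expect_equal(r1$family, r2$family)
  expect_equal(nrow(r1$family), 4)  # 2 predictors x 2 tails
  expect_equal(r1$family$p_fdr, adjust_fdr(r1$family$p_fwe))
  # the strong planted clique is detected in the positive tail
  pos <- which(r1$family$predictor == 1 & r1$family$tail == "positive")
  expect_lt(r1$family$p_fwe[pos], 0.05)
  best <- r1$contrasts[[pos]]$components[[1]]
  expect_true(all(best$edges[, 1] %in% 1:5))
  expect_error(run_nbs(s$stack, x, n_perm = 100), "seed")
})
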