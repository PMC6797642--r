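test_that("max_lambdas bounds are sharp under refit verification", {
  mb <- random_multiblock(12, c(5, 4), seed = 11)
  for (method in c("component", "block")) {
    mx <- max_lambdas(mb, 2, method)
    at_max <- fit_sparse_sca(mb, 2, mx$lambda_l, 0, method = method,
                             n_starts = 3, seed = 1)
    expect_true(all(at_max$model$loadings == 0))
    below <- fit_sparse_sca(mb, 2, 0.99 * mx$lambda_l, 0, method = method,
                            n_starts = 3, seed = 1)
    expect_true(any(below$model$loadings != 0))
    g_max <- fit_sparse_sca(mb, 2, 0, mx$lambda_g, method = method,
                            n_starts = 3, seed = 1)
    expect_true(all(g_max$model$loadings == 0))
    g_below <- fit_sparse_sca(mb, 2, 0, 0.99 * mx$lambda_g, method = method,
                              n_starts = 3, seed = 1)
    expect_true(any(g_below$model$loadings != 0))
  }
})

test_that("max_lambdas matches the closed form on simple cases", {
  # all-zero data: both maxima zero (guard the degenerate limit)
  zero <- multiblock(list(A = matrix(0, 5, 3) + 0))
  zero$blocks$A[1, 1] <- 1e-30      # keep rank 1 so fit_sca works
  mx0 <- max_lambdas(zero, 1)
  expect_lt(mx0$lambda_l, 1e-29)
  # single-block toy: lambda_l_max = 2 max |X'T|
  mb <- random_multiblock(10, 4, seed = 13)
  m <- fit_sca(mb, 2)
  B <- crossprod(mb$blocks[[1]], m$scores)
  expect_equal(max_lambdas(mb, 2)$lambda_l, 2 * max(abs(B)))
})

test_that("make_cell_folds partitions cells evenly and reproducibly", {
  f <- make_cell_folds(10, 10, 10, seed = 1)
  expect_true(all(table(f) == 10))
  expect_identical(f, make_cell_folds(10, 10, 10, seed = 1))
  f2 <- make_cell_folds(21, 20, 10, seed = 2)
  expect_lte(diff(range(table(f2))), 1)
  expect_error(make_cell_folds(5, 5, 1), "at least 2")
})

test_that("one_se_select implements both modes with sparse tie-breaks", {
  mspe <- c(1.0, 0.8, 0.85, 1.2)
  se <- c(0.2, 0.1, 0.1, 0.3)
  grid <- 1:4
  expect_equal(one_se_select(mspe, se, grid, "not_higher")$index, 3)
  # all equal: largest penalty wins
  expect_equal(one_se_select(rep(1, 4), rep(0.1, 4), grid)$index, 4)
  # steep rise: only the minimum qualifies in both modes
  m2 <- c(0.8, 1.5, 2.0); s2 <- c(0.1, 0.1, 0.1)
  expect_equal(one_se_select(m2, s2, 1:3, "not_higher")$index, 1)
  expect_equal(one_se_select(m2, s2, 1:3, "closest")$index, 1)
  # not_higher never exceeds the threshold
  set.seed(3)
  for (i in 1:20) {
    m <- runif(8); s <- runif(8, 0, 0.2)
    sel <- one_se_select(m, s, 1:8, "not_higher")
    b <- which.min(m)
    expect_lte(m[sel$index], m[b] + s[b] + 1e-12)
  }
})

test_that("enumerate_structures counts candidates and respects the cap", {
  expect_length(enumerate_structures(2, 1), 3)
  expect_length(enumerate_structures(2, 2), 6)
  expect_length(enumerate_structures(3, 1), 7)
  expect_length(enumerate_structures(2, 4), choose(3 + 4 - 1, 4))
  for (m in enumerate_structures(3, 2)) expect_true(all(colSums(m) > 0))
  expect_error(enumerate_structures(4, 10, cap = 100), "cap")
})

test_that("rotate_to_target finds satisfying rotations", {
  set.seed(17)
  partition <- make_partition(c(4, 3))
  # loadings already satisfying the mask: identity is optimal
  P <- rbind(cbind(rnorm(4), 0), cbind(0, rnorm(3)))
  tgt <- matrix(c(1, 0, 0, 1), 2, 2)
  r <- rotate_to_target(P, tgt, partition)
  expect_lt(r$criterion, 1e-10)
  # all-ones target: empty mask, identity and criterion 0
  r2 <- rotate_to_target(P, matrix(1, 2, 2), partition)
  expect_equal(r2$rotation, diag(2))
  expect_equal(r2$criterion, 0)
  # masked structure hidden by a known 45-degree rotation is recovered
  theta <- pi / 4
  Q <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  r3 <- rotate_to_target(P %*% Q, tgt, partition)
  expect_lt(r3$criterion, 1e-10)
  expect_gte(r3$criterion, 0)
})

test_that("disco_sca recovers generative structures", {
  sim <- simulate_multiblock(simulation_design(
    40, c(10, 9), 4, structure = matrix(c(1, 1, 1, 1, 1, 0, 0, 1), 2, 4),
    noise_proportion = 0.02, seed = 3))
  res <- disco_sca(sim$data, 4)
  # compare as multisets of column patterns (order-free)
  pat <- function(m) unname(sort(apply(m, 2, paste, collapse = "")))
  expect_equal(pat(res$structure), pat(sim$design$structure))
  # rotated model still reconstructs the data identically
  m0 <- fit_sca(sim$data, 4)
  expect_equal(tcrossprod(res$model$scores, res$model$loadings),
               tcrossprod(m0$scores, m0$loadings), tolerance = 1e-8)
  # asymmetric toy: tiny-noise second block yields a block-1 distinctive
  set.seed(5)
  b1 <- outer(rnorm(20), rnorm(6))
  b2 <- matrix(rnorm(20 * 4, sd = 1e-3), 20, 4)
  toy <- pre_process(multiblock(list(A = b1, B = b2)), scale = "none")
  expect_equal(unname(disco_sca(toy, 1)$structure[, 1]), c(1, 0))
})

test_that("pca_gca counts common components from canonical correlations", {
  # two identical blocks: all canonical correlations 1
  set.seed(23)
  X <- matrix(rnorm(30 * 5), 30, 5)
  same <- pre_process(multiblock(list(A = X, B = X)))
  res <- pca_gca(same, c(3, 3))
  expect_equal(res$pairs$n_common, 3)
  expect_equal(res$total_R, 3)
  # independent blocks at large I: no common components
  big <- random_multiblock(2000, c(4, 4), seed = 29)
  ind <- pca_gca(big, c(2, 2))
  expect_equal(ind$pairs$n_common, 0)
  expect_equal(ind$total_R, 4)
  expect_true(all(ind$pairs$correlations[[1]] < 0.2))
  # threshold validation and monotonicity
  expect_error(pca_gca(same, c(2, 2), threshold = 0), "threshold")
  shared <- simulate_multiblock(simulation_design(
    60, c(6, 6), 3, structure = matrix(c(1, 1, 1, 0, 0, 1), 2, 3),
    noise_proportion = 0.05, seed = 31))
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th)
    pca_gca(shared$data, c(2, 2), threshold = th)$pairs$n_common, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("eigen_screen matches the SVD and the trace identity", {
  mb <- random_multiblock(15, c(6, 4), seed = 37)
  es <- eigen_screen(mb, 1)
  d2 <- svd(mb$blocks[[1]])$d^2
  expect_equal(es$eigenvalue, d2 / 14, tolerance = 1e-10)
  expect_equal(sum(es$eigenvalue), sum(mb$blocks[[1]]^2) / 14)
  expect_equal(utils::tail(es$cumulative_vaf, 1), 1)
  # rank-2 block: exactly two nonzero eigenvalues
  low <- pre_process(multiblock(list(
    A = matrix(rnorm(20 * 2), 20, 2) %*% matrix(rnorm(2 * 6), 2, 6))),
    scale = "none")
  e2 <- eigen_screen(low, 1)
  expect_equal(sum(e2$eigenvalue > 1e-10 * e2$eigenvalue[1]), 2)
  expect_error(eigen_screen(mb, 1, max_R = 20), "max_R")
})

test_that("cv_sparse_sca is reproducible and sane at the grid extremes", {
  sim <- simulate_multiblock(simulation_design(20, c(5, 4), 2,
                                               noise_proportion = 0,
                                               seed = 41))
  mx <- max_lambdas(sim$data, 2)
  grid_l <- c(1e-8, mx$lambda_l)
  grid_g <- c(1e-8, mx$lambda_g)
  cv <- cv_sparse_sca(sim$data, 2, grid_l, grid_g, n_folds = 4, seed = 7)
  cv2 <- cv_sparse_sca(sim$data, 2, grid_l, grid_g, n_folds = 4, seed = 7)
  expect_identical(cv$mspe, cv2$mspe)
  expect_identical(cv$selected, cv2$selected)
  # noiseless data: near-zero penalties predict better than the zero model
  i_low <- which(cv$grid$lambda_l == 1e-8 & cv$grid$lambda_g == 1e-8)
  i_high <- which(cv$grid$lambda_l == mx$lambda_l &
                    cv$grid$lambda_g == mx$lambda_g)
  expect_lt(cv$mspe[i_low], cv$mspe[i_high])
  # at both maxima the prediction is the zero matrix, so the MSPE is the
  # mean squared held-out cell
  X <- concatenate_blocks(sim$data)
  folds <- make_cell_folds(20, 9, 4, seed = 7)
  zero_mspe <- mean(vapply(1:4, function(f) mean(X[folds == f]^2), 0))
  expect_equal(cv$mspe[i_high], zero_mspe, tolerance = 1e-8)
  expect_error(cv_sparse_sca(sim$data, 2, numeric(0), 1), "non-empty")
})

test_that("cv_structured_sca reports a region and honors forced rules", {
  sim <- simulate_multiblock(simulation_design(25, c(5, 4), 2,
                                               structure = matrix(c(1, 1, 1, 0), 2, 2),
                                               noise_proportion = 0.1,
                                               seed = 43))
  tgt <- sim$design$structure
  # grid of length 1: region collapses to that value
  cv1 <- cv_structured_sca(sim$data, 2, tgt, lambda_l_grid = 0.1,
                           n_folds = 3, seed = 1)
  expect_equal(cv1$region, c(0.1, 0.1))
  # mid-grid CV on a small grid: selected lies in the grid and the region
  # brackets it
  cv <- cv_structured_sca(sim$data, 2, tgt, n_grid = 8, n_folds = 5,
                          seed = 2)
  expect_true(cv$selected$lambda_l %in% cv$grid$lambda_l)
  expect_gte(cv$selected$lambda_l, cv$region[1] - 1e-12)
  b <- cv$best_index
  expect_lte(cv$mspe[cv$selected$index], cv$mspe[b] + cv$se[b] + 1e-12)
})

test_that("monotone-increasing MSPE forces the smallest penalty", {
  # the one-SE rule on a strictly rising curve can only pick the smallest
  # lambda: emulate with a synthetic curve through the public helper
  sel <- one_se_select(c(0.5, 0.9, 1.4, 2.0), rep(0.05, 4), 1:4,
                       "not_higher")
  expect_equal(sel$index, 1)
})

test_that("target matrices round-trip through CSV", {
  tgt <- matrix(c(1L, 1L, 0L, 1L, 1L, 0L), 2, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_target(tgt, path)
  back <- read_target(path)
  expect_equal(unname(as.matrix(back)), unname(tgt))
})
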