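#' Smallest penalties that zero out all loadings
#'
#' Computes, from the closed-form updates evaluated at the unpenalized SCA
#' scores, the smallest Lasso weight (`lambda_g = 0`) and the smallest
#' Group Lasso weight (`lambda_l = 0`) at which the fitted concatenated
#' loading matrix is identically zero. These maxima bound the useful search
#' grids for cross-validation.
#'
#' With scores `T` from [fit_sca] and `B_k = X_k' T`:
#' `lambda_l_max = 2 * max |B_k|` (soft-thresholding kills every entry), and
#' per group g with OLS coefficients `b_g`, the group factor clamps once
#' `lambda_g >= 2 ||b_g|| / sqrt(J_k)`, so `lambda_g_max` is the maximum of
#' that bound over groups (components within blocks for the component-wise
#' method, whole blocks for the block-wise method).
#'
#' @param data a preprocessed [multiblock] object.
#' @param R number of components.
#' @param method grouping convention, `"component"` (default) or `"block"`.
#' @return list with `lambda_l` and `lambda_g`.
#' @export
max_lambdas <- function(data, R, method = c("component", "block")) {
  method <- match.arg(method)
  model <- fit_sca(data, R)
  lmax <- 0
  gmax <- 0
  for (k in seq_len(n_blocks(data))) {
    B <- crossprod(data$blocks[[k]], model$scores)
    Jk <- nrow(B)
    lmax <- max(lmax, 2 * max(abs(B)))
    gmax <- max(gmax, if (method == "block") {
      2 * sqrt(sum(B^2)) / sqrt(Jk)
    } else {
      2 * sqrt(colSums(B^2)) / sqrt(Jk)
    })
  }
  # one part in 1e10 of headroom so a refit at the returned value lands on
  # the zero side of the knife edge despite floating-point rounding
  list(lambda_l = lmax * (1 + 1e-10), lambda_g = gmax * (1 + 1e-10))
}

#' Random cell partition for cell-wise cross-validation
#'
#' Splits the I x total_J cell grid into `n_folds` near-equal folds
#' (sizes differ by at most one), reproducibly under `seed`.
#'
#' @param I,total_J grid dimensions.
#' @param n_folds number of folds, at least 2.
#' @param seed RNG seed.
#' @return I x total_J integer matrix of fold labels in `1..n_folds`.
#' @export
make_cell_folds <- function(I, total_J, n_folds = 10L, seed = NULL) {
  if (n_folds < 2L) stop_config("n_folds must be at least 2")
  n <- I * total_J
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(n)
  folds[sample.int(n)] <- rep_len(seq_len(n_folds), n)
  matrix(folds, I, total_J)
}

#' One-standard-error penalty selection
#'
#' Let `b = argmin(mspe)` and `threshold = mspe[b] + se[b]`. Under
#' `mode = "not_higher"` the selected point is, among those with
#' `mspe <= threshold`, the one whose MSPE is closest to the threshold —
#' the sparsest model not significantly worse than the best. Under
#' `mode = "closest"` the point with `|mspe - threshold|` minimal is taken,
#' which may sit slightly above the threshold. Ties go to the larger
#' penalty.
#'
#' @param mspe,se equal-length numeric vectors of mean squared prediction
#'   errors and their standard errors per grid point.
#' @param grid penalty values (used for tie-breaking toward sparsity); for
#'   2-D grids pass a penalty-magnitude ordering key.
#' @param mode `"not_higher"` (default) or `"closest"`.
#' @return list with `index` and `value` (the grid entry).
#' @export
one_se_select <- function(mspe, se, grid,
                          mode = c("not_higher", "closest")) {
  mode <- match.arg(mode)
  stopifnot(length(mspe) == length(se), length(mspe) == length(grid))
  b <- which.min(mspe)
  threshold <- mspe[b] + se[b]
  cand <- if (mode == "not_higher") which(mspe <= threshold) else
    seq_along(mspe)
  d <- abs(threshold - mspe[cand])
  best_d <- min(d)
  tied <- cand[d <= best_d + 1e-12]
  index <- tied[which.max(grid[tied])]
  list(index = index, value = grid[index])
}

# shared CV engine: given a list of fit closures (one per grid point),
# returns fold-level squared prediction errors. `fit_fun(data_imputed)`
# must return an sca_model.
run_cell_cv <- function(data, fold_matrix, fit_funs) {
  X <- concatenate_blocks(data)
  partition <- attr(X, "partition")
  n_folds <- max(fold_matrix)
  errs <- matrix(NA_real_, n_folds, length(fit_funs))
  for (f in seq_len(n_folds)) {
    held <- fold_matrix == f
    Xtrain <- X
    Xtrain[held] <- NA
    mu <- colMeans(Xtrain, na.rm = TRUE)
    mu[is.na(mu)] <- 0                       # column fully held out
    idx <- which(held, arr.ind = TRUE)
    Xtrain[held] <- mu[idx[, 2L]]
    dtrain <- split_concatenated(Xtrain, partition)
    for (g in seq_along(fit_funs)) {
      model <- fit_funs[[g]](dtrain)
      Xhat <- tcrossprod(model$scores, model$loadings)
      errs[f, g] <- mean((Xhat[held] - X[held])^2)
    }
  }
  errs
}

#' Cross-validation over a (lambda_l, lambda_g) grid
#'
#' Cell-wise K-fold cross-validation for the regularized SCA model with
#' unknown structure. One random partition of the data cells is drawn per
#' run; for each fold the held-out cells are replaced by the column mean of
#' the retained cells, the model is fit on the imputed data, and the
#' squared error of the low-rank reconstruction against the true held-out
#' values is recorded. The default grids are `n_grid` points from 1e-8 to
#' the respective [max_lambdas] value. The pair is selected by the
#' one-standard-error rule ([one_se_select]); 2-D tie-breaks order penalty
#' magnitude by `lambda_g` then `lambda_l`.
#'
#' @param data a preprocessed [multiblock] object.
#' @param R number of components.
#' @param lambda_l_grid,lambda_g_grid numeric grids; `NULL` for defaults.
#' @param n_grid default grid length per penalty (default 20).
#' @param n_folds number of folds (default 10).
#' @param method grouping convention for the Group Lasso.
#' @param n_starts starts per fit inside CV (default 1: the SVD start).
#' @param seed RNG seed controlling the fold draw and any random starts.
#' @param tol,max_iter solver controls passed to [fit_sparse_sca].
#' @param se_scale `"none"` (default) uses the sample standard deviation
#'   of the fold-level errors as the standard error; `"sqrt_k"` divides by
#'   `sqrt(n_folds)`.
#' @return object of class `sca_cv`: `grid` (data.frame), `mspe`, `se`,
#'   `best_index`, `selected`, `fold_errors`, `n_folds`, `seed`.
#' @export
cv_sparse_sca <- function(data, R, lambda_l_grid = NULL,
                          lambda_g_grid = NULL, n_grid = 20L,
                          n_folds = 10L, method = c("component", "block"),
                          n_starts = 1L, seed = NULL, tol = 1e-6,
                          max_iter = 1000L, se_scale = c("none", "sqrt_k")) {
  method <- match.arg(method)
  se_scale <- match.arg(se_scale)
  if (is.null(lambda_l_grid) || is.null(lambda_g_grid)) {
    mx <- max_lambdas(data, R, method)
    if (is.null(lambda_l_grid))
      lambda_l_grid <- seq(1e-8, mx$lambda_l, length.out = n_grid)
    if (is.null(lambda_g_grid))
      lambda_g_grid <- seq(1e-8, mx$lambda_g, length.out = n_grid)
  }
  if (!length(lambda_l_grid) || !length(lambda_g_grid))
    stop_config("penalty grids must be non-empty")
  grid <- expand.grid(lambda_l = lambda_l_grid, lambda_g = lambda_g_grid,
                      KEEP.OUT.ATTRS = FALSE)
  folds <- make_cell_folds(n_samples(data), sum(block_widths(data)),
                           n_folds, seed = seed)
  fit_funs <- lapply(seq_len(nrow(grid)), function(g) {
    ll <- grid$lambda_l[g]; lg <- grid$lambda_g[g]
    function(d) fit_sparse_sca(d, R, ll, lg, method = method,
                               n_starts = n_starts, seed = seed,
                               tol = tol, max_iter = max_iter)$model
  })
  errs <- run_cell_cv(data, folds, fit_funs)
  mspe <- colMeans(errs)
  se <- apply(errs, 2L, stats::sd)
  if (se_scale == "sqrt_k") se <- se / sqrt(n_folds)
  order_key <- order(order(grid$lambda_g, grid$lambda_l))
  sel <- one_se_select(mspe, se, order_key)
  structure(list(grid = grid, mspe = mspe, se = se,
                 best_index = which.min(mspe),
                 selected = list(index = sel$index,
                                 lambda_l = grid$lambda_l[sel$index],
                                 lambda_g = grid$lambda_g[sel$index]),
                 fold_errors = errs, n_folds = n_folds, seed = seed,
                 method = method, R = R),
            class = "sca_cv")
}

#' Cross-validation over lambda_l with a known structure
#'
#' 1-D analogue of [cv_sparse_sca] for [fit_structured_sca]. The default
#' grid has 50 points from 1e-7 to `lambda_l_max`. Besides the selected
#' value (one-SE rule, not-higher mode) a closed `region` of plausible
#' Lasso weights is reported: from the not-higher selection up to the
#' "closest" selection, which may sit slightly above the threshold.
#'
#' @inheritParams cv_sparse_sca
#' @param target K x R binary status matrix.
#' @param position components carrying the Lasso penalty.
#' @param lambda_l_grid numeric grid; `NULL` for the 50-point default.
#' @param n_grid default grid length (default 50).
#' @return object of class `sca_cv` with additional element `region`.
#' @export
cv_structured_sca <- function(data, R, target, position = seq_len(R),
                              lambda_l_grid = NULL, n_grid = 50L,
                              n_folds = 10L, n_starts = 1L, seed = NULL,
                              tol = 1e-6, max_iter = 1000L,
                              se_scale = c("none", "sqrt_k")) {
  se_scale <- match.arg(se_scale)
  target <- validate_target(target, n_blocks(data), R)
  if (is.null(lambda_l_grid)) {
    mx <- max_lambdas(data, R)
    lambda_l_grid <- seq(1e-7, mx$lambda_l, length.out = n_grid)
  }
  if (!length(lambda_l_grid)) stop_config("penalty grid must be non-empty")
  folds <- make_cell_folds(n_samples(data), sum(block_widths(data)),
                           n_folds, seed = seed)
  fit_funs <- lapply(lambda_l_grid, function(ll) {
    function(d) fit_structured_sca(d, R, target, position, lambda_l = ll,
                                   n_starts = n_starts, seed = seed,
                                   tol = tol, max_iter = max_iter)$model
  })
  errs <- run_cell_cv(data, folds, fit_funs)
  mspe <- colMeans(errs)
  se <- apply(errs, 2L, stats::sd)
  if (se_scale == "sqrt_k") se <- se / sqrt(n_folds)
  sel <- one_se_select(mspe, se, lambda_l_grid, mode = "not_higher")
  rec <- one_se_select(mspe, se, lambda_l_grid, mode = "closest")
  structure(list(grid = data.frame(lambda_l = lambda_l_grid), mspe = mspe,
                 se = se, best_index = which.min(mspe),
                 selected = list(index = sel$index, lambda_l = sel$value),
                 region = sort(c(sel$value, rec$value)),
                 fold_errors = errs, n_folds = n_folds, seed = seed, R = R),
            class = "sca_cv")
}

#' @export
print.sca_cv <- function(x, ...) {
  cat("cell-wise ", x$n_folds, "-fold cross-validation, ",
      nrow(x$grid), " grid points\n", sep = "")
  cat("minimum MSPE ", format(x$mspe[x$best_index], digits = 6), " at ",
      paste(names(x$grid), "=",
            format(unlist(x$grid[x$best_index, ]), digits = 6),
            collapse = ", "), "\n", sep = "")
  cat("one-SE selection: ",
      paste(setdiff(names(x$selected), "index"), "=",
            format(unlist(x$selected[setdiff(names(x$selected), "index")]),
                   digits = 7), collapse = ", "), "\n", sep = "")
  if (!is.null(x$region))
    cat("plausible region: [", format(x$region[1L], digits = 7), ", ",
        format(x$region[2L], digits = 7), "]\n", sep = "")
  invisible(x)
}

#' @rdname cv_sparse_sca
#' @param x an `sca_cv` object.
#' @param path CSV destination (grid, MSPE, SE).
#' @export
write_cv <- function(x, path) {
  stopifnot(inherits(x, "sca_cv"))
  utils::write.csv(cbind(x$grid, mspe = x$mspe, se = x$se), path,
                   row.names = FALSE)
  invisible(path)
}

#' Enumerate candidate common/distinctive structures
#'
#' All K x R binary status matrices without an all-zero column,
#' deduplicated up to column permutation (a structure is a multiset of
#' column patterns). With K blocks there are `2^K - 1` admissible column
#' patterns, giving `choose(2^K - 2 + R, R)` candidates.
#'
#' @param K number of blocks (>= 2).
#' @param R number of components.
#' @param cap error out if the candidate count exceeds this (default 1e5).
#' @return list of K x R integer matrices.
#' @export
enumerate_structures <- function(K, R, cap = 1e5) {
  stopifnot(K >= 2L, R >= 1L)
  n_pat <- 2^K - 1
  n_cand <- choose(n_pat + R - 1, R)
  if (n_cand > cap)
    stop_config(n_cand, " candidate structures exceed the cap of ", cap)
  patterns <- lapply(seq_len(n_pat), function(i) {
    as.integer(intToBits(i))[seq_len(K)]
  })
  out <- list()
  recurse <- function(prefix, lo) {
    if (length(prefix) == R) {
      out[[length(out) + 1L]] <<- do.call(cbind, patterns[prefix])
      return()
    }
    for (i in lo:n_pat) recurse(c(prefix, i), i)
  }
  recurse(integer(0), 1L)
  lapply(out, function(m) {
    dimnames(m) <- list(paste0("block", seq_len(K)), paste0("C", seq_len(R)))
    m
  })
}

#' Rotate loadings toward a target structure
#'
#' Finds the orthonormal R x R rotation minimizing the sum of squared
#' rotated loadings in the cells a candidate structure marks as zero
#' (block-level zeros expanded to all variables of the block). Solved by
#' alternating projections: impose the zero mask on the current rotated
#' loadings to form a partially-specified target, then take the orthogonal
#' Procrustes rotation toward it. The identity start is supplemented by
#' seeded random restarts to escape local minima.
#'
#' @param P sum(J_k) x R concatenated loading matrix.
#' @param target K x R binary status matrix.
#' @param partition named list of loading row indices per block.
#' @param n_restarts random restarts beyond the identity start (default 10).
#' @param seed RNG seed for the restarts.
#' @param tol,max_iter convergence controls.
#' @return list with `rotation` (R x R orthonormal), `rotated` (P %*%
#'   rotation), `criterion` (sum of squared loadings in intended-zero
#'   cells).
#' @export
rotate_to_target <- function(P, target, partition, n_restarts = 10L,
                             seed = 1L, tol = 1e-9, max_iter = 1000L) {
  R <- ncol(P)
  target <- validate_target(target, length(partition), R)
  mask <- matrix(FALSE, nrow(P), R)          # TRUE = must-be-zero cell
  for (k in seq_along(partition))
    mask[partition[[k]], target[k, ] == 0L] <- TRUE
  if (!any(mask))
    return(list(rotation = diag(R), rotated = P, criterion = 0))
  crit <- function(B) sum((P %*% B)[mask]^2)
  if (!is.null(seed)) set.seed(seed)
  starts <- c(list(diag(R)),
              lapply(seq_len(n_restarts), function(i) random_orthonormal(R, R)))
  best <- NULL
  for (B in starts) {
    old <- crit(B)
    for (it in seq_len(max_iter)) {
      G <- P %*% B
      G[mask] <- 0
      sv <- svd(crossprod(P, G))
      B <- tcrossprod(sv$u, sv$v)
      new <- crit(B)
      if (abs(old - new) < tol * max(old, .Machine$double.eps)) break
      old <- new
    }
    if (is.null(best) || crit(B) < best$criterion)
      best <- list(rotation = B, rotated = P %*% B, criterion = crit(B))
  }
  best
}

#' DISCO structure search
#'
#' Fits the unpenalized SCA model, then rotates its loadings toward every
#' candidate common/distinctive structure ([enumerate_structures]) and
#' scores each candidate by the mean squared rotated loading over its
#' intended-zero cells (per-cell normalization so candidates with different
#' zero counts are comparable). A candidate is *satisfied* when its
#' intended-zero cells jointly carry at most `floor_frac` of the total
#' squared loading mass after rotation, i.e. its zeros hold up to noise
#' (the bound is on the mass fraction, so it is scale-free and does not
#' depend on the zero count). Among satisfied
#' candidates the most constrained one (most zero cells) wins — otherwise
#' any satisfied structure would be beaten by its own less-constrained
#' sub-patterns on noise alone. If no candidate is satisfied the minimum
#' criterion wins. The all-common candidate has no zero cells (criterion 0
#' by construction) and is only selected when no other candidate is
#' satisfied and every competing criterion exceeds the floor. Scores are
#' rotated consistently with the winning rotation.
#'
#' @param data a preprocessed [multiblock] object.
#' @param R number of components.
#' @param cap candidate-count guard (see [enumerate_structures]).
#' @param floor_frac all-common exclusion floor (default 0.01).
#' @param n_restarts,seed rotation restart controls ([rotate_to_target]).
#' @return list with `structure` (K x R), `model` (rotated [sca_model]),
#'   `table` (data.frame of candidates and criteria).
#' @export
disco_sca <- function(data, R, cap = 1e5, floor_frac = 0.01,
                      n_restarts = 10L, seed = 1L) {
  model <- fit_sca(data, R)
  K <- n_blocks(data)
  cands <- enumerate_structures(K, R, cap)
  partition <- model$partition
  crit <- numeric(length(cands))
  zero_cells <- integer(length(cands))
  rots <- vector("list", length(cands))
  for (i in seq_along(cands)) {
    tg <- cands[[i]]
    rot <- rotate_to_target(model$loadings, tg, partition,
                            n_restarts = n_restarts, seed = seed)
    widths <- block_widths(data)
    n_zero <- sum((1L - tg) * widths)        # variable-level zero cells
    zero_cells[i] <- n_zero
    crit[i] <- if (n_zero == 0L) 0 else rot$criterion / n_zero
    rots[[i]] <- rot
  }
  all_common <- vapply(cands, function(m) all(m == 1L), TRUE)
  zero_mass <- crit * zero_cells                 # raw ssq in intended zeros
  satisfied <- !all_common & zero_mass <= floor_frac * frob2(model$loadings)
  win <- if (any(satisfied)) {
    # most constrained satisfied structure; ties by lower criterion
    which(satisfied)[order(-zero_cells[satisfied], crit[satisfied])][1L]
  } else if (any(all_common)) {
    which(all_common)[1L]
  } else {
    order(crit, -zero_cells)[1L]
  }
  rot <- rots[[win]]
  rotated <- sca_model(model$scores %*% rot$rotation, rot$rotated, partition)
  tab <- data.frame(
    candidate = seq_along(cands),
    structure = vapply(cands, function(m)
      paste(apply(m, 1L, paste, collapse = ""), collapse = "/"), ""),
    zero_cells = zero_cells,
    criterion = crit)
  structure_win <- cands[[win]]
  rownames(structure_win) <- data$block_names
  list(structure = structure_win, model = rotated, table = tab)
}

#' Per-block eigenvalue screen
#'
#' Eigenvalues of a block's covariance matrix (squared singular values of
#' the preprocessed block divided by I - 1) with cumulative proportions of
#' variance — the scree input for choosing a per-block component count.
#'
#' @param data a preprocessed [multiblock] object.
#' @param block block name or index.
#' @param max_R how many eigenvalues to report (default all).
#' @return data.frame with `eigenvalue` and `cumulative_vaf`.
#' @export
eigen_screen <- function(data, block, max_R = NULL) {
  Xk <- data$blocks[[block]]
  d2 <- svd(Xk, nu = 0, nv = 0)$d^2
  max_R <- max_R %||% length(d2)
  if (max_R > min(dim(Xk)))
    stop_config("max_R exceeds min(I, J_k) = ", min(dim(Xk)))
  data.frame(component = seq_len(max_R),
             eigenvalue = (d2 / (nrow(Xk) - 1L))[seq_len(max_R)],
             cumulative_vaf = (cumsum(d2) / sum(d2))[seq_len(max_R)])
}

#' PCA-GCA structure screen
#'
#' Runs PCA per block, retains `per_block_R[k]` score vectors per block,
#' and counts, for every pair of blocks, the canonical correlations between
#' their score matrices that reach `threshold` — each one a common
#' component linking the pair. For two blocks this implies a total
#' component count `R = R_1 + R_2 - n_common` and a concrete target
#' structure (common columns first, then each block's distinctive columns).
#' With more than two blocks the pairwise counts are reported without
#' forcing a single global structure.
#'
#' @param data a preprocessed [multiblock] object.
#' @param per_block_R integer vector, components retained per block.
#' @param threshold canonical-correlation cutoff in (0, 1]; default 0.7.
#' @return object of class `pca_gca`: per-block eigenvalue tables, a
#'   pairwise table (`block_a`, `block_b`, canonical correlations,
#'   `n_common`), and for K = 2 the implied `structure` and `total_R`.
#' @export
pca_gca <- function(data, per_block_R, threshold = 0.7) {
  K <- n_blocks(data)
  if (length(per_block_R) != K)
    stop_config("per_block_R must have one entry per block")
  if (threshold <= 0 || threshold > 1)
    stop_config("threshold must be in (0, 1]")
  I <- n_samples(data)
  scores <- vector("list", K)
  eigs <- vector("list", K)
  for (k in seq_len(K)) {
    Rk <- per_block_R[k]
    if (Rk > min(I, ncol(data$blocks[[k]])))
      stop_config("per_block_R[", k, "] exceeds min(I, J_k)")
    sv <- svd(data$blocks[[k]], nu = Rk, nv = 0)
    scores[[k]] <- sv$u
    eigs[[k]] <- eigen_screen(data, k)
  }
  pairs <- utils::combn(K, 2L)
  tab <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    cc <- stats::cancor(scores[[a]], scores[[b]])$cor
    data.frame(block_a = data$block_names[a], block_b = data$block_names[b],
               correlations = I(list(cc)), n_common = sum(cc >= threshold))
  }))
  out <- list(eigenvalues = stats::setNames(eigs, data$block_names),
              pairs = tab, per_block_R = per_block_R,
              threshold = threshold, structure = NULL, total_R = NULL)
  if (K == 2L) {
    nc <- tab$n_common[1L]
    total_R <- sum(per_block_R) - nc
    distinct_col <- function(pattern, n)
      matrix(rep(pattern, max(n, 0L)), 2L, max(n, 0L))
    structure <- cbind(
      matrix(1L, 2L, nc),
      distinct_col(c(1L, 0L), per_block_R[1L] - nc),
      distinct_col(c(0L, 1L), per_block_R[2L] - nc))
    dimnames(structure) <- list(data$block_names,
                                paste0("C", seq_len(total_R)))
    out$structure <- structure
    out$total_R <- total_R
  }
  class(out) <- "pca_gca"
  out
}

#' @export
print.pca_gca <- function(x, ...) {
  for (k in seq_along(x$eigenvalues)) {
    cat("block '", names(x$eigenvalues)[k], "': retained ",
        x$per_block_R[k], " components; leading eigenvalues ",
        paste(format(utils::head(x$eigenvalues[[k]]$eigenvalue, 5), digits = 4),
              collapse = ", "), "\n", sep = "")
  }
  for (i in seq_len(nrow(x$pairs))) {
    cat(x$pairs$block_a[i], " vs ", x$pairs$block_b[i],
        ": canonical correlations ",
        paste(format(x$pairs$correlations[[i]], digits = 4), collapse = ", "),
        " -> ", x$pairs$n_common[i], " common component(s) at threshold ",
        x$threshold, "\n", sep = "")
  }
  if (!is.null(x$total_R))
    cat("implied total R = ", x$total_R, "\n", sep = "")
  invisible(x)
}

#' Read/write a target structure as CSV
#'
#' Tiny plain-text interchange: rows are blocks, columns components,
#' entries 0/1.
#'
#' @param target K x R binary matrix.
#' @param path file path.
#' @return `write_target` returns `path` invisibly; `read_target` the
#'   validated matrix.
#' @export
write_target <- function(target, path) {
  utils::write.csv(as.data.frame(target), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_target
#' @export
read_target <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  validate_target(as.matrix(df))
}
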