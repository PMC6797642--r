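#' Soft-thresholding operator
#'
#' `S(x, lam) = sign(x) * max(|x| - lam, 0)`, applied elementwise. This is
#' the Lasso solution under an orthonormal design and the building block of
#' all penalized loading updates.
#'
#' @param x numeric vector, matrix or scalar.
#' @param lam nonnegative threshold.
#' @return same shape as `x`.
#' @export
soft_threshold <- function(x, lam) {
  if (length(lam) != 1L || is.na(lam) || lam < 0)
    stop_config("'lam' must be a single nonnegative number")
  sign(x) * pmax(abs(x) - lam, 0)
}

#' Procrustes update of the score matrix
#'
#' Given fixed loadings, the orthonormal `T` minimizing the SCA loss
#' maximizes `trace(T' X_C P_C)`: with `U D V'` the SVD of `P_C' X_C'`,
#' the optimum is `T = V U'`.
#'
#' @param X I x sum(J_k) concatenated data matrix.
#' @param P sum(J_k) x R concatenated loading matrix.
#' @return I x R matrix with `T'T = I`.
#' @export
update_scores <- function(X, P) {
  M <- crossprod(P, t(X))            # R x I
  sv <- svd(M, nu = nrow(M), nv = nrow(M))
  tcrossprod(sv$v, sv$u)
}

# Shared kernel of the two closed-form updates (Yuan & Lin form under an
# orthonormal design): argmin_p ||p - b||^2 + lam_l ||p||_1 + lam_2 ||p||_2
# is S(b, lam_l / 2) scaled by the group factor [1 - lam_2 / (2 ||S||)]_+.
# The degenerate ||S|| = 0 case returns the zero vector (the limit). A
# group factor within 1e-12 of zero is clamped to zero: at the knife edge
# lam_2 = 2||S|| the exact solution is the zero vector, and rounding must
# not leave a ~1e-16 survivor that later grows into a spurious solution.
sparse_group_update <- function(b, lambda_l, lambda_2) {
  s <- soft_threshold(b, lambda_l / 2)
  ns <- sqrt(sum(s^2))
  zero <- b
  zero[] <- 0
  if (ns == 0) return(zero)
  fac <- 1 - lambda_2 / (2 * ns)
  if (fac <= 1e-12) zero else fac * s
}

#' Closed-form loading update for one block (block-wise Group Lasso)
#'
#' Solves the conditional sparse Group Lasso problem
#' `min ||X_k - T P_k'||^2 + lambda_l ||P_k||_1 + lambda_g sqrt(J_k) ||P_k||_2`
#' exactly: soft-threshold the OLS loadings `X_k' T`, then shrink the whole
#' block by the positive-part group factor — which zeroes the entire block
#' once `lambda_g sqrt(J_k)` reaches the threshold. Zeros are exact.
#'
#' @param Xk I x J_k block.
#' @param Tmat I x R orthonormal scores.
#' @param lambda_l,lambda_g nonnegative Lasso / Group Lasso weights.
#' @return J_k x R loading matrix.
#' @export
update_block_loadings <- function(Xk, Tmat, lambda_l, lambda_g) {
  b <- crossprod(Xk, Tmat)
  sparse_group_update(b, lambda_l, lambda_g * sqrt(ncol(Xk)))
}

#' Closed-form loading update for one component of one block
#'
#' The component-wise analogue of [update_block_loadings]: given the
#' partial residual `R_k = X_k' - sum_{s != r} p_s^k t_s'` and the unit
#' score vector `t_r`, solves
#' `min ||R_k - p t_r'||^2 + lambda_l ||p||_1 + lambda_g sqrt(J_k) ||p||_2`
#' in closed form. The group factor kills the whole component within the
#' block when the penalty is strong enough.
#'
#' @param Rk J_k x I partial residual.
#' @param t_r unit-norm score column.
#' @param lambda_l,lambda_g nonnegative penalty weights.
#' @param Jk block width used in the group weight `sqrt(J_k)`.
#' @return numeric vector of length J_k.
#' @export
update_component_loadings <- function(Rk, t_r, lambda_l, lambda_g,
                                      Jk = nrow(Rk)) {
  b <- drop(Rk %*% t_r)
  drop(sparse_group_update(b, lambda_l, lambda_g * sqrt(Jk)))
}

#' Penalized SCA objective
#'
#' `sum_k ||X_k - T P_k'||^2 + lambda_l * sum |P| + ` group term: block-wise
#' `lambda_g * sum_k sqrt(J_k) ||P_k||_2`, component-wise
#' `lambda_g * sum_k sqrt(J_k) sum_r ||p_r^k||_2`.
#'
#' @param data a preprocessed [multiblock] object.
#' @param model an [sca_model].
#' @param lambda_l,lambda_g penalty weights.
#' @param method `"component"` (default) or `"block"` grouping.
#' @return nonnegative scalar.
#' @export
sca_objective <- function(data, model, lambda_l, lambda_g,
                          method = c("component", "block")) {
  method <- match.arg(method)
  sse <- model_sse(data, model)
  pen <- lambda_l * sum(abs(model$loadings))
  for (k in seq_along(model$partition)) {
    Pk <- model$loadings[model$partition[[k]], , drop = FALSE]
    Jk <- nrow(Pk)
    pen <- pen + if (method == "block") {
      lambda_g * sqrt(Jk) * sqrt(sum(Pk^2))
    } else {
      lambda_g * sqrt(Jk) * sum(sqrt(colSums(Pk^2)))
    }
  }
  sse + pen
}

# one full sweep of conditional loading updates at fixed T, in place on the
# concatenated P. Component method refreshes the partial residual after
# every column (Gauss-Seidel), preserving monotone descent.
sweep_loadings <- function(blocks, Tmat, P, partition, lambda_l, lambda_g,
                           method) {
  for (k in seq_along(partition)) {
    idx <- partition[[k]]
    Xk <- blocks[[k]]
    if (method == "block") {
      P[idx, ] <- update_block_loadings(Xk, Tmat, lambda_l, lambda_g)
    } else {
      Xt <- t(Xk)
      for (r in seq_len(ncol(Tmat))) {
        Rk <- Xt - tcrossprod(P[idx, -r, drop = FALSE],
                              Tmat[, -r, drop = FALSE])
        P[idx, r] <- update_component_loadings(Rk, Tmat[, r],
                                               lambda_l, lambda_g,
                                               Jk = ncol(Xk))
      }
    }
  }
  P
}

new_sca_fit <- function(model, loss_history, converged, start_index, config) {
  structure(list(model = model, loss_history = loss_history,
                 converged = converged,
                 n_iterations = length(loss_history) - 1L,
                 start_index = start_index, config = config),
            class = "sca_fit")
}

#' @export
print.sca_fit <- function(x, ...) {
  cat(sprintf(
    "sparse SCA fit: R = %d, final loss %.6g after %d iterations (%s), start %d\n",
    x$model$R, utils::tail(x$loss_history, 1L), x$n_iterations,
    if (x$converged) "converged" else "NOT converged", x$start_index))
  print(block_component_status(x$model))
  invisible(x)
}

# core alternating loop shared by the sparse and structured fitters.
# update_fun(Tmat, P) must return the new P; loss_fun(Tmat, P) the objective.
alternate_fit <- function(X, P0, update_fun, loss_fun, tol, max_iter) {
  P <- P0
  Tmat <- update_scores(X, P)
  loss <- loss_fun(Tmat, P)
  history <- loss
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (any(P != 0)) Tmat <- update_scores(X, P)   # degenerate P = 0: keep T
    P <- update_fun(Tmat, P)
    new_loss <- loss_fun(Tmat, P)
    history <- c(history, new_loss)
    if (abs(loss - new_loss) < tol * max(loss, .Machine$double.eps)) {
      converged <- TRUE
      loss <- new_loss
      break
    }
    loss <- new_loss
  }
  list(Tmat = Tmat, P = P, history = history, converged = converged)
}

#' Fit the regularized SCA model (unknown component structure)
#'
#' Alternates the Procrustes score update with the closed-form penalized
#' loading updates until the relative loss change drops below `tol`. The
#' loss never increases. Because the problem is biconvex the algorithm can
#' land in local minima, so it is repeated from `n_starts` starting values
#' and the lowest-loss run is returned (ties broken toward the lowest start
#' index). By default the first start is the unpenalized SCA solution and
#' the rest draw loadings i.i.d. standard normal under `seed`.
#'
#' @param data a preprocessed [multiblock] object.
#' @param R number of components.
#' @param lambda_l,lambda_g nonnegative Lasso / Group Lasso weights.
#' @param method `"component"` (default): the Group Lasso acts on each
#'   component within each block, identifying common and distinctive
#'   components directly. `"block"`: it acts on whole blocks, useful to
#'   drop uninformative sources.
#' @param n_starts number of starts (default 20).
#' @param seed RNG seed for the random starts.
#' @param init_sca logical; use the SVD solution as start 1 (default TRUE).
#' @param tol relative loss-change tolerance (default 1e-9).
#' @param max_iter iteration cap per start (default 10000).
#' @return an object of class `sca_fit`: `model` ([sca_model]),
#'   `loss_history`, `converged`, `n_iterations`, `start_index`, `config`.
#' @export
fit_sparse_sca <- function(data, R, lambda_l = 0, lambda_g = 0,
                           method = c("component", "block"),
                           n_starts = 20L, seed = NULL, init_sca = TRUE,
                           tol = 1e-9, max_iter = 10000L) {
  stopifnot(inherits(data, "multiblock"), n_starts >= 1L)
  method <- match.arg(method)
  if (lambda_l < 0 || lambda_g < 0) stop_config("penalties must be nonnegative")
  X <- concatenate_blocks(data)
  partition <- make_partition(block_widths(data), data$block_names)
  J_total <- ncol(X)
  if (!is.null(seed)) set.seed(seed)
  inits <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    inits[[s]] <- if (s == 1L && init_sca) {
      fit_sca(data, R)$loadings
    } else {
      matrix(stats::rnorm(J_total * R), J_total, R)
    }
  }
  loss_fun <- function(Tmat, P) {
    sse <- frob2(X - tcrossprod(Tmat, P))
    pen <- lambda_l * sum(abs(P))
    for (k in seq_along(partition)) {
      Pk <- P[partition[[k]], , drop = FALSE]
      pen <- pen + if (method == "block") {
        lambda_g * sqrt(nrow(Pk)) * sqrt(sum(Pk^2))
      } else {
        lambda_g * sqrt(nrow(Pk)) * sum(sqrt(colSums(Pk^2)))
      }
    }
    sse + pen
  }
  update_fun <- function(Tmat, P) {
    sweep_loadings(data$blocks, Tmat, P, partition, lambda_l, lambda_g, method)
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    run <- alternate_fit(X, inits[[s]], update_fun, loss_fun, tol, max_iter)
    final <- utils::tail(run$history, 1L)
    if (is.null(best) || final < best$final) {
      best <- list(run = run, final = final, start = s)
    }
  }
  P <- best$run$P
  dimnames(P) <- list(colnames(X), paste0("C", seq_len(R)))
  model <- sca_model(best$run$Tmat, P, partition)
  new_sca_fit(model, best$run$history, best$run$converged, best$start,
              list(R = R, lambda_l = lambda_l, lambda_g = lambda_g,
                   method = method, n_starts = n_starts, seed = seed,
                   tol = tol, max_iter = max_iter))
}

#' Validate a target (status) matrix
#'
#' A target structure is a K x R binary matrix: entry (k, r) = 1 means
#' block k may load on component r, 0 forces that block's loadings on the
#' component to zero. A column of all ones encodes a common component; a
#' column with at least one zero a distinctive one. A column of all zeros
#' would leave the component empty and is rejected.
#'
#' @param target matrix of 0/1 entries, K rows.
#' @param K,R expected dimensions (optional).
#' @return the validated integer matrix, invisibly usable downstream.
#' @export
validate_target <- function(target, K = nrow(target), R = ncol(target)) {
  target <- as.matrix(target)
  if (!all(target %in% c(0, 1)))
    stop_config("target matrix must be binary (0/1)")
  if (nrow(target) != K || ncol(target) != R)
    stop_config("target must be ", K, " x ", R)
  if (any(colSums(target) == 0))
    stop_config("target has an all-zero column: component would be empty")
  storage.mode(target) <- "integer"
  target
}

#' Fit the regularized SCA model with known component structure
#'
#' When the common/distinctive structure is known a priori (e.g. from DISCO
#' or PCA-GCA), cells with target status 0 are held at exactly zero and the
#' Group Lasso is dropped. Components listed in `position` are estimated
#' with the Lasso penalty (soft-thresholding restricted to the allowed
#' cells); the remaining components are estimated by unpenalized least
#' squares on their allowed cells. Scores are updated by Procrustes as in
#' [fit_sparse_sca], with the same multi-start logic.
#'
#' @param data a preprocessed [multiblock] object.
#' @param R number of components.
#' @param target K x R binary status matrix (see [validate_target]).
#' @param position integer vector of components carrying the Lasso penalty
#'   (default all).
#' @param lambda_l nonnegative Lasso weight.
#' @inheritParams fit_sparse_sca
#' @return an object of class `sca_fit`.
#' @export
fit_structured_sca <- function(data, R, target, position = seq_len(R),
                               lambda_l = 0, n_starts = 20L, seed = NULL,
                               init_sca = TRUE, tol = 1e-9,
                               max_iter = 10000L) {
  stopifnot(inherits(data, "multiblock"), n_starts >= 1L)
  K <- n_blocks(data)
  target <- validate_target(target, K, R)
  if (lambda_l < 0) stop_config("lambda_l must be nonnegative")
  position <- as.integer(position)
  if (length(position) && !all(position %in% seq_len(R)))
    stop_config("'position' must be component indices in 1..R")
  X <- concatenate_blocks(data)
  partition <- make_partition(block_widths(data), data$block_names)
  J_total <- ncol(X)
  penalized <- seq_len(R) %in% position
  if (!is.null(seed)) set.seed(seed)
  inits <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    P0 <- if (s == 1L && init_sca) fit_sca(data, R)$loadings
          else matrix(stats::rnorm(J_total * R), J_total, R)
    for (k in seq_len(K)) P0[partition[[k]], target[k, ] == 0L] <- 0
    inits[[s]] <- P0
  }
  loss_fun <- function(Tmat, P) {
    frob2(X - tcrossprod(Tmat, P)) +
      lambda_l * sum(abs(P[, penalized, drop = FALSE]))
  }
  update_fun <- function(Tmat, P) {
    for (k in seq_len(K)) {
      idx <- partition[[k]]
      Xt <- t(data$blocks[[k]])
      for (r in seq_len(R)) {
        if (target[k, r] == 0L) { P[idx, r] <- 0; next }
        Rk <- Xt - tcrossprod(P[idx, -r, drop = FALSE],
                              Tmat[, -r, drop = FALSE])
        v <- drop(Rk %*% Tmat[, r])
        P[idx, r] <- if (penalized[r]) soft_threshold(v, lambda_l / 2) else v
      }
    }
    P
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    run <- alternate_fit(X, inits[[s]], update_fun, loss_fun, tol, max_iter)
    final <- utils::tail(run$history, 1L)
    if (is.null(best) || final < best$final) {
      best <- list(run = run, final = final, start = s)
    }
  }
  P <- best$run$P
  dimnames(P) <- list(colnames(X), paste0("C", seq_len(R)))
  model <- sca_model(best$run$Tmat, P, partition)
  new_sca_fit(model, best$run$history, best$run$converged, best$start,
              list(R = R, lambda_l = lambda_l, target = target,
                   position = position, n_starts = n_starts, seed = seed,
                   tol = tol, max_iter = max_iter))
}

#' Serialize a fit to JSON
#'
#' Writes scores, loadings, partition, penalties, loss history and seed so
#' a run can be archived and reloaded losslessly.
#'
#' @param fit an `sca_fit`.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "sca_fit"))
  payload <- list(
    scores = fit$model$scores,
    loadings = fit$model$loadings,
    variable_names = rownames(fit$model$loadings),
    partition = lapply(fit$model$partition, as.integer),
    loss_history = fit$loss_history,
    converged = fit$converged,
    start_index = fit$start_index,
    config = fit$config)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
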