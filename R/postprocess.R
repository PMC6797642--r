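#' Sparsity pattern of a fitted loading matrix
#'
#' The penalized solvers produce exact (bit) zeros, so the pattern is read
#' off with an exact-zero test, not a tolerance.
#'
#' @param P a loading matrix, or an [sca_model] / `sca_fit`.
#' @return logical matrix, `TRUE` = free cell, `FALSE` = fixed zero.
#' @export
sparsity_pattern <- function(P) {
  if (inherits(P, "sca_fit")) P <- P$model
  if (inherits(P, "sca_model")) P <- P$loadings
  P != 0
}

#' Undo penalty-induced shrinkage by OLS re-estimation
#'
#' Both penalties shrink the surviving loadings toward zero. This
#' re-estimates them without penalty while holding the recovered zero
#' pattern fixed: free cells get their least-squares value given the
#' current scores, fixed-zero cells stay exactly zero, and the scores are
#' re-estimated by Procrustes in alternation (set `refit_scores = FALSE` to
#' keep the scores frozen at the SVD solution). The SSE is non-increasing
#' over iterations and can only improve on the penalized fit at the same
#' pattern.
#'
#' @param data a preprocessed [multiblock] object.
#' @param R number of components.
#' @param pattern sum(J_k) x R logical/0-1 matrix of free cells (see
#'   [sparsity_pattern]).
#' @param tol relative SSE-change tolerance (default 1e-9).
#' @param max_iter iteration cap (default 10000).
#' @param refit_scores alternate the score update (default TRUE).
#' @param scores_init optional I x R orthonormal starting scores; defaults
#'   to the unpenalized SCA scores.
#' @return an `sca_fit` (loss history holds plain SSE).
#' @export
undo_shrinkage <- function(data, R, pattern, tol = 1e-9, max_iter = 10000L,
                           refit_scores = TRUE, scores_init = NULL) {
  stopifnot(inherits(data, "multiblock"))
  X <- concatenate_blocks(data)
  partition <- attr(X, "partition")
  pattern <- as.matrix(pattern) != 0
  if (nrow(pattern) != ncol(X) || ncol(pattern) != R)
    stop_config("pattern must be ", ncol(X), " x ", R)
  if (!any(pattern)) {
    warning("all-zero pattern: returning the zero model", call. = FALSE)
    Tmat <- scores_init %||% fit_sca(data, R)$scores
    model <- sca_model(Tmat, matrix(0, ncol(X), R,
                                    dimnames = list(colnames(X), NULL)),
                       partition)
    return(new_sca_fit(model, frob2(X), TRUE, 1L,
                       list(R = R, refit_scores = refit_scores)))
  }
  Tmat <- scores_init %||% fit_sca(data, R)$scores
  P <- matrix(0, ncol(X), R, dimnames = list(colnames(X),
                                             paste0("C", seq_len(R))))
  loss <- frob2(X - tcrossprod(Tmat, P))
  history <- loss
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (it > 1L && refit_scores && any(P != 0)) Tmat <- update_scores(X, P)
    for (k in seq_along(partition)) {
      idx <- partition[[k]]
      Xt <- t(data$blocks[[k]])
      for (r in seq_len(R)) {
        free <- pattern[idx, r]
        if (!any(free)) { P[idx, r] <- 0; next }
        Rk <- Xt - tcrossprod(P[idx, -r, drop = FALSE],
                              Tmat[, -r, drop = FALSE])
        v <- drop(Rk %*% Tmat[, r])
        P[idx, r] <- ifelse(free, v, 0)
      }
    }
    new_loss <- frob2(X - tcrossprod(Tmat, P))
    history <- c(history, new_loss)
    if (abs(loss - new_loss) < tol * max(loss, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    loss <- new_loss
  }
  model <- sca_model(Tmat, P, partition)
  new_sca_fit(model, history, converged, 1L,
              list(R = R, refit_scores = refit_scores, tol = tol,
                   max_iter = max_iter))
}

#' Match components between two loading matrices
#'
#' Component solutions are identified only up to column permutation and
#' sign, so comparing an estimate to a reference requires matching first.
#' Finds the permutation and sign flips maximizing the mean Tucker
#' congruence (absolute normalized inner product) between matched columns —
#' exactly by enumeration for R <= 8, greedily above. A zero column has
#' congruence 0 against anything.
#'
#' @param P_est,P_ref equal-shape loading matrices.
#' @return list with `permutation` (est column matched to each ref column),
#'   `signs`, `congruence` per matched pair, and `mean_congruence`.
#' @export
match_components <- function(P_est, P_ref) {
  stopifnot(all(dim(P_est) == dim(P_ref)))
  R <- ncol(P_ref)
  cong <- function(x, y) {
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) 0 else sum(x * y) / (nx * ny)
  }
  C <- outer(seq_len(R), seq_len(R),
             Vectorize(function(i, j) cong(P_est[, i], P_ref[, j])))
  score <- abs(C)
  if (R <= 8L) {
    perms <- permutations_of(R)
    vals <- vapply(perms, function(p) mean(score[cbind(p, seq_len(R))]), 0)
    perm <- perms[[which.max(vals)]]
  } else {
    perm <- integer(R)
    avail <- seq_len(R)
    for (j in order(apply(score, 2L, max), decreasing = TRUE)) {
      i <- avail[which.max(score[avail, j])]
      perm[j] <- i
      avail <- setdiff(avail, i)
    }
  }
  cg <- score[cbind(perm, seq_len(R))]
  sg <- ifelse(C[cbind(perm, seq_len(R))] < 0, -1, 1)
  list(permutation = perm, signs = sg, congruence = cg,
       mean_congruence = mean(cg))
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in permutations_of(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Export loadings as labeled CSV
#'
#' @param model an [sca_model] or `sca_fit`.
#' @param path CSV destination; variable names label the rows.
#' @export
write_loadings <- function(model, path) {
  if (inherits(model, "sca_fit")) model <- model$model
  utils::write.csv(model$loadings, path, row.names = TRUE)
  invisible(path)
}
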