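#' Simultaneous component model
#'
#' Container for an SCA solution: one orthonormal score matrix `T`
#' (I x R, `T'T = I`) shared by all blocks, and a concatenated loading
#' matrix `P` (sum(J_k) x R) whose row blocks are the per-block loadings
#' `P_k`, so each block is modeled as `X_k = T P_k' + E_k`.
#'
#' @param scores I x R orthonormal score matrix.
#' @param loadings sum(J_k) x R concatenated loading matrix.
#' @param partition named list mapping blocks to row index ranges of
#'   `loadings` (see [concatenate_blocks]).
#' @return an object of class `sca_model` with elements `scores`,
#'   `loadings`, `partition`, `R`.
#' @export
sca_model <- function(scores, loadings, partition) {
  scores <- as.matrix(scores); loadings <- as.matrix(loadings)
  R <- ncol(scores)
  if (ncol(loadings) != R)
    stop_config("scores and loadings must have the same number of columns")
  gram <- crossprod(scores)
  if (max(abs(gram - diag(R))) > 1e-8)
    stop_config("score matrix is not orthonormal (T'T != I)")
  idx <- sort(unlist(partition, use.names = FALSE))
  if (!identical(idx, seq_len(nrow(loadings))))
    stop_config("partition does not tile the loading rows")
  structure(list(scores = scores, loadings = loadings,
                 partition = partition, R = R),
            class = "sca_model")
}

#' @export
print.sca_model <- function(x, ...) {
  cat(sprintf("SCA model: %d components, %d samples, %d variables in %d blocks\n",
              x$R, nrow(x$scores), nrow(x$loadings), length(x$partition)))
  status <- block_component_status(x)
  cat("block-component status (1 = active):\n")
  print(status)
  invisible(x)
}

#' @rdname sca_model
#' @param model an `sca_model`.
#' @param k block name or index.
#' @export
block_loadings <- function(model, k) {
  model$loadings[model$partition[[k]], , drop = FALSE]
}

#' Which block-component cells carry nonzero loadings
#'
#' @param model an `sca_model`.
#' @return K x R binary matrix; entry (k, r) is 1 when block k has at least
#'   one nonzero loading on component r. A column of all ones is a common
#'   component; a column with a zero is distinctive.
#' @export
block_component_status <- function(model) {
  K <- length(model$partition)
  status <- matrix(0L, K, model$R,
                   dimnames = list(names(model$partition),
                                   paste0("C", seq_len(model$R))))
  for (k in seq_len(K)) {
    Pk <- block_loadings(model, k)
    status[k, ] <- as.integer(colSums(Pk != 0) > 0L)
  }
  status
}

# model reconstruction and per-block SSE against a multiblock object
model_sse <- function(data, model) {
  Xhat <- tcrossprod(model$scores, model$loadings)
  X <- concatenate_blocks(data)
  frob2(X - Xhat)
}

#' Unpenalized SCA by SVD of the concatenated data
#'
#' Minimizes `sum_k ||X_k - T P_k'||^2` over orthonormal `T`: the scores are
#' the first R left singular vectors of the column-concatenated data and the
#' loadings are `X_C' T` (Eckart–Young). Each component's sign is fixed so
#' that its largest-magnitude loading is positive, making the output stable
#' across SVD backends.
#'
#' @param data a preprocessed [multiblock] object.
#' @param R number of components, `1 <= R <=` attainable rank.
#' @return an [sca_model].
#' @export
fit_sca <- function(data, R) {
  stopifnot(inherits(data, "multiblock"))
  X <- concatenate_blocks(data)
  R <- as.integer(R)
  if (R < 1L || R > min(dim(X)))
    stop_config("R must be between 1 and min(I, total J) = ", min(dim(X)))
  sv <- svd(X)
  attainable <- sum(sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1L])
  if (R > attainable)
    stop_config("R = ", R, " exceeds the attainable rank ", attainable)
  Tmat <- sv$u[, seq_len(R), drop = FALSE]
  P <- crossprod(X, Tmat)
  # sign convention: dominant loading positive per component
  for (r in seq_len(R)) {
    j <- which.max(abs(P[, r]))
    if (P[j, r] < 0) { P[, r] <- -P[, r]; Tmat[, r] <- -Tmat[, r] }
  }
  rownames(P) <- colnames(X)
  rownames(Tmat) <- data$row_ids
  sca_model(Tmat, P, attr(X, "partition"))
}

#' Variance accounted for, per block and per component
#'
#' Fits the unpenalized SCA model with `R` components and reports, for each
#' block, the proportion of its total sum of squares explained by the whole
#' model (`block_vaf`) and by each component (`component_vaf[k, r] =
#' ||p_r^k||^2 / ||X_k||_F^2`; valid because `T'T = I`). Screening these
#' proportions at a generous `R` is the usual way to choose the number of
#' components to retain.
#'
#' @param data a preprocessed [multiblock] object.
#' @param R number of components to evaluate.
#' @return an object of class `vaf_result`: list with `block_vaf` (length
#'   K), `component_vaf` (K x R matrix), `R`.
#' @export
compute_vaf <- function(data, R) {
  model <- fit_sca(data, R)
  K <- n_blocks(data)
  comp <- matrix(0, K, R, dimnames = list(data$block_names,
                                          paste0("C", seq_len(R))))
  blockv <- numeric(K)
  for (k in seq_len(K)) {
    denom <- frob2(data$blocks[[k]])
    Pk <- block_loadings(model, k)
    comp[k, ] <- colSums(Pk^2) / denom
    blockv[k] <- frob2(Pk) / denom
  }
  names(blockv) <- data$block_names
  structure(list(block_vaf = blockv, component_vaf = comp, R = R),
            class = "vaf_result")
}

#' @export
print.vaf_result <- function(x, digits = 3, ...) {
  cat("Proportion of variance accounted for (", x$R, " components)\n\n", sep = "")
  cat("Per block (full model):\n")
  print(round(x$block_vaf, digits))
  cat("\nPer component, per block:\n")
  print(round(x$component_vaf, digits))
  invisible(x)
}

#' @rdname compute_vaf
#' @param x a `vaf_result`.
#' @param path CSV destination (rows = blocks, columns = components).
#' @export
write_vaf <- function(x, path) {
  stopifnot(inherits(x, "vaf_result"))
  utils::write.csv(x$component_vaf, path, row.names = TRUE)
  invisible(path)
}
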