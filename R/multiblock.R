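#' Multiblock data container
#'
#' Bundles K numeric matrices ("blocks") that share the same samples (rows)
#' but hold different variable sets, e.g. several omics layers or
#' questionnaire batteries measured on the same subjects. All downstream
#' fitting functions take this container.
#'
#' @param blocks list of K numeric matrices, each with the same number of
#'   rows in the same row order. Column names are used as variable names;
#'   unnamed columns get `V1, V2, ...` within each block.
#' @param row_ids optional character vector of sample identifiers; defaults
#'   to the rownames of the first block, or `s1, s2, ...`.
#' @param block_names optional names for the blocks; defaults to
#'   `names(blocks)` or `block1, block2, ...`.
#' @return an object of class `multiblock`: a list with elements `blocks`,
#'   `row_ids`, `block_names`.
#' @examples
#' mb <- multiblock(list(A = matrix(rnorm(20), 5), B = matrix(rnorm(15), 5)))
#' n_blocks(mb)
#' @export
multiblock <- function(blocks, row_ids = NULL, block_names = NULL) {
  if (!is.list(blocks) || length(blocks) < 1L)
    stop_config("'blocks' must be a non-empty list of matrices")
  blocks <- lapply(blocks, function(b) {
    b <- as.matrix(b)
    if (!is.numeric(b)) stop_data("all blocks must be numeric")
    b
  })
  I <- nrow(blocks[[1L]])
  if (any(vapply(blocks, nrow, 0L) != I))
    stop_data("all blocks must have the same number of rows")
  if (any(vapply(blocks, ncol, 0L) < 1L))
    stop_data("every block needs at least one variable")
  block_names <- block_names %||% names(blocks) %||%
    paste0("block", seq_along(blocks))
  names(blocks) <- block_names
  row_ids <- row_ids %||% rownames(blocks[[1L]]) %||% paste0("s", seq_len(I))
  blocks <- lapply(blocks, function(b) {
    rownames(b) <- row_ids
    if (is.null(colnames(b))) colnames(b) <- paste0("V", seq_len(ncol(b)))
    if (anyDuplicated(colnames(b)))
      stop_data("variable names must be unique within a block")
    b
  })
  structure(list(blocks = blocks, row_ids = row_ids,
                 block_names = block_names),
            class = "multiblock")
}

#' @export
print.multiblock <- function(x, ...) {
  cat("multiblock data:", n_blocks(x), "blocks,", n_samples(x), "samples\n")
  for (k in seq_len(n_blocks(x)))
    cat(sprintf("  %s: %d variables\n", x$block_names[k], ncol(x$blocks[[k]])))
  invisible(x)
}

#' @rdname multiblock
#' @param x a `multiblock` object.
#' @export
n_blocks <- function(x) length(x$blocks)

#' @rdname multiblock
#' @export
n_samples <- function(x) nrow(x$blocks[[1L]])

#' @rdname multiblock
#' @export
block_widths <- function(x) vapply(x$blocks, ncol, 0L)

#' Read multiblock data from delimited files
#'
#' Each file holds one block: a header row of variable names and a leading
#' sample-ID column. Rows are aligned by sample ID to the order of the first
#' file; files whose ID sets disagree raise an error naming the offending
#' IDs.
#'
#' @param paths character vector of file paths, one per block; names become
#'   block names.
#' @param delimiter field separator, `","` (default) or `"\t"` etc.
#' @return a [multiblock] object.
#' @export
read_blocks <- function(paths, delimiter = ",") {
  if (length(paths) < 1L) stop_config("need at least one file")
  block_names <- names(paths) %||%
    sub("\\.[^.]*$", "", basename(paths))
  raw <- lapply(seq_along(paths), function(i) {
    df <- utils::read.table(paths[i], header = TRUE, sep = delimiter,
                            check.names = FALSE, colClasses = "character",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
      stop_data(paths[i], ": needs an ID column plus at least one variable")
    ids <- df[[1L]]
    if (anyDuplicated(ids))
      stop_data(paths[i], ": duplicated sample IDs: ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    num <- suppressWarnings(array(as.numeric(m), dim = dim(m),
                                  dimnames = dimnames(m)))
    bad <- which(is.na(num) & !is.na(m) & !(trimws(m) %in% c("", "NA")))
    if (length(bad)) {
      rc <- arrayInd(bad[1L], dim(m))
      stop_data(paths[i], ": non-numeric value '", m[bad[1L]],
                "' at data row ", rc[1L], ", column '", colnames(m)[rc[2L]], "'")
    }
    rownames(num) <- ids
    num
  })
  ref_ids <- rownames(raw[[1L]])
  blocks <- lapply(seq_along(raw), function(i) {
    ids <- rownames(raw[[i]])
    missing_here <- setdiff(ref_ids, ids)
    extra_here <- setdiff(ids, ref_ids)
    if (length(missing_here) || length(extra_here))
      stop_data(paths[i], ": sample IDs do not match the first file",
                if (length(missing_here))
                  paste0("; absent: ", paste(missing_here, collapse = ", ")),
                if (length(extra_here))
                  paste0("; unexpected: ", paste(extra_here, collapse = ", ")))
    raw[[i]][ref_ids, , drop = FALSE]
  })
  names(blocks) <- block_names
  multiblock(blocks, row_ids = ref_ids, block_names = block_names)
}

#' Impute missing entries in multiblock data
#'
#' Missing cells (`NA`) are filled deterministically; observed cells are
#' never touched. `"column_mean"` replaces each missing cell by the mean of
#' the observed cells in its column. `"iterative_svd"` is an EM-style
#' low-rank completion: starting from column-mean fill, the matrix is
#' repeatedly approximated by its rank-`rank` truncated SVD and missing
#' cells are overwritten by the approximation, until the imputed cells move
#' less than `tol` (default 1e-8) or `max_iter` iterations.
#'
#' @param data a [multiblock] object, possibly containing `NA`s.
#' @param method `"column_mean"` (default) or `"iterative_svd"`.
#' @param rank target rank for `"iterative_svd"`.
#' @param tol,max_iter convergence controls for `"iterative_svd"`.
#' @return a [multiblock] object with no missing values.
#' @export
impute_missing <- function(data, method = c("column_mean", "iterative_svd"),
                           rank = 2L, tol = 1e-8, max_iter = 500L) {
  stopifnot(inherits(data, "multiblock"))
  method <- match.arg(method)
  blocks <- lapply(seq_len(n_blocks(data)), function(k) {
    X <- data$blocks[[k]]
    if (!anyNA(X)) return(X)
    full_miss <- colSums(!is.na(X)) == 0L
    if (any(full_miss))
      stop_data("block '", data$block_names[k], "': column(s) ",
                paste(colnames(X)[full_miss], collapse = ", "),
                " are entirely missing and cannot be imputed")
    miss <- is.na(X)
    mu <- colMeans(X, na.rm = TRUE)
    X[miss] <- rep(mu, each = nrow(X))[miss]
    if (method == "iterative_svd") {
      r <- min(rank, dim(X))
      for (it in seq_len(max_iter)) {
        sv <- svd(X, nu = r, nv = r)
        Xhat <- sv$u %*% (sv$d[seq_len(r)] * t(sv$v))
        delta <- max(abs(Xhat[miss] - X[miss]))
        X[miss] <- Xhat[miss]
        if (delta < tol) break
      }
    }
    X
  })
  names(blocks) <- data$block_names
  multiblock(blocks, row_ids = data$row_ids, block_names = data$block_names)
}

#' Pre-process multiblock data
#'
#' Mean-centers every column and scales it, per block, the way the sparse
#' SCA objective expects. Under `scale = "norm_one"` each column ends with
#' sum of squares 1, so a block's total sum of squares equals its number of
#' variables. `"unit_variance"` divides by the sample standard deviation
#' instead. Optionally each block is further divided by `sqrt(J_k)` so that
#' wide blocks do not dominate the joint fit.
#'
#' Constant columns cannot be scaled; they become all-zero with a warning
#' rather than aborting, so degenerate survey items do not kill a run.
#'
#' @param data a [multiblock] object with no missing values
#'   (see [impute_missing]).
#' @param center logical; subtract column means (default `TRUE`).
#' @param scale one of `"norm_one"` (default), `"unit_variance"`, `"none"`.
#' @param block_weight logical; divide block k by `sqrt(J_k)`
#'   (default `FALSE`).
#' @return a [multiblock] object, preprocessed.
#' @export
pre_process <- function(data, center = TRUE,
                        scale = c("norm_one", "unit_variance", "none"),
                        block_weight = FALSE) {
  stopifnot(inherits(data, "multiblock"))
  scale <- match.arg(scale)
  if (anyNA(unlist(data$blocks, use.names = FALSE)))
    stop_data("data contain missing values; run impute_missing() first")
  blocks <- lapply(seq_len(n_blocks(data)), function(k) {
    X <- data$blocks[[k]]
    if (center) X <- sweep(X, 2L, colMeans(X), "-")
    if (scale != "none") {
      s <- if (scale == "norm_one") sqrt(colSums(X^2)) else apply(X, 2L, stats::sd)
      const <- s < .Machine$double.eps^0.5
      if (any(const)) {
        warning("block '", data$block_names[k], "': constant column(s) ",
                paste(colnames(X)[const], collapse = ", "),
                " scaled to all-zero", call. = FALSE)
        s[const] <- 1
        X[, const] <- 0
      }
      X <- sweep(X, 2L, s, "/")
    }
    if (block_weight) X <- X / sqrt(ncol(X))
    X
  })
  names(blocks) <- data$block_names
  multiblock(blocks, row_ids = data$row_ids, block_names = data$block_names)
}

#' Concatenate blocks into one wide matrix
#'
#' @param data a [multiblock] object.
#' @return the I x sum(J_k) matrix with an attribute `"partition"`: a named
#'   list giving each block's column indices.
#' @seealso [split_concatenated] for the inverse.
#' @export
concatenate_blocks <- function(data) {
  stopifnot(inherits(data, "multiblock"))
  X <- do.call(cbind, data$blocks)
  colnames(X) <- unlist(lapply(data$blocks, colnames), use.names = FALSE)
  attr(X, "partition") <- make_partition(block_widths(data), data$block_names)
  X
}

#' Split a concatenated matrix back into a multiblock object
#'
#' @param X a matrix as returned by [concatenate_blocks].
#' @param partition named list of column index vectors; defaults to the
#'   `"partition"` attribute of `X`.
#' @return a [multiblock] object.
#' @export
split_concatenated <- function(X, partition = attr(X, "partition")) {
  if (is.null(partition)) stop_config("no partition supplied")
  blocks <- lapply(partition, function(j) X[, j, drop = FALSE])
  multiblock(blocks, row_ids = rownames(X), block_names = names(partition))
}

#' Write preprocessed blocks back to CSV
#'
#' One file per block, full double precision, leading ID column — the same
#' layout [read_blocks] consumes.
#'
#' @param data a [multiblock] object.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_blocks <- function(data, dir) {
  stopifnot(inherits(data, "multiblock"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_len(n_blocks(data)), function(k) {
    path <- file.path(dir, paste0(data$block_names[k], ".csv"))
    df <- data.frame(id = data$row_ids,
                     format(data$blocks[[k]], digits = 17, trim = TRUE),
                     check.names = FALSE)
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
    path
  }, "")
  invisible(paths)
}
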