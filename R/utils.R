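`%||%` <- function(a, b) if (is.null(a)) b else a

# QR-based random orthonormal I x R matrix; sign-fixed so the result is a
# deterministic function of the RNG stream across LAPACK builds.
random_orthonormal <- function(I, R) {
  stopifnot(R <= I)
  qr_dec <- qr(matrix(stats::rnorm(I * R), I, R))
  Q <- qr.Q(qr_dec)
  d <- diag(qr.R(qr_dec))
  Q * rep(ifelse(d < 0, -1, 1), each = I)
}

frob2 <- function(M) sum(M * M)

# Column index ranges of the concatenated matrix, one element per block.
make_partition <- function(J, block_names = NULL) {
  ends <- cumsum(J)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  part <- mapply(function(s, e) seq.int(s, e), starts, ends, SIMPLIFY = FALSE)
  names(part) <- block_names %||% paste0("block", seq_along(J))
  part
}

stop_data <- function(...) {
  stop(structure(class = c("blocksca_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("blocksca_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
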