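#' Simulation design for synthetic multiblock data
#'
#' States the generative world: an orthonormal score matrix, block-wise
#' loadings with designated zero blocks (the common/distinctive target
#' structure), optional extra within-component sparsity, and Gaussian noise
#' contributing a fixed proportion of the total variance.
#'
#' @param I number of samples.
#' @param J integer vector of block widths.
#' @param R number of components.
#' @param structure K x R binary status matrix (default all-common).
#' @param within_sparsity proportion of loadings zeroed inside each allowed
#'   block-component cell, in `[0, 1)` (default 0).
#' @param noise_proportion fraction of total variance due to noise, in
#'   `[0, 1)` (default 0.05).
#' @param seed RNG seed.
#' @return an object of class `simulation_design`.
#' @export
simulation_design <- function(I, J, R, structure = NULL,
                              within_sparsity = 0, noise_proportion = 0.05,
                              seed = 1L) {
  K <- length(J)
  structure <- if (is.null(structure)) matrix(1L, K, R) else
    validate_target(structure, K, R)
  if (within_sparsity < 0 || within_sparsity >= 1)
    stop_config("within_sparsity must be in [0, 1)")
  if (noise_proportion < 0 || noise_proportion >= 1)
    stop_config("noise_proportion must be in [0, 1)")
  if (R > I) stop_config("R cannot exceed I")
  structure(class = "simulation_design",
            list(I = as.integer(I), J = as.integer(J), R = as.integer(R),
                 structure = structure, within_sparsity = within_sparsity,
                 noise_proportion = noise_proportion, seed = as.integer(seed)))
}

#' Generate synthetic multiblock data with known ground truth
#'
#' Draws `T` as a random I x R orthonormal basis (QR of a Gaussian matrix,
#' sign-fixed), loadings i.i.d. standard normal zeroed per the design's
#' structure and within-component sparsity (always leaving at least one
#' survivor per allowed block-component), and Gaussian noise rescaled so
#' that exactly `noise_proportion` of the total sum of squares of
#' `T P' + E` is noise (solved in closed form, so the fraction is exact to
#' rounding). The returned data are centered and column-normalized via
#' [pre_process]; the raw (unprocessed) blocks are included for checks that
#' need the exact generative scale.
#'
#' Because [pre_process] divides each column j by its centered norm s_j,
#' the generative loadings expressed in the analyzed coordinate system are
#' `diag(1/s_j) P`; these are returned as `loadings_std` and are the right
#' reference when comparing against a model fitted to `data`. The zero
#' pattern is identical in both scalings.
#'
#' @param design a [simulation_design].
#' @return list with `data` (preprocessed [multiblock]), `raw` (same before
#'   preprocessing), `scores` (true T), `loadings` (true concatenated P on
#'   the raw scale), `loadings_std` (row-rescaled to the preprocessed
#'   scale), `noise_fraction` (measured), `design`.
#' @export
simulate_multiblock <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  I <- design$I; J <- design$J; R <- design$R
  K <- length(J)
  total_J <- sum(J)
  partition <- make_partition(J)
  Tmat <- random_orthonormal(I, R)
  P <- matrix(stats::rnorm(total_J * R), total_J, R)
  for (k in seq_len(K)) {
    idx <- partition[[k]]
    for (r in seq_len(R)) {
      if (design$structure[k, r] == 0L) {
        P[idx, r] <- 0
      } else if (design$within_sparsity > 0) {
        n_zero <- floor(design$within_sparsity * J[k])
        if (J[k] - n_zero < 1L)
          stop_config("within_sparsity would empty block ", k,
                      " on component ", r)
        if (n_zero > 0L)
          P[idx[sample.int(J[k], n_zero)], r] <- 0
      }
    }
  }
  S <- tcrossprod(Tmat, P)
  f <- design$noise_proportion
  if (f > 0) {
    E <- matrix(stats::rnorm(I * total_J), I, total_J)
    # choose c with ||cE||^2 / ||S + cE||^2 = f:
    # c^2 e2 (1 - f) - 2 f c se - f s2 = 0, positive root
    e2 <- frob2(E); s2 <- frob2(S); se <- sum(S * E)
    cc <- (2 * f * se + sqrt(4 * f^2 * se^2 + 4 * e2 * (1 - f) * f * s2)) /
      (2 * e2 * (1 - f))
    E <- cc * E
    X <- S + E
    measured <- frob2(E) / frob2(X)
  } else {
    X <- S
    measured <- 0
  }
  dimnames(X) <- list(paste0("s", seq_len(I)),
                      unlist(lapply(seq_len(K), function(k)
                        paste0("b", k, "v", seq_len(J[k])))))
  rownames(P) <- colnames(X)
  colnames(P) <- paste0("C", seq_len(R))
  raw <- split_concatenated(X, stats::setNames(partition,
                                               paste0("block", seq_len(K))))
  s <- sqrt(colSums(sweep(X, 2L, colMeans(X), "-")^2))
  s[s < .Machine$double.eps^0.5] <- 1
  list(data = pre_process(raw), raw = raw, scores = Tmat, loadings = P,
       loadings_std = P / s, noise_fraction = measured, design = design)
}

#' Compare an estimated loading matrix to the generative truth
#'
#' Matches components ([match_components]) and reports: the proportion of
#' block-component zero/nonzero statuses recovered, the proportion of
#' individual cells whose zero/nonzero status is recovered, and the mean
#' Tucker congruence of the matched columns.
#'
#' @param P_true,P_est equal-shape loading matrices.
#' @param partition named list of loading row indices per block.
#' @return list with `structure_accuracy`, `cell_accuracy`,
#'   `mean_congruence`, `matching`.
#' @export
recovery_report <- function(P_true, P_est, partition) {
  stopifnot(all(dim(P_true) == dim(P_est)))
  m <- match_components(P_est, P_true)
  P_al <- P_est[, m$permutation, drop = FALSE] %*% diag(m$signs,
                                                        length(m$signs))
  status <- function(P) {
    do.call(rbind, lapply(partition, function(idx)
      as.integer(colSums(P[idx, , drop = FALSE] != 0) > 0L)))
  }
  list(structure_accuracy = mean(status(P_al) == status(P_true)),
       cell_accuracy = mean((P_al != 0) == (P_true != 0)),
       mean_congruence = m$mean_congruence,
       matching = m)
}
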