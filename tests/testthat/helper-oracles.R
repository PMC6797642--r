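# Independent numeric oracles for the penalized conditional problems.
#
# The conditional sparse Group Lasso problem under an orthonormal design
# reduces (up to an additive constant) to the proximal problem
#   min_x ||x - b||^2 + l1 * ||x||_1 + l2 * ||x||_2 .
# Its solution support is always a top-|b| set, so an independent oracle
# can enumerate supports by descending |b| and solve each sign-restricted
# smooth subproblem with a generic quasi-Newton minimizer. No shrinkage
# formula is used anywhere.
oracle_prox <- function(b, l1, l2) {
  n <- length(b)
  obj <- function(x) sum((x - b)^2) + l1 * sum(abs(x)) + l2 * sqrt(sum(x^2))
  best <- obj(numeric(n))
  bestx <- numeric(n)
  ord <- order(abs(b), decreasing = TRUE)
  for (m in seq_len(n)) {
    S <- ord[seq_len(m)]
    s <- sign(b[S])
    g <- function(y) sum((y - b[S])^2) + l1 * sum(s * y) +
      l2 * sqrt(sum(y^2) + 1e-300)
    gr <- function(y) 2 * (y - b[S]) + l1 * s +
      l2 * y / sqrt(sum(y^2) + 1e-300)
    r <- stats::optim(b[S] / 2, g, gr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-16))
    x <- numeric(n)
    x[S] <- r$par
    v <- obj(x)
    if (v < best) { best <- v; bestx <- x }
  }
  list(value = best, x = bestx)
}

# full conditional objective of the block problem, for oracle comparisons:
# ||Xk - T P'||^2 + l1 ||P||_1 + l2 ||P||_2 (l2 already includes sqrt(Jk))
block_objective <- function(Xk, Tmat, P, l1, l2) {
  sum((Xk - tcrossprod(Tmat, P))^2) + l1 * sum(abs(P)) +
    l2 * sqrt(sum(P^2))
}

component_objective <- function(Rk, t_r, p, l1, l2) {
  sum((Rk - tcrossprod(p, t_r))^2) + l1 * sum(abs(p)) + l2 * sqrt(sum(p^2))
}

# exact scalar Lasso oracle by golden-section search, for the structured
# (lambda_g = 0) updates: min_p (p - v)^2 * 1 + l1 |p| per coordinate.
oracle_lasso_scalar <- function(v, l1) {
  vapply(v, function(vj) {
    f <- function(p) (p - vj)^2 + l1 * abs(p)
    stats::optimize(f, interval = c(-abs(vj) - 1, abs(vj) + 1),
                    tol = 1e-12)$minimum
  }, 0)
}

# quick random preprocessed multiblock dataset
random_multiblock <- function(I, J, seed = 1L) {
  set.seed(seed)
  blocks <- lapply(J, function(j) matrix(rnorm(I * j), I, j))
  names(blocks) <- paste0("block", seq_along(J))
  pre_process(multiblock(blocks))
}

# KKT residuals of the component-wise solution at convergence (orthonormal
# T): for each block k and component r with p != 0,
#   2 p - 2 R_k t_r + l1 sign(p) + l2 sqrt(Jk) p / ||p|| = 0 on nonzeros,
# |2 v_j| <= l1 on zeros within an active group, and
# ||S(2 v, l1)|| <= l2 sqrt(Jk) for a dead group.
kkt_residual_component <- function(data, model, lambda_l, lambda_g) {
  worst <- 0
  Tmat <- model$scores
  for (k in seq_along(model$partition)) {
    idx <- model$partition[[k]]
    Xt <- t(data$blocks[[k]])
    Jk <- length(idx)
    for (r in seq_len(model$R)) {
      p <- model$loadings[idx, r]
      Rk <- Xt - tcrossprod(model$loadings[idx, -r, drop = FALSE],
                            Tmat[, -r, drop = FALSE])
      v <- drop(Rk %*% Tmat[, r])
      if (all(p == 0)) {
        slack <- sqrt(sum(soft_threshold(2 * v, lambda_l)^2)) -
          lambda_g * sqrt(Jk)
        worst <- max(worst, slack)
      } else {
        np <- sqrt(sum(p^2))
        nz <- p != 0
        grad <- 2 * p - 2 * v + lambda_l * sign(p) + lambda_g * sqrt(Jk) * p / np
        worst <- max(worst, max(abs(grad[nz])))
        if (any(!nz))
          worst <- max(worst, max(pmax(abs(2 * v[!nz]) - lambda_l, 0)))
      }
    }
  }
  worst
}
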