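# Consensus ADMM for ridge regression over horizontally partitioned rows.
#
# Objective (for one block and penalty lambda):
#   min_{beta_p, b}  sum_p ||X_p beta_p - y_p||^2 + lambda ||b||^2
#   s.t. beta_p = b for all p.
# With scaled duals u_p and penalty ell the updates are
#   beta_p <- (X_p'X_p + ell I)^{-1} (X_p'y_p + ell (z - u_p))
#   z      <- ell * sum_p(beta_p + u_p) / (lambda + P ell)
#   u_p    <- u_p + beta_p - z,
# whose fixed point solves (sum_p X_p'X_p + lambda I) z = sum_p X_p'y_p, the
# pooled ridge problem. The server runs exactly this recursion on the
# encoded payloads: R_p = Q (X_p'X_p + ell I)^{-1} Q' and g_p = Q X_p'y_p
# (up to the shared non-zero constant), which conjugate every quantity into
# the obfuscated coordinate system without changing the algebra, because Q
# has orthonormal columns and all iterates stay in its range.

#' Consensus-ADMM ridge solver
#'
#' Solves the pooled ridge problem for a whole penalty grid at once from
#' per-node payloads: the local solve operators
#' `R_p = (X_p'X_p + ell I)^{-1}` (possibly conjugated by an orthonormal
#' obfuscation matrix) and the local cross products `g_p = X_p'y`. All grid
#' columns share the iteration; each column stops when its relative primal
#' and dual residuals drop below `tol`.
#'
#' @param Rinv_list Per-node solve operators (`D x D`).
#' @param g_list Per-node cross-product vectors (length `D`).
#' @param lambdas Ridge penalties (one column of iterates per penalty).
#' @param ell ADMM penalty (augmented-Lagrangian weight).
#' @param relax Over-relaxation factor in `[1, 2)`.
#' @param max_iter Iteration cap.
#' @param tol Relative residual tolerance.
#' @param strict Error (rather than warn) on non-convergence.
#' @return List with `Z` (`D x length(lambdas)` consensus solutions),
#'   `iterations`, `primal`, `dual`, `converged`.
#' @export
#' @examples
#' X <- matrix(rnorm(40), 20); y <- rnorm(20)
#' out <- consensus_ridge_admm(list(solve(crossprod(X) + 10 * diag(2))),
#'                             list(drop(crossprod(X, y))), lambdas = 3,
#'                             ell = 10)
#' drop(out$Z) - drop(solve(crossprod(X) + 3 * diag(2), crossprod(X, y)))
consensus_ridge_admm <- function(Rinv_list, g_list, lambdas, ell,
                                 relax = 1.8, max_iter = 600L, tol = 1e-11,
                                 strict = FALSE) {
  P <- length(Rinv_list)
  D <- nrow(Rinv_list[[1L]])
  R <- length(lambdas)
  if (ell <= 0) stopf("ADMM penalty ell must be positive")
  G <- lapply(g_list, function(g) matrix(g, D, R))
  Z <- matrix(0, D, R)
  U <- replicate(P, matrix(0, D, R), simplify = FALSE)
  Bs <- replicate(P, matrix(0, D, R), simplify = FALSE)
  denom <- lambdas + P * ell
  gnorm <- pmax(sqrt(colSums(G[[1L]]^2)), 1e-300)
  active <- rep(TRUE, R)
  prim <- dual <- rep(Inf, R)
  iters <- rep(max_iter, R)
  for (i in seq_len(max_iter)) {
    a <- which(active)
    Zold <- Z[, a, drop = FALSE]
    S <- matrix(0, D, length(a))
    for (p in seq_len(P)) {
      Bp <- Rinv_list[[p]] %*% (G[[p]][, a, drop = FALSE] +
                                  ell * (Zold - U[[p]][, a, drop = FALSE]))
      Bs[[p]][, a] <- Bp
      S <- S + relax * Bp + (1 - relax) * Zold + U[[p]][, a, drop = FALSE]
    }
    Znew <- sweep(S, 2L, ell / denom[a], `*`)
    for (p in seq_len(P)) {
      U[[p]][, a] <- U[[p]][, a, drop = FALSE] +
        relax * Bs[[p]][, a, drop = FALSE] + (1 - relax) * Zold - Znew
    }
    Z[, a] <- Znew
    # residuals (relative): primal sum_p ||beta_p - z||, dual ell ||z - z_old||
    pr <- numeric(length(a))
    for (p in seq_len(P))
      pr <- pr + colSums((Bs[[p]][, a, drop = FALSE] - Znew)^2)
    zsc <- pmax(sqrt(colSums(Znew^2)), gnorm[a] / ell, 1e-300)
    prim[a] <- sqrt(pr) / zsc
    dual[a] <- ell * sqrt(colSums((Znew - Zold)^2)) / zsc
    done <- prim[a] < tol & dual[a] < tol
    iters[a[done]] <- i
    active[a[done]] <- FALSE
    if (!any(active)) break
  }
  if (any(active)) {
    msg <- sprintf(
      "ADMM did not converge for %d penalt%s after %d iterations (max primal %.3g, dual %.3g)",
      sum(active), if (sum(active) > 1L) "ies" else "y", max_iter,
      max(prim[active]), max(dual[active]))
    if (strict) stopf("%s", msg) else warning(msg, call. = FALSE)
  }
  list(Z = Z, iterations = iters, primal = prim, dual = dual,
       converged = !active)
}

#' Conjugate-gradient solve of a ridge-regularized Gram system
#'
#' Solves `(W + omega I) x = b` for symmetric positive semi-definite `W`
#' using conjugate gradients, the Level-1 server-side solver. Converges in
#' at most `dim(W)` steps in exact arithmetic; stops early when the residual
#' norm falls below `tol * ||b||`.
#'
#' @param W Symmetric PSD matrix (the prediction Gram).
#' @param b Right-hand side.
#' @param omega Ridge penalty (`> 0`).
#' @param tol Relative residual tolerance.
#' @param max_iter Iteration cap (default `min(dim, 200)`).
#' @return List with `x`, `iterations`, `residual`.
#' @export
#' @examples
#' cg_ridge_solve(diag(2), c(2, 4), omega = 1)$x  # (1, 2)
cg_ridge_solve <- function(W, b, omega, tol = 1e-12, max_iter = NULL) {
  n <- length(b)
  max_iter <- max_iter %||% min(n, 200L)
  x <- numeric(n)
  z <- b                 # residual
  y <- z                 # direction
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = x, iterations = 0L, residual = 0))
  zz <- sum(z^2)
  it <- 0L
  for (i in seq_len(max_iter)) {
    it <- i
    alpha <- drop(W %*% y) + omega * y
    gamma <- zz / sum(y * alpha)
    x <- x + gamma * y
    z <- z - gamma * alpha
    zz_new <- sum(z^2)
    if (sqrt(zz_new) <= tol * bnorm) { zz <- zz_new; break }
    delta <- zz_new / zz
    y <- z + delta * y
    zz <- zz_new
  }
  list(x = x, iterations = it, residual = sqrt(zz) / bnorm)
}
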