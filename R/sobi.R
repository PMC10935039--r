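#' Whiten multichannel data
#'
#' Mean-centres each channel and applies `Q = Lambda^(-1/2) E^T` from the
#' eigendecomposition of the zero-lag covariance, so the whitened data have
#' identity covariance.
#'
#' @param X Numeric matrix, channels x samples.
#' @return List with `W` (whitened channels x samples), `Q` (whitening
#'   matrix) and `means` (per-channel means removed).
#' @export
whiten <- function(X) {
  if (!is.matrix(X) || nrow(X) < 2) abort("whiten() needs >= 2 channels.")
  if (ncol(X) <= nrow(X)) abort("whiten() needs more samples than channels.")
  means <- rowMeans(X)
  Xc <- X - means
  C0 <- tcrossprod(Xc) / (ncol(X) - 1)
  eg <- eigen(C0, symmetric = TRUE)
  tol <- max(eg$values) * 1e-10
  bad <- which(eg$values < tol)
  if (length(bad) > 0) {
    # identify which channels make the covariance singular
    vars <- apply(X, 1, var)
    flat <- which(vars < .Machine$double.eps)
    culprit <- if (length(flat) > 0) {
      paste("constant channel(s):", paste(flat, collapse = ", "))
    } else {
      cm <- abs(cor(t(Xc)))
      diag(cm) <- 0
      dup <- which(cm > 1 - 1e-10, arr.ind = TRUE)
      if (nrow(dup) > 0) {
        paste("duplicated channel pair(s):",
              paste(unique(apply(dup, 1, function(p)
                paste(sort(p), collapse = "&"))), collapse = ", "))
      } else "collinear channels"
    }
    abort(paste0("Rank-deficient covariance (", culprit,
                 "); whitening is undefined."))
  }
  Q <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  list(W = Q %*% Xc, Q = Q, means = means)
}

#' Time-lagged covariance matrices
#'
#' `D(rho) = E[W(t + rho) W(t)^T]`, symmetrised as `(D + D^T)/2` so the
#' Jacobi joint-diagonalisation scheme applies.
#'
#' @param W Numeric matrix, channels x samples (typically whitened).
#' @param lags Integer vector of sample delays.
#' @return List of symmetric matrices, one per lag.
#' @export
lagged_covariances <- function(W, lags) {
  n <- ncol(W)
  if (max(lags) >= n / 2) abort("Largest lag must be < n_samples / 2.")
  lapply(lags, function(p) {
    D <- tcrossprod(W[, (1 + p):n, drop = FALSE],
                    W[, 1:(n - p), drop = FALSE]) / (n - p)
    (D + t(D)) / 2
  })
}

#' Joint approximate diagonalization by Jacobi rotations
#'
#' Finds one orthogonal matrix `V` that simultaneously near-diagonalises a
#' set of symmetric matrices, by sweeping Givens rotations that minimise the
#' summed squared off-diagonal entries. For each index pair the optimal
#' rotation angle has a closed form; sweeps repeat until every angle in a
#' sweep is below `tol`.
#'
#' @param mats List of symmetric matrices of equal size.
#' @param tol Rotation-angle threshold in radians (default 1e-8).
#' @param max_sweeps Sweep cap (default 100).
#' @return Orthogonal matrix `V` with `t(V) %*% D %*% V` near-diagonal for
#'   every input `D`.
#' @export
joint_diagonalize <- function(mats, tol = 1e-8, max_sweeps = 100) {
  if (length(mats) == 0) abort("joint_diagonalize() needs >= 1 matrix.")
  k <- nrow(mats[[1]])
  for (D in mats) {
    if (!is.matrix(D) || nrow(D) != k || ncol(D) != k) {
      abort("All matrices must be square and of equal size.")
    }
    if (max(abs(D - t(D))) > 1e-8 * max(1, max(abs(D)))) {
      abort("joint_diagonalize() requires symmetric matrices.")
    }
  }
  A <- lapply(mats, identity)
  V <- diag(k)
  if (k == 1) return(V)
  for (sweep in seq_len(max_sweeps)) {
    biggest <- 0
    for (p in 1:(k - 1)) {
      for (q in (p + 1):k) {
        # closed-form Givens angle minimising the off-diagonal criterion:
        # the rotated off-diagonal entry is v*cos(2t) - u*sin(2t) with
        # u = (D[p,p]-D[q,q])/2, v = D[p,q]; summing its square over all
        # matrices gives a sinusoid in 4t whose minimum is analytic.
        su2 <- sv2 <- suv <- 0
        for (D in A) {
          u <- (D[p, p] - D[q, q]) / 2
          v <- D[p, q]
          su2 <- su2 + u * u
          sv2 <- sv2 + v * v
          suv <- suv + u * v
        }
        P <- (sv2 - su2) / 2
        R <- suv
        rho <- sqrt(P^2 + R^2)
        if (rho == 0) next
        theta <- atan2(R, -P) / 4
        if (abs(theta) <= tol) next
        biggest <- max(biggest, abs(theta))
        cs <- cos(theta); sn <- sin(theta)
        G <- diag(k)
        G[p, p] <- cs; G[q, q] <- cs
        G[p, q] <- -sn; G[q, p] <- sn
        A <- lapply(A, function(D) crossprod(G, D) %*% G)
        V <- V %*% G
      }
    }
    if (biggest <= tol) break
  }
  V
}

#' Second-order blind identification
#'
#' Separates an instantaneous linear mixture `X = A S` using only
#' second-order temporal statistics: whitening followed by joint approximate
#' diagonalization of time-lagged covariance matrices. Works whenever the
#' sources have distinct autocovariance structure; no non-Gaussianity is
#' needed. Sources are returned ordered by decreasing variance of their
#' back-projections, and each carries the usual blind-source-separation
#' sign/permutation/scale indeterminacy.
#'
#' @param X Numeric matrix, channels x samples (>= 2 channels).
#' @param lags Integer sample delays for the lagged covariances
#'   (default 1:20).
#' @param tol Jacobi rotation tolerance, see [joint_diagonalize()].
#' @return An object of class `sobi_result`: list with `S` (sources x
#'   samples), `A_hat` (estimated mixing matrix), `C_sep` (separation
#'   matrix, `C_sep %*% A_hat = I`), `Q` (whitener), `V` (orthogonal
#'   diagonaliser), `means`, `lags`.
#' @export
sobi_separate <- function(X, lags = 1:20, tol = 1e-8) {
  if (!is.matrix(X) || nrow(X) < 2) {
    abort("sobi_separate() needs >= 2 channels; blind separation of a single observation is underdetermined.")
  }
  wh <- whiten(X)
  mats <- lagged_covariances(wh$W, lags)
  V <- joint_diagonalize(mats, tol = tol)
  Q <- wh$Q
  A_hat <- pracma::pinv(Q) %*% V
  C_sep <- t(V) %*% Q
  S <- C_sep %*% (X - wh$means)
  # order sources by energy of their back-projection into sensor space
  energy <- colSums(A_hat^2) * apply(S, 1, function(s) mean(s^2))
  ord <- order(energy, decreasing = TRUE)
  res <- list(S = S[ord, , drop = FALSE],
              A_hat = A_hat[, ord, drop = FALSE],
              C_sep = C_sep[ord, , drop = FALSE],
              Q = Q, V = V, means = wh$means, lags = lags)
  class(res) <- "sobi_result"
  res
}

#' Reconstruct observations from (possibly modified) SOBI sources
#'
#' @param res A `sobi_result`.
#' @param S_mod Source matrix of the same shape as `res$S`; defaults to the
#'   unmodified sources (identity round trip).
#' @return Numeric matrix channels x samples, channel means restored.
#' @export
sobi_reconstruct <- function(res, S_mod = res$S) {
  if (!all(dim(S_mod) == dim(res$S))) {
    abort("S_mod must have the same shape as the separated sources.")
  }
  res$A_hat %*% S_mod + res$means
}

#' @export
print.sobi_result <- function(x, ...) {
  cat(sprintf("<sobi_result> %d sources x %d samples, lags 1..%d\n",
              nrow(x$S), ncol(x$S), max(x$lags)))
  invisible(x)
}

#' @rdname sobi_separate
#' @param x A `sobi_result`.
#' @param ... Unused.
#' @export
glance.sobi_result <- function(x, ...) {
  tibble(n_sources = nrow(x$S), n_samples = ncol(x$S),
         n_lags = length(x$lags),
         whiteness = max(abs(tcrossprod(x$Q %*% (x$A_hat %*% x$S)) /
                               (ncol(x$S) - 1) - diag(nrow(x$S)))))
}
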