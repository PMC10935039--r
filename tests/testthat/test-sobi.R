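test_that("whitening produces identity covariance and names culprits", {
  X <- matrix(seeded_noise(4 * 2000, 41), 4)
  wh <- whiten(X)
  C <- tcrossprod(wh$W) / (ncol(X) - 1)
  expect_lt(max(abs(C - diag(4))), 1e-8)

  Xc <- rbind(X[1:2, ], rep(5, 2000))
  expect_error(whiten(Xc), "constant channel")
  Xd <- rbind(X[1:2, ], X[2, ])
  expect_error(whiten(Xd), "duplicated")
  expect_error(whiten(X[1, , drop = FALSE]), "2 channels")
})

test_that("lagged covariances reflect the sources' autocorrelation", {
  W <- whiten(matrix(seeded_noise(3 * 4000, 42), 3))$W
  # lag-0 covariance normalises by n, the whitener by n - 1
  D0 <- lagged_covariances(W, 0)[[1]]
  n <- ncol(W)
  expect_equal(D0, (n - 1) / n * diag(3), tolerance = 1e-10)

  # white noise: all lag-1 entries within the sampling-error bound
  D1 <- lagged_covariances(W, 1)[[1]]
  expect_lt(max(abs(D1)), 3 / sqrt(4000))

  # a sinusoid at a quarter-period lag has near-zero autocovariance
  X <- rbind(make_tone(5, 200, 10), seeded_noise(2000, 43))
  Dq <- lagged_covariances(X, 10)[[1]]  # 10 samples = T/4 at 5 Hz, 200 Hz
  expect_lt(abs(Dq[1, 1]) / stats::var(X[1, ]), 0.02)

  expect_error(lagged_covariances(W, 3000), "lag")
})

test_that("joint diagonalization recovers a planted rotation", {
  withr::local_seed(44)
  k <- 5
  V0 <- qr.Q(qr(matrix(rnorm(k * k), k)))
  mats <- lapply(1:8, function(i) V0 %*% diag(rnorm(k)) %*% t(V0))
  V <- joint_diagonalize(mats)
  off <- sum(vapply(mats, function(D) {
    E <- t(V) %*% D %*% V
    sum((E - diag(diag(E)))^2)
  }, numeric(1)))
  expect_lt(off, 1e-8)
  # V matches V0 up to permutation and sign
  P <- abs(t(V) %*% V0)
  expect_true(all(apply(P, 1, max) > 1 - 1e-6))
  expect_true(all(apply(P, 2, max) > 1 - 1e-6))

  # already-diagonal input needs no rotation
  dmats <- lapply(1:3, function(i) diag(c(3, 2, 1) + i))
  expect_equal(joint_diagonalize(dmats), diag(3))

  # a single matrix reduces to its eigendecomposition
  M <- mats[[1]]
  Vs <- joint_diagonalize(list(M))
  ev <- eigen(M, symmetric = TRUE)$vectors
  match <- abs(t(Vs) %*% ev)
  expect_true(all(apply(match, 1, max) > 1 - 1e-6))

  expect_error(joint_diagonalize(list(matrix(1:6, 2))), "square")
  expect_error(joint_diagonalize(list(matrix(c(0, 1, 2, 0), 2))), "symmetric")
})

test_that("SOBI recovers temporally distinct sources from a random mixture", {
  case <- make_sobi_case(1)
  res <- sobi_separate(case$X)
  m <- abs(cor(t(case$S), t(res$S)))
  expect_gt(min(apply(m, 1, max)), 0.95)

  # identity mixing: sources come back up to scale and permutation
  res_i <- sobi_separate(case$S)
  mi <- abs(cor(t(case$S), t(res_i$S)))
  expect_gt(min(apply(mi, 1, max)), 0.99)

  expect_error(sobi_separate(case$X[1, , drop = FALSE]), "2 channels")
})

test_that("separation is invariant to channel rescaling", {
  case <- make_sobi_case(2)
  r1 <- sobi_separate(case$X)
  r2 <- sobi_separate(diag(c(10, 0.1, 3, 1)) %*% case$X)
  m <- abs(cor(t(r1$S), t(r2$S)))
  expect_gt(min(apply(m, 1, max)), 0.99)
})

test_that("reconstruction inverts separation", {
  case <- make_sobi_case(3)
  res <- sobi_separate(case$X)
  back <- sobi_reconstruct(res)
  expect_lt(max(abs(back - case$X)) / max(abs(case$X)), 1e-6)

  expect_equal(sobi_reconstruct(res, matrix(0, 4, 2000)),
               matrix(res$means, 4, 2000))

  # zeroing one recovered source approximates the 3-source mixture
  m <- abs(cor(t(case$S), t(res$S)))
  drop_true <- 4                      # drop the weakest-autocorrelation source
  drop_rec <- which.max(m[drop_true, ])
  S_mod <- res$S
  S_mod[drop_rec, ] <- 0
  x3 <- case$A[, -drop_true] %*% case$S[-drop_true, ]
  back3 <- sobi_reconstruct(res, S_mod)
  cors <- vapply(1:4, function(i) cor(back3[i, ], x3[i, ]), numeric(1))
  expect_gt(min(abs(cors)), 0.95)

  expect_error(sobi_reconstruct(res, res$S[1:2, ]), "shape")

  # algebraic invariants
  expect_lt(max(abs(res$C_sep %*% res$A_hat - diag(4))), 1e-6)
  expect_lt(max(abs(crossprod(res$V) - diag(4))), 1e-8)
})
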