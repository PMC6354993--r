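test_that("POD modes are orthonormal and capture energy in sigma order", {
  set.seed(31)
  x <- matrix(rnorm(300), 30, 10)
  b <- pod(x, 6)
  expect_equal(b$method, "POD")
  gram <- crossprod(b$modes)
  expect_lt(max(abs(gram - diag(6))), 1e-10)
  expect_true(all(diff(b$singular_values) <= 1e-12))
  # Frobenius error of the rank-r reconstruction equals the tail energy
  recon <- b$modes %*% crossprod(b$modes, x)
  expect_equal(norm(x - recon, "F"),
               sqrt(sum(b$singular_values[7:10]^2)), tolerance = 1e-10)
})

test_that("POD detects numerical rank and truncates with a warning", {
  u <- rnorm(20)
  v <- rnorm(8)
  x <- outer(u, v)
  b <- suppressWarnings(pod(x, 3))
  sig <- b$singular_values
  expect_equal(sum(sig > 1e-10 * sig[1]), 1)
  expect_warning(pod(x, 3), "numerical rank")
  expect_equal(suppressWarnings(pod(x, 3))$rank_used, 1)
})

test_that("PCA equals POD on the centered matrix up to column sign", {
  set.seed(32)
  x <- matrix(rnorm(400), 40, 10) + 5
  b_pca <- pca(x, 4)
  b_pod <- pod(x - rowMeans(x), 4)
  agree <- abs(colSums(b_pca$modes * b_pod$modes))
  expect_equal(agree, rep(1, 4), tolerance = 1e-10)
  expect_equal(b_pca$mean, rowMeans(x))
  # total energy of the centered decomposition is the centered Frobenius
  # norm
  expect_equal(sum(b_pca$singular_values^2),
               norm(x - rowMeans(x), "F")^2, tolerance = 1e-8)
  # an already-centered matrix makes the two identical up to sign
  xc <- x - rowMeans(x)
  agree2 <- abs(colSums(pca(xc, 3)$modes * pod(xc, 3)$modes))
  expect_equal(agree2, rep(1, 3), tolerance = 1e-10)
})

test_that("DMD recovers a planted two-mode map and handles edge dynamics", {
  set.seed(33)
  a_op <- diag(c(0.9, 0.5))
  q <- matrix(rnorm(20), 10, 2)
  tr <- lifted_trajectories(a_op, q, list(c(1, 1), c(2, -1), c(-1, 3)))
  b <- dmd(tr$x_prime, tr$x_dprime, 2)
  expect_equal(sort(Mod(b$eigenvalues)), c(0.5, 0.9), tolerance = 1e-8)

  x <- matrix(rnorm(50), 10, 5)
  ident <- dmd(x, x, 4)
  expect_lt(max(Mod(ident$eigenvalues - 1)), 1e-10)

  annih <- suppressWarnings(dmd(x, 0 * x, 3))
  expect_lt(max(Mod(annih$eigenvalues)), 1e-10)
  expect_error(dmd(0 * x, x, 2), "zero")
})

test_that("DMD one-step prediction is exact on noiseless linear data", {
  set.seed(34)
  theta <- 2 * pi / 7
  a_op <- rbind(c(cos(theta), -sin(theta), 0),
                c(sin(theta), cos(theta), 0),
                c(0, 0, 0.8))
  q <- qr.Q(qr(matrix(rnorm(60), 20, 3)))
  tr <- lifted_trajectories(a_op, q, list(c(1, 0, 1), c(0, 2, -1)),
                            n_steps = 5)
  b <- dmd(tr$x_prime, tr$x_dprime, 3)
  phi_pinv <- aeromode:::pinv(b$modes)
  pred <- Re(b$modes %*% (b$eigenvalues * (phi_pinv %*% tr$x_prime)))
  rel <- norm(pred - tr$x_dprime, "F") / norm(tr$x_dprime, "F")
  expect_lt(rel, 1e-6)
})

test_that("DMDC reduces to DMD for zero control and inverts a known system", {
  set.seed(35)
  # exactly linear low-rank data: both fits capture the same invariant
  # subspace, so zero control input must reproduce the DMD eigenvalues
  a_op <- diag(c(0.9, 0.6, 0.3))
  q <- qr.Q(qr(matrix(rnorm(60), 20, 3)))
  tr <- lifted_trajectories(a_op, q, list(c(1, 2, 1), c(-1, 1, 2),
                                          c(2, -1, 1)))
  y0 <- matrix(0, 2, ncol(tr$x_prime))
  d_plain <- dmd(tr$x_prime, tr$x_dprime, 3)
  d_ctrl <- suppressWarnings(dmdc(tr$x_prime, tr$x_dprime, y0, r = 3))
  expect_equal(sort(Mod(d_ctrl$basis$eigenvalues)),
               sort(Mod(d_plain$eigenvalues)), tolerance = 1e-8)
  expect_lt(max(abs(Im(d_ctrl$basis$eigenvalues))), 1e-8)

  # hand-sized system with exactly known augmented operator G = [A C]:
  # the fitted reduced operators are the compression of G through the
  # output basis, which at full rank lifts back to G itself
  a_true <- matrix(c(0.7, 0.2, 0, 0.1, 0.5, 0.3, 0, -0.2, 0.9), 3, 3)
  c_true <- matrix(c(1, -0.5, 0.25), 3, 1)
  xp2 <- matrix(rnorm(12), 3, 4)
  y2 <- matrix(rnorm(4), 1, 4)
  xpp2 <- a_true %*% xp2 + c_true %*% y2
  # oracle: explicit pseudoinverse of the augmented data matrix
  g_oracle <- xpp2 %*% aeromode:::pinv(rbind(xp2, y2))
  expect_equal(g_oracle, cbind(a_true, c_true), tolerance = 1e-10)
  fit <- dmdc(xp2, xpp2, y2, p = 4, r = 3)
  uh <- fit$basis$state_basis
  a_red <- crossprod(uh, a_true %*% uh)
  expect_equal(uh %*% fit$control$values, c_true, tolerance = 1e-10)
  lam_fit <- fit$basis$eigenvalues[order(Re(fit$basis$eigenvalues),
                                         Im(fit$basis$eigenvalues))]
  lam_true <- eigen(a_red)$values
  lam_true <- lam_true[order(Re(lam_true), Im(lam_true))]
  expect_equal(lam_fit, lam_true, tolerance = 1e-10)
})

test_that("continuous eigenvalue transform follows the principal branch", {
  expect_equal(continuous_frequencies(1), 0 + 0i)
  w <- continuous_frequencies(exp(-pi))
  expect_equal(Re(w), -0.5, tolerance = 1e-12)
  expect_equal(Im(w), 0, tolerance = 1e-12)
  set.seed(36)
  lam <- complex(real = runif(50, -1, 1), imaginary = runif(50, -1, 1))
  lam <- lam[Mod(lam) > 0]
  om <- continuous_frequencies(lam)
  expect_true(all(Im(om) > -0.5 & Im(om) <= 0.5))
  # stability reading: inside the unit circle <=> negative growth rate
  expect_true(all(sign(Re(om)) == sign(Mod(lam) - 1)))
  expect_warning(z <- continuous_frequencies(0), "-Inf")
  expect_true(Re(suppressWarnings(continuous_frequencies(0))) == -Inf)
})

test_that("spectrum peaks find planted oscillations and ignore flat spectra", {
  # planted oscillations at periods 3, 5, 9, separated by weakly
  # excited filler modes so each planted frequency is a local maximum,
  # plus a dominant quasi-static mode that must be excluded
  f2a <- function(f) 0.9 * exp(c(1, -1) * 2i * pi * f)
  lam <- c(0.97, f2a(1 / 3), f2a(1 / 5), f2a(1 / 9),
           f2a(0.15), f2a(0.27), f2a(0.45))
  amp <- c(10, 3, 3, 2, 2, 4, 4, 0.3, 0.3, 0.5, 0.5, 0.2, 0.2)
  pk <- spectrum_peaks(fake_dmd_basis(lam, amp))
  expect_equal(nrow(pk), 3)
  expect_equal(sort(pk$frequency), c(1 / 9, 1 / 5, 1 / 3),
               tolerance = 1e-8)
  expect_equal(pk$amplitude, c(4, 3, 2))

  single <- fake_dmd_basis(0.9 * exp(0.9i), 1.5)
  expect_equal(nrow(spectrum_peaks(single)), 1)

  flat <- fake_dmd_basis(0.9 * exp(1i * seq(0.3, 2, length.out = 6)),
                         rep(1, 6))
  expect_equal(nrow(spectrum_peaks(flat)), 0)
})

test_that("cumulative energy is monotone and complete", {
  sig <- c(5, 3, 2, 1, 0.5)
  en <- cumulative_energy(sig, seq_along(sig))
  expect_equal(en[length(sig)], 1)
  expect_true(all(diff(en) >= 0))
  expect_equal(cumulative_energy(c(7, 0, 0), 1), 1)
  expect_error(cumulative_energy(c(0, 0), 1), "zero")
  expect_error(cumulative_energy(sig, 6), "1..length")
})

test_that("projection is a least-squares solve with exact reproduction", {
  set.seed(37)
  b <- pod(matrix(rnorm(300), 30, 10), 4)
  # image equal to the first mode projects to the first unit vector
  co <- project_modes(b, b$modes[, 1], 4)
  expect_equal(co, c(1, 0, 0, 0), tolerance = 1e-10)
  # image orthogonal to all retained modes projects to zero
  resid <- rnorm(30)
  resid <- resid - b$modes %*% crossprod(b$modes, resid)
  expect_equal(project_modes(b, as.numeric(resid), 4), rep(0, 4),
               tolerance = 1e-10)
  # linearity
  x1 <- rnorm(30)
  x2 <- rnorm(30)
  lhs <- project_modes(b, 2 * x1 - 3 * x2)
  rhs <- 2 * project_modes(b, x1) - 3 * project_modes(b, x2)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  expect_error(project_modes(b, rnorm(29)), "does not match")
})

test_that("non-orthogonal complex projections match the normal equations", {
  set.seed(38)
  x <- matrix(rnorm(300), 30, 10)
  b <- dmd(x[, 1:9], x[, 2:10], 5)
  img <- rnorm(30)
  co <- project_modes(b, img, 5)
  phi <- b$modes[, 1:5]
  oracle <- Re(solve(Conj(t(phi)) %*% phi, Conj(t(phi)) %*% img))
  expect_equal(co, as.numeric(oracle), tolerance = 1e-8)
})

test_that("feature tables nest for orthonormal bases and track labels", {
  d <- make_dataset(seed = 41, h = 16, w = 16)
  snap <- assemble_snapshots(d)
  b <- pod(snap, 10)
  f10 <- build_feature_table(b, snap, 10)
  f3 <- build_feature_table(b, snap, 3)
  expect_equal(dim(f10$features), c(405, 10))
  expect_equal(f3$features, f10$features[, 1:3])
  expect_equal(levels(f3$labels), c("A0", "A1", "A2", "A3", "A4"))
  expect_equal(as.character(f3$labels), snap$columns$class_label)
  # an all-zero image projects to an all-zero row under POD
  zero_row <- project_modes(b, rep(0, 256), 10)
  expect_equal(zero_row, rep(0, 10))
})

test_that("DMD/DMDC feature realification keeps conjugate pairs informative", {
  d <- make_dataset(seed = 43, h = 16, w = 16)
  snap <- assemble_snapshots(d)
  sp <- split_transitions(snap)
  b <- dmd(sp$x_prime, sp$x_dprime, 12)
  ft <- build_feature_table(b, snap, 12)
  expect_equal(dim(ft$features), c(405, 12))
  expect_true(all(is.finite(ft$features)))
  # conjugate pairs must not duplicate columns
  dup <- duplicated(round(t(ft$features), 8))
  expect_false(any(dup))
})
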