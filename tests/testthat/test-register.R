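test_that("joint histograms enumerate pixel pairs over the overlap", {
  a <- matrix(c(0, 0, 1, 1), 2, 2)           # identical images: diagonal
  jh <- joint_histogram(a, a, bins = 2)
  expect_equal(jh$p_ab, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(sum(jh$p_ab), 1)
  expect_equal(jh$overlap_fraction, 1)

  # left/right split vs top/bottom split: independent, all cells 0.25
  A <- matrix(c(0, 0, 1, 1), 2, 2)           # columns differ
  B <- matrix(c(0, 1, 0, 1), 2, 2)           # rows differ
  jh2 <- joint_histogram(A, B, bins = 2)
  expect_equal(jh2$p_ab, matrix(0.25, 2, 2))
  expect_equal(jh2$p_a, rowSums(jh2$p_ab))
  expect_equal(jh2$p_b, colSums(jh2$p_ab))

  expect_error(joint_histogram(A, B, rigid_transform(100, 100, 0), bins = 2),
               "overlap")
})

test_that("entropy follows the Shannon formula in bits", {
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(shannon_entropy(c(-0.1, 1.1)), "negative")
  expect_error(shannon_entropy(c(0.3, 0.3)), "sum")
})

test_that("mutual information satisfies its information-theoretic identities", {
  half <- matrix(c(rep(0, 32), rep(1, 32)), 8, 8)
  self <- mutual_information(half, half, bins = 2)
  expect_equal(self$mi, 1)                  # MI(A, A) = H(A) = 1 bit
  expect_equal(self$mi, self$h_a, tolerance = 1e-12)

  A <- matrix(rep(c(0, 1), each = 32), 8, 8)   # left/right split
  B <- matrix(rep(c(0, 1), times = 32), 8, 8)  # top/bottom split
  ind <- mutual_information(A, B, bins = 2)
  expect_equal(ind$mi, 0, tolerance = 1e-9)

  set.seed(17)
  for (i in 1:20) {
    X <- matrix(stats::runif(16^2), 16, 16)
    Y <- matrix(stats::runif(16^2), 16, 16)
    r <- mutual_information(X, Y, bins = sample(4:32, 1))
    expect_equal(r$mi, r$h_a + r$h_b - r$h_ab, tolerance = 1e-9)
    expect_gte(r$mi, -1e-9)
    expect_lte(r$mi, min(r$h_a, r$h_b) + 1e-9)
  }

  # symmetry MI(A,B) = MI(B,A) under the identity
  r_ab <- mutual_information(A, B, bins = 2)
  r_ba <- mutual_information(B, A, bins = 2)
  expect_equal(r_ab$mi, r_ba$mi, tolerance = 1e-12)
})

test_that("the direction-set optimizer minimises standard test functions", {
  bowl <- powell_optimize(function(p) (p[1] - 3)^2 + (p[2] + 1)^2, c(0, 0),
                          tol = 1e-10, line_tol = 1e-8)
  expect_equal(bowl$x, c(3, -1), tolerance = 1e-4)

  quart <- powell_optimize(function(p) p^4, 2, tol = 1e-10, line_tol = 1e-8)
  expect_lt(abs(quart$x), 1e-2)

  rosen <- function(p) (1 - p[1])^2 + 100 * (p[2] - p[1]^2)^2
  po <- powell_optimize(rosen, c(-1.2, 1), tol = 1e-12, max_cycles = 500,
                        line_range = 2, line_tol = 1e-10)
  expect_equal(po$x, c(1, 1), tolerance = 1e-3)
  # agreement with an independent optimizer run
  nm <- stats::optim(c(-1.2, 1), rosen, method = "Nelder-Mead",
                     control = list(maxit = 5000, reltol = 1e-14))
  expect_equal(po$x, nm$par, tolerance = 1e-3)
  # best value per cycle never increases
  expect_true(all(diff(po$trace) <= 1e-12))

  expect_error(powell_optimize(function(p) NaN, 0), "non-finite")
})

test_that("rigid registration recovers phantom misalignments", {
  s <- generate_slice(fast_params(seed = 41L,
                                  misalignment = rigid_transform(5, -3, 0)))
  r <- register_rigid(s$ct, s$pet)
  expect_lt(abs(r$transform$tx - 5), 1)
  expect_lt(abs(r$transform$ty + 3), 1)
  expect_lt(abs(r$transform$theta), 1)
  expect_gt(r$mi$mi, mutual_information(
    s$ct$pixels, resample_image(s$pet$activity, dim(s$ct$pixels)))$mi)

  # an aligned pair stays near the identity
  s0 <- generate_slice(fast_params(seed = 42L,
                                   misalignment = rigid_transform(0, 0, 0)))
  r0 <- register_rigid(s0$ct, s0$pet)
  expect_lt(abs(r0$transform$tx), 0.5)
  expect_lt(abs(r0$transform$ty), 0.5)
  expect_lt(abs(r0$transform$theta), 0.5)
})
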