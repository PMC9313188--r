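test_that("kernel width shrinks with sample size toward the template term", {
  ks <- kernel_spec(sigma_template_mm = 3, sigma_subject_mm = 6)
  expect_equal(kernel_sigma(4, ks), sqrt(9 + 36 / 4))
  expect_lt(kernel_sigma(30, ks), kernel_sigma(10, ks))
  expect_equal(kernel_sigma(1e9, ks), 3, tolerance = 1e-6)
  expect_error(kernel_sigma(0, ks), ">= 1")
})

test_that("single-focus MA map is the kernel, peaked at the nearest voxel", {
  g <- tiny_grid(c(11, 11, 11))
  ks <- kernel_spec(sigma_template_mm = 3, sigma_subject_mm = 6)
  e <- experiment("s", 4, rbind(c(0.6, -0.9, 0)))  # snaps to the voxel at mm (0,0,0)
  ma <- compute_ma_map(e, g, ks)
  peak_lin <- which.max(ma)
  pk_mm <- voxel_to_mm(g, cbma:::linear_to_ijk(g, peak_lin))
  expect_equal(unname(pk_mm[1, ]), c(0, 0, 0))
  sigma <- kernel_sigma(4, ks)
  expect_equal(max(ma), (2 * pi * sigma^2)^(-1.5) * g$voxel_volume_mm3)
  expect_true(all(ma >= 0 & ma <= 1))
  # value at an off-centre voxel equals the Gaussian mass at that distance
  probe <- cbma:::ijk_to_linear(g, mm_to_voxel(g, rbind(c(4, 2, -2))))
  d2 <- sum(c(4, 2, -2)^2)
  expect_equal(ma[probe],
               (2 * pi * sigma^2)^(-1.5) * exp(-d2 / (2 * sigma^2)) *
                 g$voxel_volume_mm3)
})

test_that("max rule is idempotent for coincident foci and additive rules
          stay bounded", {
  g <- tiny_grid(c(11, 11, 11))
  ks <- kernel_spec(sigma_template_mm = 3, sigma_subject_mm = 6)
  one <- compute_ma_map(experiment("s", 8, rbind(c(0, 0, 0))), g, ks)
  two <- compute_ma_map(experiment("s", 8, rbind(c(0, 0, 0), c(0, 0, 0))),
                        g, ks)
  expect_identical(two, one)
  ks_u <- kernel_spec(sigma_template_mm = 3, sigma_subject_mm = 6,
                      combine = "union")
  two_u <- compute_ma_map(experiment("s", 8,
                                     rbind(c(0, 0, 0), c(0, 0, 0))), g, ks_u)
  expect_equal(two_u, 1 - (1 - one)^2)
  expect_true(all(two_u <= 1))
})

test_that("well-separated foci give disjoint supports matching their
          single-focus maps", {
  g <- load_or_make_grid(shape = c(40, 12, 12), spacing_mm = 2,
                         center_mm = c(0, 0, 0),
                         radii_mm = c(1e3, 1e3, 1e3))
  ks <- kernel_spec(sigma_template_mm = 1.5, sigma_subject_mm = 2,
                    truncation_radius_sd = 4)
  f1 <- c(-30, 0, 0); f2 <- c(30, 0, 0)  # separation >> 2 * truncation
  both <- compute_ma_map(experiment("s", 10, rbind(f1, f2)), g, ks)
  m1 <- compute_ma_map(experiment("s", 10, rbind(f1)), g, ks)
  m2 <- compute_ma_map(experiment("s", 10, rbind(f2)), g, ks)
  expect_true(!any(m1 > 0 & m2 > 0))
  expect_equal(both, pmax(m1, m2))
})

test_that("ALE is the complement-product union of MA maps", {
  g <- tiny_grid(c(6, 6, 6))
  mask_n <- sum(g$mask)
  v1 <- rep(0, mask_n); v1[1:10] <- 0.5
  v2 <- rep(0, mask_n); v2[6:15] <- 0.5
  stk <- stack_from_values(g, list(v1, v2))
  ale <- compute_ale_map(stk)
  mask_lin <- which(g$mask)
  expect_equal(ale[mask_lin[6]], 0.75)       # 1 - 0.5^2
  expect_equal(ale[mask_lin[1]], 0.5)
  expect_equal(ale[mask_lin[16]], 0)
  # single term: identity
  expect_equal(compute_ale_map(stack_from_values(g, list(v1)))[mask_lin],
               v1)
  # union bound and order invariance
  expect_true(all(ale[mask_lin] >= pmax(v1, v2) - 1e-12))
  expect_equal(compute_ale_map(stack_from_values(g, list(v2, v1))), ale)
})

test_that("experiment order does not change ALE or the analytic null on a
          real corpus", {
  g <- small_mask_grid()
  corp <- generate_null_corpus(4, 3, g, seed = 11)
  ks <- kernel_spec()
  stk <- ma_stack(corp, g, ks)
  stk_rev <- ma_stack(corpus(rev(corp$experiments)), g, ks)
  expect_equal(compute_ale_map(stk), compute_ale_map(stk_rev))
  n1 <- compute_analytic_null(stk, 1e-5)
  n2 <- compute_analytic_null(stk_rev, 1e-5)
  expect_equal(n1$survival, n2$survival)
})

test_that("analytic null reproduces the exact two-point enumeration", {
  g <- tiny_grid(c(4, 4, 4))
  nm <- sum(g$mask)
  half <- nm / 2
  v <- c(rep(0.5, half), rep(0, nm - half))
  stk <- stack_from_values(g, list(v, v))
  null <- compute_analytic_null(stk, 1e-5)
  expect_equal(null_survival(null, 0.75), 0.25)
  expect_equal(null_survival(null, 0.5), 0.75)
  expect_equal(null_survival(null, 0), 1)
  expect_equal(null_survival(null, 0.76), 0)
})

test_that("single-experiment null equals the empirical MA survival", {
  g <- small_mask_grid()
  corp <- generate_null_corpus(1, 5, g, seed = 3)
  stk <- ma_stack(corp, g, kernel_spec())
  null <- compute_analytic_null(stk, 1e-5)
  mask_lin <- which(g$mask)
  ma <- compute_ma_map(corp$experiments[[1]], g, kernel_spec())
  vals <- ma[mask_lin]
  # empirical survival by direct counting under the documented half-up
  # binning; independent of the convolution path being checked
  bin <- function(x) floor(-log1p(-x) / null$bin_width + 0.5)
  for (s in c(0, quantile(vals[vals > 0], c(0.25, 0.75)), max(vals))) {
    expect_equal(null_survival(null, s), mean(bin(vals) >= bin(s)),
                 tolerance = 1e-9)
  }
})

test_that("null survival is a proper non-increasing tail function", {
  g <- small_mask_grid()
  corp <- generate_null_corpus(3, 4, g, seed = 5)
  stk <- ma_stack(corp, g, kernel_spec())
  null <- compute_analytic_null(stk, 1e-5)
  expect_equal(null$survival[1], 1)
  expect_true(all(diff(null$survival) <= 1e-15))
  expect_true(all(null$survival >= 0 & null$survival <= 1))
  max_possible <- 1 - prod(1 - vapply(stk$maps, function(m) max(m$val), 0))
  expect_equal(null_survival(null, max_possible + 1e-3), 0)
  expect_error(compute_analytic_null(stk, 0), "bin_width")
})

test_that("analytic null matches a Monte-Carlo voxel-sampling oracle", {
  g <- small_mask_grid()  # 18x20x18, well under 20^3
  corp <- generate_null_corpus(3, c(4, 5, 3), g, seed = 7)
  stk <- ma_stack(corp, g, kernel_spec())
  null <- compute_analytic_null(stk, 1e-5)
  mask_lin <- which(g$mask)
  nm <- length(mask_lin)
  dense <- lapply(stk$maps, function(m) {
    v <- numeric(prod(g$shape)); v[m$idx] <- m$val; v[mask_lin]
  })
  B <- 1e6
  set.seed(1234)
  acc <- rep(1, B)
  for (d in dense) acc <- acc * (1 - d[sample.int(nm, B, replace = TRUE)])
  draws <- 1 - acc
  probes <- c(quantile(draws[draws > 0], c(0.5, 0.9, 0.99, 0.999)),
              max(draws) * 0.99)
  for (s in probes) {
    mc <- mean(draws >= s)
    se <- sqrt(mc * (1 - mc) / B)
    expect_lt(abs(null_survival(null, s) - mc), 3 * se + 1e-12)
  }
})

test_that("voxelwise thresholding converts tail p to z and flags
          suprathreshold voxels monotonically", {
  g <- small_mask_grid()
  corp <- generate_null_corpus(5, 6, g, seed = 9)
  stk <- ma_stack(corp, g, kernel_spec())
  ale <- compute_ale_map(stk)
  null <- compute_analytic_null(stk, 1e-5)
  thr <- voxelwise_threshold(ale, null, 0.001, g)
  # z at p = 0.05 is the one-sided normal quantile
  expect_equal(stats::qnorm(0.05, lower.tail = FALSE), 1.6449, tolerance = 1e-3)
  i <- which(g$mask & ale > 0)[1]
  expect_equal(thr$z[i],
               stats::qnorm(max(null_survival(null, ale[i]), null$p_min),
                            lower.tail = FALSE))
  # zero map: nothing survives
  thr0 <- voxelwise_threshold(array(0, dim = g$shape), null, 0.001, g)
  expect_false(any(thr0$supra))
  # relaxing the threshold never removes voxels
  thr_strict <- voxelwise_threshold(ale, null, 0.001, g)
  thr_loose <- voxelwise_threshold(ale, null, 0.01, g)
  expect_true(all(thr_loose$supra[thr_strict$supra]))
  expect_true(all(is.finite(thr$z)))
})
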