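make_two_pattern_docs <- function(tokens_per_voxel = 3L) {
  mk <- function(sup) list(words = sup,
                           counts = rep(tokens_per_voxel, length(sup)))
  lda_documents(c(lapply(1:6, function(i) mk(1:30)),
                  lapply(1:6, function(i) mk(31:60))), V = 60)
}

best_of_seeds <- function(docs, cfg, n_seeds, seed = 0) {
  best <- NULL
  for (i in seq_len(n_seeds)) {
    f <- cvb0_fit(docs, cfg, seed = seed + i)
    if (is.null(best) || f$log_likelihood > best$log_likelihood) best <- f
  }
  best
}

test_that("K = 1 posterior equals its closed form", {
  docs <- lda_documents(list(list(words = c(1L, 2L), counts = c(2L, 1L)),
                             list(words = c(2L, 3L), counts = c(1L, 1L))),
                        V = 4)
  fit <- cvb0_fit(docs, topic_config(K = 1, alpha = 100, eta = 0.01), seed = 1)
  expect_equal(fit$theta, matrix(1, 2, 1))
  expect_equal(fit$beta[1, ],
               (c(2, 2, 1, 0) + 0.01) / (5 + 4 * 0.01), tolerance = 1e-8)
  expect_equal(fit$log_likelihood,
               sum(c(2, 1, 1, 1) * log((c(2, 2, 2, 1) + 0.01) / 5.04)),
               tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("theta and beta rows are probability distributions for any K", {
  docs <- make_two_pattern_docs()
  for (K in c(2, 3)) {
    fit <- cvb0_fit(docs, topic_config(K = K, alpha = 100, eta = 0.01,
                                       max_iter = 40), seed = 3)
    expect_equal(rowSums(fit$theta), rep(1, docs$D), tolerance = 1e-8)
    expect_equal(rowSums(fit$beta), rep(1, K), tolerance = 1e-8)
    expect_true(all(fit$theta >= 0) && all(fit$beta >= 0))
  }
})

test_that("monitored log-likelihood is non-decreasing up to numerical
          slack and fits are seed-deterministic", {
  docs <- make_two_pattern_docs()
  cfg <- topic_config(K = 2, alpha = 100, eta = 0.01, max_iter = 60,
                      tol = 1e-8)
  fit <- cvb0_fit(docs, cfg, seed = 7)
  tr <- fit$ll_trace
  expect_true(all(diff(tr) >= -1e-6 * abs(tr[-length(tr)])))
  expect_identical(cvb0_fit(docs, cfg, seed = 7)$theta, fit$theta)
})

test_that("planted two-factor structure is recovered and agrees with an
          EM oracle on a two-word toy", {
  docs <- make_two_pattern_docs()
  cfg <- topic_config(K = 2, alpha = 100, eta = 0.01, max_iter = 200,
                      tol = 1e-8)
  best <- best_of_seeds(docs, cfg, 20)
  # label matching: factor 1 is whichever loads on words 1..30
  k1 <- which.max(rowSums(best$beta[, 1:30, drop = FALSE]))
  k2 <- 3 - k1
  expect_true(all(best$theta[1:6, k1] > 0.6))
  expect_true(all(best$theta[7:12, k2] > 0.6))
  gt1 <- c(rep(1 / 30, 30), rep(0, 30))
  expect_gt(stats::cor(best$beta[k1, ], gt1), 0.9)
  expect_gt(stats::cor(best$beta[k2, ], rev(gt1)), 0.9)

  # two-word toy: independent smoothed-EM oracle on the same model
  toy <- lda_documents(list(list(words = 1L, counts = 20L),
                            list(words = 2L, counts = 20L)), V = 2)
  em_oracle <- function(alpha, eta, iters = 500) {
    theta <- matrix(c(0.6, 0.4, 0.4, 0.6), 2, 2)
    beta <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2)  # K x V
    counts <- rbind(c(20, 0), c(0, 20))
    for (it in seq_len(iters)) {
      Ndk <- matrix(0, 2, 2); Nkw <- matrix(0, 2, 2)
      for (d in 1:2) for (w in 1:2) {
        if (counts[d, w] == 0) next
        r <- theta[d, ] * beta[, w]
        r <- r / sum(r)
        Ndk[d, ] <- Ndk[d, ] + counts[d, w] * r
        Nkw[, w] <- Nkw[, w] + counts[d, w] * r
      }
      theta <- (Ndk + alpha) / rowSums(Ndk + alpha)
      beta <- (Nkw + eta) / rowSums(Nkw + eta)
    }
    list(theta = theta, beta = beta)
  }
  em <- em_oracle(alpha = 1, eta = 0.01)
  cv <- best_of_seeds(toy, topic_config(K = 2, alpha = 1, eta = 0.01,
                                        max_iter = 500, tol = 1e-10), 20)
  kk1 <- which.max(cv$beta[, 1])
  ek1 <- which.max(em$beta[, 1])
  expect_equal(cv$beta[kk1, ], em$beta[ek1, ], tolerance = 0.05)
  expect_equal(cv$theta[1, kk1], em$theta[1, ek1], tolerance = 0.05)
  expect_gt(cv$theta[1, kk1], 0.9)
})

test_that("BIC follows the stated penalized-likelihood formula", {
  # fixed LL = -1000, V = 101, D = 10, K = 2, W = e^4 -> BIC = -1420
  pen <- cbma:::bic_penalty(2, 101, 10, exp(4))
  expect_equal(-1000 - pen, -1420)
})

test_that("model selection picks the planted number of factors and the
          representative fit has the best likelihood of its seeds", {
  docs2 <- make_two_pattern_docs()
  cfg <- topic_config(K = 1, alpha = 100, eta = 0.01, n_seeds = 10,
                      max_iter = 100)
  sel <- model_selection(docs2, 1:4, cfg, seed = 0)
  expect_equal(sel$best_K, 2L)
  # representative fit is the max-likelihood restart
  refit_ll <- vapply(1:10, function(i)
    cvb0_fit(docs2, topic_config(K = 2, alpha = 100, eta = 0.01,
                                 max_iter = 100), seed = i)$log_likelihood, 0)
  expect_equal(sel$fits[["2"]]$log_likelihood, max(refit_ll))
  # one shared pattern -> K = 1
  mk <- function(sup) list(words = sup, counts = rep(3L, length(sup)))
  docs1 <- lda_documents(lapply(1:12, function(i) mk(1:30)), V = 30)
  sel1 <- model_selection(docs1, 1:4, cfg, seed = 0)
  expect_equal(sel1$best_K, 1L)
})

test_that("label permutation leaves likelihood and BIC unchanged", {
  docs <- make_two_pattern_docs()
  fit <- cvb0_fit(docs, topic_config(K = 2, alpha = 100, eta = 0.01,
                                     max_iter = 60), seed = 5)
  perm_theta <- fit$theta[, 2:1]
  perm_beta <- fit$beta[2:1, ]
  d_id <- rep(1:12, each = 30)
  w_id <- unlist(lapply(docs$docs, `[[`, "words"))
  cnt <- unlist(lapply(docs$docs, `[[`, "counts"))
  ll <- function(th, be) sum(cnt * log(rowSums(th[d_id, ] * t(be)[w_id, ])))
  expect_equal(ll(perm_theta, perm_beta), ll(fit$theta, fit$beta),
               tolerance = 1e-10)
})

test_that("documents are binary spheres on the downsampled grid", {
  g <- load_or_make_grid()
  corp <- make_corpus(list(rbind(c(0, -17, 8)),
                           rbind(c(0, -17, 8), c(2, -15, 8))))
  bd <- build_documents(corp, g, radius_mm = 10, spacing_mm = 4)
  voc <- bd$vocabulary
  d1 <- bd$documents$docs[[1]]
  expect_true(all(d1$counts == 1))
  # exact geometric support: in-mask voxels within 10 mm of the focus
  mm <- cbma:::voxel_to_mm(voc$grid,
                           cbma:::linear_to_ijk(voc$grid, voc$voxel_ids))
  d2c <- sqrt(rowSums(sweep(mm, 2, c(0, -17, 8))^2))
  expect_setequal(voc$voxel_ids[d1$words], voc$voxel_ids[d2c <= 10])
  # overlapping spheres never double-count
  d2 <- bd$documents$docs[[2]]
  expect_true(all(d2$counts == 1))
  expect_gte(length(d2$words), length(d1$words))
  # a focus far outside the mask neighbourhood is an error
  far <- make_corpus(list(rbind(c(150, 150, 150))))
  expect_error(build_documents(far, g, 10, 4), "no in-mask voxel")
})

test_that("factor volumes place Pr(Voxel|Factor) on the vocabulary and sum
          to one", {
  g <- load_or_make_grid()
  corp <- make_corpus(list(rbind(c(0, -17, 8)), rbind(c(8, -17, 0))))
  bd <- build_documents(corp, g)
  fit <- cvb0_fit(bd$documents, topic_config(K = 1, alpha = 100, eta = 0.01))
  vol <- factor_to_volume(fit, 1, bd$vocabulary)
  expect_equal(sum(vol), 1, tolerance = 1e-6)
  # K = 1 support is the union of the documents' voxels
  expect_setequal(which(vol > 0), bd$vocabulary$voxel_ids)
  expect_error(factor_to_volume(fit, 2, bd$vocabulary), "out of range")
})
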