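#' Build study-by-voxel documents for latent factor analysis
#'
#' Studies are documents and in-mask voxels are words. The analysis grid
#' is downsampled to `spacing_mm`; for each experiment, every in-mask
#' voxel of the downsampled grid lying within `radius_mm` of ANY focus
#' receives count 1 (binary per experiment: overlapping focus spheres do
#' not double-count). The vocabulary is the union of all documents'
#' voxels.
#'
#' @param corp corpus in MNI space.
#' @param grid a [brain_grid()] (full-resolution analysis grid).
#' @param radius_mm sphere radius around each focus (default 10 mm).
#' @param spacing_mm vocabulary grid spacing (default 4 mm).
#' @return List with `vocabulary` (class `lda_vocabulary`: downsampled
#'   `grid`, `voxel_ids` linear indices, `V`) and `documents` (class
#'   `lda_documents`: per-study sparse counts over the vocabulary, `D`,
#'   total token count `W`).
#' @export
build_documents <- function(corp, grid, radius_mm = 10, spacing_mm = 4) {
  stopifnot(inherits(corp, "cbma_corpus"), length(corp$experiments) >= 1)
  g <- resample_grid(grid, spacing_mm)
  sp <- sqrt(colSums(g$affine[1:3, 1:3]^2))
  r <- as.integer(ceiling(radius_mm / sp))
  off <- as.matrix(expand.grid(di = -r[1]:r[1], dj = -r[2]:r[2],
                               dk = -r[3]:r[3]))
  per_doc <- lapply(corp$experiments, function(e) {
    ctr_ijk <- mm_to_voxel(g, e$foci)
    vox <- integer(0)
    for (f in seq_len(nrow(e$foci))) {
      ijk <- cbind(ctr_ijk[f, 1] + off[, 1], ctr_ijk[f, 2] + off[, 2],
                   ctr_ijk[f, 3] + off[, 3])
      lin <- ijk_to_linear(g, ijk)
      ok <- !is.na(lin)
      lin <- lin[ok]
      lin <- lin[g$mask[lin]]
      if (length(lin)) {
        mm <- voxel_to_mm(g, linear_to_ijk(g, lin))
        d2 <- (mm[, 1] - e$foci[f, 1])^2 + (mm[, 2] - e$foci[f, 2])^2 +
              (mm[, 3] - e$foci[f, 3])^2
        vox <- c(vox, lin[d2 <= radius_mm^2])
      }
    }
    if (!length(vox))
      stop_cbma("study '%s': no in-mask voxel within %g mm of any focus",
                e$study_id, radius_mm)
    sort(unique(vox))
  })
  voxel_ids <- sort(unique(unlist(per_doc)))
  vocab <- structure(list(grid = g, voxel_ids = voxel_ids,
                          V = length(voxel_ids)),
                     class = "lda_vocabulary")
  docs <- lapply(per_doc, function(v) {
    w <- match(v, voxel_ids)
    list(words = w, counts = rep(1L, length(w)))
  })
  documents <- structure(
    list(docs = docs, D = length(docs),
         W = sum(vapply(docs, function(d) sum(d$counts), 0L)),
         V = length(voxel_ids),
         study_ids = vapply(corp$experiments, `[[`, "", "study_id")),
    class = "lda_documents")
  list(vocabulary = vocab, documents = documents)
}

#' Assemble an `lda_documents` object from raw sparse counts
#'
#' For simulation studies and tests that construct documents directly.
#'
#' @param docs list of lists with integer `words` (vocabulary ids) and
#'   `counts` (positive integers).
#' @param V vocabulary size.
#' @param study_ids optional document labels.
#' @return An `lda_documents` object.
#' @export
lda_documents <- function(docs, V, study_ids = NULL) {
  stopifnot(length(docs) >= 1)
  for (d in docs) {
    stopifnot(length(d$words) == length(d$counts), all(d$counts >= 1),
              all(d$words >= 1), all(d$words <= V))
    if (!length(d$words)) stop_cbma("every document needs >= 1 token")
  }
  structure(list(docs = docs, D = length(docs),
                 W = sum(vapply(docs, function(d) sum(d$counts), 0)),
                 V = as.integer(V),
                 study_ids = study_ids %||%
                   sprintf("doc_%02d", seq_along(docs))),
            class = "lda_documents")
}

#' Latent factor model configuration
#'
#' @param K number of latent factors.
#' @param alpha symmetric per-component Dirichlet parameter on
#'   Pr(Factor|Study) (default 100, as passed to the inference).
#' @param eta symmetric Dirichlet parameter on Pr(Voxel|Factor)
#'   (default 0.01).
#' @param n_seeds random restarts per K (default 100).
#' @param max_iter,tol CVB0 stopping rule: stop when the relative change
#'   of the monitored log-likelihood falls below `tol`, or at `max_iter`.
#' @param alpha_per_k if `TRUE`, rescale alpha to `alpha / K` (off by
#'   default; alpha is then the total concentration).
#' @return An object of class `topic_config`.
#' @export
topic_config <- function(K, alpha = 100, eta = 0.01, n_seeds = 100,
                         max_iter = 200, tol = 1e-6, alpha_per_k = FALSE) {
  stopifnot(K >= 1, alpha > 0, eta > 0, n_seeds >= 1, max_iter >= 1, tol > 0)
  structure(list(K = as.integer(K), alpha = alpha, eta = eta,
                 n_seeds = as.integer(n_seeds), max_iter = as.integer(max_iter),
                 tol = tol, alpha_per_k = alpha_per_k),
            class = "topic_config")
}

bic_penalty <- function(K, V, D, W) 0.5 * (K * (V - 1) + D * (K - 1)) * log(W)

#' Fit latent factors by zeroth-order collapsed variational Bayes
#'
#' Per-token factor responsibilities are iterated with the CVB0 update
#' `gamma[d,w,k] proportional to (alpha + Ndk - gamma) * (eta + Nkw -
#' gamma) / (V*eta + Nk - gamma)` (counts excluding the token's own
#' contribution), updated in chunks with count refresh between chunks,
#' until the relative change of the monitored log-likelihood drops below
#' `tol`. Point estimates are the smoothed count ratios
#' `theta[d,k] = (alpha + Ndk) / sum_k'(alpha + Ndk')` and
#' `beta[k,w] = (eta + Nkw) / (V*eta + Nk)`; the reported log-likelihood
#' is `sum over tokens of log sum_k theta[d,k] beta[k,w]`. `K = 1` has a
#' closed-form posterior and skips iteration.
#'
#' @param documents an `lda_documents`.
#' @param config a [topic_config()].
#' @param seed integer; responsibilities are initialized from seeded
#'   Dirichlet(1) noise, making the fit deterministic given the seed.
#' @return An object of class `topic_fit`: `theta` (D x K), `beta`
#'   (K x V), `log_likelihood`, `bic`, `seed`, `converged`, `n_iter`,
#'   `ll_trace`.
#' @export
cvb0_fit <- function(documents, config, seed = 1) {
  stopifnot(inherits(documents, "lda_documents"),
            inherits(config, "topic_config"))
  K <- config$K
  D <- documents$D
  V <- documents$V
  W <- documents$W
  alpha <- if (config$alpha_per_k) config$alpha / K else config$alpha
  eta <- config$eta
  if (K > D) warning("K exceeds the number of documents; fit may be degenerate")
  d_id <- unlist(lapply(seq_len(D), function(d)
    rep(d, length(documents$docs[[d]]$words))))
  w_id <- unlist(lapply(documents$docs, `[[`, "words"))
  cnt <- as.numeric(unlist(lapply(documents$docs, `[[`, "counts")))
  M <- length(w_id)

  if (K == 1L) {
    nw <- numeric(V)
    agg <- rowsum(cnt, w_id)
    nw[as.integer(rownames(agg))] <- agg[, 1]
    beta <- matrix((nw + eta) / (W + V * eta), nrow = 1)
    theta <- matrix(1, nrow = D, ncol = 1)
    ll <- sum(cnt * log(beta[1, w_id]))
    return(structure(list(theta = theta, beta = beta, log_likelihood = ll,
                          bic = ll - bic_penalty(1, V, D, W), seed = seed,
                          converged = TRUE, n_iter = 0L, ll_trace = ll,
                          K = 1L, alpha = alpha, eta = eta),
                     class = "topic_fit"))
  }

  set.seed(seed)
  g <- matrix(stats::rgamma(M * K, 1), M, K)
  g <- g / rowSums(g)
  Ndk <- rowsum(g * cnt, d_id)                    # D x K
  Nkw <- rowsum(g * cnt, w_id)                    # (distinct w) x K
  Nkw_full <- matrix(0, V, K)
  Nkw_full[as.integer(rownames(Nkw)), ] <- Nkw
  Nk <- colSums(g * cnt)

  chunks <- split(seq_len(M), cut(seq_len(M), breaks = min(8L, M),
                                  labels = FALSE))
  loglik <- function() {
    theta <- (Ndk + alpha) / rowSums(Ndk + alpha)
    beta <- sweep(Nkw_full + eta, 2, Nk + V * eta, "/")  # V x K
    p <- rowSums(theta[d_id, , drop = FALSE] * beta[w_id, , drop = FALSE])
    sum(cnt * log(p))
  }
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    for (S in chunks) {
      gs <- g[S, , drop = FALSE]
      num <- pmax(Ndk[d_id[S], , drop = FALSE] - gs + alpha, 1e-12) *
             pmax(Nkw_full[w_id[S], , drop = FALSE] - gs + eta, 1e-12)
      den <- sweep(-gs, 2, Nk + V * eta, "+")
      num <- num / pmax(den, 1e-12)
      gnew <- num / rowSums(num)
      delta <- (gnew - gs) * cnt[S]
      Ndk <- Ndk + rowsum_into(delta, d_id[S], D)
      Nkw_full <- Nkw_full + rowsum_into(delta, w_id[S], V)
      Nk <- Nk + colSums(delta)
      g[S, ] <- gnew
    }
    ll <- loglik()
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < config$tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  theta <- unname((Ndk + alpha) / rowSums(Ndk + alpha))
  beta <- unname(t(sweep(Nkw_full + eta, 2, Nk + V * eta, "/")))  # K x V
  ll <- ll_trace[length(ll_trace)]
  structure(list(theta = theta, beta = beta, log_likelihood = ll,
                 bic = ll - bic_penalty(K, V, D, W), seed = seed,
                 converged = converged, n_iter = iter, ll_trace = ll_trace,
                 K = K, alpha = alpha, eta = eta),
            class = "topic_fit")
}

# rowsum onto a fixed number of rows, zero-filled
rowsum_into <- function(x, group, n) {
  agg <- rowsum(x, group)
  out <- matrix(0, n, ncol(x))
  out[as.integer(rownames(agg)), ] <- agg
  out
}

#' Select the number of latent factors by BIC
#'
#' For each K in `K_range`, runs `n_seeds` restarts of [cvb0_fit()] and
#' keeps the restart with the highest log-likelihood as that K's
#' representative; `BIC(K) = log_likelihood - (1/2) (K (V - 1) +
#' D (K - 1)) ln W` with W the total token count. The optimal K maximizes
#' BIC (ties go to the smaller K).
#'
#' @param documents an `lda_documents`.
#' @param K_range integer vector of candidate factor counts.
#' @param config a [topic_config()]; its `K` field is overridden per
#'   candidate.
#' @param seed master seed; restart i of any K uses `seed + i`.
#' @return List with `best_K`, `fits` (named list of representative
#'   `topic_fit` per K), and `bic` (data frame K, log_likelihood, bic).
#' @export
model_selection <- function(documents, K_range, config, seed = 1) {
  stopifnot(length(K_range) >= 1)
  K_range <- as.integer(sort(K_range))
  fits <- list()
  rows <- list()
  for (K in K_range) {
    cfg <- config
    cfg$K <- K
    best <- NULL
    for (i in seq_len(config$n_seeds)) {
      fit <- cvb0_fit(documents, cfg, seed = seed + i)
      if (is.null(best) || fit$log_likelihood > best$log_likelihood)
        best <- fit
      if (K == 1L) break  # closed form; restarts are identical
    }
    fits[[as.character(K)]] <- best
    rows[[as.character(K)]] <- data.frame(K = K,
                                          log_likelihood = best$log_likelihood,
                                          bic = best$bic)
  }
  bic <- do.call(rbind, rows)
  best_K <- bic$K[which.max(bic$bic)]  # which.max takes the first maximum
  list(best_K = best_K, fits = fits, bic = bic)
}

#' Write one factor's voxel distribution as a volume lattice
#'
#' Places `Pr(Voxel|Factor = k)` at each vocabulary voxel (0 elsewhere);
#' the in-mask values sum to 1.
#'
#' @param fit a `topic_fit`.
#' @param k factor index in 1..K.
#' @param vocab the `lda_vocabulary` the fit was built on.
#' @return Numeric array on the vocabulary grid.
#' @export
factor_to_volume <- function(fit, k, vocab) {
  stopifnot(inherits(fit, "topic_fit"), inherits(vocab, "lda_vocabulary"))
  if (k < 1 || k > nrow(fit$beta)) stop_cbma("factor index %d out of range", k)
  out <- array(0, dim = vocab$grid$shape)
  out[vocab$voxel_ids] <- fit$beta[k, ]
  out
}
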