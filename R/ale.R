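#' Gaussian kernel specification for modeled-activation maps
#'
#' The spatial uncertainty of a reported peak is modeled as an isotropic
#' Gaussian whose width combines a fixed between-template term with a
#' between-subject term that shrinks with the square root of the sample
#' size, so larger studies get tighter kernels. Defaults derive from the
#' commonly used between-template (5.7 mm) and between-subject (11.6 mm)
#' Euclidean displacement estimates, converted to a per-axis standard
#' deviation by dividing by 2*sqrt(2/pi).
#'
#' @param sigma_template_mm between-template standard deviation (mm).
#' @param sigma_subject_mm between-subject standard deviation (mm), scaled
#'   by 1/sqrt(n) per experiment.
#' @param truncation_radius_sd kernels are truncated beyond this many
#'   standard deviations (default 5).
#' @param combine rule for combining a study's focus kernels at a voxel:
#'   `"max"` (the revised non-additive algorithm, default) or `"union"`
#'   (probabilistic union).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(sigma_template_mm = 5.7 / (2 * sqrt(2 / pi)),
                        sigma_subject_mm = 11.6 / (2 * sqrt(2 / pi)),
                        truncation_radius_sd = 5,
                        combine = c("max", "union")) {
  stopifnot(sigma_template_mm > 0, sigma_subject_mm > 0,
            truncation_radius_sd > 0)
  structure(list(sigma_template_mm = sigma_template_mm,
                 sigma_subject_mm = sigma_subject_mm,
                 truncation_radius_sd = truncation_radius_sd,
                 combine = match.arg(combine)),
            class = "kernel_spec")
}

#' Kernel width for a given sample size
#'
#' `sqrt(sigma_template^2 + sigma_subject^2 / n)`: strictly decreasing in
#' `n`, approaching the template term as `n` grows.
#'
#' @param n_subjects positive integer.
#' @param spec a [kernel_spec()].
#' @return Kernel standard deviation in mm.
#' @export
kernel_sigma <- function(n_subjects, spec = kernel_spec()) {
  if (!is.numeric(n_subjects) || any(n_subjects < 1))
    stop_cbma("n_subjects must be >= 1")
  sqrt(spec$sigma_template_mm^2 + spec$sigma_subject_mm^2 / n_subjects)
}

# Precompute the truncated kernel stencil for one sigma on a grid:
# 0-based ijk offsets and the per-voxel probability mass at each offset.
kernel_stencil <- function(grid, sigma, trunc_sd) {
  sp <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  rad <- trunc_sd * sigma
  r <- pmax(0L, as.integer(floor(rad / sp)))
  off <- as.matrix(expand.grid(di = -r[1]:r[1], dj = -r[2]:r[2],
                               dk = -r[3]:r[3]))
  d2 <- (off[, 1] * sp[1])^2 + (off[, 2] * sp[2])^2 + (off[, 3] * sp[3])^2
  keep <- d2 <= rad^2
  off <- off[keep, , drop = FALSE]
  d2 <- d2[keep]
  val <- (2 * pi * sigma^2)^(-1.5) * exp(-d2 / (2 * sigma^2)) *
    grid$voxel_volume_mm3
  val <- pmin(val, 1 - 1e-12)  # probability-mass cap for degenerate spacing
  list(offsets = off, values = val)
}

# Sparse modeled-activation map for one experiment: foci are snapped to
# the nearest voxel centre, each contributes the stencil, and contributions
# at a voxel are combined by max (default) or probabilistic union.
# Returns list(idx = 1-based linear in-mask indices, val = MA values).
ma_sparse <- function(foci_lin, grid, stencil, combine = "max") {
  ctr <- linear_to_ijk(grid, foci_lin)
  n_off <- nrow(stencil$offsets)
  idx_all <- integer(0); val_all <- numeric(0)
  for (f in seq_along(foci_lin)) {
    ijk <- cbind(ctr[f, 1] + stencil$offsets[, 1],
                 ctr[f, 2] + stencil$offsets[, 2],
                 ctr[f, 3] + stencil$offsets[, 3])
    lin <- ijk_to_linear(grid, ijk)
    ok <- !is.na(lin)
    lin <- lin[ok]
    inm <- grid$mask[lin]
    idx_all <- c(idx_all, lin[inm])
    val_all <- c(val_all, stencil$values[ok][inm])
  }
  if (!length(idx_all)) return(list(idx = integer(0), val = numeric(0)))
  if (combine == "max") {
    o <- order(idx_all, val_all)
    i2 <- idx_all[o]; v2 <- val_all[o]
    last <- c(i2[-1] != i2[-length(i2)], TRUE)
    list(idx = i2[last], val = v2[last])
  } else {
    s <- rowsum(log1p(-val_all), idx_all)
    list(idx = as.integer(rownames(s)), val = -expm1(s[, 1]))
  }
}

#' Modeled-activation map for one experiment
#'
#' Each focus (snapped to its nearest voxel) contributes an isotropic
#' Gaussian kernel of width [kernel_sigma()] expressed as per-voxel
#' probability mass (trivariate normal density times voxel volume), so the
#' kernel maximum equals the mass of one voxel at distance zero. A study's
#' focus kernels are combined voxel-wise by the maximum (default) or by
#' probabilistic union, truncated at the spec's radius, and zeroed outside
#' the mask.
#'
#' @param exp_ a `cbma_experiment` in MNI space with at least one focus.
#' @param grid a [brain_grid()].
#' @param spec a [kernel_spec()].
#' @return A numeric array of the grid shape with values in \[0, 1\].
#' @export
compute_ma_map <- function(exp_, grid, spec = kernel_spec()) {
  stopifnot(inherits(exp_, "cbma_experiment"))
  if (!nrow(exp_$foci)) stop_cbma("experiment '%s' has no foci", exp_$study_id)
  sigma <- kernel_sigma(exp_$n_subjects, spec)
  st <- kernel_stencil(grid, sigma, spec$truncation_radius_sd)
  lin <- ijk_to_linear(grid, mm_to_voxel(grid, exp_$foci))
  if (any(is.na(lin)))
    stop_cbma("focus outside the grid lattice in study '%s'", exp_$study_id)
  sp <- ma_sparse(lin, grid, st, spec$combine)
  out <- array(0, dim = grid$shape)
  out[sp$idx] <- sp$val
  out
}

#' Stack of modeled-activation maps for a corpus
#'
#' Maps are held sparsely (in-mask support indices and values per
#' experiment), aligned to one grid.
#'
#' @param corp a corpus in MNI space.
#' @inheritParams compute_ma_map
#' @return An object of class `ma_stack`.
#' @export
ma_stack <- function(corp, grid, spec = kernel_spec()) {
  stopifnot(inherits(corp, "cbma_corpus"))
  if (!length(corp$experiments)) stop_cbma("empty corpus")
  maps <- lapply(corp$experiments, function(e) {
    sigma <- kernel_sigma(e$n_subjects, spec)
    st <- kernel_stencil(grid, sigma, spec$truncation_radius_sd)
    lin <- ijk_to_linear(grid, mm_to_voxel(grid, e$foci))
    if (any(is.na(lin)))
      stop_cbma("focus outside the grid lattice in study '%s'", e$study_id)
    ma_sparse(lin, grid, st, spec$combine)
  })
  structure(list(grid = grid, maps = maps,
                 study_ids = vapply(corp$experiments, `[[`, "", "study_id")),
            class = "ma_stack")
}

#' Union ALE score map from a stack of MA maps
#'
#' `ALE(v) = 1 - prod_e (1 - MA_e(v))`: the probability that at least one
#' experiment's modeled activation covers voxel v, the convergence score.
#'
#' @param stack an [ma_stack()].
#' @return A numeric array of the grid shape.
#' @export
compute_ale_map <- function(stack) {
  stopifnot(inherits(stack, "ma_stack"))
  if (!length(stack$maps)) stop_cbma("empty MA stack")
  nvox <- prod(stack$grid$shape)
  acc <- rep(1, nvox)
  for (m in stack$maps) acc[m$idx] <- acc[m$idx] * (1 - m$val)
  array(1 - acc, dim = stack$grid$shape)
}

#' Analytic null distribution of the ALE score
#'
#' The random-spatial-association null: draw one in-mask voxel uniformly
#' from each experiment's MA map and take the union of the drawn values.
#' Its exact distribution is obtained by histogram convolution: each MA
#' map's values are binned on a lattice in the log-complement domain
#' (L = -log(1 - MA), where the union becomes a plain sum), the
#' per-experiment histograms are convolved iteratively, and the result is
#' reported as a survival function on the ALE-score axis. The lattice step
#' equals `bin_width` (at ALE scores of realistic magnitude,
#' dALE and dL agree to second order).
#'
#' @param stack an [ma_stack()].
#' @param bin_width lattice step on the ALE-score axis (default 1e-5).
#' @return An object of class `ale_null` with `bin_width`, `survival`
#'   (vector indexed by bin, `survival[1] = P(ALE >= 0) = 1`), and `p_min`,
#'   the smallest strictly positive attainable p.
#' @export
compute_analytic_null <- function(stack, bin_width = 1e-5) {
  stopifnot(inherits(stack, "ma_stack"))
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop_cbma("bin_width must be > 0")
  n_mask <- sum(stack$grid$mask)
  pmfs <- lapply(stack$maps, function(m) {
    bins <- as.integer(round_half_up(-log1p(-m$val) / bin_width))
    nb <- max(bins, 0L)
    pmf <- numeric(nb + 1L)
    pos <- bins > 0L
    if (any(pos)) {
      tb <- tabulate(bins[pos], nbins = nb)
      pmf[-1L] <- tb
    }
    pmf[1L] <- n_mask - sum(pos)
    pmf / n_mask
  })
  p <- pmfs[[1]]
  for (q in pmfs[-1]) p <- convolve_pmf(p, q)
  p[p < 0] <- 0
  p <- p / sum(p)
  surv <- rev(cumsum(rev(p)))
  surv[1] <- 1
  structure(list(bin_width = bin_width, survival = surv,
                 p_min = min(surv[surv > 0])),
            class = "ale_null")
}

# open (polynomial) convolution of two pmf vectors, FFT with padding to a
# highly composite length so awkward sizes stay fast
convolve_pmf <- function(p, q) {
  if (length(p) == 1L) return(p[1] * q)
  if (length(q) == 1L) return(q[1] * p)
  n <- length(p) + length(q) - 1L
  N <- stats::nextn(n, c(2L, 3L, 5L))
  P <- stats::fft(c(p, numeric(N - length(p))))
  Q <- stats::fft(c(q, numeric(N - length(q))))
  out <- Re(stats::fft(P * Q, inverse = TRUE))[seq_len(n)] / N
  out[out < 0] <- 0
  out
}

# bin index (1-based into survival vector) for ALE scores
ale_score_bin <- function(null, scores) {
  L <- -log1p(-pmin(pmax(scores, 0), 1 - 1e-15))
  as.integer(round_half_up(L / null$bin_width)) + 1L
}

#' Null survival probability at given ALE scores
#'
#' `P(ALE >= score)` under the random-association null.
#'
#' @param null an `ale_null`.
#' @param scores numeric vector of ALE scores.
#' @return Numeric vector of tail probabilities.
#' @export
null_survival <- function(null, scores) {
  b <- ale_score_bin(null, scores)
  out <- numeric(length(b))
  inside <- b <= length(null$survival)
  out[inside] <- null$survival[b[inside]]
  out
}

# smallest ALE score (bin lower bound) whose null survival is < p_voxel;
# NA when no bin reaches it
null_ale_cutoff <- function(null, p_voxel) {
  b <- which(null$survival < p_voxel)
  if (!length(b)) return(NA_real_)
  # score at which rounding first maps into bin b[1]
  -expm1(-(b[1] - 1 - 0.5) * null$bin_width)
}

#' Voxel-wise thresholding of an ALE map against its analytic null
#'
#' Converts ALE scores to one-sided p-values via the null survival
#' function, to z-scores via the standard-normal quantile (p floored at the
#' null's resolution limit so z stays finite), and flags the voxels passing
#' the cluster-forming threshold.
#'
#' @param ale ALE score array.
#' @param null an `ale_null` from [compute_analytic_null()].
#' @param p_voxel cluster-forming voxel-level threshold (default 0.001).
#' @param grid optional [brain_grid()]; when given, out-of-mask voxels get
#'   p = 1, z = 0, and are never suprathreshold.
#' @return List with arrays `p`, `z`, and logical `supra`.
#' @export
voxelwise_threshold <- function(ale, null, p_voxel = 0.001, grid = NULL) {
  stopifnot(p_voxel > 0, p_voxel < 1)
  p <- null_survival(null, ale)
  supra <- p < p_voxel
  pz <- pmax(p, null$p_min)
  z <- stats::qnorm(pz, lower.tail = FALSE)
  z[z < 0] <- 0
  if (!is.null(grid)) {
    p[!grid$mask] <- 1
    z[!grid$mask] <- 0
    supra[!grid$mask] <- FALSE
  }
  dim(p) <- dim(ale); dim(z) <- dim(ale); dim(supra) <- dim(ale)
  list(p = p, z = z, supra = supra)
}
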