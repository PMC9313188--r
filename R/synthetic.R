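#' Specification for a synthetic foci corpus with planted convergence
#'
#' Emulates the structure of an intentional-forgetting meta-analytic
#' corpus: a modest number of studies (10-35), sample sizes in the 11-32
#' range of the included-study table, a handful of foci per experiment,
#' convergent foci drawn as planted ground-truth centers plus isotropic
#' Gaussian displacement, and uniformly scattered non-convergent noise
#' foci.
#'
#' @param n_studies number of experiments to generate.
#' @param n_subjects_sampler function(k) returning k sample sizes; the
#'   default resamples the n column of the bundled included-study table
#'   (range 11-32, mean 466/23).
#' @param centers numeric matrix (m x 3) of planted cluster centers (MNI
#'   mm), or NULL for none.
#' @param center_participation probability that a study emits a focus for
#'   each center.
#' @param participation_exact if `TRUE`, each center is emitted by exactly
#'   `ceiling(center_participation * n_studies)` randomly chosen studies,
#'   guaranteeing the nominal participation fraction is realized; if
#'   `FALSE` (default) emission is an independent Bernoulli draw per study
#'   and center.
#' @param jitter_sd_mm standard deviation of the isotropic Gaussian
#'   displacement applied to emitted center foci.
#' @param n_noise_foci uniformly scattered foci per study.
#' @param seed integer seed making generation deterministic.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_studies = 23,
                           n_subjects_sampler = included_n_sampler(),
                           centers = NULL,
                           center_participation = 0.6,
                           jitter_sd_mm = 8,
                           n_noise_foci = 5,
                           participation_exact = FALSE,
                           seed = 1) {
  stopifnot(n_studies >= 1,
            center_participation >= 0, center_participation <= 1,
            jitter_sd_mm >= 0, n_noise_foci >= 0)
  if (!is.null(centers)) centers <- matrix(centers, ncol = 3)
  structure(list(n_studies = as.integer(n_studies),
                 n_subjects_sampler = n_subjects_sampler,
                 centers = centers,
                 center_participation = center_participation,
                 jitter_sd_mm = jitter_sd_mm,
                 n_noise_foci = as.integer(n_noise_foci),
                 participation_exact = isTRUE(participation_exact),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Sample-size sampler drawn from the included-study table
#'
#' Returns a function that resamples (with replacement) the published n
#' column of the bundled 23-study table, so synthetic corpora match the
#' real corpus's sample-size distribution (total 466 over 23 studies).
#'
#' @return function(k) returning k integers.
#' @export
included_n_sampler <- function() {
  ns <- vapply(included_studies()$experiments, `[[`, 0L, "n_subjects")
  function(k) sample(ns, k, replace = TRUE)
}

#' Generate a synthetic corpus with known ground truth
#'
#' Per study: each planted center is emitted with probability
#' `center_participation` as `center + N(0, jitter_sd^2 I)` (redrawn until
#' in-mask, at most 100 attempts); then `n_noise_foci` foci are placed at
#' uniformly drawn in-mask voxel centers. Deterministic given the spec
#' seed.
#'
#' @param spec a [synthetic_spec()].
#' @param grid a [brain_grid()]; planted centers must be in-mask.
#' @return List with `corpus` and `ground_truth` (data frame with one row
#'   per focus: study_id, x, y, z, origin = planted center index or 0 for
#'   noise).
#' @export
generate_corpus <- function(spec, grid) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(grid, "brain_grid"))
  mask_lin <- which(grid$mask)
  in_mask_mm <- function(xyz) {
    lin <- ijk_to_linear(grid, mm_to_voxel(grid, xyz))
    !is.na(lin) & grid$mask[ifelse(is.na(lin), 1L, lin)]
  }
  if (!is.null(spec$centers) && !all(in_mask_mm(spec$centers)))
    stop_cbma("planted center outside the grid mask")
  set.seed(spec$seed)
  ns <- spec$n_subjects_sampler(spec$n_studies)
  emits <- NULL
  if (!is.null(spec$centers)) {
    n_c <- nrow(spec$centers)
    if (spec$participation_exact) {
      m <- min(spec$n_studies,
               as.integer(ceiling(spec$center_participation * spec$n_studies)))
      emits <- vapply(seq_len(n_c), function(ci) {
        e <- logical(spec$n_studies)
        e[sample.int(spec$n_studies, m)] <- TRUE
        e
      }, logical(spec$n_studies))
    } else {
      emits <- matrix(stats::runif(spec$n_studies * n_c) <=
                        spec$center_participation, spec$n_studies, n_c)
    }
  }
  exps <- vector("list", spec$n_studies)
  gt <- list()
  for (s in seq_len(spec$n_studies)) {
    id <- sprintf("synth_%02d", s)
    foci <- NULL; origin <- integer(0)
    if (!is.null(spec$centers)) {
      for (ci in seq_len(nrow(spec$centers))) {
        if (!emits[s, ci]) next
        for (attempt in seq_len(100)) {
          f <- spec$centers[ci, ] + stats::rnorm(3, 0, spec$jitter_sd_mm)
          if (in_mask_mm(rbind(f))) break
          if (attempt == 100)
            stop_cbma("could not place an in-mask jittered focus for center %d",
                      ci)
        }
        foci <- rbind(foci, f)
        origin <- c(origin, ci)
      }
    }
    if (spec$n_noise_foci > 0) {
      lin <- mask_lin[sample.int(length(mask_lin), spec$n_noise_foci,
                                 replace = TRUE)]
      noise <- voxel_to_mm(grid, linear_to_ijk(grid, lin))
      foci <- rbind(foci, noise)
      origin <- c(origin, rep(0L, spec$n_noise_foci))
    }
    if (is.null(foci))
      stop_cbma("study %s generated no foci; raise participation or noise", id)
    exps[[s]] <- experiment(id, ns[s], foci, space = "MNI")
    gt[[s]] <- data.frame(study_id = id, x = foci[, 1], y = foci[, 2],
                          z = foci[, 3], origin = origin)
  }
  list(corpus = corpus(exps, provenance = "synthetic planted-cluster corpus"),
       ground_truth = do.call(rbind, gt))
}

#' Generate a null corpus: independent uniform foci
#'
#' Embodies the random-spatial-association hypothesis as a generative
#' model: every focus is drawn i.i.d. uniformly over in-mask voxel
#' centers.
#'
#' @param n_studies number of experiments.
#' @param foci_per_study foci per experiment (scalar or vector).
#' @param grid a [brain_grid()].
#' @param seed integer seed.
#' @param n_subjects_sampler as in [synthetic_spec()].
#' @return A [corpus()].
#' @export
generate_null_corpus <- function(n_studies, foci_per_study, grid, seed = 1,
                                 n_subjects_sampler = included_n_sampler()) {
  stopifnot(n_studies >= 1, all(foci_per_study >= 1))
  foci_per_study <- rep_len(as.integer(foci_per_study), n_studies)
  set.seed(seed)
  mask_lin <- which(grid$mask)
  ns <- n_subjects_sampler(n_studies)
  exps <- lapply(seq_len(n_studies), function(s) {
    lin <- mask_lin[sample.int(length(mask_lin), foci_per_study[s],
                               replace = TRUE)]
    experiment(sprintf("null_%02d", s), ns[s],
               voxel_to_mm(grid, linear_to_ijk(grid, lin)), space = "MNI")
  })
  corpus(exps, provenance = "synthetic null corpus (uniform foci)")
}
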