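# Connected components (26-neighbourhood) over a set of suprathreshold
# voxels given as 1-based linear indices into a grid lattice.
# Returns a list of integer vectors (component members, linear indices).
label_components_26 <- function(lin, grid) {
  if (!length(lin)) return(list())
  d <- grid$shape
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  inset <- logical(prod(d))
  inset[lin] <- TRUE
  seen <- logical(prod(d))
  comps <- list()
  for (s in lin) {
    if (seen[s]) next
    members <- integer(0)
    frontier <- s
    seen[s] <- TRUE
    while (length(frontier)) {
      members <- c(members, frontier)
      ijk <- linear_to_ijk(grid, frontier)
      nxt <- integer(0)
      for (o in seq_len(nrow(off))) {
        nb <- cbind(ijk[, 1] + off[o, 1], ijk[, 2] + off[o, 2],
                    ijk[, 3] + off[o, 3])
        nl <- ijk_to_linear(grid, nb)
        nl <- nl[!is.na(nl)]
        nl <- nl[inset[nl] & !seen[nl]]
        if (length(nl)) { seen[nl] <- TRUE; nxt <- c(nxt, nl) }
      }
      frontier <- unique(nxt)
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

# One permutation draw: relocate every focus of every experiment to an
# independent uniform in-mask voxel, rebuild MA/ALE, and return the size of
# the largest suprathreshold 26-connected component.
perm_max_cluster_size <- function(foci_counts, stencils, grid, spec,
                                  mask_lin, cutoff_ale) {
  nvox <- prod(grid$shape)
  acc <- rep(1, nvox)
  for (e in seq_along(foci_counts)) {
    ctr <- mask_lin[sample.int(length(mask_lin), foci_counts[e],
                               replace = TRUE)]
    m <- ma_sparse(ctr, grid, stencils[[e]], spec$combine)
    acc[m$idx] <- acc[m$idx] * (1 - m$val)
  }
  supra_lin <- which(1 - acc >= cutoff_ale)
  if (!length(supra_lin)) return(0L)
  comps <- label_components_26(supra_lin, grid)
  max(vapply(comps, length, 0L))
}

#' Cluster-level inference with permutation family-wise error control
#'
#' Suprathreshold voxels are grouped into 26-connected components. The
#' null distribution of the maximum cluster size is built by relocating
#' every focus of every experiment to an independent uniform in-mask voxel,
#' recomputing the MA/ALE maps, thresholding at the same analytic-null
#' cutoff, and recording the largest component, `n_permutations` times.
#' A cluster's FWE p is the add-one permutation estimate
#' `(b + 1) / (n_permutations + 1)` with `b` the number of permutation
#' maxima at least as large as the cluster.
#'
#' @param thr result of [voxelwise_threshold()] (needs `supra` and `z`).
#' @param ale observed ALE array.
#' @param corp corpus (MNI space) the observed maps came from.
#' @param grid a [brain_grid()].
#' @param spec a [kernel_spec()].
#' @param null the observed stack's `ale_null`.
#' @param p_voxel cluster-forming threshold used for `thr`.
#' @param cluster_alpha cluster-level FWE threshold; only clusters with
#'   `fwe_p < cluster_alpha` are reported (default 0.05).
#' @param n_permutations number of relocation permutations (default 1000).
#' @param seed master seed; permutation r uses `seed + r`.
#' @return An object of class `ale_clusters`: list with `clusters` (each
#'   with linear `voxel_indices`, `size_voxels`, `volume_mm3`,
#'   `weighted_center_mm`, `peak_mm`, `peak_z`, `fwe_p`, `hemisphere`),
#'   `perm_max_sizes`, and `component_sizes` of all observed components.
#' @export
cluster_inference <- function(thr, ale, corp, grid, spec, null,
                              p_voxel = 0.001, cluster_alpha = 0.05,
                              n_permutations = 1000, seed = 1) {
  stopifnot(n_permutations >= 1)
  supra_lin <- which(thr$supra)
  comps <- label_components_26(supra_lin, grid)
  cutoff_ale <- null_ale_cutoff(null, p_voxel)
  if (is.na(cutoff_ale)) cutoff_ale <- Inf
  ns <- vapply(corp$experiments, `[[`, 0L, "n_subjects")
  stencils <- lapply(ns, function(n)
    kernel_stencil(grid, kernel_sigma(n, spec), spec$truncation_radius_sd))
  foci_counts <- vapply(corp$experiments, function(e) nrow(e$foci), 0L)
  mask_lin <- which(grid$mask)
  perm_max <- integer(n_permutations)
  for (r in seq_len(n_permutations)) {
    set.seed(seed + r)
    perm_max[r] <- perm_max_cluster_size(foci_counts, stencils, grid, spec,
                                         mask_lin, cutoff_ale)
  }
  clusters <- lapply(comps, function(members) {
    size <- length(members)
    b <- sum(perm_max >= size)
    w <- ale[members]
    mm <- voxel_to_mm(grid, linear_to_ijk(grid, members))
    zc <- thr$z[members]
    peak_i <- which(zc == max(zc))
    peak_i <- peak_i[which.min(members[peak_i])]  # ties: lowest linear index
    peak <- mm[peak_i, ]
    list(voxel_indices = members,
         size_voxels = size,
         volume_mm3 = size * grid$voxel_volume_mm3,
         weighted_center_mm = colSums(mm * w) / sum(w),
         peak_mm = peak,
         peak_z = zc[peak_i],
         fwe_p = (b + 1) / (n_permutations + 1),
         hemisphere = if (peak[1] > 0) "R" else if (peak[1] < 0) "L" else "M")
  })
  keep <- vapply(clusters, function(cl) cl$fwe_p < cluster_alpha, TRUE)
  structure(list(clusters = clusters[keep],
                 perm_max_sizes = perm_max,
                 component_sizes = vapply(comps, length, 0L)),
            class = "ale_clusters")
}

#' Cluster report table
#'
#' One row per significant cluster, sorted by descending size: peak MNI
#' coordinates (rounded to integer mm), voxel count, hemisphere (L/R/M by
#' the sign of the peak x coordinate), peak z, and the FWE-corrected
#' cluster p. The anatomical-structure column is emitted empty (labeling
#' against a named atlas is out of scope).
#'
#' @param cl an `ale_clusters` object or a bare list of clusters.
#' @return A data frame.
#' @export
make_cluster_table <- function(cl) {
  clusters <- if (inherits(cl, "ale_clusters")) cl$clusters else cl
  if (!length(clusters)) {
    return(data.frame(cluster = integer(0), x = integer(0), y = integer(0),
                      z = integer(0), n_voxels = integer(0),
                      hemisphere = character(0), peak_z = numeric(0),
                      fwe_p = numeric(0),
                      anatomical_structure = character(0)))
  }
  o <- order(-vapply(clusters, `[[`, 0, "size_voxels"))
  clusters <- clusters[o]
  data.frame(
    cluster = seq_along(clusters),
    x = vapply(clusters, function(c) as.integer(round_half_up(c$peak_mm[1])), 0L),
    y = vapply(clusters, function(c) as.integer(round_half_up(c$peak_mm[2])), 0L),
    z = vapply(clusters, function(c) as.integer(round_half_up(c$peak_mm[3])), 0L),
    n_voxels = as.integer(vapply(clusters, `[[`, 0, "size_voxels")),
    hemisphere = vapply(clusters, `[[`, "", "hemisphere"),
    peak_z = vapply(clusters, `[[`, 0, "peak_z"),
    fwe_p = vapply(clusters, `[[`, 0, "fwe_p"),
    anatomical_structure = "")
}

#' Run the full ALE analysis on a corpus
#'
#' Convenience wrapper chaining [ma_stack()], [compute_ale_map()],
#' [compute_analytic_null()], [voxelwise_threshold()], and
#' [cluster_inference()].
#'
#' @inheritParams cluster_inference
#' @param corp corpus in MNI space.
#' @param bin_width ALE-axis lattice step for the analytic null.
#' @return An object of class `ale_result`: `ale_map`, `z_map`, `p_map`,
#'   `null`, `clusters` (an `ale_clusters`), `cluster_table`, and a
#'   `config` echo.
#' @export
ale_analysis <- function(corp, grid, spec = kernel_spec(),
                         p_voxel = 0.001, cluster_alpha = 0.05,
                         n_permutations = 1000, bin_width = 1e-5,
                         seed = 1) {
  stack <- ma_stack(corp, grid, spec)
  ale <- compute_ale_map(stack)
  null <- compute_analytic_null(stack, bin_width)
  thr <- voxelwise_threshold(ale, null, p_voxel, grid)
  cl <- cluster_inference(thr, ale, corp, grid, spec, null, p_voxel,
                          cluster_alpha, n_permutations, seed)
  structure(list(ale_map = ale, z_map = thr$z, p_map = thr$p,
                 supra = thr$supra, null = null, clusters = cl,
                 cluster_table = make_cluster_table(cl),
                 config = list(p_voxel = p_voxel,
                               cluster_alpha = cluster_alpha,
                               n_permutations = n_permutations,
                               bin_width = bin_width, seed = seed,
                               kernel = unclass(spec))),
            class = "ale_result")
}

#' @export
print.ale_result <- function(x, ...) {
  cat(sprintf("ale_result: %d significant clusters (p_voxel = %g, alpha = %g, %d permutations)\n",
              nrow(x$cluster_table), x$config$p_voxel,
              x$config$cluster_alpha, x$config$n_permutations))
  if (nrow(x$cluster_table)) print(x$cluster_table)
  invisible(x)
}
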