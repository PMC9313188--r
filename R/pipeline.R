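#' Assemble and validate a pipeline run configuration
#'
#' Configuration may come from a YAML file or a named list; explicit
#' `overrides` (e.g. command-line flags) win over file values, which win
#' over defaults. Keys: `input` (list: `path`, `dialect`), `grid` (list:
#' `mask` NIfTI path, or synthetic `shape`/`spacing_mm`/`center_mm`/
#' `radii_mm`), `ale` (`p_voxel`, `cluster_alpha`, `n_permutations`,
#' `bin_width`, `sigma_template_mm`, `sigma_subject_mm`,
#' `truncation_radius_sd`, `combine`), `lda` (`K_range`, `alpha`, `eta`,
#' `n_seeds`, `radius_mm`, `spacing_mm`, `tol`, `max_iter`), `seed`,
#' `out_dir`, `verbosity`.
#'
#' @param config path to a YAML file, or a named list (possibly partial).
#' @param overrides named list merged on top.
#' @return A validated `run_config` list.
#' @export
run_config <- function(config = list(), overrides = list()) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop_cbma("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  merge2 <- function(base, extra) {
    for (nm in names(extra)) {
      base[[nm]] <- if (is.list(extra[[nm]]) && is.list(base[[nm]]))
        merge2(base[[nm]], extra[[nm]]) else extra[[nm]]
    }
    base
  }
  cfg <- merge2(default_run_config(), config)
  cfg <- merge2(cfg, overrides)
  if (!is.null(cfg$input$path) && !file.exists(cfg$input$path))
    stop_cbma("input corpus file not found: %s", cfg$input$path)
  if (!is.null(cfg$grid$mask) && !file.exists(cfg$grid$mask))
    stop_cbma("grid mask file not found: %s", cfg$grid$mask)
  stopifnot(cfg$ale$p_voxel > 0, cfg$ale$p_voxel < 1,
            cfg$ale$cluster_alpha > 0, cfg$ale$cluster_alpha < 1,
            cfg$ale$n_permutations >= 1)
  class(cfg) <- "run_config"
  cfg
}

default_run_config <- function() {
  list(
    input = list(path = NULL, dialect = "sleuth"),
    grid = list(mask = NULL, shape = c(91L, 109L, 91L), spacing_mm = 2,
                center_mm = c(0, -17, 8), radii_mm = c(72, 86, 78)),
    ale = list(p_voxel = 0.001, cluster_alpha = 0.05, n_permutations = 1000,
               bin_width = 1e-5, sigma_template_mm = 5.7 / (2 * sqrt(2 / pi)),
               sigma_subject_mm = 11.6 / (2 * sqrt(2 / pi)),
               truncation_radius_sd = 5, combine = "max"),
    lda = list(K_range = 1:4, alpha = 100, eta = 0.01, n_seeds = 100,
               radius_mm = 10, spacing_mm = 4, tol = 1e-6, max_iter = 200),
    seed = 1L,
    out_dir = "cbma_out",
    verbosity = 1L)
}

pipeline_grid <- function(cfg) {
  if (!is.null(cfg$grid$mask)) load_or_make_grid(cfg$grid$mask)
  else load_or_make_grid(NULL, shape = cfg$grid$shape,
                         spacing_mm = cfg$grid$spacing_mm,
                         center_mm = cfg$grid$center_mm,
                         radii_mm = cfg$grid$radii_mm)
}

#' Run the analysis pipeline: ingestion, ALE, LDA, reports
#'
#' Reads the corpus, normalizes it to MNI, and runs the requested stages,
#' writing NIfTI maps, CSV tables, a `run.log`, and a `manifest.json`
#' listing every output file with its MD5 checksum plus the full config
#' echo, so a run can be reproduced bit-identically from its manifest.
#'
#' @param config a [run_config()] (or anything accepted by it).
#' @param stages subset of `c("ale", "lda")`.
#' @param corp optional pre-built corpus (overrides `config$input`).
#' @return The manifest, invisibly: list with `files` (data frame of path,
#'   md5), `config`, `timings_sec`, and stage results (`ale`, `lda`).
#' @export
run_pipeline <- function(config, stages = c("ale", "lda"), corp = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$out_dir, "run.log")
  log_line <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(fmt, ...))
    if (cfg$verbosity > 0) message(msg)
    cat(msg, "\n", file = logf, append = TRUE)
  }
  log_line("cbma %s; seed = %d; stages: %s",
           as.character(utils::packageVersion("cbma")), cfg$seed,
           paste(stages, collapse = ", "))
  files <- character(0)
  timings <- list()
  result <- list()

  if (is.null(corp)) {
    if (is.null(cfg$input$path)) stop_cbma("no input corpus configured")
    corp <- read_corpus_table(cfg$input$path, cfg$input$dialect)
  }
  corp <- convert_tal_to_mni(corp)
  s <- summarize_corpus(corp)
  log_line("corpus: %d studies, %d subjects, %d foci",
           s$n_studies, s$n_subjects_total, s$n_foci_total)
  grid <- pipeline_grid(cfg)
  spec <- kernel_spec(cfg$ale$sigma_template_mm, cfg$ale$sigma_subject_mm,
                      cfg$ale$truncation_radius_sd, cfg$ale$combine)
  emit <- function(path) files <<- c(files, path)

  if ("ale" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    res <- ale_analysis(corp, grid, spec,
                        p_voxel = cfg$ale$p_voxel,
                        cluster_alpha = cfg$ale$cluster_alpha,
                        n_permutations = cfg$ale$n_permutations,
                        bin_width = cfg$ale$bin_width,
                        seed = cfg$seed)
    emit(write_volume(res$ale_map, grid, file.path(cfg$out_dir, "ale.nii.gz")))
    emit(write_volume(res$z_map, grid, file.path(cfg$out_dir, "z.nii.gz")))
    zt <- res$z_map
    zt[!res$supra] <- 0
    emit(write_volume(zt, grid,
                      file.path(cfg$out_dir, "thresholded_z.nii.gz")))
    cpath <- file.path(cfg$out_dir, "clusters.csv")
    utils::write.csv(res$cluster_table, cpath, row.names = FALSE)
    emit(cpath)
    timings$ale <- proc.time()[["elapsed"]] - t0
    log_line("ale: %d significant clusters in %.1f s",
             nrow(res$cluster_table), timings$ale)
    result$ale <- res
  }

  if ("lda" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    bd <- build_documents(corp, grid, radius_mm = cfg$lda$radius_mm,
                          spacing_mm = cfg$lda$spacing_mm)
    tc <- topic_config(K = 1, alpha = cfg$lda$alpha, eta = cfg$lda$eta,
                       n_seeds = cfg$lda$n_seeds, max_iter = cfg$lda$max_iter,
                       tol = cfg$lda$tol)
    sel <- model_selection(bd$documents, cfg$lda$K_range, tc, seed = cfg$seed)
    best <- sel$fits[[as.character(sel$best_K)]]
    for (k in seq_len(best$K)) {
      emit(write_volume(factor_to_volume(best, k, bd$vocabulary),
                        bd$vocabulary$grid,
                        file.path(cfg$out_dir, sprintf("factor_%d.nii.gz", k))))
    }
    tpath <- file.path(cfg$out_dir, "theta.csv")
    theta <- as.data.frame(best$theta)
    names(theta) <- sprintf("factor_%d", seq_len(best$K))
    theta <- cbind(study_id = bd$documents$study_ids, theta)
    utils::write.csv(theta, tpath, row.names = FALSE)
    emit(tpath)
    bpath <- file.path(cfg$out_dir, "bic_by_k.csv")
    utils::write.csv(sel$bic, bpath, row.names = FALSE)
    emit(bpath)
    timings$lda <- proc.time()[["elapsed"]] - t0
    log_line("lda: best K = %d in %.1f s", sel$best_K, timings$lda)
    result$lda <- c(sel, list(vocabulary = bd$vocabulary,
                              documents = bd$documents))
  }

  manifest <- list(
    files = data.frame(path = files, md5 = unname(tools::md5sum(files))),
    config = unclass(cfg),
    timings_sec = timings)
  jsonlite::write_json(manifest[c("files", "config", "timings_sec")],
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("wrote %d files + manifest.json", length(files))
  invisible(c(manifest, result))
}
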