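# Shared fixtures, built in code at test time.

# small all-inclusive grid: identity-ish affine, everything in-mask
tiny_grid <- function(shape = c(8, 8, 8), spacing = 2) {
  load_or_make_grid(NULL, shape = shape, spacing_mm = spacing,
                    center_mm = c(0, 0, 0), radii_mm = c(1e3, 1e3, 1e3))
}

# small brain-like grid with a real proper-subset mask
small_mask_grid <- function(shape = c(18, 20, 18), spacing = 2) {
  load_or_make_grid(NULL, shape = shape, spacing_mm = spacing,
                    center_mm = c(0, 0, 0),
                    radii_mm = spacing * (shape / 2 - 1))
}

two_study_sleuth <- function(path) {
  writeLines(c(
    "// Reference = MNI",
    "// Smith 2019; forget > remember",
    "// Subjects = 14",
    "10 20 30",
    "-12 4 8",
    "0 0 52",
    "",
    "// Jones 2021; suppress > recall",
    "// Subjects = 22",
    "6 -40 22",
    "-30 14 -8",
    "44 2 36",
    ""), path)
  path
}

# corpus built directly in code
make_corpus <- function(foci_list, ns = NULL, spaces = NULL) {
  n <- length(foci_list)
  ns <- ns %||% rep(20L, n)
  spaces <- spaces %||% rep("MNI", n)
  corpus(lapply(seq_len(n), function(i)
    experiment(sprintf("study_%d", i), ns[i], foci_list[[i]],
               space = spaces[i])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# dense MA stack from explicit value vectors over the mask (for null tests)
stack_from_values <- function(grid, value_vectors) {
  mask_lin <- which(grid$mask)
  maps <- lapply(value_vectors, function(v) {
    stopifnot(length(v) == length(mask_lin))
    keep <- v > 0
    list(idx = mask_lin[keep], val = v[keep])
  })
  structure(list(grid = grid, maps = maps,
                 study_ids = sprintf("s%d", seq_along(maps))),
            class = "ma_stack")
}
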