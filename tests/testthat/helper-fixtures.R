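# Shared small fixtures, built in code.

tiny_synth <- function(...) {
  defaults <- list(n_compounds = 40L, n_plates = 1L, n_features = 50L,
                   n_replicates = 4L, baseline_cell_count = 500L, seed = 101L)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

fast_config <- function(...) {
  pipeline_config(replicating = list(n_null = 400L, seed = 11L), ...)
}

# Minimal hand-built profile table: one plate, wells assigned down the rows
# A-P then across columns; position carries no meaning here (the functions
# under test key on role and compound, not column).
toy_profiles <- function(feature_mat, roles, compounds = NULL,
                         replicate = 1L, plate = "plateA") {
  n <- nrow(feature_mat)
  stopifnot(length(roles) == n, n <= 384)
  idx <- seq_len(n) - 1L
  rows <- LETTERS[(idx %% 16L) + 1L]
  cols <- (idx %/% 16L) + 1L
  if (is.null(compounds)) {
    compounds <- ifelse(roles == "negative_control", "DMSO",
                        sprintf("cpd%02d", seq_len(n)))
  }
  if (is.null(colnames(feature_mat))) {
    colnames(feature_mat) <- sprintf("f%02d", seq_len(ncol(feature_mat)))
  }
  dplyr::bind_cols(
    tibble::tibble(
      site = "s", cell_line = "c", plate_id = plate,
      replicate = as.integer(replicate),
      well = well_address(rows, cols),
      compound_id = compounds, role = roles,
      concentration_uM = ifelse(roles == "negative_control", 0, 10),
      cell_count = 100L
    ),
    tibble::as_tibble(feature_mat)
  )
}

toy_cells <- function(feature_mat, well = "A01", plate = "plateA") {
  colnames(feature_mat) <- colnames(feature_mat) %||%
    sprintf("f%02d", seq_len(ncol(feature_mat)))
  dplyr::bind_cols(
    tibble::tibble(plate_id = plate, well = well, field = 1L,
                   object_id = seq_len(nrow(feature_mat))),
    tibble::as_tibble(feature_mat)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Seeded evaluation without disturbing the session RNG state.
with_seed_for_tests <- function(seed, code) {
  withr::with_seed(seed, code)
}
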