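# Tabular domain types and their CSV readers/writers.
#
# All tables are plain tibbles with documented column contracts:
#   ProfileTable    — one row per (plate, replicate, well); metadata columns
#                     PROFILE_METADATA_COLS, all remaining numeric columns are
#                     features.
#   SingleCellTable — one row per segmented cell; metadata columns
#                     CELL_METADATA_COLS, remaining numeric columns features.
#   PlateLayout     — one row per well of a plate, well -> compound/role map.
#   ConsensusTable  — one row per compound (median over replicates).

#' Metadata column names of the tabular domain types
#'
#' `profile_metadata_cols()` lists the reserved metadata columns of a
#' well-level profile table; every other numeric column is treated as an
#' image feature. `cell_metadata_cols()` does the same for single-cell
#' tables.
#'
#' @return Character vector of column names.
#' @export
profile_metadata_cols <- function() {
  c("site", "cell_line", "plate_id", "replicate", "well",
    "compound_id", "role", "concentration_uM", "cell_count")
}

#' @rdname profile_metadata_cols
#' @export
cell_metadata_cols <- function() {
  c("plate_id", "well", "field", "object_id")
}

#' Feature columns of a profile or single-cell table
#'
#' @param table A profile or single-cell tibble.
#' @param metadata Character vector of metadata column names to exclude.
#' @return Character vector of feature column names, in table order.
#' @export
feature_cols <- function(table, metadata = NULL) {
  if (is.null(metadata)) {
    metadata <- if (all(c("well", "object_id") %in% names(table))) {
      cell_metadata_cols()
    } else {
      profile_metadata_cols()
    }
  }
  setdiff(names(table), metadata)
}

validate_profile_table <- function(profiles, what = "profile table") {
  missing <- setdiff(profile_metadata_cols(), names(profiles))
  if (length(missing)) {
    abort_paintqc(
      sprintf("%s is missing metadata column(s): %s", what,
              paste(missing, collapse = ", ")),
      "paintqc_schema_error"
    )
  }
  feats <- feature_cols(profiles)
  bad <- feats[!vapply(profiles[feats], is.numeric, logical(1))]
  if (length(bad)) {
    abort_paintqc(
      sprintf("%s has non-numeric feature column(s): %s", what,
              paste(bad, collapse = ", ")),
      "paintqc_schema_error"
    )
  }
  key <- paste(profiles$plate_id, profiles$replicate, profiles$well)
  if (anyDuplicated(key)) {
    abort_paintqc(
      sprintf("%s has duplicated (plate_id, replicate, well) rows", what),
      "paintqc_schema_error"
    )
  }
  if (any(profiles$cell_count < 0, na.rm = TRUE)) {
    abort_paintqc(sprintf("%s has negative cell_count", what), "paintqc_schema_error")
  }
  invisible(profiles)
}

validate_cell_table <- function(cells, what = "single-cell table") {
  missing <- setdiff(cell_metadata_cols(), names(cells))
  if (length(missing)) {
    abort_paintqc(
      sprintf("%s is missing metadata column(s): %s", what,
              paste(missing, collapse = ", ")),
      "paintqc_schema_error"
    )
  }
  invisible(cells)
}

#' Read and write well-level profile tables
#'
#' Profile tables are header-first CSV. On read, all metadata columns of
#' [profile_metadata_cols()] must be present; every remaining column is
#' parsed as a numeric feature. On write, floating-point values are
#' serialized with 17 significant digits (`%.17g`), so a write/read
#' round-trip reproduces every value bit for bit; `NaN`, `Inf` and `NA` are
#' written literally and recovered as such.
#'
#' @param path File path of a delimited (comma) text file.
#' @return `read_profiles()` returns a validated profile tibble;
#'   `write_profiles()` returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' prof <- simulate_profiles(synthetic_config(
#'   n_compounds = 4, n_plates = 1, n_features = 3
#' ))$profiles
#' write_profiles(prof, tf)
#' identical(read_profiles(tf), prof)
#' @export
read_profiles <- function(path) {
  tab <- read_typed_csv(path, character_cols = c(
    "site", "cell_line", "plate_id", "well", "compound_id", "role"
  ), integer_cols = c("replicate", "cell_count"))
  validate_profile_table(tab, what = basename(path))
  tab
}

#' @rdname read_profiles
#' @param profiles A profile tibble.
#' @export
write_profiles <- function(profiles, path) {
  validate_profile_table(profiles)
  write_typed_csv(profiles, path)
}

#' Read and write single-cell feature tables
#'
#' Same CSV conventions as [read_profiles()], with the single-cell metadata
#' contract ([cell_metadata_cols()]).
#'
#' @param path File path.
#' @return `read_cells()` returns a validated single-cell tibble;
#'   `write_cells()` returns `path` invisibly.
#' @export
read_cells <- function(path) {
  tab <- read_typed_csv(path, character_cols = c("plate_id", "well"),
                        integer_cols = c("field", "object_id"))
  validate_cell_table(tab, what = basename(path))
  tab
}

#' @rdname read_cells
#' @param cells A single-cell tibble.
#' @export
write_cells <- function(cells, path) {
  validate_cell_table(cells)
  write_typed_csv(cells, path)
}

# CSV write with %.17g numeric formatting: shortest text that is still a
# bitwise round-trip for doubles; NaN/Inf written literally.
write_typed_csv <- function(tab, path) {
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  for (nm in names(out)) {
    col <- out[[nm]]
    if (is.double(col)) {
      txt <- sprintf("%.17g", col)
      txt[is.na(col) & !is.nan(col)] <- "NA"
      out[[nm]] <- txt
    }
  }
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) abort_paintqc(
                    sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)),
                    "paintqc_io_error"))
  on.exit(close(con))
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

read_typed_csv <- function(path, character_cols, integer_cols) {
  if (!file.exists(path)) {
    abort_paintqc(sprintf("file not found: %s", path), "paintqc_io_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in names(raw)) {
    if (nm %in% character_cols) {
      raw[[nm]] <- as.character(raw[[nm]])
    } else if (nm %in% integer_cols) {
      raw[[nm]] <- as.integer(raw[[nm]])
    } else {
      col <- raw[[nm]]
      if (is.character(col)) {
        num <- suppressWarnings(as.numeric(col))
        bad <- which(!is.na(col) & col != "NA" & is.na(num) & col != "NaN")
        if (length(bad)) {
          abort_paintqc(
            sprintf("non-numeric value '%s' in column '%s', row %d of %s",
                    col[bad[1]], nm, bad[1], basename(path)),
            "paintqc_parse_error"
          )
        }
        raw[[nm]] <- num
      } else {
        raw[[nm]] <- as.numeric(col)
      }
    }
  }
  tibble::as_tibble(raw)
}

#' Build 384-well plate layouts for a compound set
#'
#' Distributes `compounds` over `n_plates` plates of 384 wells. Test
#' compounds fill columns 1--22 row-major (row A columns 1--22, then row B,
#' ...) across consecutive plates; each plate holds up to 352 test wells.
#' Columns 23--24 carry the controls in a fixed, declared pattern: column 23
#' is DMSO vehicle (role `negative_control`, concentration 0), column 24
#' alternates nocodazole (odd rows A, C, ...) and tetrandrine (even rows) at
#' 5 uM. Unfilled test wells get role `empty` with `NA` compound.
#'
#' @param n_plates Number of plates.
#' @param compounds Ordered character vector of compound identifiers,
#'   length at most `352 * n_plates`.
#' @return A tibble with one row per well and columns `plate_id`, `well`,
#'   `row`, `column`, `compound_id`, `role`, `concentration_uM`.
#' @examples
#' layout <- build_layout(1, sprintf("CPD%03d", 1:352))
#' table(layout$role)
#' @export
build_layout <- function(n_plates, compounds) {
  n_plates <- as.integer(n_plates)
  capacity <- n_plates * TEST_WELLS_PER_PLATE
  if (length(compounds) > capacity) {
    abort_paintqc(
      sprintf("%d compounds exceed capacity of %d plates (%d test wells)",
              length(compounds), n_plates, capacity),
      "paintqc_capacity_error"
    )
  }
  if (anyDuplicated(compounds)) {
    abort_paintqc("compound identifiers must be unique", "paintqc_capacity_error")
  }
  plates <- lapply(seq_len(n_plates), function(p) {
    test_grid <- expand.grid(column = TEST_COLS, row = PLATE_ROWS,
                             stringsAsFactors = FALSE)[, c("row", "column")]
    idx <- (p - 1L) * TEST_WELLS_PER_PLATE + seq_len(TEST_WELLS_PER_PLATE)
    cpd <- ifelse(idx <= length(compounds), compounds[idx], NA_character_)
    test <- tibble::tibble(
      plate_id = sprintf("plate%02d", p),
      well = well_address(test_grid$row, test_grid$column),
      row = test_grid$row,
      column = as.integer(test_grid$column),
      compound_id = cpd,
      role = ifelse(is.na(cpd), "empty", "test"),
      concentration_uM = ifelse(is.na(cpd), NA_real_, 10)
    )
    ctrl_role <- c(
      rep("negative_control", 16),
      rep(c("positive_control_nocodazole", "positive_control_tetrandrine"), 8)
    )
    ctrl <- tibble::tibble(
      plate_id = sprintf("plate%02d", p),
      well = c(well_address(PLATE_ROWS, 23L), well_address(PLATE_ROWS, 24L)),
      row = rep(PLATE_ROWS, 2),
      column = rep(c(23L, 24L), each = 16),
      compound_id = c(rep("DMSO", 16),
                      rep(c("nocodazole", "tetrandrine"), 8)),
      role = ctrl_role,
      concentration_uM = c(rep(0, 16), rep(5, 16))
    )
    dplyr::arrange(dplyr::bind_rows(test, ctrl), .data$row, .data$column)
  })
  dplyr::bind_rows(plates)
}

validate_layout <- function(layout) {
  stopifnot(all(c("plate_id", "well", "row", "column", "compound_id",
                  "role", "concentration_uM") %in% names(layout)))
  per_plate <- table(layout$plate_id)
  if (any(per_plate != WELLS_PER_PLATE)) {
    abort_paintqc("each plate must have exactly 384 wells", "paintqc_schema_error")
  }
  test_in_ctrl <- layout$role == "test" & layout$column %in% CONTROL_COLS
  ctrl_in_test <- grepl("control", layout$role) & layout$column %in% TEST_COLS
  if (any(test_in_ctrl) || any(ctrl_in_test)) {
    abort_paintqc("test compounds belong in columns 1-22, controls in 23-24",
                  "paintqc_schema_error")
  }
  invisible(layout)
}

#' Read and write plate layout and compound annotation tables
#'
#' Plate layouts are CSV with columns `plate_id, well, row, column,
#' compound_id, role, concentration_uM`. Annotation tables are CSV with
#' columns `compound_id, targets, moas`, where `targets` and `moas` are
#' pipe-separated lists (empty string for none).
#'
#' @param path File path.
#' @return `read_layout()` a layout tibble; `read_annotations()` a tibble
#'   with list-columns `targets` and `moas`.
#' @export
read_layout <- function(path) {
  tab <- read_typed_csv(path, character_cols = c("plate_id", "well", "row",
                                                 "compound_id", "role"),
                        integer_cols = "column")
  validate_layout(tab)
  tab
}

#' @rdname read_layout
#' @param layout A layout tibble.
#' @export
write_layout <- function(layout, path) {
  validate_layout(layout)
  write_typed_csv(layout, path)
}

#' @rdname read_layout
#' @export
read_annotations <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("compound_id", "targets", "moas") %in% names(raw)))
  if (anyDuplicated(raw$compound_id)) {
    abort_paintqc("compound_id must be unique in annotation table",
                  "paintqc_schema_error")
  }
  split_pipe <- function(x) {
    lapply(x, function(s) {
      if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, "|", fixed = TRUE)[[1]]
    })
  }
  tibble::tibble(
    compound_id = as.character(raw$compound_id),
    targets = split_pipe(raw$targets),
    moas = split_pipe(raw$moas)
  )
}

#' @rdname read_layout
#' @param annotations An annotation tibble with list-columns.
#' @export
write_annotations <- function(annotations, path) {
  flat <- data.frame(
    compound_id = annotations$compound_id,
    targets = vapply(annotations$targets, paste, character(1), collapse = "|"),
    moas = vapply(annotations$moas, paste, character(1), collapse = "|"),
    stringsAsFactors = FALSE
  )
  utils::write.table(flat, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
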