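# Internal helpers: well addressing, seed derivation, robust scale, rounding.

PLATE_ROWS <- LETTERS[1:16]
PLATE_COLS <- 1:24
TEST_COLS <- 1:22
CONTROL_COLS <- 23:24
WELLS_PER_PLATE <- 384L
TEST_WELLS_PER_PLATE <- 352L

#' Compose and decompose 384-well addresses
#'
#' Well addresses follow plate-reader convention: letter row `A`--`P` plus
#' 1-based integer column `1`--`24`, e.g. `"A01"`, `"P24"`. Columns are
#' zero-padded to width 2 so addresses sort lexicographically.
#'
#' @param row Character vector of row letters (`A`--`P`).
#' @param col Integer vector of columns (1--24).
#' @return `well_address()` returns a character vector; `well_row()` and
#'   `well_col()` extract the components from an address.
#' @examples
#' well_address("A", 1)
#' well_col("B13")
#' @export
well_address <- function(row, col) {
  stopifnot(all(row %in% PLATE_ROWS), all(col %in% PLATE_COLS))
  sprintf("%s%02d", row, as.integer(col))
}

#' @rdname well_address
#' @param well Character vector of well addresses.
#' @export
well_row <- function(well) substr(well, 1L, 1L)

#' @rdname well_address
#' @export
well_col <- function(well) as.integer(substr(well, 2L, nchar(well)))

# Deterministic substream derivation from one global seed. A small integer
# hash keeps every derived seed in 32-bit range; stream labels make plate /
# stage substreams independently reproducible.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
    h <- (h * 69069 + v + 1) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Raw median absolute deviation: median(|x - median(x)|), no 1.4826
# consistency factor. The robust-normalization and induction conventions in
# morphological profiling use the raw MAD.
raw_mad <- function(x) {
  stats::median(abs(x - stats::median(x)))
}

# IEC 60559 round-half-even at `digits` decimals (base round(), with a guard
# against representation noise at the .5 boundary).
round_half_even <- function(x, digits = 0) {
  round(x, digits)
}

# Ceiling at two significant digits (0 stays 0); used for heatmap count anchors.
ceiling_signif2 <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v) || v == 0) return(v)
    s <- sign(v)
    v <- abs(v)
    p <- 10^(floor(log10(v)) - 1)
    s * ceiling(v / p - 1e-9) * p
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_paintqc <- function(msg, class) {
  stop(structure(
    class = c(class, "paintqc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
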