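# The 4 x 4 reference array: cell position classes and jigsaw puzzle cuts.
#
# A missing piece is one cell of the array. Each cell edge that does not lie
# on the outer frame carries a binary jigsaw tab (outward or inward), so a
# cell with k internal edges admits 2^k distinct cut shapes: 4 for corner
# cells, 8 for non-corner border cells, 16 for internal cells — 144 in all.

GRID_N <- 4L
EDGE_LABELS <- c("N", "E", "S", "W")

check_grid_cell <- function(row, col) {
  if (!is.numeric(row) || !is.numeric(col) ||
      any(row != floor(row)) || any(col != floor(col)) ||
      any(row < 0L) || any(row > GRID_N - 1L) ||
      any(col < 0L) || any(col > GRID_N - 1L)) {
    stop("grid coordinates must be integers in 0..", GRID_N - 1L, call. = FALSE)
  }
  invisible(NULL)
}

#' Classify a 4 x 4 array position
#'
#' Vectorised over `row` and `col` (0-based, row downward).
#'
#' @param row,col Integer coordinates in 0..3.
#' @return Character vector: `"corner"`, `"border"` or `"internal"`.
#' @examples
#' position_class(0, 0) # corner
#' position_class(0, 2) # border
#' @export
position_class <- function(row, col) {
  check_grid_cell(row, col)
  edge_r <- row %in% c(0L, GRID_N - 1L)
  edge_c <- col %in% c(0L, GRID_N - 1L)
  dplyr::case_when(
    edge_r & edge_c ~ "corner",
    !edge_r & !edge_c ~ "internal",
    .default = "border"
  )
}

#' All 16 positions of the reference array
#'
#' @return A tibble with columns `row`, `col`, `position_class`.
#' @export
grid_positions <- function() {
  g <- tidyr::expand_grid(row = 0:(GRID_N - 1L), col = 0:(GRID_N - 1L))
  dplyr::mutate(g, position_class = position_class(row, col))
}

#' Internal edges of an array cell
#'
#' Edges not lying on the outer frame, in fixed N, E, S, W order. These are
#' the edges that carry jigsaw tabs.
#'
#' @param row,col A single cell position (0-based).
#' @return Character vector, a subset of `c("N", "E", "S", "W")`.
#' @examples
#' internal_edges(0, 0) # "E" "S"
#' @export
internal_edges <- function(row, col) {
  check_grid_cell(row, col)
  stopifnot(length(row) == 1L, length(col) == 1L)
  keep <- c(
    N = row > 0L,
    E = col < GRID_N - 1L,
    S = row < GRID_N - 1L,
    W = col > 0L
  )
  EDGE_LABELS[keep]
}

#' Enumerate the puzzle cuts of a cell
#'
#' Every assignment of a tab polarity (outward/inward) to each internal edge
#' of the cell, in deterministic order of an integer cut code whose bits
#' follow the N, E, S, W edge order (bit set = outward).
#'
#' @param row,col A single cell position (0-based).
#' @return A tibble with one row per cut: `row`, `col`, `position_class`,
#'   `cut` (integer code), and `tab_N`, `tab_E`, `tab_S`, `tab_W`
#'   (`"outward"`, `"inward"`, or `NA` for frame edges).
#' @examples
#' nrow(puzzle_cuts(0, 0)) # 4
#' nrow(puzzle_cuts(1, 1)) # 16
#' @export
puzzle_cuts <- function(row, col) {
  edges <- internal_edges(row, col)
  k <- length(edges)
  codes <- 0:(2^k - 1L)
  tabs <- matrix(NA_character_, nrow = length(codes), ncol = 4L,
                 dimnames = list(NULL, paste0("tab_", EDGE_LABELS)))
  for (j in seq_along(edges)) {
    bit <- bitwAnd(codes %/% 2^(j - 1L), 1L)
    tabs[, paste0("tab_", edges[j])] <- ifelse(bit == 1L, "outward", "inward")
  }
  tibble::tibble(
    row = row, col = col,
    position_class = position_class(row, col),
    cut = codes,
    tab_N = tabs[, "tab_N"], tab_E = tabs[, "tab_E"],
    tab_S = tabs[, "tab_S"], tab_W = tabs[, "tab_W"]
  )
}

#' Every puzzle cut of every cell
#'
#' @return The row-bound [puzzle_cuts()] of all 16 positions; 144 rows.
#' @export
all_puzzle_cuts <- function() {
  g <- grid_positions()
  purrr::pmap_dfr(g[, c("row", "col")], puzzle_cuts)
}
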