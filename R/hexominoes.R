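# Polyomino enumeration and canonical forms.
#
# Cells are integer matrices with columns (col, row), screen convention:
# col grows rightward, row grows downward, so a "clockwise" quarter turn
# maps (c, r) -> (-r, c) before re-normalisation.

normalize_cells <- function(cells) {
  cells[, 1L] <- cells[, 1L] - min(cells[, 1L])
  cells[, 2L] <- cells[, 2L] - min(cells[, 2L])
  cells[order(cells[, 1L], cells[, 2L]), , drop = FALSE]
}

rotate_cells_cw <- function(cells) {
  normalize_cells(cbind(-cells[, 2L], cells[, 1L]))
}

reflect_cells <- function(cells) {
  normalize_cells(cbind(-cells[, 1L], cells[, 2L]))
}

cells_key <- function(cells) {
  paste(cells[, 1L], cells[, 2L], sep = ",", collapse = ";")
}

cells_from_key <- function(key) {
  parts <- strsplit(strsplit(key, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
  m <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
  colnames(m) <- c("col", "row")
  m
}

# All transforms of a cell set under the group implied by `mode`.
transform_orbit <- function(cells, mode) {
  rots <- vector("list", 4L)
  rots[[1L]] <- normalize_cells(cells)
  for (i in 2:4) rots[[i]] <- rotate_cells_cw(rots[[i - 1L]])
  if (mode == "fixed") return(rots[1L])
  if (mode == "free") {
    refl <- reflect_cells(cells)
    mirr <- vector("list", 4L)
    mirr[[1L]] <- refl
    for (i in 2:4) mirr[[i]] <- rotate_cells_cw(mirr[[i - 1L]])
    rots <- c(rots, mirr)
  }
  rots
}

canonical_cells <- function(cells, mode = c("free", "one_sided", "fixed")) {
  mode <- match.arg(mode)
  orbit <- transform_orbit(cells, mode)
  keys <- vapply(orbit, cells_key, character(1))
  orbit[[order(keys)[1L]]]
}

symmetry_order_cells <- function(cells) {
  base <- cells_key(normalize_cells(cells))
  cur <- cells
  n <- 0L
  for (i in 1:4) {
    cur <- rotate_cells_cw(cur)
    if (cells_key(cur) == base) n <- n + 1L
  }
  n
}

#' Enumerate polyominoes of a given size
#'
#' Grows polyominoes cell by cell from the monomino and de-duplicates by
#' canonical form under the transform group selected by `mode`: `"fixed"`
#' (translations only), `"one_sided"` (quarter-turn rotations) or `"free"`
#' (rotations and reflections). Size 6 in `"free"` mode yields the 35
#' hexominoes from which a 4 x 4 reference array draws its 16 shapes.
#'
#' @param size Number of cells per shape (1 to 8; the bound guards against
#'   combinatorial blowup and can be lifted with `max_size`).
#' @param mode Transform group for counting shapes as equal.
#' @param max_size Upper bound on `size` accepted without error.
#' @return A tibble with one row per shape: `id` (stable, ordered by
#'   canonical form), `key` (canonical cell string), `symmetry_order`
#'   (quarter turns mapping the shape onto itself: 1, 2 or 4), and `cells`,
#'   a list column of integer matrices with columns `col`, `row`.
#' @examples
#' nrow(polyominoes(6, "free")) # 35
#' @export
polyominoes <- function(size, mode = c("free", "one_sided", "fixed"),
                        max_size = 8L) {
  mode <- match.arg(mode)
  if (!is.numeric(size) || length(size) != 1L || size != as.integer(size) ||
      size < 1L || size > max_size) {
    stop("`size` must be a single integer between 1 and ", max_size,
         " (raise `max_size` deliberately to go larger).", call. = FALSE)
  }
  size <- as.integer(size)

  # fixed-mode growth: every polyomino of size n+1 extends one of size n
  shapes <- list(matrix(c(0L, 0L), ncol = 2L))
  names(shapes) <- cells_key(shapes[[1L]])
  if (size > 1L) {
    for (s in seq_len(size - 1L)) {
      nxt <- new.env(parent = emptyenv())
      for (cells in shapes) {
        occupied <- paste(cells[, 1L], cells[, 2L])
        for (i in seq_len(nrow(cells))) {
          for (d in list(c(0L, -1L), c(1L, 0L), c(0L, 1L), c(-1L, 0L))) {
            cand <- cells[i, ] + d
            if (paste(cand[1L], cand[2L]) %in% occupied) next
            grown <- normalize_cells(rbind(cells, cand))
            assign(cells_key(grown), grown, envir = nxt)
          }
        }
      }
      shapes <- as.list(nxt)
    }
  }

  canon <- lapply(unname(shapes), canonical_cells, mode = mode)
  keys <- vapply(canon, cells_key, character(1))
  keep <- !duplicated(keys)
  canon <- canon[keep]
  keys <- keys[keep]
  ord <- order(keys)
  canon <- canon[ord]
  keys <- keys[ord]
  canon <- lapply(canon, function(m) {
    colnames(m) <- c("col", "row")
    m
  })

  tibble::tibble(
    id = sprintf("p%d_%s_%03d", size, mode, seq_along(canon)),
    key = keys,
    symmetry_order = vapply(canon, symmetry_order_cells, integer(1)),
    cells = canon
  )
}

#' Hexominoes: the order-6 polyominoes
#'
#' Convenience wrapper around [polyominoes()] with `size = 6`.
#'
#' @inheritParams polyominoes
#' @return See [polyominoes()].
#' @export
hexominoes <- function(mode = c("free", "one_sided", "fixed")) {
  polyominoes(6L, match.arg(mode))
}

#' Unnest shape cells into a long tibble
#'
#' @param shapes A tibble from [polyominoes()].
#' @return A tibble with columns `id`, `col`, `row`, one row per cell.
#' @export
shape_cells <- function(shapes) {
  tibble::tibble(
    id = rep(shapes$id, vapply(shapes$cells, nrow, integer(1))),
    col = unlist(lapply(shapes$cells, function(m) m[, 1L])),
    row = unlist(lapply(shapes$cells, function(m) m[, 2L]))
  )
}
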