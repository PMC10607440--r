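# Monochrome SVG rendering of items, plus an integer occupancy raster used
# to check that the cut-out region is blank and that the correct option
# tile reconstructs the rotated array.

#' Rendering style parameters
#'
#' @param cell Cell side in px.
#' @param margin Outer margin in px.
#' @param tab_radius Jigsaw tab radius as a fraction of the cell side.
#' @param shape_scale Fraction of the cell side filled by a hexomino's
#'   bounding box.
#' @param stroke Stroke width in px.
#' @return A `render_style` list.
#' @export
render_style <- function(cell = 60, margin = 20, tab_radius = 0.2,
                         shape_scale = 0.7, stroke = 2) {
  if (tab_radius <= 0 || tab_radius >= 0.5) {
    stop("`tab_radius` must lie in (0, 0.5).", call. = FALSE)
  }
  if (shape_scale <= 0 || shape_scale > 1) {
    stop("`shape_scale` must lie in (0, 1].", call. = FALSE)
  }
  structure(list(cell = cell, margin = margin, tab_radius = tab_radius,
                 shape_scale = shape_scale, stroke = stroke),
            class = "render_style")
}

fmt <- function(x) sprintf("%.2f", x)

# Displayed cell matrix of the hexomino shown at (row, col) of the array
# rotated by `rotation` quarter turns.
displayed_shape_cells <- function(reference, row, col, rotation) {
  id <- displayed_hexomino(reference, row, col, rotation)
  cells <- reference$shapes$cells[[match(id, reference$shapes$id)]]
  for (i in seq_len(rotation %% 4L)) cells <- rotate_cells_cw(cells)
  cells
}

# Pixel rects of a shape centred in a cell at (x0, y0).
hexomino_rects <- function(cells, x0, y0, cell, scale) {
  bw <- max(cells[, 1L]) + 1L
  bh <- max(cells[, 2L]) + 1L
  unit <- scale * cell / max(bw, bh)
  ox <- x0 + (cell - bw * unit) / 2
  oy <- y0 + (cell - bh * unit) / 2
  data.frame(x = ox + cells[, 1L] * unit, y = oy + cells[, 2L] * unit,
             w = unit, h = unit)
}

svg_shape <- function(cells, x0, y0, style) {
  r <- hexomino_rects(cells, x0, y0, style$cell, style$shape_scale)
  paste(sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="black"/>',
                fmt(r$x), fmt(r$y), fmt(r$w), fmt(r$h)),
        collapse = "\n")
}

# Path of a cell square whose internal edges carry jigsaw tabs. Traversed
# clockwise; an outward tab is a semicircle bulging out of the cell
# (sweep 1), inward bulges in (sweep 0). `tabs` is a named character vector
# over N,E,S,W with values "outward"/"inward"/NA (frame edge).
cut_path <- function(x0, y0, style, tabs) {
  cell <- style$cell
  rr <- style$tab_radius * cell
  seg <- function(edge, from, to, mid) {
    tab <- tabs[[edge]]
    if (is.na(tab)) {
      return(sprintf("L %s %s", fmt(to[1]), fmt(to[2])))
    }
    d <- (to - from) / sqrt(sum((to - from)^2))
    p1 <- mid - rr * d
    p2 <- mid + rr * d
    sweep <- if (tab == "outward") 1L else 0L
    paste(
      sprintf("L %s %s", fmt(p1[1]), fmt(p1[2])),
      sprintf("A %s %s 0 0 %d %s %s", fmt(rr), fmt(rr), sweep,
              fmt(p2[1]), fmt(p2[2])),
      sprintf("L %s %s", fmt(to[1]), fmt(to[2]))
    )
  }
  tl <- c(x0, y0); tr <- c(x0 + cell, y0)
  br <- c(x0 + cell, y0 + cell); bl <- c(x0, y0 + cell)
  paste(
    sprintf("M %s %s", fmt(tl[1]), fmt(tl[2])),
    seg("N", tl, tr, (tl + tr) / 2),
    seg("E", tr, br, (tr + br) / 2),
    seg("S", br, bl, (br + bl) / 2),
    seg("W", bl, tl, (bl + tl) / 2),
    "Z"
  )
}

svg_grid_lines <- function(x0, y0, style) {
  cell <- style$cell
  xs <- x0 + cell * 0:GRID_N
  ys <- y0 + cell * 0:GRID_N
  c(
    sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="%s"/>',
            fmt(xs), fmt(ys[1]), fmt(xs), fmt(ys[GRID_N + 1L]), fmt(style$stroke / 2)),
    sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="%s"/>',
            fmt(xs[1]), fmt(ys), fmt(xs[GRID_N + 1L]), fmt(ys), fmt(style$stroke / 2))
  )
}

svg_array_panel <- function(reference, rotation, x0, y0, style, hole = NULL) {
  out <- svg_grid_lines(x0, y0, style)
  g <- grid_positions()
  for (i in seq_len(nrow(g))) {
    if (!is.null(hole) && g$row[i] == hole$row && g$col[i] == hole$col) next
    cells <- displayed_shape_cells(reference, g$row[i], g$col[i], rotation)
    out <- c(out, svg_shape(cells, x0 + g$col[i] * style$cell,
                            y0 + g$row[i] * style$cell, style))
  }
  if (!is.null(hole)) {
    tabs <- c(N = hole$tab_N, E = hole$tab_E, S = hole$tab_S, W = hole$tab_W)
    path <- cut_path(x0 + hole$col * style$cell, y0 + hole$row * style$cell,
                     style, tabs)
    out <- c(out, sprintf('<path d="%s" fill="white" stroke="black" stroke-width="%s"/>',
                          path, fmt(style$stroke)))
  }
  out
}

svg_option <- function(item, j, x0, y0, style) {
  o <- item$options[j, ]
  cell <- style$cell
  box <- sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="none" stroke="black" stroke-width="%s"/>',
                 fmt(x0), fmt(y0), fmt(cell * 1.4), fmt(cell * 1.4),
                 fmt(style$stroke / 2))
  label <- sprintf('<text x="%s" y="%s" font-family="sans-serif" font-size="%s" fill="black">%s</text>',
                   fmt(x0 + 4), fmt(y0 + 14), fmt(12), LETTERS[j])
  if (o$kind != "piece") {
    glyph <- if (o$kind == "dont_know") "?" else "X"
    mark <- sprintf('<text x="%s" y="%s" text-anchor="middle" font-family="sans-serif" font-size="%s" fill="black">%s</text>',
                    fmt(x0 + cell * 0.7), fmt(y0 + cell * 0.85), fmt(cell / 2), glyph)
    return(c(box, label, mark))
  }
  px <- x0 + cell * 0.2
  py <- y0 + cell * 0.2
  cuts <- puzzle_cuts(o$cut_row, o$cut_col)
  cutrow <- cuts[cuts$cut == o$cut, ]
  tabs <- c(N = cutrow$tab_N, E = cutrow$tab_E, S = cutrow$tab_S, W = cutrow$tab_W)
  path <- cut_path(px, py, style, tabs)
  cells <- displayed_shape_cells(item$target$reference, o$cut_row, o$cut_col,
                                 item$target$rotation)
  shape <- svg_shape(cells, px, py, style)
  cx <- px + cell / 2
  cy <- py + cell / 2
  c(box, label,
    sprintf('<g transform="rotate(%s %s %s)">', fmt(90 * o$rotation), fmt(cx), fmt(cy)),
    sprintf('<path d="%s" fill="none" stroke="black" stroke-width="%s"/>',
            path, fmt(style$stroke)),
    shape,
    "</g>")
}

#' Render an item to SVG
#'
#' Black-and-white only: the unrotated reference array on the left, the
#' rotated target with its jigsaw cut-out on the right, and the eight
#' labelled response options below. Output bytes are a pure function of
#' `(item, style)`.
#'
#' @param item A `rotation_item`.
#' @param style A [render_style()].
#' @param path Optional file to write the SVG to.
#' @return The SVG document as a single string.
#' @export
render_item <- function(item, style = render_style(), path = NULL) {
  stopifnot(inherits(item, "rotation_item"))
  if (!inherits(style, "render_style")) {
    stop("`style` must come from render_style().", call. = FALSE)
  }
  cell <- style$cell
  m <- style$margin
  panel <- GRID_N * cell
  gap <- cell
  width <- 2 * m + 2 * panel + gap
  opt_w <- cell * 1.4
  opt_gap <- (width - 2 * m - 8 * opt_w) / 7
  opt_y <- m + panel + cell
  height <- opt_y + opt_w + m

  body <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
            fmt(width), fmt(height), fmt(width), fmt(height)),
    sprintf('<rect x="0" y="0" width="%s" height="%s" fill="white"/>',
            fmt(width), fmt(height)),
    svg_array_panel(item$target$reference, 0L, m, m, style),
    svg_array_panel(item$target$reference, item$target$rotation,
                    m + panel + gap, m, style, hole = item$target$cut),
    unlist(lapply(seq_len(8L), function(j) {
      svg_option(item, j, m + (j - 1L) * (opt_w + opt_gap), opt_y, style)
    })),
    "</svg>"
  )
  doc <- paste(body, collapse = "\n")
  if (!is.null(path)) writeLines(doc, path)
  doc
}

# Integer occupancy of a shape inside a res x res cell block. unit and
# offsets are integers so reconstruction is exact.
block_occupancy <- function(cells, res, scale) {
  bw <- max(cells[, 1L]) + 1L
  bh <- max(cells[, 2L]) + 1L
  unit <- max(1L, floor(scale * res / max(bw, bh)))
  ox <- (res - bw * unit) %/% 2L
  oy <- (res - bh * unit) %/% 2L
  occ <- matrix(FALSE, res, res)
  for (i in seq_len(nrow(cells))) {
    xs <- ox + cells[i, 1L] * unit + seq_len(unit)
    ys <- oy + cells[i, 2L] * unit + seq_len(unit)
    occ[ys, xs] <- TRUE
  }
  occ
}

#' Occupancy raster of an item's target panel
#'
#' A logical matrix marking which pixels of the rotated target array are
#' covered by hexomino cells (tab geometry excluded). The missing piece's
#' cell is left blank unless `include_hole` is set.
#'
#' @param item A `rotation_item`.
#' @param res Pixels per grid cell.
#' @param include_hole Draw the deleted hexomino too (the complete rotated
#'   array).
#' @return A `4*res` x `4*res` logical matrix (rows = y, downward).
#' @export
target_occupancy <- function(item, res = 12L, include_hole = FALSE) {
  stopifnot(inherits(item, "rotation_item"))
  occ <- matrix(FALSE, GRID_N * res, GRID_N * res)
  g <- grid_positions()
  hole <- item$target$cut
  for (i in seq_len(nrow(g))) {
    if (!include_hole && g$row[i] == hole$row && g$col[i] == hole$col) next
    cells <- displayed_shape_cells(item$target$reference, g$row[i], g$col[i],
                                   item$target$rotation)
    block <- block_occupancy(cells, res, 0.7)
    occ[g$row[i] * res + seq_len(res), g$col[i] * res + seq_len(res)] <- block
  }
  occ
}

#' Occupancy raster of a piece option, rotated back to the target frame
#'
#' @param item A `rotation_item`.
#' @param index Option position (1..8); must be a piece option.
#' @param res Pixels per grid cell.
#' @return A `res` x `res` logical matrix in target-frame orientation.
#' @export
option_occupancy <- function(item, index, res = 12L) {
  o <- item$options[index, ]
  if (o$kind != "piece") stop("option ", index, " is not a piece.", call. = FALSE)
  cells <- displayed_shape_cells(item$target$reference, o$cut_row, o$cut_col,
                                 item$target$rotation)
  block_occupancy(cells, res, 0.7)
}
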