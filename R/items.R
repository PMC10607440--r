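# Item assembly: 16-hexomino reference arrays, rotated targets with a
# jigsaw-cut missing piece, and 8-option multiple-choice response sets.

#' Select a set of visually distinct hexominoes
#'
#' @param shapes A shape tibble from [polyominoes()] or [hexominoes()].
#' @param k Number of shapes to select (16 for the standard array).
#' @param seed Integer seed; the selection is a pure function of
#'   `(shapes, k, seed, rule)`.
#' @param rule `"rotation_distinct"` (no two selected shapes are
#'   quarter-turn equivalent), `"greedy_dissimilar"` (farthest-point greedy
#'   on a cell-overlap distance, seeded start), or `"explicit"` (take `ids`).
#' @param ids Shape ids, used when `rule = "explicit"`.
#' @return A `k`-row shape tibble.
#' @export
select_hexomino_set <- function(shapes, k = 16L, seed = 1L,
                                rule = c("rotation_distinct",
                                         "greedy_dissimilar", "explicit"),
                                ids = NULL) {
  rule <- match.arg(rule)
  if (rule == "explicit") {
    if (is.null(ids)) stop("rule \"explicit\" requires `ids`.", call. = FALSE)
    missing <- setdiff(ids, shapes$id)
    if (length(missing)) {
      stop("unknown shape ids: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    return(shapes[match(ids, shapes$id), ])
  }
  if (nrow(shapes) < k) {
    stop("need at least ", k, " shapes, got ", nrow(shapes), call. = FALSE)
  }
  os_key <- vapply(shapes$cells, function(m) {
    cells_key(canonical_cells(m, "one_sided"))
  }, character(1))

  if (rule == "rotation_distinct") {
    groups <- split(seq_len(nrow(shapes)), os_key)
    if (length(groups) < k) {
      stop("rule \"rotation_distinct\" is infeasible: only ", length(groups),
           " quarter-turn-distinct shapes available for k = ", k, call. = FALSE)
    }
    idx <- withr::with_seed(seed, {
      picked_groups <- sample(names(groups), k)
      vapply(groups[picked_groups], function(g) {
        if (length(g) == 1L) g else sample(g, 1L)
      }, integer(1))
    })
    return(shapes[sort(idx), ])
  }

  # greedy_dissimilar: distance = 6 - best cell overlap over the 4 rotations
  n <- nrow(shapes)
  overlap <- function(a, b) {
    ka <- strsplit(cells_key(a), ";", fixed = TRUE)[[1]]
    best <- 0L
    cur <- b
    for (r in 1:4) {
      cur <- rotate_cells_cw(cur)
      kb <- strsplit(cells_key(cur), ";", fixed = TRUE)[[1]]
      best <- max(best, length(intersect(ka, kb)))
    }
    best
  }
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- 6L - overlap(shapes$cells[[i]], shapes$cells[[j]])
    }
  }
  chosen <- withr::with_seed(seed, sample.int(n, 1L))
  while (length(chosen) < k) {
    rest <- setdiff(seq_len(n), chosen)
    score <- apply(d[rest, chosen, drop = FALSE], 1L, min)
    chosen <- c(chosen, rest[order(-score, shapes$id[rest])[1L]])
  }
  shapes[sort(chosen), ]
}

#' Arrange 16 hexominoes into a reference array
#'
#' The assignment of shapes to the 4 x 4 grid is a seeded random
#' permutation; 16! (about 20 x 10^12) orderings are possible.
#'
#' @param shapes Exactly 16 shapes (tibble from [select_hexomino_set()]).
#' @param seed Integer seed for the permutation.
#' @return A `reference_array` object: list with `grid` (tibble `row`,
#'   `col`, `hexomino_id` in row-major order), `shapes`, `seed`.
#' @export
make_reference <- function(shapes, seed = 1L) {
  if (nrow(shapes) != 16L || anyDuplicated(shapes$id)) {
    stop("a reference array needs exactly 16 distinct shapes.", call. = FALSE)
  }
  perm <- withr::with_seed(seed, sample.int(16L))
  grid <- grid_positions()
  grid$hexomino_id <- shapes$id[perm]
  structure(
    list(grid = grid, shapes = shapes, seed = as.integer(seed)),
    class = "reference_array"
  )
}

#' @export
print.reference_array <- function(x, ...) {
  m <- matrix(x$grid$hexomino_id, 4L, 4L, byrow = TRUE)
  cat("<reference_array> 4 x 4, seed", x$seed, "\n")
  print(m, quote = FALSE)
  invisible(x)
}

#' Number of distinct orderings of a 16-shape array
#'
#' @return 16! as a double (20,922,789,888,000).
#' @export
n_array_orderings <- function() factorial(16)

# Cell of the unrotated array shown at displayed position (row, col) after
# `rotation` clockwise quarter turns.
source_cell <- function(row, col, rotation) {
  r <- row; c <- col
  for (i in seq_len(rotation %% 4L)) {
    tmp <- r
    r <- GRID_N - 1L - c
    c <- tmp
  }
  c(row = r, col = c)
}

# Hexomino id displayed at (row, col) of the rotated array.
displayed_hexomino <- function(reference, row, col, rotation) {
  src <- source_cell(row, col, rotation)
  g <- reference$grid
  g$hexomino_id[g$row == src["row"] & g$col == src["col"]]
}

#' Build a target figure
#'
#' A target is the reference array rotated clockwise by 0-3 quarter turns
#' with one cell removed along a jigsaw puzzle cut. The cut cell is given in
#' the displayed (rotated) frame.
#'
#' @param reference A [make_reference()] array.
#' @param rotation Clockwise quarter turns, 0-3.
#' @param cut_row,cut_col Cell of the missing piece, displayed frame.
#' @param cut Integer cut code (see [puzzle_cuts()]).
#' @return A `target_figure` object.
#' @export
target_figure <- function(reference, rotation, cut_row, cut_col, cut) {
  stopifnot(inherits(reference, "reference_array"))
  if (!rotation %in% 0:3) stop("`rotation` must be 0..3.", call. = FALSE)
  cuts <- puzzle_cuts(cut_row, cut_col)
  if (!cut %in% cuts$cut) {
    stop("cut code ", cut, " is out of range for cell (", cut_row, ",",
         cut_col, ").", call. = FALSE)
  }
  structure(
    list(
      reference = reference,
      rotation = as.integer(rotation),
      cut = cuts[cuts$cut == cut, ]
    ),
    class = "target_figure"
  )
}

#' Count the distinct missing-piece targets of a reference array
#'
#' Sums the number of puzzle cuts over all 16 cells at a fixed rotation
#' (144); multiplying by the 4 rotations gives the 576 stimulus:target
#' pairings reported by [n_stimulus_pairings()].
#'
#' @param reference A [make_reference()] array.
#' @return Integer count of (cell, cut) combinations.
#' @export
count_targets <- function(reference) {
  stopifnot(inherits(reference, "reference_array"))
  sum(vapply(seq_len(nrow(reference$grid)), function(i) {
    nrow(puzzle_cuts(reference$grid$row[i], reference$grid$col[i]))
  }, integer(1)))
}

#' @rdname count_targets
#' @export
n_stimulus_pairings <- function(reference) 4L * count_targets(reference)

#' Classify an item's rotation demand
#'
#' @param stimulus_rotation,option_rotation Quarter turns in 0..3.
#' @return `"NONE"`, `"STIMULUS_ONLY"`, `"OPTION_ONLY"` or `"BOTH"`
#'   (vectorised).
#' @export
classify_item <- function(stimulus_rotation, option_rotation) {
  if (!all(stimulus_rotation %in% 0:3) || !all(option_rotation %in% 0:3)) {
    stop("rotations must be quarter turns in 0..3.", call. = FALSE)
  }
  dplyr::case_when(
    stimulus_rotation == 0L & option_rotation == 0L ~ "NONE",
    stimulus_rotation > 0L & option_rotation == 0L ~ "STIMULUS_ONLY",
    stimulus_rotation == 0L & option_rotation > 0L ~ "OPTION_ONLY",
    .default = "BOTH"
  )
}

ITEM_TYPES <- c("NONE", "STIMULUS_ONLY", "OPTION_ONLY", "BOTH")

#' Build the 8-option response set of a target
#'
#' One correct piece (the deleted hexomino with the target's cut), one
#' near-distractor (same hexomino, a different cut of the same cell), four
#' fillers drawn without replacement from the remaining pieces of the same
#' position class, and the two meta options ("don't know", "not listed").
#' All six piece options share the target cell's position class and are
#' displayed at a common `option_rotation`; option order is a seeded
#' shuffle.
#'
#' @param target A [target_figure()].
#' @param option_rotation Quarter turns applied to every piece option.
#' @param seed Integer seed.
#' @return A list with `options` (tibble of 8 rows: `position`, `kind`,
#'   `hexomino_id`, `cut_row`, `cut_col`, `cut`, `rotation`, `correct`) and
#'   `correct_index`.
#' @export
build_response_set <- function(target, option_rotation = 0L, seed = 1L) {
  stopifnot(inherits(target, "target_figure"))
  if (!option_rotation %in% 0:3) stop("`option_rotation` must be 0..3.", call. = FALSE)
  cls <- target$cut$position_class
  cells <- dplyr::filter(grid_positions(), .data$position_class == cls)
  pieces <- purrr::pmap_dfr(cells[, c("row", "col")], puzzle_cuts)
  pieces$hexomino_id <- vapply(seq_len(nrow(pieces)), function(i) {
    displayed_hexomino(target$reference, pieces$row[i], pieces$col[i],
                       target$rotation)
  }, character(1))

  is_correct <- pieces$row == target$cut$row & pieces$col == target$cut$col &
    pieces$cut == target$cut$cut
  same_cell <- pieces$row == target$cut$row & pieces$col == target$cut$col
  stopifnot(sum(is_correct) == 1L)

  drawn <- withr::with_seed(seed, {
    distractor_pool <- which(same_cell & !is_correct)
    distractor <- distractor_pool[sample.int(length(distractor_pool), 1L)]
    filler_pool <- setdiff(seq_len(nrow(pieces)), c(which(is_correct), distractor))
    fillers <- filler_pool[sample.int(length(filler_pool), 4L)]
    ord <- sample.int(8L)
    list(distractor = distractor, fillers = fillers, ord = ord)
  })

  piece_rows <- pieces[c(which(is_correct), drawn$distractor, drawn$fillers), ]
  options <- tibble::tibble(
    kind = c(rep("piece", 6L), "dont_know", "none_of_these"),
    hexomino_id = c(piece_rows$hexomino_id, NA, NA),
    cut_row = c(piece_rows$row, NA, NA),
    cut_col = c(piece_rows$col, NA, NA),
    cut = c(piece_rows$cut, NA, NA),
    rotation = c(rep(as.integer(option_rotation), 6L), NA, NA),
    correct = c(TRUE, rep(FALSE, 7L))
  )
  options <- options[drawn$ord, ]
  options$position <- seq_len(8L)
  options <- options[, c("position", setdiff(names(options), "position"))]
  list(options = options, correct_index = which(options$correct))
}

#' Assemble a complete item
#'
#' @param reference A [make_reference()] array.
#' @param stimulus_rotation,option_rotation Quarter turns in 0..3.
#' @param cut_row,cut_col,cut Missing-piece cell (displayed frame) and cut
#'   code.
#' @param seed Integer seed driving the response-set draw and shuffle.
#' @return A `rotation_item` object with a provenance id of the form
#'   `r{rotation}_c{row}{col}_k{cut}_o{option_rotation}`.
#' @export
make_item <- function(reference, stimulus_rotation, cut_row, cut_col, cut,
                      option_rotation = 0L, seed = 1L) {
  target <- target_figure(reference, stimulus_rotation, cut_row, cut_col, cut)
  rs <- build_response_set(target, option_rotation, seed)
  structure(
    list(
      id = sprintf("r%d_c%d%d_k%d_o%d", stimulus_rotation, cut_row, cut_col,
                   cut, option_rotation),
      target = target,
      options = rs$options,
      correct_index = rs$correct_index,
      item_type = classify_item(stimulus_rotation, option_rotation),
      option_rotation = as.integer(option_rotation),
      seed = as.integer(seed)
    ),
    class = "rotation_item"
  )
}

#' @export
print.rotation_item <- function(x, ...) {
  cat("<rotation_item>", x$id, " type:", x$item_type,
      " correct option:", x$correct_index, "\n")
  invisible(x)
}

#' Composition presets for item pools
#'
#' `"paper70"` is a 70-item pool with 12 items requiring no rotation and 58
#' rotation-demanding items split across the three demanding types.
#'
#' @param name Preset name.
#' @return A tibble with columns `item_type`, `n`.
#' @export
pool_spec <- function(name = "paper70") {
  switch(name,
    paper70 = tibble::tibble(
      item_type = ITEM_TYPES,
      n = c(12L, 19L, 19L, 20L)
    ),
    stop("unknown pool spec preset: ", name, call. = FALSE)
  )
}

#' Generate an item pool
#'
#' Draws items stratum by stratum so that every (stimulus rotation, cell,
#' cut) triple in the pool is unique — no two items share a stimulus:target
#' pairing — and the requested composition is met exactly.
#'
#' @param spec Tibble with columns `item_type` and `n` (see [pool_spec()]);
#'   an optional `position_class` column restricts a stratum to cells of
#'   that class (`"any"` for no restriction).
#' @param seed Integer seed; pools are reproducible byte for byte.
#' @param reference Optional [make_reference()] array; by default one is
#'   built from a rotation-distinct selection of the 35 free hexominoes
#'   using `seed`.
#' @return An `item_pool` object.
#' @export
generate_pool <- function(spec = pool_spec("paper70"), seed = 1L,
                          reference = NULL) {
  if (!all(c("item_type", "n") %in% names(spec))) {
    stop("`spec` needs columns item_type and n.", call. = FALSE)
  }
  if (!all(spec$item_type %in% ITEM_TYPES)) {
    stop("unknown item_type in spec.", call. = FALSE)
  }
  if (!"position_class" %in% names(spec)) spec$position_class <- "any"
  if (is.null(reference)) {
    shapes <- select_hexomino_set(hexominoes("free"), 16L, seed = seed)
    reference <- make_reference(shapes, seed = seed)
  }

  cuts <- all_puzzle_cuts()
  triples <- tidyr::expand_grid(stimulus_rotation = 0:3, i = seq_len(nrow(cuts)))
  triples <- dplyr::bind_cols(triples["stimulus_rotation"], cuts[triples$i, ])
  used <- rep(FALSE, nrow(triples))

  items <- list()
  withr::with_seed(seed, {
    for (s in seq_len(nrow(spec))) {
      type <- spec$item_type[s]
      n_want <- spec$n[s]
      cls <- spec$position_class[s]
      stim_allowed <- if (type %in% c("NONE", "OPTION_ONLY")) 0L else 1:3
      avail <- which(!used &
                       triples$stimulus_rotation %in% stim_allowed &
                       (cls == "any" | triples$position_class == cls))
      if (length(avail) < n_want) {
        stop("infeasible pool spec: stratum ", type, "/", cls, " needs ",
             n_want, " items but only ", length(avail),
             " unused stimulus:target pairings remain.", call. = FALSE)
      }
      take <- avail[sample.int(length(avail), n_want)]
      used[take] <- TRUE
      for (t in take) {
        opt_rot <- if (type %in% c("NONE", "STIMULUS_ONLY")) 0L
                   else sample(1:3, 1L)
        item_seed <- sample.int(.Machine$integer.max, 1L)
        items[[length(items) + 1L]] <- make_item(
          reference,
          stimulus_rotation = triples$stimulus_rotation[t],
          cut_row = triples$row[t], cut_col = triples$col[t],
          cut = triples$cut[t],
          option_rotation = opt_rot, seed = item_seed
        )
      }
    }
  })

  composition <- dplyr::count(
    tibble::tibble(item_type = vapply(items, `[[`, character(1), "item_type")),
    .data$item_type, name = "n"
  )
  structure(
    list(items = items, composition = composition,
         bank_version = "hexrot-bank v1", seed = as.integer(seed),
         reference = reference),
    class = "item_pool"
  )
}

#' @export
print.item_pool <- function(x, ...) {
  cat("<item_pool>", length(x$items), "items, bank", x$bank_version,
      ", seed", x$seed, "\n")
  print(x$composition)
  invisible(x)
}

#' Tidy an item pool into a per-item tibble
#'
#' @param x An `item_pool`.
#' @param ... Unused.
#' @return One row per item: id, type, rotations, cut cell and code,
#'   correct option position.
#' @export
tidy.item_pool <- function(x, ...) {
  purrr::map_dfr(x$items, function(it) {
    tibble::tibble(
      item_id = it$id,
      item_type = it$item_type,
      stimulus_rotation = it$target$rotation,
      option_rotation = it$option_rotation,
      cut_row = it$target$cut$row,
      cut_col = it$target$cut$col,
      cut = it$target$cut$cut,
      position_class = it$target$cut$position_class,
      correct_index = it$correct_index
    )
  })
}
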