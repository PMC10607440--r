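shapes35 <- hexominoes("free")

test_that("hexomino-set selection is deterministic and rotation-distinct", {
  s1 <- select_hexomino_set(shapes35, 16L, seed = 7L)
  s2 <- select_hexomino_set(shapes35, 16L, seed = 7L)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 16L)
  expect_identical(anyDuplicated(s1$id), 0L)
  one_sided <- vapply(s1$cells, function(m) {
    hexrot:::cells_key(hexrot:::canonical_cells(m, "one_sided"))
  }, character(1))
  expect_identical(anyDuplicated(one_sided), 0L)
  expect_error(select_hexomino_set(shapes35[1:10, ], 16L), "at least 16")
  expect_error(
    select_hexomino_set(shapes35[rep(1, 20), ], 16L, rule = "rotation_distinct"),
    "infeasible"
  )
})

test_that("greedy-dissimilar and explicit selection honour their contracts", {
  g <- select_hexomino_set(shapes35, 5L, seed = 3L, rule = "greedy_dissimilar")
  expect_identical(nrow(g), 5L)
  expect_identical(g, select_hexomino_set(shapes35, 5L, seed = 3L,
                                          rule = "greedy_dissimilar"))
  ids <- shapes35$id[c(3, 1, 9)]
  e <- select_hexomino_set(shapes35, rule = "explicit", ids = ids)
  expect_identical(e$id, ids)
  expect_error(select_hexomino_set(shapes35, rule = "explicit", ids = "nope"),
               "unknown shape ids")
})

test_that("reference arrays fill all 16 cells bijectively and reproducibly", {
  sel <- select_hexomino_set(shapes35, 16L, seed = 1L)
  ref <- make_reference(sel, seed = 11L)
  expect_identical(nrow(ref$grid), 16L)
  expect_identical(sort(ref$grid$hexomino_id), sort(sel$id))
  expect_identical(make_reference(sel, seed = 11L)$grid, ref$grid)
  expect_error(make_reference(sel[1:15, ]), "exactly 16")
  expect_identical(n_array_orderings(), factorial(16))
  expect_gte(n_array_orderings(), 2.0e13)
})

ref <- make_reference(select_hexomino_set(shapes35, 16L, seed = 1L), seed = 1L)

test_that("target counting reproduces the 144 targets and 576 pairings", {
  expect_identical(count_targets(ref), 144L)
  expect_identical(n_stimulus_pairings(ref), 576L)
  corner_targets <- sum(vapply(list(c(0, 0), c(0, 3), c(3, 0), c(3, 3)),
                               function(p) nrow(puzzle_cuts(p[1], p[2])),
                               integer(1)))
  expect_identical(corner_targets, 16L)
})

test_that("rotating the displayed frame four times returns the original grid", {
  for (rot in 0:3) {
    ids <- vapply(seq_len(16L), function(i) {
      g <- grid_positions()
      hexrot:::displayed_hexomino(ref, g$row[i], g$col[i], rot)
    }, character(1))
    expect_setequal(ids, ref$grid$hexomino_id)
  }
  g <- grid_positions()
  ids0 <- vapply(seq_len(16L), function(i) {
    hexrot:::displayed_hexomino(ref, g$row[i], g$col[i], 0L)
  }, character(1))
  expect_identical(ids0, ref$grid$hexomino_id)
})

test_that("response sets have 6 same-class pieces, 2 meta options, 1 correct", {
  tgt <- target_figure(ref, rotation = 1L, cut_row = 0L, cut_col = 0L, cut = 2L)
  rs <- build_response_set(tgt, option_rotation = 2L, seed = 5L)
  opts <- rs$options
  expect_identical(nrow(opts), 8L)
  expect_identical(sum(opts$kind == "piece"), 6L)
  expect_setequal(opts$kind[opts$kind != "piece"], c("dont_know", "none_of_these"))
  expect_identical(sum(opts$correct), 1L)
  expect_identical(opts$position[opts$correct], rs$correct_index)
  pieces <- opts[opts$kind == "piece", ]
  expect_true(all(position_class(pieces$cut_row, pieces$cut_col) == "corner"))
  expect_true(all(pieces$rotation == 2L))
  # correct option reproduces the deleted piece
  correct <- opts[opts$correct, ]
  expect_identical(correct$hexomino_id,
                   hexrot:::displayed_hexomino(ref, 0L, 0L, 1L))
  expect_identical(correct$cut, 2L)
  # near-distractor: same hexomino, same cell, different cut
  same_hex <- pieces[!pieces$correct &
                       pieces$cut_row == 0L & pieces$cut_col == 0L, ]
  expect_gte(nrow(same_hex), 1L)
  expect_true(all(same_hex$hexomino_id == correct$hexomino_id))
  expect_true(all(same_hex$cut != correct$cut))
  # determinism
  expect_identical(build_response_set(tgt, 2L, seed = 5L)$options, opts)
})

test_that("item-type classification follows the rotation-demand rule", {
  expect_identical(classify_item(0L, 0L), "NONE")
  expect_identical(classify_item(2L, 0L), "STIMULUS_ONLY")
  expect_identical(classify_item(0L, 3L), "OPTION_ONLY")
  expect_identical(classify_item(1L, 3L), "BOTH")
  expect_error(classify_item(4L, 0L), "0\\.\\.3")
})

test_that("generated pools match their composition spec exactly", {
  pool <- generate_pool(pool_spec("paper70"), seed = 2L)
  expect_identical(length(pool$items), 70L)
  td <- generics::tidy(pool)
  expect_identical(sum(td$item_type == "NONE"), 12L)
  expect_identical(sum(td$item_type != "NONE"), 58L)
  expect_identical(sum(pool$composition$n), 70L)
  expect_identical(anyDuplicated(td$item_id), 0L)
  # no duplicate stimulus:target pairings
  expect_identical(anyDuplicated(td[, c("stimulus_rotation", "cut_row",
                                        "cut_col", "cut")]), 0L)
  # classification consistent with rotations
  expect_identical(classify_item(td$stimulus_rotation, td$option_rotation),
                   td$item_type)
  one <- generate_pool(tibble::tibble(item_type = "BOTH", n = 1L), seed = 9L)
  expect_identical(generics::tidy(one)$item_type, "BOTH")
})

test_that("infeasible pool specs fail naming the stratum", {
  spec <- tibble::tibble(item_type = "NONE", n = 200L)
  expect_error(generate_pool(spec, seed = 1L), "NONE")
  corner_overflow <- tibble::tibble(item_type = "BOTH", n = 70L,
                                    position_class = "corner")
  expect_error(generate_pool(corner_overflow, seed = 1L), "BOTH/corner")
})

test_that("pool serialization round-trips losslessly and rejects bad input", {
  pool <- generate_pool(tibble::tibble(item_type = c("NONE", "BOTH"),
                                       n = c(2L, 3L)), seed = 4L)
  json <- serialize_pool(pool)
  back <- parse_pool(json)
  expect_identical(serialize_pool(back), json)
  expect_identical(generics::tidy(back), generics::tidy(pool))
  expect_identical(back$reference$grid, pool$reference$grid)
  # byte-identical regeneration from the same spec + seed
  pool2 <- generate_pool(tibble::tibble(item_type = c("NONE", "BOTH"),
                                        n = c(2L, 3L)), seed = 4L)
  expect_identical(serialize_pool(pool2), json)
  # truncation and unknown fields are rejected outright
  expect_error(parse_pool(substr(json, 1, nchar(json) %/% 2)), "parse error")
  tampered <- sub('"seed":', '"surprise": 1, "seed":', json)
  expect_error(parse_pool(tampered), "unknown field")
  empty <- generate_pool(tibble::tibble(item_type = "NONE", n = 0L), seed = 1L)
  expect_identical(length(parse_pool(serialize_pool(empty))$items), 0L)
})
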