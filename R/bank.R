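# Item-bank serialization: JSON schema "hexrot-bank v1".
#
# The bank is self-contained: it carries the shape set (canonical cell
# keys), the reference grid, and per-item targets and option lists, so a
# parsed bank reconstructs the same item objects byte for byte.

BANK_VERSION <- "hexrot-bank v1"

bank_top_fields <- c("bank_version", "seed", "shapes", "reference", "items")
bank_item_fields <- c("id", "item_type", "stimulus_rotation", "option_rotation",
                      "cut_row", "cut_col", "cut", "correct_index", "seed",
                      "options")
bank_option_fields <- c("position", "kind", "hexomino_id", "cut_row", "cut_col",
                        "cut", "rotation", "correct")

#' Serialize an item pool to JSON
#'
#' @param pool An `item_pool` from [generate_pool()].
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON text, invisibly when `path` is given.
#' @export
serialize_pool <- function(pool, path = NULL) {
  stopifnot(inherits(pool, "item_pool"))
  ref <- pool$reference
  obj <- list(
    bank_version = pool$bank_version,
    seed = pool$seed,
    shapes = lapply(seq_len(nrow(ref$shapes)), function(i) {
      list(id = ref$shapes$id[i], key = ref$shapes$key[i],
           symmetry_order = ref$shapes$symmetry_order[i])
    }),
    reference = list(
      seed = ref$seed,
      grid = ref$grid$hexomino_id # row-major over grid_positions()
    ),
    items = lapply(pool$items, function(it) {
      list(
        id = it$id,
        item_type = it$item_type,
        stimulus_rotation = it$target$rotation,
        option_rotation = it$option_rotation,
        cut_row = it$target$cut$row,
        cut_col = it$target$cut$col,
        cut = it$target$cut$cut,
        correct_index = it$correct_index,
        seed = it$seed,
        options = lapply(seq_len(nrow(it$options)), function(j) {
          o <- it$options[j, ]
          keep <- list(
            position = o$position, kind = o$kind,
            hexomino_id = o$hexomino_id, cut_row = o$cut_row,
            cut_col = o$cut_col, cut = o$cut, rotation = o$rotation,
            correct = o$correct
          )
          keep[!vapply(keep, function(v) is.na(v) && !is.logical(v), logical(1))]
        })
      )
    })
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

bank_fail <- function(path, msg) {
  stop("item-bank parse error at ", path, ": ", msg, call. = FALSE)
}

check_fields <- function(x, allowed, required, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    bank_fail(where, paste("unknown field(s):", paste(extra, collapse = ", ")))
  }
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    bank_fail(where, paste("missing field(s):", paste(missing, collapse = ", ")))
  }
}

#' Parse an item bank from JSON
#'
#' Strict: the schema version must match, unknown fields are rejected, and
#' a malformed document yields an error (with the offending JSON path)
#' rather than a partial pool.
#'
#' @param json JSON text, or a file path to read.
#' @return An `item_pool`.
#' @export
parse_pool <- function(json) {
  if (length(json) == 1L && !grepl("^\\s*\\{", json) && file.exists(json)) {
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  obj <- tryCatch(jsonlite::fromJSON(json, simplifyVector = FALSE),
                  error = function(e) bank_fail("$", conditionMessage(e)))
  check_fields(obj, bank_top_fields, bank_top_fields, "$")
  if (!identical(obj$bank_version, BANK_VERSION)) {
    bank_fail("$.bank_version", paste0("expected \"", BANK_VERSION, "\""))
  }

  shapes <- purrr::map_dfr(obj$shapes, function(s) {
    check_fields(s, c("id", "key", "symmetry_order"),
                 c("id", "key", "symmetry_order"), "$.shapes[]")
    tibble::tibble(id = s$id, key = s$key,
                   symmetry_order = as.integer(s$symmetry_order))
  })
  shapes$cells <- lapply(shapes$key, cells_from_key)
  if (nrow(shapes) != 16L) bank_fail("$.shapes", "expected 16 shapes")

  check_fields(obj$reference, c("seed", "grid"), c("seed", "grid"), "$.reference")
  grid_ids <- unlist(obj$reference$grid)
  if (length(grid_ids) != 16L || !setequal(grid_ids, shapes$id)) {
    bank_fail("$.reference.grid", "grid must hold the 16 shape ids")
  }
  grid <- grid_positions()
  grid$hexomino_id <- grid_ids
  reference <- structure(
    list(grid = grid, shapes = shapes, seed = as.integer(obj$reference$seed)),
    class = "reference_array"
  )

  items <- lapply(seq_along(obj$items), function(i) {
    it <- obj$items[[i]]
    where <- sprintf("$.items[%d]", i)
    check_fields(it, bank_item_fields, bank_item_fields, where)
    target <- target_figure(reference, as.integer(it$stimulus_rotation),
                            as.integer(it$cut_row), as.integer(it$cut_col),
                            as.integer(it$cut))
    options <- purrr::map_dfr(it$options, function(o) {
      check_fields(o, bank_option_fields,
                   c("position", "kind", "correct"), paste0(where, ".options[]"))
      tibble::tibble(
        position = as.integer(o$position),
        kind = o$kind,
        hexomino_id = o$hexomino_id %||% NA_character_,
        cut_row = as.integer(o$cut_row %||% NA_integer_),
        cut_col = as.integer(o$cut_col %||% NA_integer_),
        cut = as.integer(o$cut %||% NA_integer_),
        rotation = as.integer(o$rotation %||% NA_integer_),
        correct = o$correct
      )
    })
    if (nrow(options) != 8L || sum(options$correct) != 1L) {
      bank_fail(paste0(where, ".options"), "need 8 options with one correct")
    }
    structure(
      list(
        id = it$id, target = target, options = options,
        correct_index = as.integer(it$correct_index),
        item_type = it$item_type,
        option_rotation = as.integer(it$option_rotation),
        seed = as.integer(it$seed)
      ),
      class = "rotation_item"
    )
  })

  item_types <- vapply(items, `[[`, character(1), "item_type")
  composition <- dplyr::count(tibble::tibble(item_type = item_types),
                              .data$item_type, name = "n")
  structure(
    list(items = items, composition = composition,
         bank_version = obj$bank_version, seed = as.integer(obj$seed),
         reference = reference),
    class = "item_pool"
  )
}
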