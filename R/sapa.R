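# Planned-missingness ("synthetic aperture") administration designs and
# synthetic response data: each examinee sees a small random subset of the
# pool, so item-level statistics rest on pairwise co-administrations.

#' Default items-per-person distribution
#'
#' Echoes the reported administration pattern of the original data
#' collection, where roughly 45% of examinees answered a single rotation
#' item and 97% were administered three or fewer.
#'
#' @return Named numeric vector: names are item counts, values
#'   probabilities.
#' @export
sapa_count_dist <- function() {
  c(`1` = 0.45, `2` = 0.27, `3` = 0.25, `6` = 0.03)
}

#' Draw a planned-missingness administration design
#'
#' Per-person item counts are i.i.d. from `dist`; the administered items
#' are then a uniform draw without replacement from the pool.
#'
#' @param n_persons,n_items Population and pool sizes.
#' @param dist Named probability vector over items-per-person counts; must
#'   sum to 1 with every count between 1 and `n_items`.
#' @param seed Integer seed; the design is reproducible from it.
#' @return A `sapa_design` object with `administrations` (long tibble
#'   `person_id`, `item_id`), `counts` (per person), and the settings.
#' @export
sapa_design <- function(n_persons, n_items, dist = sapa_count_dist(),
                        seed = 1L) {
  counts_allowed <- as.integer(names(dist))
  if (is.null(names(dist)) || any(is.na(counts_allowed)) ||
      abs(sum(dist) - 1) > 1e-8 || any(dist < 0) ||
      any(counts_allowed < 1L) || any(counts_allowed > n_items)) {
    stop("`dist` must be a probability vector named by counts in 1..n_items.",
         call. = FALSE)
  }
  item_ids <- sprintf("it%02d", seq_len(n_items))
  drawn <- withr::with_seed(seed, {
    k <- counts_allowed[sample.int(length(counts_allowed), n_persons,
                                   replace = TRUE, prob = dist)]
    items <- unlist(lapply(k, function(ki) sample.int(n_items, ki)))
    list(k = k, items = items)
  })
  structure(
    list(
      administrations = tibble::tibble(
        person_id = rep(sprintf("p%d", seq_len(n_persons)), drawn$k),
        item_id = item_ids[drawn$items]
      ),
      counts = tibble::tibble(person_id = sprintf("p%d", seq_len(n_persons)),
                              n_items = as.integer(drawn$k)),
      n_persons = as.integer(n_persons),
      n_items = as.integer(n_items),
      item_ids = item_ids,
      dist = dist,
      seed = as.integer(seed)
    ),
    class = "sapa_design"
  )
}

#' @export
print.sapa_design <- function(x, ...) {
  cat("<sapa_design>", x$n_persons, "persons x", x$n_items, "items, ",
      nrow(x$administrations), "administrations, seed", x$seed, "\n")
  invisible(x)
}

#' Pairwise administration counts
#'
#' @param design A [sapa_design()].
#' @return A symmetric items x items integer matrix; the diagonal holds
#'   per-item administration totals, off-diagonal entries the number of
#'   persons administered both items.
#' @export
pairwise_counts <- function(design) {
  stopifnot(inherits(design, "sapa_design"))
  adm <- design$administrations
  M <- Matrix::sparseMatrix(
    i = match(adm$person_id, unique(adm$person_id)),
    j = match(adm$item_id, design$item_ids),
    x = 1,
    dims = c(length(unique(adm$person_id)), design$n_items)
  )
  counts <- as.matrix(Matrix::crossprod(M))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(design$item_ids, design$item_ids)
  counts
}

#' Item pairs below the pairwise-administration threshold
#'
#' The original protocol kept administering items until every pair had at
#' least 500 joint administrations; this reports the pairs still below a
#' threshold, ascending by count.
#'
#' @param counts A pairwise count matrix from [pairwise_counts()].
#' @param threshold Minimum acceptable joint count (default 500).
#' @return Tibble `item_i`, `item_j`, `n` for pairs with `n < threshold`.
#' @export
min_pairwise_filter <- function(counts, threshold = 500L) {
  idx <- which(lower.tri(counts) & counts < threshold, arr.ind = TRUE)
  out <- tibble::tibble(
    item_i = rownames(counts)[idx[, "row"]],
    item_j = colnames(counts)[idx[, "col"]],
    n = counts[idx]
  )
  dplyr::arrange(out, .data$n, .data$item_i, .data$item_j)
}

#' Simulate 2PL responses under an administration design
#'
#' Administered cells are Bernoulli draws with the 2PL success probability
#' at the person's trait value; everything else stays missing.
#'
#' @param design A [sapa_design()].
#' @param params Parameter tibble (`item_id`, `a`, `b`) covering the pool.
#' @param thetas Optional trait values (length `n_persons`); drawn N(0,1)
#'   from `seed` when omitted.
#' @param seed Integer seed.
#' @return Long tibble `person_id`, `item_id`, `response`, with the drawn
#'   `thetas` attached as an attribute of the same name.
#' @export
simulate_responses <- function(design, params, thetas = NULL, seed = 1L) {
  stopifnot(inherits(design, "sapa_design"))
  missing_par <- setdiff(design$item_ids, params$item_id)
  if (length(missing_par)) {
    stop("missing parameters for item(s): ",
         paste(utils::head(missing_par, 5L), collapse = ", "), call. = FALSE)
  }
  adm <- design$administrations
  person_ids <- design$counts$person_id
  withr::with_seed(seed, {
    if (is.null(thetas)) thetas <- stats::rnorm(design$n_persons)
    if (length(thetas) != design$n_persons) {
      stop("`thetas` must have length n_persons.", call. = FALSE)
    }
    th <- thetas[match(adm$person_id, person_ids)]
    p <- params[match(adm$item_id, params$item_id), ]
    pr <- prob_2pl(th, p$a, p$b)
    resp <- stats::rbinom(length(pr), 1L, pr)
  })
  out <- tibble::tibble(person_id = adm$person_id, item_id = adm$item_id,
                        response = as.integer(resp))
  attr(out, "thetas") <- stats::setNames(thetas, person_ids)
  out
}

#' Complete-data design covering every person x item cell
#'
#' Convenience for fully-crossed simulations (e.g. parameter recovery).
#'
#' @inheritParams sapa_design
#' @return A `sapa_design` whose mask administers every item to everyone.
#' @export
complete_design <- function(n_persons, n_items) {
  item_ids <- sprintf("it%02d", seq_len(n_items))
  structure(
    list(
      administrations = tibble::tibble(
        person_id = rep(sprintf("p%d", seq_len(n_persons)), each = n_items),
        item_id = rep(item_ids, n_persons)
      ),
      counts = tibble::tibble(person_id = sprintf("p%d", seq_len(n_persons)),
                              n_items = n_items),
      n_persons = as.integer(n_persons),
      n_items = as.integer(n_items),
      item_ids = item_ids,
      dist = stats::setNames(1, n_items),
      seed = NA_integer_
    ),
    class = "sapa_design"
  )
}

#' Specify a bifactor population model
#'
#' Latent structure: one general factor plus one of four group factors per
#' item, all orthogonal standard normals; an item's continuous response is
#' `g * F_general + s * F_group + sqrt(1 - g^2 - s^2) * e`, optionally
#' dichotomised at a per-item threshold.
#'
#' @param general General-factor loading per item.
#' @param group Group assignment per item (factor/character, up to four
#'   levels mirroring the rotation-demand types).
#' @param group_loading Group-factor loading per item.
#' @param threshold Dichotomisation threshold per item (default 0).
#' @param item_id Optional ids.
#' @return A `bifactor_spec` tibble.
#' @export
bifactor_spec <- function(general, group, group_loading,
                          threshold = 0, item_id = NULL) {
  n <- length(general)
  spec <- tibble::tibble(
    item_id = item_id %||% sprintf("it%02d", seq_len(n)),
    general = general,
    group = as.character(group),
    group_loading = rep_len(group_loading, n),
    threshold = rep_len(threshold, n)
  )
  bad <- spec$general^2 + spec$group_loading^2 >= 1
  if (any(bad)) {
    stop("inadmissible loadings (g^2 + s^2 >= 1) for item(s): ",
         paste(spec$item_id[bad], collapse = ", "), call. = FALSE)
  }
  class(spec) <- c("bifactor_spec", class(spec))
  spec
}

#' Model-implied correlation matrix of a bifactor population
#'
#' @param spec A [bifactor_spec()].
#' @return Items x items correlation matrix (continuous scale).
#' @export
bifactor_sigma <- function(spec) {
  g <- spec$general
  s <- spec$group_loading
  same <- outer(spec$group, spec$group, `==`)
  R <- outer(g, g) + outer(s, s) * same
  diag(R) <- 1
  dimnames(R) <- list(spec$item_id, spec$item_id)
  R
}

#' Simulate complete data from a bifactor population
#'
#' @param n_persons Number of rows to draw.
#' @param spec A [bifactor_spec()].
#' @param seed Integer seed.
#' @param dichotomize Threshold the continuous responses into 0/1.
#' @return A tibble (persons x items); continuous, or 0/1 integers when
#'   `dichotomize` is set.
#' @export
simulate_bifactor <- function(n_persons, spec, seed = 1L, dichotomize = FALSE) {
  stopifnot(inherits(spec, "bifactor_spec"))
  groups <- unique(spec$group)
  X <- withr::with_seed(seed, {
    Fg <- stats::rnorm(n_persons)
    Fs <- matrix(stats::rnorm(n_persons * length(groups)), n_persons)
    E <- matrix(stats::rnorm(n_persons * nrow(spec)), n_persons)
    uniq <- sqrt(1 - spec$general^2 - spec$group_loading^2)
    vapply(seq_len(nrow(spec)), function(j) {
      spec$general[j] * Fg +
        spec$group_loading[j] * Fs[, match(spec$group[j], groups)] +
        uniq[j] * E[, j]
    }, numeric(n_persons))
  })
  colnames(X) <- spec$item_id
  if (dichotomize) {
    X <- vapply(seq_len(ncol(X)), function(j) {
      as.integer(X[, j] > spec$threshold[j])
    }, integer(n_persons))
    colnames(X) <- spec$item_id
  }
  tibble::as_tibble(X)
}
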