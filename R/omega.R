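# Hierarchical omega: general-factor saturation of a composite after a
# Schmid-Leiman transformation, with omega total and coefficient alpha.

#' Omega reliability decomposition
#'
#' Factors `R` (minres, oblimin), extracts a general factor by
#' Schmid-Leiman, and reports general-factor saturation. With
#' `Vt = sum(R)` (unit diagonal): `omega_h = (sum g_i)^2 / Vt`,
#' `omega_t = 1 - sum(psi_i) / Vt`, and
#' `alpha = J/(J-1) * (1 - J/Vt)`. With one factor the single factor is
#' the general factor.
#'
#' @param R Correlation matrix (complete). Indefinite input is smoothed
#'   first via [smooth_correlation()].
#' @param n_factors Number of lower-order factors (default 4, mirroring
#'   the four rotation-demand item types).
#' @param seed Seed for the factor-analysis restarts.
#' @return An `omega_result`: `omega_h`, `omega_t`, `alpha`, `per_group`
#'   (tibble of per-group-factor omegas), and the Schmid-Leiman solution.
#' @export
omega <- function(R, n_factors = 4L, seed = 1L) {
  R <- as.matrix(R)
  J <- ncol(R)
  if (is.null(colnames(R))) {
    dimnames(R) <- list(sprintf("it%02d", seq_len(J)),
                        sprintf("it%02d", seq_len(J)))
  }
  Vt <- sum(R)
  if (Vt <= 0) stop("total composite variance must be positive.", call. = FALSE)
  R <- smooth_correlation(R)

  sol <- efa_minres(R, n_factors, rotation = if (n_factors > 1L) "oblimin" else "none",
                    seed = seed)
  if (n_factors == 1L) {
    general <- as.vector(sol$loadings)
    names(general) <- colnames(R)
    group <- matrix(0, J, 1L, dimnames = list(colnames(R), "F1"))
    sl <- list(general = general, group = group,
               higher_order = c(F1 = 1), loadings = sol$loadings,
               factor_correlations = sol$factor_correlations,
               uniquenesses = sol$uniquenesses)
  } else {
    sl <- schmid_leiman(sol)
  }

  omega_h <- sum(sl$general)^2 / Vt
  omega_t <- 1 - sum(sol$uniquenesses) / Vt
  alpha <- (J / (J - 1)) * (1 - J / Vt)

  per_group <- purrr::map_dfr(seq_len(ncol(sl$group)), function(j) {
    items <- abs(sl$group[, j]) > 1e-8 &
      max.col(abs(sl$loadings), ties.method = "first") == j
    if (!any(items)) {
      return(tibble::tibble(factor = colnames(sl$group)[j] %||% paste0("F", j),
                            n_items = 0L, omega_group = NA_real_))
    }
    Vg <- sum(R[items, items])
    tibble::tibble(
      factor = colnames(sl$group)[j] %||% paste0("F", j),
      n_items = sum(items),
      omega_group = (sum(sl$general[items])^2 + sum(sl$group[items, j])^2) / Vg
    )
  })

  structure(
    list(omega_h = omega_h, omega_t = omega_t, alpha = alpha,
         per_group = per_group, schmid_leiman = sl, n_factors = n_factors,
         n_items = J),
    class = "omega_result"
  )
}

#' @export
print.omega_result <- function(x, ...) {
  cat("<omega_result>", x$n_items, "items,", x$n_factors, "factors\n")
  cat(sprintf("  omega_h = %.3f  omega_t = %.3f  alpha = %.3f\n",
              x$omega_h, x$omega_t, x$alpha))
  invisible(x)
}

#' @rdname omega
#' @param x An `omega_result`.
#' @param ... Unused.
#' @export
glance.omega_result <- function(x, ...) {
  tibble::tibble(omega_h = x$omega_h, omega_t = x$omega_t, alpha = x$alpha,
                 n_factors = x$n_factors, n_items = x$n_items)
}

#' @rdname omega
#' @export
tidy.omega_result <- function(x, ...) {
  tibble::tibble(
    item = names(x$schmid_leiman$general),
    general = unname(x$schmid_leiman$general),
    uniqueness = unname(x$schmid_leiman$uniquenesses)
  ) |>
    dplyr::bind_cols(tibble::as_tibble(x$schmid_leiman$group))
}

#' Population omega_h implied by a bifactor specification
#'
#' Closed form on the continuous scale: `(sum g_i)^2 / sum(Sigma)` with
#' `Sigma` the model-implied correlation matrix.
#'
#' @param spec A [bifactor_spec()].
#' @return Scalar population omega hierarchical.
#' @export
population_omega_h <- function(spec) {
  sum(spec$general)^2 / sum(bifactor_sigma(spec))
}

#' Coefficient alpha from raw scores
#'
#' Classical variance-ratio definition, used as an independent check of
#' the correlation-based formula.
#'
#' @param X Complete numeric persons x items data.
#' @return Cronbach's alpha.
#' @export
alpha_from_scores <- function(X) {
  X <- as.matrix(X)
  J <- ncol(X)
  (J / (J - 1)) * (1 - sum(apply(X, 2L, stats::var)) / stats::var(rowSums(X)))
}

#' Do items load on their own type's factor?
#'
#' Fits a `n_factors` oblimin solution and asks, for the best assignment
#' of factors to item-type labels, what fraction of items have their
#' largest absolute pattern loading on the factor matched to their own
#' type.
#'
#' @param R Correlation matrix.
#' @param item_type One label per item; the number of distinct labels must
#'   equal `n_factors`.
#' @param n_factors Number of factors (default 4).
#' @param seed Seed for the factor-analysis restarts.
#' @return A list: `fraction` matched, `assignment` (factor -> type),
#'   `dominant` tibble per item.
#' @export
item_type_factor_check <- function(R, item_type, n_factors = 4L, seed = 1L) {
  R <- as.matrix(R)
  if (length(item_type) != ncol(R)) {
    stop("`item_type` must have one label per item.", call. = FALSE)
  }
  types <- sort(unique(item_type))
  if (length(types) != n_factors) {
    stop("need exactly ", n_factors, " distinct item-type labels, got ",
         length(types), ".", call. = FALSE)
  }
  sol <- efa_minres(smooth_correlation(R), n_factors, rotation = "oblimin",
                    seed = seed)
  dominant <- max.col(abs(sol$loadings), ties.method = "first")

  perms <- permutations_of(seq_len(n_factors))
  best <- NULL
  for (p in perms) {
    frac <- mean(types[p[dominant]] == item_type)
    if (is.null(best) || frac > best$fraction) {
      best <- list(fraction = frac, perm = p)
    }
  }
  list(
    fraction = best$fraction,
    assignment = tibble::tibble(factor = colnames(sol$loadings),
                                item_type = types[best$perm]),
    dominant = tibble::tibble(
      item = colnames(R),
      item_type = item_type,
      dominant_factor = colnames(sol$loadings)[dominant],
      matched = types[best$perm[dominant]] == item_type
    ),
    solution = sol
  )
}

permutations_of <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}
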