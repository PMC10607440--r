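# BISCUIT: Best Items Scales that are Cross validated, Unit weighted,
# Informative, and Transparent. Predictors are ranked by their pairwise-
# complete correlation with the criterion within each training fold,
# selected by an absolute-correlation cut or a top-n rule, unit weighted
# by the sign of the training correlation, and evaluated on the held-out
# fold.

#' Rank predictors by criterion correlation
#'
#' Pairwise-complete correlations of every predictor with the criterion,
#' ordered by absolute value (descending) with deterministic ties broken
#' by predictor name. Zero-variance predictors get `NA`.
#'
#' @param data A data frame; all columns except `criterion` are treated as
#'   predictors. Missing values allowed throughout.
#' @param criterion Name of the criterion column.
#' @return Tibble `predictor`, `r`, `n` (pairwise sample size), ranked.
#' @export
rank_predictors <- function(data, criterion) {
  if (!criterion %in% names(data)) {
    stop("criterion column `", criterion, "` not found.", call. = FALSE)
  }
  y <- data[[criterion]]
  if (stats::var(y, na.rm = TRUE) == 0 || all(is.na(y))) {
    stop("criterion has no variance.", call. = FALSE)
  }
  X <- data[setdiff(names(data), criterion)]
  if (ncol(X) < 1L) stop("need at least one predictor.", call. = FALSE)
  out <- purrr::map_dfr(names(X), function(nm) {
    x <- X[[nm]]
    both <- !is.na(x) & !is.na(y)
    r <- if (sum(both) < 3L || stats::var(x[both]) == 0) {
      NA_real_
    } else {
      stats::cor(x[both], y[both])
    }
    tibble::tibble(predictor = nm, r = r, n = sum(both))
  })
  dplyr::arrange(out, dplyr::desc(abs(.data$r)), .data$predictor)
}

#' Unit-weighted composite scores
#'
#' @param data Data frame of predictors (missing allowed).
#' @param key Named vector of +1/-1/0 weights over (a subset of) the
#'   predictor columns; must contain at least one nonzero weight.
#' @return Numeric composite per row: mean of the sign-adjusted observed
#'   keyed predictors; `NA` when none are observed.
#' @export
unit_weight_score <- function(data, key) {
  key <- key[key != 0]
  if (length(key) == 0L) stop("`key` has no nonzero weights.", call. = FALSE)
  missing_cols <- setdiff(names(key), names(data))
  if (length(missing_cols)) {
    stop("key names absent from data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(data[names(key)])
  Xs <- sweep(X, 2L, key, `*`)
  n_obs <- rowSums(!is.na(Xs))
  out <- rowMeans(Xs, na.rm = TRUE)
  out[n_obs == 0L] <- NA_real_
  out
}

#' Cross-validated best-scales construction (BISCUIT)
#'
#' k-fold cross-validation (folds stratified on criterion deciles): within
#' each training fold predictors are ranked by pairwise-complete
#' correlation with the criterion and selected by the rule; the selected
#' predictors are unit weighted by the sign of their training correlation
#' and the composite is correlated with the criterion on the held-out
#' fold. Per-predictor selection frequency and the mean/SD of the
#' training correlation across selected folds are reported, alongside the
#' final key (the rule applied to the full sample) and the cross-validated
#' composite-criterion correlation.
#'
#' @param data Data frame with the criterion column and predictors.
#' @param criterion Name of the criterion column.
#' @param k Number of folds (>= 2, default 10).
#' @param selection `"abs_r_cut"` (keep predictors with `|r| >= r_cut`;
#'   a fold where none pass selects nothing and contributes no composite)
#'   or `"top_n"`.
#' @param r_cut Absolute-correlation cut (default 0.2).
#' @param n_items Number kept under `"top_n"`.
#' @param seed Seed for fold assignment.
#' @return A `biscuit` object.
#' @export
best_scales_cv <- function(data, criterion, k = 10L,
                           selection = c("abs_r_cut", "top_n"),
                           r_cut = 0.2, n_items = 10L, seed = 1L) {
  selection <- match.arg(selection)
  if (k < 2L) stop("`k` must be at least 2.", call. = FALSE)
  if (selection == "abs_r_cut" && (r_cut <= 0 || r_cut >= 1)) {
    stop("`r_cut` must lie in (0, 1).", call. = FALSE)
  }
  y_all <- data[[criterion]]
  keep <- !is.na(y_all)
  data <- data[keep, ]
  y <- y_all[keep]
  n <- nrow(data)
  if (n < 10L * k) {
    stop("need at least 10 * k rows with an observed criterion (", 10L * k,
         "), got ", n, ".", call. = FALSE)
  }
  predictors <- setdiff(names(data), criterion)

  # fold assignment stratified on criterion deciles
  fold <- withr::with_seed(seed, {
    dec <- cut(rank(y, ties.method = "first"), breaks = 10L, labels = FALSE)
    f <- integer(n)
    for (d in unique(dec)) {
      idx <- which(dec == d)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })

  select_rule <- function(ranked) {
    ranked <- dplyr::filter(ranked, !is.na(.data$r))
    if (selection == "top_n") {
      return(utils::head(ranked, n_items))
    }
    dplyr::filter(ranked, abs(.data$r) >= r_cut)
  }

  fold_results <- list()
  cv_r <- numeric(0)
  used_folds <- 0L
  for (f in seq_len(k)) {
    train <- data[fold != f, ]
    valid <- data[fold == f, ]
    if (stats::var(train[[criterion]], na.rm = TRUE) == 0 ||
        stats::var(valid[[criterion]], na.rm = TRUE) == 0) {
      warning("fold ", f, " skipped: criterion has no variance.", call. = FALSE)
      next
    }
    used_folds <- used_folds + 1L
    ranked <- rank_predictors(train, criterion)
    sel <- select_rule(ranked)
    if (nrow(sel) == 0L) next
    key <- stats::setNames(sign(sel$r), sel$predictor)
    comp <- unit_weight_score(valid[predictors], key)
    ok <- !is.na(comp)
    cv_r <- c(cv_r, stats::cor(comp[ok], valid[[criterion]][ok]))
    fold_results[[f]] <- dplyr::mutate(sel, fold = f)
  }
  per_fold <- dplyr::bind_rows(fold_results)
  if (nrow(per_fold) == 0L) {
    per_fold <- tibble::tibble(predictor = character(0), r = numeric(0),
                               n = integer(0), fold = integer(0))
  }
  report <- per_fold |>
    dplyr::group_by(.data$predictor) |>
    dplyr::summarise(
      frequency = dplyr::n(),
      mean_r = mean(.data$r),
      sd_r = ifelse(dplyr::n() > 1L, stats::sd(.data$r), 0),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$frequency), dplyr::desc(abs(.data$mean_r)))

  # final key: the selection rule applied to the full sample
  final_sel <- select_rule(rank_predictors(data, criterion))
  final_key <- stats::setNames(rep(0, length(predictors)), predictors)
  in_sample_r <- NA_real_
  if (nrow(final_sel) > 0L) {
    final_key[final_sel$predictor] <- sign(final_sel$r)
    comp_all <- unit_weight_score(data[predictors], final_key)
    ok <- !is.na(comp_all)
    in_sample_r <- stats::cor(comp_all[ok], y[ok])
  }

  structure(
    list(
      report = report,
      key = final_key,
      cv_r = if (length(cv_r)) mean(cv_r) else NA_real_,
      cv_r_folds = cv_r,
      in_sample_r = in_sample_r,
      k = used_folds,
      n = n,
      criterion = criterion,
      selection = selection,
      r_cut = if (selection == "abs_r_cut") r_cut else NA_real_,
      n_items = if (selection == "top_n") n_items else NA_integer_,
      seed = as.integer(seed)
    ),
    class = "biscuit"
  )
}

#' @export
print.biscuit <- function(x, digits = 2, ...) {
  cat("BISCUIT best scales for `", x$criterion, "` (k = ", x$k,
      ", n = ", x$n, ")\n", sep = "")
  cat(sprintf("cross-validated composite r = %.3f (in-sample %.3f)\n\n",
              x$cv_r, x$in_sample_r))
  hdr <- sprintf("%-24s %9s %16s %18s", "Predictor", "Frequency",
                 "Mean Correlation", "Standard Deviation")
  cat(hdr, "\n")
  for (i in seq_len(nrow(x$report))) {
    cat(sprintf("%-24s %9d %16.2f %18.2f\n",
                x$report$predictor[i], x$report$frequency[i],
                round(x$report$mean_r[i], digits),
                round(x$report$sd_r[i], digits)))
  }
  invisible(x)
}

#' @rdname best_scales_cv
#' @param x A `biscuit` object.
#' @param ... Unused.
#' @return For `tidy()`: the per-predictor report (frequency out of k,
#'   mean and SD of the training correlation, final key weight).
#' @export
tidy.biscuit <- function(x, ...) {
  dplyr::mutate(x$report, key = unname(x$key[.data$predictor]))
}

#' @rdname best_scales_cv
#' @export
glance.biscuit <- function(x, ...) {
  tibble::tibble(
    k = x$k, n = x$n, cv_r = x$cv_r, in_sample_r = x$in_sample_r,
    n_selected = sum(x$key != 0), selection = x$selection
  )
}

#' @rdname best_scales_cv
#' @param object A `biscuit` object.
#' @export
autoplot.biscuit <- function(object, ...) {
  d <- tidy(object)
  d$predictor <- factor(d$predictor,
                        levels = rev(d$predictor[order(-d$frequency,
                                                       -abs(d$mean_r))]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frequency, y = .data$predictor)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = paste0("Folds selected (of ", object$k, ")"),
                  y = NULL)
}
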