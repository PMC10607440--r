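# Correlation estimation under planned missingness: pairwise-complete
# Pearson and maximum-likelihood tetrachoric estimates, with pairwise
# sample-size accounting and eigenvalue smoothing for the non-PSD
# matrices pairwise estimation routinely produces.

#' Convert long responses to a persons x items matrix
#'
#' @param responses Long tibble (`person_id`, `item_id`, `response`).
#' @return Numeric matrix with `NA` for unadministered cells.
#' @export
as_response_matrix <- function(responses) {
  responses_to_matrix(responses)
}

# Standard-normal bivariate CDF P(X <= h, Y <= k) by fixed Gauss-Legendre
# quadrature on x in [-8, h].
pbvnorm <- function(h, k, rho) {
  if (rho == 0) return(stats::pnorm(h) * stats::pnorm(k))
  if (h <= -8) return(0)
  gl <- pracma::gaussLegendre(48, -8, h)
  sum(gl$w * stats::dnorm(gl$x) *
        stats::pnorm((k - rho * gl$x) / sqrt(1 - rho^2)))
}

#' Maximum-likelihood tetrachoric correlation from a 2x2 table
#'
#' Estimates the correlation of a latent bivariate normal dichotomised at
#' thresholds set from the table margins. Zero cells receive a 0.5
#' continuity correction.
#'
#' @param tab 2x2 count matrix; rows index the first item's 0/1, columns
#'   the second item's 0/1.
#' @param correct Continuity correction added to empty cells.
#' @return The ML correlation estimate (scalar).
#' @export
tetrachoric <- function(tab, correct = 0.5) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0)) {
    stop("`tab` must be a nonnegative 2x2 count table.", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate margins: one variable is constant.", call. = FALSE)
  }
  if (any(tab == 0)) tab <- tab + correct
  n <- sum(tab)
  # margins: P(first = 1), P(second = 1); thresholds on the latent scale
  p1 <- sum(tab[2L, ]) / n
  p2 <- sum(tab[, 2L]) / n
  t1 <- stats::qnorm(1 - p1)
  t2 <- stats::qnorm(1 - p2)
  negll <- function(rho) {
    p11 <- pbvnorm(-t1, -t2, rho) # P(first = 1, second = 1)
    pr <- c(p11,
            (1 - p1) - (p2 - p11),  # (0,0): 1 - p1 - p2 + p11
            p2 - p11,               # (0,1)
            p1 - p11)               # (1,0)
    pr <- pmax(pr, 1e-12)
    -(tab[2L, 2L] * log(pr[1L]) + tab[1L, 1L] * log(pr[2L]) +
        tab[1L, 2L] * log(pr[3L]) + tab[2L, 1L] * log(pr[4L]))
  }
  stats::optimize(negll, c(-0.999, 0.999), tol = 1e-6)$minimum
}

#' Pairwise-complete correlation matrix under missingness
#'
#' Each entry is computed over the rows where both items are observed —
#' the natural estimator for planned-missingness data, where any given
#' item pair is co-administered to a modest subsample. Entries whose
#' pairwise n falls below `min_n` are set to `NA` and reported.
#'
#' @param data Wide numeric data (tibble or matrix), `NA` = missing; for
#'   `method = "tetrachoric"` entries must be 0/1.
#' @param method `"pearson"` or `"tetrachoric"`.
#' @param min_n Minimum pairwise sample size to retain an entry.
#' @return A `pairwise_cor` object: `R`, `n_pairs`, `method`, `dropped`
#'   (tibble of suppressed or inestimable pairs).
#' @export
pairwise_correlation <- function(data, method = c("pearson", "tetrachoric"),
                                 min_n = 0L) {
  method <- match.arg(method)
  X <- as.matrix(data)
  if (ncol(X) < 2L) stop("need at least two items.", call. = FALSE)
  J <- ncol(X)
  obs <- !is.na(X)
  n_pairs <- crossprod(obs)
  storage.mode(n_pairs) <- "integer"

  zero_var <- vapply(seq_len(J), function(j) {
    v <- X[obs[, j], j]
    length(v) == 0L || stats::var(v) == 0
  }, logical(1))
  if (any(zero_var)) {
    warning("item(s) with zero observed variance: ",
            paste(colnames(X)[zero_var], collapse = ", "), call. = FALSE)
  }

  R <- diag(1, J)
  dimnames(R) <- dimnames(n_pairs) <- list(colnames(X), colnames(X))
  dropped <- list()
  for (i in seq_len(J - 1L)) {
    for (j in (i + 1L):J) {
      both <- obs[, i] & obs[, j]
      reason <- NULL
      r <- NA_real_
      if (n_pairs[i, j] < min_n) {
        reason <- "below min_n"
      } else if (zero_var[i] || zero_var[j] || sum(both) < 2L) {
        reason <- "zero variance"
      } else if (method == "pearson") {
        r <- stats::cor(X[both, i], X[both, j])
        if (is.na(r)) reason <- "zero variance"
      } else {
        tab <- table(factor(X[both, i], levels = 0:1),
                     factor(X[both, j], levels = 0:1))
        if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
          reason <- "degenerate margins"
        } else {
          r <- tetrachoric(tab)
        }
      }
      R[i, j] <- R[j, i] <- r
      if (!is.null(reason)) {
        dropped[[length(dropped) + 1L]] <-
          tibble::tibble(item_i = colnames(X)[i], item_j = colnames(X)[j],
                         n = n_pairs[i, j], reason = reason)
      }
    }
  }
  structure(
    list(R = R, n_pairs = n_pairs, method = method,
         dropped = dplyr::bind_rows(dropped)),
    class = "pairwise_cor"
  )
}

#' @export
print.pairwise_cor <- function(x, ...) {
  cat("<pairwise_cor>", ncol(x$R), "items,", x$method,
      "; pairwise n in [", min(x$n_pairs[lower.tri(x$n_pairs)]), ",",
      max(x$n_pairs[lower.tri(x$n_pairs)]), "];",
      nrow(x$dropped) %||% 0L, "entries dropped\n")
  invisible(x)
}

#' @rdname pairwise_correlation
#' @param x A `pairwise_cor` object.
#' @param ... Unused.
#' @return For `tidy()`: long tibble `item_i`, `item_j`, `r`, `n`.
#' @export
tidy.pairwise_cor <- function(x, ...) {
  idx <- which(lower.tri(x$R), arr.ind = TRUE)
  tibble::tibble(
    item_i = rownames(x$R)[idx[, "row"]],
    item_j = colnames(x$R)[idx[, "col"]],
    r = x$R[idx],
    n = x$n_pairs[idx]
  )
}

#' Smooth a correlation matrix to positive semi-definiteness
#'
#' Pairwise estimation can produce indefinite matrices; eigenvalues below
#' `eps` are clipped and the result rescaled to unit diagonal.
#'
#' @param R Symmetric correlation matrix, no missing entries.
#' @param eps Eigenvalue floor.
#' @return A positive semi-definite correlation matrix.
#' @export
smooth_correlation <- function(R, eps = 1e-8) {
  if (anyNA(R)) stop("cannot smooth a matrix with missing entries.", call. = FALSE)
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eps) return(R)
  v <- pmax(e$values, eps)
  S <- e$vectors %*% (v * t(e$vectors))
  S <- stats::cov2cor(S)
  dimnames(S) <- dimnames(R)
  S
}
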