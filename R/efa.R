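# Minres (ULS) exploratory factor analysis, oblimin rotation by gradient
# projection, and the Schmid-Leiman transformation into orthogonal
# general + group factors.

# Loadings from the top-k eigenpairs of R with uniquenesses psi removed.
eigen_loadings <- function(R, psi, k) {
  M <- R
  diag(M) <- diag(R) - psi
  e <- eigen(M, symmetric = TRUE)
  d <- pmax(e$values[seq_len(k)], 0)
  L <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(d), k)
  # sign convention: each factor's loading sum nonnegative
  for (j in seq_len(k)) if (sum(L[, j]) < 0) L[, j] <- -L[, j]
  L
}

uls_objective <- function(psi, R, k) {
  M <- R
  diag(M) <- diag(R) - psi
  e <- eigen(M, symmetric = TRUE)
  d <- e$values
  resid_d <- d[-seq_len(k)]
  # ||M - LL'||^2 / 2 = sum of squared discarded eigenvalues (clip negatives
  # retained in L at zero)
  kept <- pmin(d[seq_len(k)], Inf)
  extra <- sum(pmin(kept, 0)^2)
  (sum(resid_d^2) + extra) / 2
}

uls_gradient <- function(psi, R, k) {
  L <- eigen_loadings(R, psi, k)
  M <- R
  diag(M) <- diag(R) - psi
  E <- M - tcrossprod(L)
  -diag(E)
}

# Quartimin criterion (oblimin with gamma = 0) and its gradient.
quartimin_vgq <- function(L) {
  L2 <- L^2
  k <- ncol(L)
  N <- matrix(1, k, k) - diag(k)
  X <- L2 %*% N
  list(f = sum(L2 * X) / 4, Gq = L * X)
}

# Gradient-projection oblique rotation (Bernaards & Jennrich).
gpf_oblimin <- function(A, max_iter = 1000L, tol = 1e-10) {
  k <- ncol(A)
  Tmat <- diag(k)
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  vgq <- quartimin_vgq(L)
  f <- vgq$f
  G <- -t(t(L) %*% vgq$Gq %*% Ti)
  al <- 1
  for (iter in seq_len(max_iter)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < tol) break
    al <- 2 * al
    for (half in 1:20) {
      X <- Tmat - al * Gp
      v <- 1 / sqrt(colSums(X^2))
      Tt <- X %*% diag(v, k)
      Ti <- solve(Tt)
      L <- A %*% t(Ti)
      vgq <- quartimin_vgq(L)
      if (vgq$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    f <- vgq$f
    G <- -t(t(L) %*% vgq$Gq %*% Ti)
  }
  list(loadings = L, Phi = t(Tmat) %*% Tmat, f = f, iterations = iter)
}

#' Minres exploratory factor analysis
#'
#' Unweighted least squares: uniquenesses are chosen (quasi-Newton with
#' analytic gradient, multiple seeded restarts) to minimise the squared
#' off-diagonal residuals of `R`, with loadings from the reduced matrix's
#' leading eigenpairs. Optional oblimin (quartimin) rotation by gradient
#' projection.
#'
#' @param R Correlation matrix (complete; smooth first if indefinite).
#' @param n_factors Number of factors; must respect the Ledermann bound.
#' @param rotation `"oblimin"` or `"none"`.
#' @param n_restarts Random restarts around the squared-multiple-
#'   correlation start.
#' @param seed Seed for the restart perturbations.
#' @return A `factor_solution`: `loadings` (pattern), `factor_correlations`
#'   (`Phi`), `uniquenesses`, `communalities`, the fit value, and for
#'   rotated solutions the unrotated loadings.
#' @export
efa_minres <- function(R, n_factors, rotation = c("oblimin", "none"),
                       n_restarts = 10L, seed = 1L) {
  rotation <- match.arg(rotation)
  R <- as.matrix(R)
  J <- ncol(R)
  if (n_factors < 1L) stop("`n_factors` must be at least 1.", call. = FALSE)
  if ((J - n_factors)^2 < J + n_factors^2) {
    stop("n_factors = ", n_factors, " exceeds the Ledermann bound for ",
         J, " items.", call. = FALSE)
  }
  e_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (e_min < -1e-6) {
    stop("R is indefinite; smooth it first (see smooth_correlation()).",
         call. = FALSE)
  }

  smc <- tryCatch(1 - 1 / diag(solve(R)), error = function(e) rep(0.5, J))
  start0 <- pmin(pmax(1 - smc, 0.05), 0.95)
  starts <- withr::with_seed(seed, {
    c(list(start0), lapply(seq_len(max(n_restarts - 1L, 0L)), function(i) {
      pmin(pmax(start0 * stats::runif(J, 0.5, 1.5), 0.01), 0.99)
    }))
  })
  best <- NULL
  for (st in starts) {
    fit <- stats::optim(st, uls_objective, uls_gradient, R = R, k = n_factors,
                        method = "L-BFGS-B", lower = 1e-3, upper = 1,
                        control = list(maxit = 500L, factr = 1e4))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  psi <- best$par
  A <- eigen_loadings(R, psi, n_factors)
  rownames(A) <- colnames(R)

  # a factor with a single salient loading contributes nothing to the
  # off-diagonal fit, so its loading is unidentified; collapse it to zero
  # and return the variance to the item's uniqueness
  for (j in seq_len(n_factors)) {
    salient <- sort(abs(A[, j]), decreasing = TRUE)
    if (length(salient) > 1L && salient[2L] < 1e-6 && salient[1L] > 0) {
      i <- which.max(abs(A[, j]))
      psi[i] <- min(psi[i] + A[i, j]^2, 1)
      A[i, j] <- 0
    }
  }

  if (rotation == "oblimin" && n_factors > 1L) {
    rot <- gpf_oblimin(A)
    loadings <- rot$loadings
    Phi <- rot$Phi
    # order factors by total absolute loading for a stable presentation
    ord <- order(-colSums(abs(loadings)))
    loadings <- loadings[, ord, drop = FALSE]
    Phi <- Phi[ord, ord, drop = FALSE]
    for (j in seq_len(n_factors)) {
      if (sum(loadings[, j]) < 0) {
        loadings[, j] <- -loadings[, j]
        Phi[j, ] <- -Phi[j, ]
        Phi[, j] <- -Phi[, j]
      }
    }
  } else {
    loadings <- A
    Phi <- diag(n_factors)
  }
  colnames(loadings) <- paste0("F", seq_len(n_factors))
  dimnames(Phi) <- list(colnames(loadings), colnames(loadings))
  communality <- rowSums((loadings %*% Phi) * loadings)

  structure(
    list(
      loadings = loadings,
      factor_correlations = Phi,
      uniquenesses = stats::setNames(psi, colnames(R)),
      communalities = stats::setNames(communality, colnames(R)),
      unrotated = A,
      rotation = rotation,
      fit = best$value,
      n_factors = n_factors
    ),
    class = "factor_solution"
  )
}

#' @export
print.factor_solution <- function(x, digits = 3, ...) {
  cat("<factor_solution>", x$n_factors, "factors,", x$rotation,
      "rotation, minres fit", format(x$fit, digits = 3), "\n")
  print(round(x$loadings, digits))
  if (x$n_factors > 1L) {
    cat("factor correlations:\n")
    print(round(x$factor_correlations, digits))
  }
  invisible(x)
}

#' @rdname efa_minres
#' @param x A `factor_solution`.
#' @param ... Unused.
#' @return For `tidy()`: long tibble `item`, `factor`, `loading`.
#' @export
tidy.factor_solution <- function(x, ...) {
  tibble::tibble(
    item = rep(rownames(x$loadings), ncol(x$loadings)),
    factor = rep(colnames(x$loadings), each = nrow(x$loadings)),
    loading = as.vector(x$loadings)
  )
}

#' Schmid-Leiman transformation
#'
#' Re-expresses a correlated-factors solution as one orthogonal general
#' factor plus orthogonal group factors: a higher-order factor is fitted
#' to the factor correlations, each item's general loading is its primary
#' loading times its factor's higher-order loading, and its group loading
#' is the primary loading times `sqrt(1 - gamma^2)`.
#'
#' @param solution A `factor_solution` with at least 2 correlated factors.
#' @return A list: `general` (per item), `group` (items x factors matrix),
#'   `higher_order` (per factor), plus the inputs.
#' @export
schmid_leiman <- function(solution) {
  stopifnot(inherits(solution, "factor_solution"))
  Phi <- solution$factor_correlations
  k <- ncol(Phi)
  if (k < 2L) stop("Schmid-Leiman needs at least 2 factors.", call. = FALSE)
  off <- Phi[lower.tri(Phi)]
  if (any(off <= 0)) {
    stop("factor correlations lack a positive manifold; no higher-order ",
         "factor is defined - treat the factors as orthogonal instead.",
         call. = FALSE)
  }
  gamma <- if (k == 2L) {
    rep(sqrt(Phi[1L, 2L]), 2L)
  } else {
    ho <- efa_minres(Phi, 1L, rotation = "none")
    as.vector(ho$loadings)
  }
  L <- solution$loadings
  general <- as.vector(L %*% gamma)
  group <- sweep(L, 2L, sqrt(pmax(1 - gamma^2, 0)), `*`)
  list(
    general = stats::setNames(general, rownames(L)),
    group = group,
    higher_order = stats::setNames(gamma, colnames(L)),
    loadings = L,
    factor_correlations = Phi,
    uniquenesses = solution$uniquenesses
  )
}
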