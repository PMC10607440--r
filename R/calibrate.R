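# Marginal maximum-likelihood calibration of the 2PL by Bock-Aitkin EM.
#
# The E step evaluates each person's likelihood on a fixed quadrature grid
# over the N(0,1) trait; the M step refits each item's logit intercept and
# slope against the expected counts by Newton-Raphson. Missing responses
# contribute nothing to the likelihood (missing at random by design, as in
# a planned-missingness administration).

responses_to_matrix <- function(responses) {
  if (is.matrix(responses)) {
    if (is.null(rownames(responses))) {
      rownames(responses) <- sprintf("p%d", seq_len(nrow(responses)))
    }
    if (is.null(colnames(responses))) {
      colnames(responses) <- sprintf("it%02d", seq_len(ncol(responses)))
    }
    return(responses)
  }
  need <- c("person_id", "item_id", "response")
  if (!all(need %in% names(responses))) {
    stop("long-format responses need columns person_id, item_id, response.",
         call. = FALSE)
  }
  bad <- !responses$response %in% c(0, 1)
  if (any(bad)) stop("responses must be 0/1.", call. = FALSE)
  persons <- unique(responses$person_id)
  items <- sort(unique(responses$item_id))
  Y <- matrix(NA_real_, length(persons), length(items),
              dimnames = list(as.character(persons), items))
  Y[cbind(match(responses$person_id, persons),
          match(responses$item_id, items))] <- responses$response
  Y
}

# One Newton-Raphson ascent of the expected M-step objective for an item,
# parameterised as logit p = alpha + beta * theta.
mstep_newton <- function(alpha, beta, r, n, nodes, a_prior_sd = NULL,
                         max_iter = 10L, tol = 1e-8) {
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(alpha + beta * nodes)
    e <- r - n * p
    g <- c(sum(e), sum(e * nodes))
    wpq <- n * p * (1 - p)
    H <- -matrix(c(sum(wpq), sum(wpq * nodes),
                   sum(wpq * nodes), sum(wpq * nodes^2)), 2L)
    if (!is.null(a_prior_sd)) {
      # log-normal prior on the slope: log beta ~ N(0, a_prior_sd^2)
      lb <- log(beta)
      g[2L] <- g[2L] - (lb / a_prior_sd^2 + 1) / beta
      H[2L, 2L] <- H[2L, 2L] + (lb / a_prior_sd^2 + 1 - 1 / a_prior_sd^2) / beta^2
    }
    step <- tryCatch(solve(H, -g), error = function(e) rep(0, 2L))
    halve <- 0L
    repeat {
      new_beta <- beta + step[2L]
      if (new_beta > 1e-3 || halve >= 8L) break
      step <- step / 2
      halve <- halve + 1L
    }
    alpha <- alpha + step[1L]
    beta <- min(max(beta + step[2L], 1e-3), 25)
    if (max(abs(step)) < tol) break
  }
  list(alpha = alpha, beta = beta, hessian = H)
}

#' Calibrate a 2PL model by marginal maximum likelihood
#'
#' Bock-Aitkin EM with fixed quadrature over a standard-normal latent
#' trait. Items with no variance among their observed responses are
#' flagged as degenerate and excluded (with a warning) rather than fitted.
#'
#' @param responses Long tibble with columns `person_id`, `item_id`,
#'   `response` (0/1; unadministered items simply absent), or a persons x
#'   items matrix with `NA` for missing.
#' @param n_nodes Number of equally spaced quadrature nodes on
#'   `[-bound, bound]`.
#' @param bound Quadrature half-width on the trait scale.
#' @param tol Convergence tolerance: maximum absolute parameter change.
#' @param max_cycles EM cycle cap; non-convergence is reported, not hidden.
#' @param a_prior_sd Optional scale of a mild log-normal prior on the
#'   slope (location 0), off by default; useful for very sparse designs.
#' @return An `irt_2pl` object: parameter tibble (`item_id`, `a`, `b`,
#'   `se_a`, `se_b`), the marginal log-likelihood trace, convergence
#'   status, and the ids of any degenerate items.
#' @export
fit_2pl <- function(responses, n_nodes = 61L, bound = 6, tol = 1e-4,
                    max_cycles = 500L, a_prior_sd = NULL) {
  Y <- responses_to_matrix(responses)
  keep_person <- rowSums(!is.na(Y)) > 0L
  Y <- Y[keep_person, , drop = FALSE]

  n_obs <- colSums(!is.na(Y))
  n_correct <- colSums(Y, na.rm = TRUE)
  degenerate <- n_obs == 0L | n_correct == 0L | n_correct == n_obs
  if (any(degenerate)) {
    warning("excluding degenerate item(s) with no response variance: ",
            paste(colnames(Y)[degenerate], collapse = ", "), call. = FALSE)
    Y <- Y[, !degenerate, drop = FALSE]
  }
  if (ncol(Y) == 0L) stop("no calibratable items remain.", call. = FALSE)

  quad <- trait_quadrature(n_nodes, bound)
  nodes <- quad$nodes
  logw <- log(quad$weights)
  J <- ncol(Y)

  Yobs <- !is.na(Y)
  Y1 <- ifelse(Yobs, Y, 0)
  storage.mode(Y1) <- "double"
  storage.mode(Yobs) <- "double"

  p_hat <- pmin(pmax(n_correct[!degenerate] / n_obs[!degenerate], 0.02), 0.98)
  alpha <- stats::qlogis(p_hat)
  beta <- rep(1, J)

  loglik_trace <- numeric(0)
  converged <- FALSE
  hessians <- vector("list", J)

  for (cycle in seq_len(max_cycles)) {
    P <- stats::plogis(outer(nodes, rep(1, J)) * rep(beta, each = n_nodes) +
                         rep(alpha, each = n_nodes)) # Q x J
    P <- pmin(pmax(P, 1e-12), 1 - 1e-12) # keep 0 * log(0) out of the products
    logP <- log(P)
    log1P <- log1p(-P)
    LL <- Y1 %*% t(logP) + (Yobs - Y1) %*% t(log1P) # N x Q
    LLw <- sweep(LL, 2L, logw, `+`)
    mx <- apply(LLw, 1L, max)
    W <- exp(LLw - mx)
    rs <- rowSums(W)
    loglik <- sum(log(rs) + mx)
    W <- W / rs

    n_mat <- crossprod(Yobs, W) # J x Q expected counts of attempts
    r_mat <- crossprod(Y1, W)   # J x Q expected correct

    max_change <- 0
    for (j in seq_len(J)) {
      upd <- mstep_newton(alpha[j], beta[j], r_mat[j, ], n_mat[j, ], nodes,
                          a_prior_sd = a_prior_sd, max_iter = 3L)
      max_change <- max(max_change, abs(upd$alpha - alpha[j]),
                        abs(upd$beta - beta[j]))
      alpha[j] <- upd$alpha
      beta[j] <- upd$beta
      hessians[[j]] <- upd$hessian
    }
    loglik_trace <- c(loglik_trace, loglik)
    if (cycle > 1L && max_change < tol) {
      converged <- TRUE
      break
    }
  }

  a <- beta
  b <- -alpha / beta
  se <- t(vapply(seq_len(J), function(j) {
    V <- tryCatch(solve(-hessians[[j]]), error = function(e) matrix(NA_real_, 2, 2))
    # delta method from (alpha, beta) to (a, b) = (beta, -alpha/beta)
    Jac <- matrix(c(0, 1, -1 / beta[j], alpha[j] / beta[j]^2), 2L, byrow = TRUE)
    Vab <- Jac %*% V %*% t(Jac)
    sqrt(pmax(diag(Vab), 0))
  }, numeric(2)))

  structure(
    list(
      params = tibble::tibble(item_id = colnames(Y), a = a, b = b,
                              se_a = se[, 1L], se_b = se[, 2L]),
      loglik = loglik_trace[length(loglik_trace)],
      loglik_trace = loglik_trace,
      converged = converged,
      cycles = length(loglik_trace),
      degenerate_items = names(degenerate)[degenerate],
      n_persons = nrow(Y),
      n_items = J,
      quadrature = list(n_nodes = n_nodes, bound = bound),
      a_prior_sd = a_prior_sd
    ),
    class = "irt_2pl"
  )
}

#' @export
print.irt_2pl <- function(x, ...) {
  cat("<irt_2pl> ", x$n_items, " items, ", x$n_persons, " persons; logLik ",
      sprintf("%.2f", x$loglik), "; ",
      if (x$converged) "converged" else "NOT converged", " in ", x$cycles,
      " cycles\n", sep = "")
  if (length(x$degenerate_items)) {
    cat("degenerate items excluded:",
        paste(x$degenerate_items, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname fit_2pl
#' @param x An `irt_2pl` fit.
#' @param ... Unused.
#' @export
tidy.irt_2pl <- function(x, ...) x$params

#' @rdname fit_2pl
#' @export
glance.irt_2pl <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, n_items = x$n_items, n_persons = x$n_persons,
    cycles = x$cycles, converged = x$converged,
    n_degenerate = length(x$degenerate_items)
  )
}

#' @rdname fit_2pl
#' @param object An `irt_2pl` fit.
#' @export
autoplot.irt_2pl <- function(object, ...) {
  plot_test_information(test_information(object$params))
}
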