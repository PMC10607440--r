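# EAP ability scoring under a standard-normal prior.

#' Score persons by expected a posteriori (EAP) ability
#'
#' Posterior mean and SD of the latent trait under an N(0,1) prior,
#' evaluated on the same fixed quadrature grid as calibration. A person
#' with no scoreable responses gets the prior back (`theta = 0`,
#' `se = 1`) and is flagged.
#'
#' @param responses Long tibble (`person_id`, `item_id`, `response`) or
#'   persons x items matrix with `NA` for missing.
#' @param params Parameter tibble with `item_id`, `a`, `b` (e.g. from
#'   [fit_2pl()] via [tidy()], or [surrogate_item_bank()]). Parameters must
#'   cover every answered item.
#' @param n_nodes,bound Quadrature settings, as in [fit_2pl()].
#' @return A tibble: `person_id`, `theta`, `se`, `n_answered`, `method`,
#'   `prior_only`.
#' @export
score_eap <- function(responses, params, n_nodes = 61L, bound = 6) {
  Y <- responses_to_matrix(responses)
  unknown <- setdiff(colnames(Y), params$item_id)
  if (length(unknown)) {
    stop("no parameters for answered item(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  p <- params[match(colnames(Y), params$item_id), ]

  quad <- trait_quadrature(n_nodes, bound)
  nodes <- quad$nodes
  logw <- log(quad$weights)

  P <- vapply(seq_len(nrow(p)), function(j) prob_2pl(nodes, p$a[j], p$b[j]),
              numeric(length(nodes))) # Q x J
  P <- pmin(pmax(P, 1e-12), 1 - 1e-12)

  Yobs <- !is.na(Y)
  Y1 <- ifelse(Yobs, Y, 0)
  storage.mode(Y1) <- "double"
  storage.mode(Yobs) <- "double"
  LL <- Y1 %*% t(log(P)) + (Yobs - Y1) %*% t(log1p(-P))
  LLw <- sweep(LL, 2L, logw, `+`)
  mx <- apply(LLw, 1L, max)
  W <- exp(LLw - mx)
  W <- W / rowSums(W)

  theta <- as.numeric(W %*% nodes)
  se <- sqrt(pmax(as.numeric(W %*% nodes^2) - theta^2, 0))
  n_answered <- as.integer(rowSums(Yobs))
  prior_only <- n_answered == 0L
  theta[prior_only] <- 0
  se[prior_only] <- 1

  tibble::tibble(
    person_id = rownames(Y),
    theta = theta,
    se = se,
    n_answered = n_answered,
    method = "EAP",
    prior_only = prior_only
  )
}
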