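# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (exhaustive subsets, grid search, quadrature with a
# different rule) so they share no code path with the implementation.

# Brute-force polyomino enumeration: all size-n subsets of an n x n box,
# kept if edge-connected, de-duplicated by canonical key under `mode`.
oracle_polyominoes <- function(n, mode) {
  box <- expand.grid(col = 0:(n - 1L), row = 0:(n - 1L))
  idx <- utils::combn(nrow(box), n)
  connected <- function(cells) {
    seen <- 1L
    frontier <- 1L
    keys <- paste(cells[, 1L], cells[, 2L])
    while (length(frontier)) {
      nxt <- integer(0)
      for (i in frontier) {
        for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
          j <- match(paste(cells[i, 1L] + d[1L], cells[i, 2L] + d[2L]), keys)
          if (!is.na(j) && !(j %in% seen)) nxt <- c(nxt, j)
        }
      }
      nxt <- unique(nxt)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    length(seen) == n
  }
  keys <- character(0)
  for (k in seq_len(ncol(idx))) {
    cells <- as.matrix(box[idx[, k], ])
    if (!connected(cells)) next
    keys <- c(keys, hexrot:::cells_key(hexrot:::canonical_cells(cells, mode)))
  }
  sort(unique(keys))
}

# Marginal proportion correct of a 2PL item under a standard-normal trait,
# via integrate() (adaptive; the engine uses a fixed quadrature grid).
oracle_marginal_p <- function(a, b) {
  stats::integrate(function(t) stats::plogis(a * (t - b)) * stats::dnorm(t),
                   -Inf, Inf)$value
}

# Bivariate normal CDF via adaptive integration (independent of the
# package's fixed-node quadrature).
oracle_pbvnorm <- function(h, k, rho) {
  stats::integrate(function(x) {
    stats::dnorm(x) * stats::pnorm((k - rho * x) / sqrt(1 - rho^2))
  }, -Inf, h)$value
}

# Grid-search ML tetrachoric estimate from a 2x2 table (counts n11 at
# (1,1) etc. with thresholds from the margins).
oracle_tetrachoric <- function(tab, step = 1e-3) {
  n <- sum(tab)
  p1 <- (tab[2, 1] + tab[2, 2]) / n # P(first = 1), rows index the first item
  p2 <- (tab[1, 2] + tab[2, 2]) / n
  t1 <- stats::qnorm(1 - p1)
  t2 <- stats::qnorm(1 - p2)
  ll <- function(rho) {
    p00 <- oracle_pbvnorm(t1, t2, rho)
    p01 <- stats::pnorm(t1) - p00
    p10 <- stats::pnorm(t2) - p00
    p11 <- 1 - p00 - p01 - p10
    obs <- c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    sum(obs * log(pmax(c(p00, p01, p10, p11), 1e-12)))
  }
  grid <- seq(-0.999, 0.999, by = step)
  grid[which.max(vapply(grid, ll, numeric(1)))]
}
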