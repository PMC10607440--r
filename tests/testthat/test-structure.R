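test_that("pairwise correlation reduces to ordinary correlation on complete data", {
  X <- withr::with_seed(1, matrix(rnorm(200 * 5), 200))
  colnames(X) <- paste0("v", 1:5)
  pc <- pairwise_correlation(X)
  expect_equal(pc$R, cor(X))
  expect_true(all(pc$n_pairs == 200L))
  # two perfectly concordant binary items
  B <- cbind(b1 = c(0, 1, 1, 0, 1), b2 = c(0, 1, 1, 0, 1))
  expect_equal(pairwise_correlation(B)$R["b1", "b2"], 1.0)
  # long-format round trip through the response-matrix converter
  long <- tibble::tibble(person_id = rep(sprintf("p%d", 1:4), each = 2),
                         item_id = rep(c("it01", "it02"), 4),
                         response = c(1, 1, 0, 0, 1, 0, 0, 1))
  M <- as_response_matrix(long)
  expect_identical(dim(M), c(4L, 2L))
  expect_identical(M["p1", "it01"], 1)
})

test_that("min_n suppression and zero-variance items are reported, not silent", {
  X <- withr::with_seed(2, matrix(rnorm(60 * 3), 60))
  colnames(X) <- paste0("v", 1:3)
  X[1:55, 3] <- NA # only 5 joint observations with v3
  pc <- pairwise_correlation(X, min_n = 10L)
  expect_true(is.na(pc$R["v1", "v3"]))
  expect_false(is.na(pc$R["v1", "v2"]))
  expect_true(all(pc$dropped$reason == "below min_n"))
  Z <- cbind(a = rnorm(30), b = rep(1, 30))
  expect_warning(pz <- pairwise_correlation(Z), "zero observed variance")
  expect_true(is.na(pz$R["a", "b"]))
})

test_that("tetrachoric matches the likelihood-grid oracle and its symmetries", {
  expect_equal(tetrachoric(matrix(c(25, 25, 25, 25), 2)), 0,
               tolerance = 1e-4)
  tab <- matrix(c(40, 10, 10, 40), 2)
  est <- tetrachoric(tab)
  expect_gt(est, 0)
  expect_equal(est, oracle_tetrachoric(tab), tolerance = 1e-3)
  expect_equal(tetrachoric(t(tab)), est, tolerance = 1e-6)
  skew <- matrix(c(50, 8, 12, 30), 2)
  expect_equal(tetrachoric(skew), oracle_tetrachoric(skew), tolerance = 2e-3)
  neg <- matrix(c(10, 40, 40, 10), 2)
  expect_equal(tetrachoric(neg), -est, tolerance = 1e-3)
  expect_error(tetrachoric(matrix(c(5, 0, 7, 0), 2)), "degenerate margins")
  expect_error(tetrachoric(matrix(1:6, 3, 2)), "2x2")
})

test_that("tetrachoric recovers a planted latent correlation from dichotomised data", {
  X <- withr::with_seed(3, {
    z1 <- rnorm(40000)
    z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(40000)
    cbind(x = as.integer(z1 > 0), y = as.integer(z2 > 0))
  })
  pc <- pairwise_correlation(X, method = "tetrachoric")
  expect_equal(pc$R["x", "y"], 0.5, tolerance = 0.03)
})

test_that("minres EFA recovers an exact one-factor structure", {
  lam <- c(0.9, 0.8, 0.7, 0.6)
  R <- tcrossprod(lam)
  diag(R) <- 1
  sol <- efa_minres(R, 1L, rotation = "none")
  expect_equal(as.vector(sol$loadings), lam, tolerance = 1e-4)
  expect_equal(unname(sol$uniquenesses), 1 - lam^2, tolerance = 1e-4)
  expect_true(all(sol$communalities <= 1 + 1e-8))
  # identity matrix: no common variance
  sol0 <- efa_minres(diag(4), 1L, rotation = "none")
  expect_lt(max(abs(sol0$loadings)), 0.05)
  expect_error(efa_minres(diag(4), 3L), "Ledermann")
})

test_that("oblimin recovers a correlated simple structure and Schmid-Leiman its closed form", {
  # 4 factors, 3 items each, primaries 0.8, factor correlations all 0.49
  k <- 4L
  lam <- 0.8
  Lambda <- matrix(0, 12, k)
  for (j in seq_len(k)) Lambda[(j - 1) * 3 + 1:3, j] <- lam
  Phi <- matrix(0.49, k, k)
  diag(Phi) <- 1
  R <- Lambda %*% Phi %*% t(Lambda)
  diag(R) <- 1
  sol <- efa_minres(R, 4L, rotation = "oblimin")
  # pattern: each item loads ~0.8 on its factor, ~0 elsewhere
  peak <- apply(abs(sol$loadings), 1L, max)
  expect_equal(unname(peak), rep(lam, 12), tolerance = 1e-3)
  offpeak <- abs(sol$loadings)[abs(sol$loadings) < 0.5]
  expect_lt(max(offpeak), 1e-2)
  expect_equal(unname(sol$factor_correlations[lower.tri(Phi)]),
               rep(0.49, 6), tolerance = 1e-3)
  sl <- schmid_leiman(sol)
  expect_equal(unname(sl$higher_order), rep(0.7, 4), tolerance = 1e-3)
  expect_equal(unname(sl$general), rep(0.56, 12), tolerance = 1e-3)
  # Pythagorean identity: general^2 + group^2 = primary^2
  grp <- apply(sl$group, 1L, function(r) sqrt(sum(r^2)))
  expect_equal(unname(sl$general^2 + grp^2), rep(lam^2, 12), tolerance = 1e-3)
  # orthogonal factors admit no higher-order factor
  sol_orth <- efa_minres(diag(0.4, 12) + 0.0 * R + diag(0.6, 12), 2L,
                         rotation = "none")
  sol_orth$factor_correlations <- diag(2)
  expect_error(schmid_leiman(sol_orth), "positive manifold")
})

test_that("omega matches closed forms on constructed structures", {
  # one general factor, loadings 0.8: Vt = 4 + 12 * 0.64 = 11.68
  lam <- rep(0.8, 4)
  R1 <- tcrossprod(lam)
  diag(R1) <- 1
  om1 <- omega(R1, n_factors = 1L)
  expect_equal(om1$omega_h, 3.2^2 / 11.68, tolerance = 1e-6)
  expect_equal(om1$omega_t, om1$omega_h, tolerance = 1e-6)
  expect_equal(om1$alpha, (4 / 3) * (1 - 4 / 11.68), tolerance = 1e-10)
  # four correlated group factors: omega_h from the Schmid-Leiman closed form
  k <- 4L
  Lambda <- matrix(0, 12, k)
  for (j in seq_len(k)) Lambda[(j - 1) * 3 + 1:3, j] <- 0.8
  Phi <- matrix(0.49, k, k)
  diag(Phi) <- 1
  R4 <- Lambda %*% Phi %*% t(Lambda)
  diag(R4) <- 1
  om4 <- omega(R4, n_factors = 4L)
  expect_equal(om4$omega_h, (12 * 0.56)^2 / sum(R4), tolerance = 1e-6)
  expect_gte(om4$omega_t, om4$omega_h)
  expect_true(all(om4$per_group$n_items == 3L))
  # identity input: alpha 0; omega_h effectively 0
  om0 <- omega(diag(6), n_factors = 1L)
  expect_equal(om0$alpha, 0)
  expect_lt(om0$omega_h, 0.01)
})

test_that("alpha formula equals the classical variance-ratio alpha", {
  X <- withr::with_seed(9, {
    f <- rnorm(500)
    sapply(1:6, function(j) 0.6 * f + 0.8 * rnorm(500))
  })
  a1 <- omega(cor(X), n_factors = 1L)$alpha
  expect_equal(a1, alpha_from_scores(scale(X)), tolerance = 1e-10)
})

test_that("estimated omega_h tracks the population value on bifactor data", {
  spec <- bifactor_spec(
    general = rep(0.6, 16),
    group = rep(c("A", "B", "C", "D"), each = 4),
    group_loading = rep(0.45, 16)
  )
  X <- simulate_bifactor(20000L, spec, seed = 77L)
  om <- omega(cor(as.matrix(X)), n_factors = 4L)
  expect_lt(abs(om$omega_h - population_omega_h(spec)), 0.05)
})

test_that("pairwise estimates converge to complete-data R under MCAR masking", {
  spec <- bifactor_spec(
    general = rep(0.55, 8),
    group = rep(c("A", "B"), each = 4),
    group_loading = rep(0.4, 8)
  )
  X <- as.matrix(simulate_bifactor(20000L, spec, seed = 13L))
  R_full <- cor(X)
  Xm <- X
  mask <- withr::with_seed(14, matrix(runif(length(X)) < 0.5, nrow(X)))
  Xm[mask] <- NA
  pc <- pairwise_correlation(Xm)
  expect_gte(min(pc$n_pairs), 500L)
  expect_lt(max(abs(pc$R - R_full)), 0.05)
})

test_that("items load dominantly on their own type's factor when group factors exist", {
  spec <- bifactor_spec(
    general = rep(0.5, 20),
    group = rep(c("BOTH", "NONE", "OPTION_ONLY", "STIMULUS_ONLY"), each = 5),
    group_loading = rep(0.5, 20)
  )
  X <- simulate_bifactor(20000L, spec, seed = 55L)
  R <- cor(as.matrix(X))
  chk <- item_type_factor_check(R, spec$group)
  expect_gte(chk$fraction, 0.9)
  # permuted labels give the same fraction
  perm <- withr::with_seed(5, sample(nrow(spec)))
  chk2 <- item_type_factor_check(R[perm, perm], spec$group[perm])
  expect_equal(chk2$fraction, chk$fraction)
  # no group structure: matching is near chance
  spec0 <- bifactor_spec(
    general = rep(0.5, 20),
    group = rep(c("BOTH", "NONE", "OPTION_ONLY", "STIMULUS_ONLY"), each = 5),
    group_loading = rep(0, 20)
  )
  X0 <- simulate_bifactor(20000L, spec0, seed = 56L)
  chk0 <- item_type_factor_check(cor(as.matrix(X0)), spec0$group)
  expect_lt(chk0$fraction, 0.6)
  expect_error(item_type_factor_check(R, rep(c("A", "B"), 10)), "distinct")
})
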