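test_that("2PL probability and information obey their closed forms", {
  expect_equal(prob_2pl(0.7, a = 2, b = 0.7), 0.5)
  expect_equal(prob_2pl(1, a = 1, b = 0), 0.7310586, tolerance = 1e-6)
  expect_gt(prob_2pl(10, a = 1.5, b = 0), 0.999)
  expect_error(prob_2pl(0, a = -1, b = 0), "positive")
  expect_equal(item_information(0, a = 2, b = 0), 1.0)
  grid <- seq(-4, 4, by = 0.01)
  expect_equal(grid[which.max(item_information(grid, a = 1.3, b = 0.8))],
               0.8, tolerance = 0.02)
  expect_equal(item_information(0.5 + 0.3, 1.7, 0.5),
               item_information(0.5 - 0.3, 1.7, 0.5))
  # derivative identity I = (p')^2 / (p(1-p)) by central difference
  h <- 1e-5
  for (th in c(-1, 0.2, 1.4)) {
    dp <- (prob_2pl(th + h, 1.8, 0.4) - prob_2pl(th - h, 1.8, 0.4)) / (2 * h)
    p <- prob_2pl(th, 1.8, 0.4)
    expect_equal(item_information(th, 1.8, 0.4), dp^2 / (p * (1 - p)),
                 tolerance = 1e-6)
  }
})

test_that("test information is additive and group curves reflect parameters", {
  pars <- tibble::tibble(a = c(1.5, 1.5), b = c(0.3, 0.3))
  tif <- test_information(pars, theta = seq(-2, 2, length.out = 21))
  single <- test_information(pars[1, ], theta = seq(-2, 2, length.out = 21))
  expect_equal(tif$information, 2 * single$information)
  expect_error(test_information(pars[0, ]), "at least one")
  # a group with larger a and b peaks higher and further right
  pars2 <- tibble::tibble(
    a = c(rep(1, 5), rep(2.5, 5)),
    b = c(rep(-0.5, 5), rep(1, 5)),
    group = rep(c("low", "high"), each = 5)
  )
  tif2 <- test_information(pars2, theta = seq(-3, 3, length.out = 301))
  peaks <- tif2 |>
    dplyr::group_by(group) |>
    dplyr::summarise(peak = max(information),
                     at = theta[which.max(information)])
  expect_gt(peaks$peak[peaks$group == "high"], peaks$peak[peaks$group == "low"])
  expect_gt(peaks$at[peaks$group == "high"], peaks$at[peaks$group == "low"])
  expect_s3_class(plot_test_information(tif2), "ggplot")
})

test_that("surrogate bank reproduces the printed parameter summaries", {
  bank <- surrogate_item_bank()
  expect_identical(nrow(bank), 57L)
  expect_equal(mean(bank$b), 0.34, tolerance = 1e-6)
  expect_equal(sd(bank$b), 0.68, tolerance = 1e-6)
  expect_equal(range(bank$b), c(-0.79, 1.96))
  expect_equal(mean(bank$a), 1.76, tolerance = 1e-6)
  expect_equal(sd(bank$a), 0.53, tolerance = 1e-6)
  expect_equal(range(bank$a), c(0.91, 3.21))
  expect_identical(as.vector(table(bank$item_type)),
                   rep(19L, 3))
})

test_that("EM calibration recovers known parameters on complete data", {
  bank <- surrogate_item_bank()[1:20, ]
  des <- complete_design(1500L, 20L)
  resp <- simulate_responses(des, bank, seed = 42L)
  fit <- fit_2pl(resp)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  est <- tidy(fit)
  est <- est[match(bank$item_id, est$item_id), ]
  expect_gt(cor(est$b, bank$b), 0.95)
  expect_gt(cor(est$a, bank$a), 0.85)
  expect_true(all(est$se_a > 0 & est$se_b > 0))
  g <- glance(fit)
  expect_identical(g$n_items, 20L)
  expect_identical(g$n_persons, 1500L)
})

test_that("duplicated item columns recover near-identical parameters", {
  bank <- surrogate_item_bank()[c(5, 25, 45), ]
  bank$item_id <- sprintf("it%02d", 1:3)
  des <- complete_design(2000L, 3L)
  resp <- simulate_responses(des, bank, seed = 7L)
  wide <- tidyr::pivot_wider(resp, names_from = "item_id",
                             values_from = "response")
  Y <- as.matrix(wide[, -1])
  Y2 <- cbind(Y, Y)
  colnames(Y2) <- sprintf("x%d", 1:6)
  fit <- fit_2pl(Y2)
  est <- tidy(fit)
  for (j in 1:3) {
    d_a <- abs(est$a[j] - est$a[j + 3])
    d_b <- abs(est$b[j] - est$b[j + 3])
    expect_lt(d_a, 2 * (est$se_a[j] + est$se_a[j + 3]))
    expect_lt(d_b, 2 * (est$se_b[j] + est$se_b[j + 3]))
  }
})

test_that("degenerate items are flagged and excluded, not silently fitted", {
  Y <- matrix(c(1, 1, 1, 1,
                0, 1, 0, 1,
                1, 0, 1, 1), 4L, 3L)
  colnames(Y) <- c("allright", "ok1", "ok2")
  expect_warning(fit <- fit_2pl(Y, max_cycles = 50L), "allright")
  expect_identical(fit$degenerate_items, "allright")
  expect_identical(fit$n_items, 2L)
})

test_that("observed marginals match the quadrature-free oracle", {
  bank <- tibble::tibble(item_id = c("it01", "it02"), a = c(1.2, 2.4),
                        b = c(-0.5, 1.1))
  des <- complete_design(50000L, 2L)
  resp <- simulate_responses(des, bank, seed = 11L)
  wide <- tidyr::pivot_wider(resp, names_from = "item_id",
                             values_from = "response")
  for (j in 1:2) {
    expect_equal(mean(wide[[bank$item_id[j]]]),
                 oracle_marginal_p(bank$a[j], bank$b[j]),
                 tolerance = 0.01)
  }
})

test_that("EAP scoring is monotone, handles empty records, and recovers theta", {
  bank <- surrogate_item_bank()
  items <- bank$item_id[1:10]
  all_right <- tibble::tibble(person_id = "hi", item_id = items, response = 1L)
  all_wrong <- tibble::tibble(person_id = "lo", item_id = items, response = 0L)
  s <- score_eap(dplyr::bind_rows(all_right, all_wrong), bank)
  expect_gt(s$theta[s$person_id == "hi"], s$theta[s$person_id == "lo"])
  # adding a correct answer never lowers theta
  base_resp <- tibble::tibble(person_id = "p", item_id = items[1:5],
                              response = c(1L, 0L, 1L, 0L, 0L))
  more <- dplyr::mutate(base_resp, response = c(1L, 1L, 1L, 0L, 0L))
  expect_gt(score_eap(more, bank)$theta, score_eap(base_resp, bank)$theta)
  # empty record returns the prior, flagged
  Y <- matrix(NA_real_, 1L, 2L, dimnames = list("px", bank$item_id[1:2]))
  s0 <- score_eap(Y, bank)
  expect_identical(s0$theta, 0)
  expect_identical(s0$se, 1)
  expect_true(s0$prior_only)
  expect_error(score_eap(tibble::tibble(person_id = "q", item_id = "mystery",
                                        response = 1L), bank),
               "no parameters")
})

test_that("EAP recovery correlation on complete 57-item data is high", {
  bank <- surrogate_item_bank()
  des <- complete_design(800L, 57L)
  resp <- simulate_responses(des, bank, seed = 3L)
  truth <- attr(resp, "thetas")
  sc <- score_eap(resp, bank)
  expect_gt(cor(sc$theta[match(names(truth), sc$person_id)], truth), 0.8)
})

test_that("reporting-metric rescaling hits mean 50 and SD 10", {
  th <- withr::with_seed(1, rnorm(200))
  sc <- rescale_scores(th)
  expect_equal(mean(sc), 50)
  expect_equal(sd(sc), 10)
  expect_equal(sc[which.min(abs(th - mean(th)))],
               50 + 10 * (th[which.min(abs(th - mean(th)))] - mean(th)) / sd(th))
  expect_error(rescale_scores(rep(1, 5)), "distinct")
})

test_that("information-spike screening flags a dominating item", {
  bank <- surrogate_item_bank()[1:15, ]
  spiked <- dplyr::bind_rows(bank,
                             tibble::tibble(item_id = "spike", a = 9, b = 0.5,
                                            item_type = "BOTH"))
  flagged <- screen_information_spikes(spiked)
  expect_true("spike" %in% flagged$item_id)
  expect_identical(nrow(screen_information_spikes(bank)), 0L)
})
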