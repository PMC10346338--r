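test_that("one-way decomposition reproduces hand-computed mean squares", {
  d <- tibble::tibble(participant_id = c("A", "A", "B", "B"),
    value = c(1, 2, 3, 4))
  dec <- decompose_oneway(d)
  expect_equal(dec$msbs, 4)
  expect_equal(dec$msws, 0.5)
  expect_equal(dec$n, 2)
  expect_equal(dec$k, 2)
  expect_true(dec$balanced)

  const <- tibble::tibble(participant_id = c("A", "A", "B", "B"),
    value = c(5, 5, 5, 5))
  dec2 <- decompose_oneway(const)
  expect_equal(dec2$msbs, 0)
  expect_equal(dec2$msws, 0)
})

test_that("unbalanced designs use Searle's effective k0", {
  d <- tibble::tibble(participant_id = c("A", "A", "B", "B", "B"),
    value = c(1, 2, 3, 4, 5))
  dec <- decompose_oneway(d)
  expect_false(dec$balanced)
  # k0 = (1/(n-1)) (sum ki - sum ki^2 / sum ki) = 5 - 13/5 = 2.4
  expect_equal(dec$k, 2.4)

  few <- tibble::tibble(participant_id = c("A", "A", "B"), value = 1:3)
  expect_warning(expect_error(decompose_oneway(few),
    class = "reliwear_data_error"), "fewer than 2")
})

test_that("ICC point estimates match the closed-form examples", {
  d <- tibble::tibble(participant_id = c("A", "A", "B", "B"),
    value = c(1, 2, 3, 4))
  dec <- decompose_oneway(d)
  r1 <- icc_single(dec)
  expect_equal(r1$estimate, (4 - 0.5) / (4 + 0.5), tolerance = 1e-12)
  expect_equal(r1$estimate, 0.7778, tolerance = 1e-4)

  rk <- icc_average(dec)
  expect_equal(rk$estimate, (4 - 0.5) / 4, tolerance = 1e-12)
  # Spearman-Brown consistency: k rho1 / (1 + (k-1) rho1)
  rho1 <- r1$estimate
  expect_equal(rk$estimate, 2 * rho1 / (1 + rho1), tolerance = 1e-12)

  # degenerate edges
  perfect <- structure(list(msbs = 4, msws = 0, n = 5, k = 2, balanced = TRUE,
    df_between = 4, df_within = 5, n_total = 10), class = "anova_decomp")
  expect_equal(icc_single(perfect)$estimate, 1)
  expect_equal(icc_average(perfect)$estimate, 1)
  noise <- structure(list(msbs = 0, msws = 2, n = 5, k = 2, balanced = TRUE,
    df_between = 4, df_within = 5, n_total = 10), class = "anova_decomp")
  expect_equal(icc_single(noise)$estimate, -1) # algebraic bound -1/(k-1)
  flat <- structure(list(msbs = 0, msws = 0, n = 5, k = 2, balanced = TRUE,
    df_between = 4, df_within = 5, n_total = 10), class = "anova_decomp")
  expect_error(icc_single(flat), class = "reliwear_degenerate_error")
  expect_error(icc_average(flat), class = "reliwear_degenerate_error")
})

test_that("icc_single matches the brute-force oracle on random balanced tables", {
  tables <- random_icc_tables(60, seed = 202)
  for (m in tables) {
    est <- icc_single(decompose_oneway(table_to_df(m)))$estimate
    expect_equal(est, brute_force_icc1(m), tolerance = 1e-10)
    msq <- brute_force_msq(m)
    dec <- decompose_oneway(table_to_df(m))
    expect_equal(dec$msbs, msq$msbs, tolerance = 1e-10)
    expect_equal(dec$msws, msq$msws, tolerance = 1e-10)
  }
})

test_that("ICC is invariant to location, scale and permutations, and stays in bounds", {
  tables <- random_icc_tables(25, seed = 303)
  withr::with_seed(99, {
    for (m in tables) {
      base <- icc_single(decompose_oneway(table_to_df(m)))$estimate
      k <- ncol(m)
      expect_gte(base, -1 / (k - 1) - 1e-12)
      expect_lte(base, 1 + 1e-12)
      shifted <- icc_single(decompose_oneway(table_to_df(m + 17.3)))$estimate
      scaled <- icc_single(decompose_oneway(table_to_df(m * 3.7)))$estimate
      expect_equal(shifted, base, tolerance = 1e-12)
      expect_equal(scaled, base, tolerance = 1e-12)
      # permute participants and replicates within participants
      perm <- m[sample(nrow(m)), ]
      for (i in seq_len(nrow(perm))) perm[i, ] <- perm[i, sample(k)]
      permuted <- icc_single(decompose_oneway(table_to_df(perm)))$estimate
      expect_equal(permuted, base, tolerance = 1e-12)
    }
  })
})

test_that("confidence bounds bracket the estimate and p-values grade evidence", {
  tables <- random_icc_tables(25, seed = 404)
  for (m in tables) {
    r <- icc_single(decompose_oneway(table_to_df(m)))
    expect_lte(r$ci_low, r$estimate + 1e-12)
    expect_gte(r$ci_high, r$estimate - 1e-12)
    expect_gte(r$p_value, 0)
    expect_lte(r$p_value, 1)
  }
  # strong separation between participants: tiny p
  strong <- matrix(c(60, 61, 80, 81, 100, 101), nrow = 3, byrow = TRUE)
  expect_lt(icc_single(decompose_oneway(table_to_df(strong)))$p_value, 0.01)
})

test_that("classification bins follow configured edges", {
  expect_equal(classify_icc(0.80), "excellent")
  expect_equal(classify_icc(0.65), "good")
  expect_equal(classify_icc(0.38), "fair")
  expect_equal(classify_icc(0.10), "poor")
  expect_equal(classify_icc(0.75), "excellent") # closed lower edge
  expect_equal(classify_icc(0.5, bins = c(low = -Inf, high = 0.6)), "low")
  expect_error(classify_icc(0.5, bins = c(a = 0.5, b = 0.2)),
    class = "reliwear_config_error")
})

test_that("simulated variance components are recovered by the ICC", {
  cfg <- sim_config(mu = 0, sigma_r = 1, sigma_s = 0, sigma_v = 1,
    n_participants = 500, k_replicates = 8, n_situations = 1, seed = 7)
  sim <- simulate_components(cfg)
  est <- icc_single(decompose_oneway(sim$data))$estimate
  expect_equal(est, 0.5, tolerance = 0.05) # rho = 1/(1+1)

  noiseless <- sim_config(mu = 0, sigma_r = 1, sigma_s = 0, sigma_v = 0,
    n_participants = 20, k_replicates = 4, n_situations = 1, seed = 8)
  est1 <- icc_single(decompose_oneway(simulate_components(noiseless)$data))$estimate
  expect_identical(est1, 1)
})
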