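noiseless_alloc <- function(seed, b_true, logA_sd = 0) {
  cfg <- simulation_config(seed = seed, noise_cv = 0, host_effect_sd = 0,
                           logA_sd = logA_sd, b_true = b_true)
  sim <- simulate_allocation_experiment(cfg)
  allocation_table(sim$colonization, sim$spore_mass)
}

test_that("noiseless trade-off data return slope -b exactly for any exponent", {
  for (b in c(0.1, 0.3, 0.7, 1, 1.5, 2)) {
    alloc <- noiseless_alloc(seed = 41, b_true = b)
    rep <- suppressMessages(tradeoff_analysis(alloc))
    expect_equal(rep$fits$uncorrected$slope, -b, tolerance = 1e-10)
  }
})

test_that("constant-allocation data satisfy inverse proportionality", {
  alloc <- noiseless_alloc(seed = 42, b_true = 1)
  rep <- suppressMessages(tradeoff_analysis(alloc))
  expect_equal(rep$fits$uncorrected$slope, -1, tolerance = 1e-12)
  expect_equal(rep$tests$uncorrected$p_value, 1)
  # log A vs log W0 is degenerate (A constant) and is skipped, not fitted
  expect_false("allocation_vs_size" %in% names(rep$fits))
  expect_message(tradeoff_analysis(alloc), "skipped")
})

test_that("a sub-proportional exponent splits into -b and +(1-b) slopes", {
  # R = A0 * W0^-0.5 with constant A0: allocation A = R W0 = A0 W0^0.5
  alloc <- noiseless_alloc(seed = 43, b_true = 0.5)
  rep <- suppressMessages(tradeoff_analysis(alloc))
  expect_equal(rep$fits$uncorrected$slope, -0.5, tolerance = 1e-10)
  expect_equal(rep$fits$allocation_vs_size$slope, 0.5, tolerance = 1e-10)
})

test_that("body-size corrections equal the uncorrected slope only for shared body size", {
  set.seed(44)
  n <- 30
  w0 <- 10^rnorm(n)
  A <- 10^rnorm(n, 1, 0.3)
  base <- tibble::tibble(
    fungal_species = sprintf("s%02d", 1:n), host_species = "h",
    spore_output = A / w0, spore_mass_w0 = w0, allocation = A,
    body_mass = 50, extraradical_length = 2
  )
  rep_const <- tradeoff_analysis(base)
  expect_equal(rep_const$fits$per_mass$slope, rep_const$fits$uncorrected$slope)
  expect_equal(rep_const$fits$per_length$slope, rep_const$fits$uncorrected$slope)

  # body size correlated with spore size changes the corrected slope
  vary <- base
  vary$body_mass <- 50 * w0^0.8
  rep_vary <- tradeoff_analysis(vary)
  expect_gt(abs(rep_vary$fits$per_mass$slope - rep_vary$fits$uncorrected$slope),
            0.1)
})

test_that("degenerate allocation inputs are rejected or excluded", {
  alloc <- noiseless_alloc(seed = 45, b_true = 1, logA_sd = 0.4)
  same_w0 <- alloc
  same_w0$spore_mass_w0 <- 0.25
  expect_error(suppressMessages(tradeoff_analysis(same_w0)), "zero variance")

  with_bad <- alloc
  with_bad$spore_output[1:3] <- 0
  expect_message(rep <- tradeoff_analysis(with_bad), "excluding 3")
  expect_equal(rep$n_points, nrow(alloc) - 3)

  expect_error(tradeoff_analysis(alloc[1:2, ]), "at least 3")
})

test_that("PIC follow-up runs only when triggered and a tree is supplied", {
  cfg <- simulation_config(seed = 46, logA_sd = 0.3)
  tree <- simulate_tree(cfg)
  sim <- simulate_allocation_experiment(cfg, tree = tree)
  alloc <- allocation_table(sim$colonization, sim$spore_mass)

  no_tree <- tradeoff_analysis(alloc)
  expect_null(no_tree$pic)
  with_tree <- tradeoff_analysis(alloc, tree = tree)
  if (with_tree$fits$uncorrected$p_correlation < 0.05) {
    expect_s3_class(with_tree$pic, "tbl_df")
    expect_true(is.finite(with_tree$pic$p_value))
  }
})

test_that("residual correction is accepted as an alternative to ratios", {
  alloc <- noiseless_alloc(seed = 47, b_true = 1, logA_sd = 0.4)
  rep_ratio <- suppressMessages(tradeoff_analysis(alloc, correction = "ratio"))
  rep_resid <- suppressMessages(tradeoff_analysis(alloc, correction = "residual"))
  expect_false(isTRUE(all.equal(rep_ratio$fits$per_mass$slope,
                                rep_resid$fits$per_mass$slope)))
  expect_equal(rep_ratio$fits$uncorrected$slope, rep_resid$fits$uncorrected$slope)
})

test_that("scaling recovers beta = 1 when output tracks body size", {
  set.seed(48)
  n <- 40
  walpha <- 10^rnorm(n, 1.5, 0.5)
  d <- tibble::tibble(
    fungal_species = sprintf("s%02d", 1:n), host_species = "h",
    spore_output = 3 * walpha, spore_mass_w0 = 0.2,
    allocation = 3 * walpha * 0.2, body_mass = walpha, extraradical_length = 1
  )
  expect_message(sc <- scaling_analysis(d), "skipped")
  expect_equal(sc$beta_hat, 1, tolerance = 1e-10)
  expect_equal(sc$fits$output_vs_body$slope, 1, tolerance = 1e-10)
  # W0 with tiny independent jitter: no association with body size
  d2 <- d
  d2$spore_mass_w0 <- 0.2 * 10^rnorm(n, 0, 0.01)
  sc2 <- scaling_analysis(d2)
  expect_gt(sc2$fits$size_vs_body$p_correlation, 0.05)

  d3 <- d
  d3$body_mass <- 7
  expect_error(suppressMessages(scaling_analysis(d3)), "zero variance")
})

test_that("spore size unrelated to body size is flagged at the nominal rate", {
  set.seed(49)
  n_rep <- 500
  rej <- vapply(seq_len(n_rep), function(i) {
    n <- 30
    d <- tibble::tibble(
      fungal_species = sprintf("s%02d", 1:n), host_species = "h",
      spore_mass_w0 = 10^rnorm(n), body_mass = 10^rnorm(n, 1, 0.5),
      spore_output = 10^rnorm(n, 1, 0.5), extraradical_length = 1
    )
    d$allocation <- d$spore_output * d$spore_mass_w0
    scaling_analysis(d)$fits$size_vs_body$p_correlation < 0.05
  }, logical(1))
  band <- qbinom(c(0.025, 0.975), n_rep, 0.05) / n_rep
  expect_gte(mean(rej), band[1])
  expect_lte(mean(rej), band[2])
})

test_that("tidy and glance summarize reports with one row per fit", {
  alloc <- noiseless_alloc(seed = 50, b_true = 1, logA_sd = 0.4)
  rep <- suppressMessages(tradeoff_analysis(alloc))
  td <- tidy(rep)
  expect_setequal(td$variant, c("uncorrected", "per_length", "per_mass",
                                "allocation_vs_size"))
  expect_true(all(c("slope", "conf.low", "conf.high", "p.correlation",
                    "p.vs.minus1") %in% names(td)))
  expect_equal(nrow(glance(rep)), 1)

  sc <- scaling_analysis(alloc)
  expect_equal(nrow(tidy(sc)), 3)
  f <- sma_fit(data.frame(x = 1:5, y = c(1, 3, 2, 5, 4)), x, y)
  expect_equal(tidy(f)$estimate[2], f$slope)
  expect_equal(glance(f)$r.squared, f$r_squared)
})
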