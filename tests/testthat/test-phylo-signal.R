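test_that("the lambda transform scales off-diagonal covariances only", {
  set.seed(21)
  tr <- ape::rtree(12)
  C <- ape::vcv(tr)
  for (lam in c(0, 0.5, 1)) {
    Ct <- ape::vcv(lambda_transform(tr, lam))[rownames(C), colnames(C)]
    expect_equal(diag(Ct), diag(C))
    off <- row(C) != col(C)
    expect_equal(Ct[off], lam * C[off], tolerance = 1e-12)
  }
  expect_error(lambda_transform(tr, -0.1), "lambda")
  expect_error(lambda_transform(tr, lambda_max(tr) + 0.01), "lambda")
})

test_that("lambda ML recovers simulated signal strengths", {
  cfg1 <- simulation_config(seed = 101, n_species = 200, lambda_true = 1)
  tr1 <- simulate_tree(cfg1)
  f1 <- fit_pagel_lambda(tr1, simulate_bm_trait(tr1, cfg1))
  expect_gte(f1$lambda, 0.85)
  expect_lte(f1$lambda, f1$lambda_max)
  expect_lt(f1$p_value, 0.001)

  cfg0 <- simulation_config(seed = 102, n_species = 200, lambda_true = 0)
  tr0 <- simulate_tree(cfg0)
  f0 <- fit_pagel_lambda(tr0, simulate_bm_trait(tr0, cfg0))
  expect_lt(f0$lambda, 0.15)

  expect_gte(f1$logLik, f1$logLik0)
  expect_gte(f1$lrt, 0)
})

test_that("the profiled optimum beats a dense grid and matches phytools", {
  cfg <- simulation_config(seed = 103, n_species = 80, lambda_true = 0.7)
  tr <- simulate_tree(cfg)
  x <- simulate_bm_trait(tr, cfg)
  f <- fit_pagel_lambda(tr, x)

  grid <- seq(0, f$lambda_max, length.out = 1001)
  grid_best <- max(vapply(grid, function(l) dense_lambda_loglik(tr, x, l),
                          numeric(1)))
  expect_gte(f$logLik + 1e-6, grid_best)
  expect_equal(f$logLik, dense_lambda_loglik(tr, x, f$lambda), tolerance = 1e-8)

  skip_if_not_installed("phytools")
  ph <- phytools::phylosig(tr, x, method = "lambda", test = TRUE)
  expect_equal(f$lambda, ph$lambda, tolerance = 1e-3)
  expect_gte(f$logLik + 1e-6, ph$logL)
  expect_equal(f$logLik0, ph$logL0, tolerance = 1e-6)
})

test_that("lambda is invariant to affine trait transforms", {
  cfg <- simulation_config(seed = 104, n_species = 60, lambda_true = 0.5)
  tr <- simulate_tree(cfg)
  x <- simulate_bm_trait(tr, cfg)
  f <- fit_pagel_lambda(tr, x)
  f_shift <- fit_pagel_lambda(tr, x + 100)
  f_scale <- fit_pagel_lambda(tr, 3.7 * x)
  expect_equal(f_shift$lambda, f$lambda, tolerance = 1e-5)
  expect_equal(f_scale$lambda, f$lambda, tolerance = 1e-5)
  expect_equal(f_scale$sigma2, 3.7^2 * f$sigma2, tolerance = 1e-4)
})

test_that("at lambda = 0 the likelihood equals the iid normal closed form", {
  cfg <- simulation_config(seed = 105, n_species = 40)
  tr <- simulate_tree(cfg)  # ultrametric: equal tip depths
  x <- simulate_bm_trait(tr, cfg)
  # at lambda = 0 the model is iid N(mu, sigma2 * depth); ML plug-ins
  mu <- mean(x)
  s2T <- mean((x - mu)^2)
  loglik_iid <- sum(stats::dnorm(x, mu, sqrt(s2T), log = TRUE))
  f <- fit_pagel_lambda(tr, x)
  expect_equal(f$logLik0, loglik_iid, tolerance = 1e-8)
})

test_that("trait validation catches constant and unmatched inputs", {
  tr <- ape::rtree(5)
  x <- setNames(rep(1, 5), tr$tip.label)
  expect_error(fit_pagel_lambda(tr, x), "zero variance")
  y <- setNames(rnorm(5), c(tr$tip.label[-1], "ghost_species"))
  expect_error(fit_pagel_lambda(tr, y), "ghost_species")
  expect_error(pic_contrasts(tr, y), "ghost_species")
  expect_error(fit_pagel_lambda(tr, setNames(rnorm(2), tr$tip.label[1:2])),
               "at least 3")
})

test_that("independent contrasts match the closed form and ape::pic exactly", {
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  cs <- pic_contrasts(cherry, c(A = 3, B = 1))
  expect_equal(abs(cs$contrast), 2 / sqrt(2))
  expect_equal(cs$variance, 2)

  tr16 <- ape::rtree(16)
  x16 <- setNames(rnorm(16), tr16$tip.label)
  expect_equal(nrow(pic_contrasts(tr16, x16)), 15)
  expect_equal(pic_contrasts(tr16, setNames(rep(4, 16), tr16$tip.label))$contrast,
               rep(0, 15))

  set.seed(22)
  for (i in 1:5) {
    tr <- ape::rtree(sample(10:40, 1))
    x <- setNames(rnorm(ape::Ntip(tr)), tr$tip.label)
    mine <- pic_contrasts(tr, x)
    ref <- ape::pic(x[tr$tip.label], tr, var.contrasts = TRUE)
    expect_equal(sort(mine$contrast), unname(sort(ref[, 1])), tolerance = 1e-12)
    expect_equal(sort(mine$variance), unname(sort(ref[, 2])), tolerance = 1e-12)
  }

  poly <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_message(cp <- pic_contrasts(poly, c(A = 1, B = 2, C = 3, D = 4)),
                 "polytomy")
  expect_equal(nrow(cp), 3)

  neg <- ape::read.tree(text = "((A:1,B:1):-0.5,C:2);")
  expect_error(pic_contrasts(neg, c(A = 1, B = 2, C = 3)), "negative")
})

test_that("contrast correlations are exact for constructed traits", {
  set.seed(23)
  tr <- ape::rtree(20)
  x <- setNames(rnorm(20), tr$tip.label)
  self <- pic_correlation(tr, x, x)
  expect_equal(self$estimate, 1)
  lin <- pic_correlation(tr, x, 2 * x + 7)
  expect_equal(lin$estimate, 1)
  expect_equal(lin$slope, 2)
})

test_that("contrast correlation has nominal type-I error for independent traits", {
  cfg <- simulation_config(seed = 106, n_species = 100)
  tr <- simulate_tree(cfg)
  n_rep <- 500
  rej <- vapply(seq_len(n_rep), function(i) {
    x <- simulate_bm_trait(tr, cfg, seed = 2 * i)
    y <- simulate_bm_trait(tr, cfg, seed = 2 * i + 1)
    pic_correlation(tr, x, y)$p_value < 0.05
  }, logical(1))
  band <- qbinom(c(0.025, 0.975), n_rep, 0.05) / n_rep
  expect_gte(mean(rej), band[1])
  expect_lte(mean(rej), band[2])
})

test_that("BM-simulated contrasts are standard normal with variance sigma2", {
  cfg <- simulation_config(seed = 107, n_species = 50, sigma2 = 2)
  tr <- simulate_tree(cfg)
  n_rep <- 500
  res <- vapply(seq_len(n_rep), function(i) {
    x <- simulate_bm_trait(tr, cfg, seed = 10000 + i)
    cs <- pic_contrasts(tr, x)$contrast
    c(var = mean(cs^2), rej = stats::shapiro.test(cs)$p.value < 0.05)
  }, numeric(2))
  # mean squared contrast estimates sigma2
  expect_equal(mean(res[1, ]), 2, tolerance = 0.1)
  # normality rejected at roughly the nominal rate
  band <- qbinom(c(0.025, 0.975), n_rep, 0.05) / n_rep
  expect_gte(mean(res[2, ]), band[1] - 0.01)
  expect_lte(mean(res[2, ]), band[2] + 0.01)
})
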