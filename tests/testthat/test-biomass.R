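test_that("ergosterol calibration inverts exactly above the intercept", {
  expect_equal(ergosterol_to_hyphal_length(0.58), 1)
  expect_equal(ergosterol_to_hyphal_length(0.18), 0)
  expect_warning(l <- ergosterol_to_hyphal_length(0.10), "clamping")
  expect_equal(l, 0)
  expect_error(ergosterol_to_hyphal_length(-0.1), "non-negative")

  # round trip E -> L -> E for E >= intercept
  k <- conversion_constants()
  E <- seq(0.18, 5, length.out = 40)
  L <- ergosterol_to_hyphal_length(E, k)
  expect_equal(k$ergosterol_slope * L + k$ergosterol_intercept, E)
})

test_that("hyphal cylinder mass matches an independent unit computation", {
  # independent chain: r = 4 um = 4e-6 m; V = pi r^2 L m^3 -> cm^3 -> g -> ug
  r_m <- 4e-6
  v_cm3 <- pi * r_m^2 * 1 * 1e6
  oracle <- v_cm3 * 0.23 * 1e6
  expect_equal(hyphal_length_to_dry_mass(1), oracle, tolerance = 1e-12)
  expect_equal(round(hyphal_length_to_dry_mass(1), 2), 11.56)

  expect_equal(hyphal_length_to_dry_mass(0), 0)
  L <- c(0.3, 1.7, 12)
  expect_equal(hyphal_length_to_dry_mass(2 * L), 2 * hyphal_length_to_dry_mass(L))
  expect_error(hyphal_length_to_dry_mass(-1), "non-negative")
})

test_that("reproductive allocation is the spore output-mass product", {
  expect_equal(reproductive_allocation(1000, 0.364), 364)
  expect_equal(reproductive_allocation(0, 0.5), 0)
  expect_error(reproductive_allocation(10, 0), "positive")
  expect_error(reproductive_allocation(-1, 0.5), "non-negative")

  # data generated as R = A0 / W0 recovers A = A0 for every species
  A0 <- 42
  w0 <- c(a = 0.01, b = 0.1, c = 2)
  expect_equal(reproductive_allocation(A0 / w0, w0), rep(A0, 3),
               ignore_attr = TRUE)
})

test_that("the allocation table composes the converters correctly", {
  col <- tibble::tibble(
    fungal_species = "sp1", host_species = "h1", replicate = 1,
    root_ergosterol_ug_per_g = 0.58, soil_hyphal_m_per_g = 1, spores_per_g = 100
  )
  alloc <- allocation_table(col, c(sp1 = 0.364))
  # root 1 m + soil 1 m = 2 m of hyphae
  expect_equal(alloc$body_mass, hyphal_length_to_dry_mass(2))
  expect_equal(round(alloc$body_mass, 2), 23.12)
  expect_equal(alloc$extraradical_length, 1)
  expect_equal(alloc$allocation, 100 * 0.364)

  # all-zero measurements give zero body size
  zero <- col
  zero$root_ergosterol_ug_per_g <- 0
  zero$soil_hyphal_m_per_g <- 0
  zero$spores_per_g <- 0
  suppressWarnings(a0 <- allocation_table(zero, c(sp1 = 0.364)))
  expect_equal(a0$body_mass, 0)
  expect_equal(a0$allocation, 0)

  # doubling both length inputs doubles body mass (E rescaled consistently)
  dbl <- col
  dbl$root_ergosterol_ug_per_g <- 0.4 * 2 + 0.18
  dbl$soil_hyphal_m_per_g <- 2
  a2 <- allocation_table(dbl, c(sp1 = 0.364))
  expect_equal(a2$body_mass, 2 * alloc$body_mass)
})

test_that("replicate aggregation commutes with the linear conversion chain", {
  set.seed(7)
  col <- tidyr::expand_grid(fungal_species = "sp1", host_species = "h1",
                            replicate = 1:5)
  col$root_ergosterol_ug_per_g <- runif(5, 0.3, 2)  # all above the intercept
  col$soil_hyphal_m_per_g <- runif(5, 0.5, 4)
  col$spores_per_g <- runif(5, 10, 100)
  agg <- allocation_table(col, c(sp1 = 0.1))
  per_rep <- allocation_table(col, c(sp1 = 0.1), aggregate_replicates = FALSE)
  expect_equal(nrow(per_rep), 5)
  expect_equal(agg$body_mass, mean(per_rep$body_mass))
  expect_equal(agg$spore_output, mean(per_rep$spore_output))
  expect_equal(agg$allocation, mean(per_rep$allocation))
})

test_that("colonization tables are validated", {
  col <- tibble::tibble(
    fungal_species = c("sp1", "sp1"), host_species = "h1", replicate = c(1, 1),
    root_ergosterol_ug_per_g = 1, soil_hyphal_m_per_g = 1, spores_per_g = 1
  )
  expect_error(read_colonization(col), "duplicate replicate")
  col$replicate <- 1:2
  col$spores_per_g[1] <- -3
  expect_error(read_colonization(col), "negative")
  expect_error(read_colonization("no/such/file.csv"), "not found")
})

test_that("species without a spore-mass entry are excluded with a message", {
  col <- tidyr::expand_grid(fungal_species = c("sp1", "sp2"),
                            host_species = "h1", replicate = 1:2)
  col$root_ergosterol_ug_per_g <- 1
  col$soil_hyphal_m_per_g <- 1
  col$spores_per_g <- 10
  expect_message(a <- allocation_table(col, c(sp1 = 0.1)), "sp2")
  expect_equal(unique(a$fungal_species), "sp1")
})
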