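test_that("trait tables parse with counts, dimorphism and row order preserved", {
  tab <- make_fixture_trait_table()
  rec <- read_spore_traits(tab)
  expect_equal(nrow(rec), nrow(tab))
  expect_equal(rec$species_id, tab$species)

  dim_rec <- rec[rec$species_id == "Ambispora fixturensis", ]
  expect_equal(nrow(dim_rec), 2)
  expect_setequal(dim_rec$morph_label, c("glomoid", "acaulosporoid"))

  # csv round trip through a file
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tab, path)
  expect_equal(nrow(read_spore_traits(path)), nrow(tab))
})

test_that("malformed trait rows fail with the offending species named", {
  tab <- make_fixture_trait_table()

  bad <- tab
  bad$inner_low_long[3] <- bad$inner_high_long[3] + 10
  expect_error(read_spore_traits(bad), bad$species[3], fixed = TRUE)

  dup <- rbind(tab, tab[1, ])
  expect_error(read_spore_traits(dup), "duplicate species x morph")

  expect_error(read_spore_traits(tab[0, ]), "empty")

  path <- withr::local_tempfile(fileext = ".csv")
  txt <- tab
  txt$inner_high_long <- as.character(txt$inner_high_long)
  txt$inner_high_long[2] <- "12O"  # letter O, a typical digitization typo
  readr::write_csv(txt, path)
  expect_error(read_spore_traits(path), txt$species[2], fixed = TRUE)

  nosub <- tab[tab$shape == "subglobose", ][1, ]
  nosub$inner_low_short <- NA
  nosub$inner_high_short <- NA
  expect_error(read_spore_traits(nosub), "short-axis")
})

test_that("spore volumes follow the sphere / prolate-spheroid formulas", {
  # globose: midpoint of (100, 120) is 110, V = (pi/6) 110^3
  one <- tibble::tibble(
    species = "Glomus testus", family = "Glomeraceae", morph = "default",
    shape = "globose", inner_low_long = 100, inner_high_long = 120
  )
  sz <- spore_sizes(read_spore_traits(one))
  expect_equal(sz$diameter_long, 110)
  expect_equal(sz$diameter_short, 110)
  expect_equal(sz$volume, (pi / 6) * 110^3)

  # subglobose: short axis duplicated
  expect_equal(spore_volume(200, 100), (pi / 6) * 200 * 100^2)
  # equal axes reduce to the sphere
  expect_equal(spore_volume(137, 137), spore_volume(137))
  # axis order is enforced
  expect_error(spore_volume(100, 200), "short-axis")
})

test_that("volume is monotone in each diameter and spheroid <= sphere", {
  set.seed(1)
  for (i in 1:25) {
    dl <- runif(1, 10, 500)
    ds <- runif(1, 5, dl)
    eps <- runif(1, 0.1, 5)
    expect_gt(spore_volume(dl + eps, ds), spore_volume(dl, ds))
    expect_gt(spore_volume(dl, min(ds + eps, dl)), spore_volume(dl, ds))
    expect_lte(spore_volume(dl, ds), spore_volume(dl))
  }
  expect_equal(spore_volume(90, 90), spore_volume(90))
})

test_that("mass conversion is the documented linear factor", {
  expect_equal(volume_to_mass(1), 3.64e-7)
  expect_equal(volume_to_mass(0), 0)
  expect_equal(volume_to_mass(1e6), 0.364)
  v1 <- 12345; v2 <- 6789
  expect_equal(volume_to_mass(v1 + v2), volume_to_mass(v1) + volume_to_mass(v2))
  expect_error(volume_to_mass(-1), "non-negative")
})

test_that("inner and outer bases yield the same records, outer falls back when absent", {
  tab <- make_fixture_trait_table()
  inner <- spore_sizes(tab, range_basis = "inner")
  outer <- spore_sizes(tab, range_basis = "outer")
  expect_equal(nrow(inner), nrow(outer))
  expect_equal(inner$species_id, outer$species_id)

  noouter <- tab
  noouter$outer_low_long <- NA_real_
  noouter$outer_high_long <- NA_real_
  expect_message(sz <- spore_sizes(noouter, range_basis = "outer"), "falling back")
  inner2 <- spore_sizes(noouter, range_basis = "inner")
  expect_equal(sz$volume, inner2$volume)
})

test_that("cross-taxa comparison computes spans and geometric fold-differences", {
  d <- tibble::tibble(
    taxon = rep(c("a", "b"), each = 3),
    size = c(10, 100, 1000, 10, 100, 1000)
  )
  cmp <- compare_taxa(d, taxon, size)
  expect_equal(cmp$groups$log10_span, c(2, 2))
  self <- cmp$pairs[cmp$pairs$taxon_1 == "a" & cmp$pairs$taxon_2 == "a", ]
  expect_equal(self$fold_geometric, 1)
  expect_equal(self$fold_arithmetic, 1)

  big <- tibble::tibble(taxon = rep(c("big", "small"), each = 4),
                        size = c(1e6, 2e6, 5e5, 3e6, 10, 20, 5, 30))
  cmp2 <- compare_taxa(big, taxon, size)
  fold <- cmp2$pairs$fold_geometric[cmp2$pairs$taxon_1 == "big" &
                                    cmp2$pairs$taxon_2 == "small"]
  indep <- exp(mean(log(big$size[1:4]))) / exp(mean(log(big$size[5:8])))
  expect_equal(fold, indep)

  d$unit <- rep(c("um3", "ug"), each = 3)
  expect_error(compare_taxa(d, taxon, size, unit = unit), "mixed units")
  d2 <- d; d2$size[1] <- -5
  expect_error(compare_taxa(d2, taxon, size), "positive")
  expect_error(compare_taxa(d[1, ], taxon, size), "at least two")
})
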