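#' Configuration for the synthetic-data generator
#'
#' Collects the seed and every true parameter used by the generator. Defaults
#' mirror the design of the greenhouse allocation experiment the pipeline
#' analyzes (14 fungal species grown on 4 plant hosts with 5 replicates each)
#' and a pure-Brownian trait history. One global seed fans out to independent
#' per-stage substreams, so each stage can be regenerated on its own.
#'
#' All "log" parameters are base-10 logs, matching the scale on which the
#' analyses run.
#'
#' @param seed Integer seed fixing every downstream draw.
#' @param n_species Number of fungal species (tree tips).
#' @param birth_rate Speciation rate of the pure-birth (Yule) tree, per unit
#'   time.
#' @param lambda_true Phylogenetic signal of simulated traits, in `[0, 1]`.
#' @param sigma2 Brownian-motion rate (variance per unit branch length).
#' @param root_state Trait value at the root.
#' @param b_true Trade-off exponent of `R = A / W0^b`; must be positive.
#' @param logA_mean,logA_sd Mean and sd of log10 reproductive allocation A
#'   (ug per g soil). Defaults give A around 3 ug/g spanning roughly an order
#'   of magnitude across species.
#' @param logW0_mean,logW0_sd Mean and sd of log10 single-spore mass (ug).
#'   Defaults center on 0.1 ug (~ 3e5 um^3) and span the observed range of
#'   AM spore masses.
#' @param w0_signal If `TRUE` and a tree is supplied, log10 W0 is evolved by
#'   Brownian motion on the tree (with `lambda_true`) instead of drawn i.i.d.,
#'   so signal in spore size and the trade-off can be emulated jointly.
#' @param body_size_cor Correlation between log10 body size and log10 A.
#' @param logL_mean,logL_sd Mean and sd of log10 total mycelium length
#'   (m per g); default ~5 m/g.
#' @param root_fraction Fraction of total mycelium length inside roots.
#' @param n_hosts Number of plant hosts (default 4).
#' @param n_replicates Replicates per species x host (default 5).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   replicate noise on each measured quantity. Default 0.3, a typical
#'   replicate CV for greenhouse colonization assays.
#' @param host_effect_sd SD (log10 scale) of the lognormal host multiplier on
#'   sporulation.
#' @return A list of class `simulation_config`.
#' @examples
#' simulation_config(seed = 1)
#' @export
simulation_config <- function(seed = 1L,
                              n_species = 14L,
                              birth_rate = 1,
                              lambda_true = 1,
                              sigma2 = 1,
                              root_state = 0,
                              b_true = 1,
                              logA_mean = 0.5,
                              logA_sd = 0.5,
                              logW0_mean = -1,
                              logW0_sd = 0.75,
                              w0_signal = FALSE,
                              body_size_cor = 0.5,
                              logL_mean = 0.7,
                              logL_sd = 0.4,
                              root_fraction = 0.5,
                              n_hosts = 4L,
                              n_replicates = 5L,
                              noise_cv = 0.3,
                              host_effect_sd = 0.2) {
  cfg <- list(
    seed = as.integer(seed), n_species = as.integer(n_species),
    birth_rate = birth_rate, lambda_true = lambda_true, sigma2 = sigma2,
    root_state = root_state, b_true = b_true,
    logA_mean = logA_mean, logA_sd = logA_sd,
    logW0_mean = logW0_mean, logW0_sd = logW0_sd, w0_signal = isTRUE(w0_signal),
    body_size_cor = body_size_cor, logL_mean = logL_mean, logL_sd = logL_sd,
    root_fraction = root_fraction,
    n_hosts = as.integer(n_hosts), n_replicates = as.integer(n_replicates),
    noise_cv = noise_cv, host_effect_sd = host_effect_sd
  )
  if (!is.finite(cfg$seed)) stop("seed must be a finite integer", call. = FALSE)
  if (cfg$n_species < 2) stop("n_species must be at least 2", call. = FALSE)
  if (cfg$birth_rate <= 0) stop("birth_rate must be positive", call. = FALSE)
  if (cfg$lambda_true < 0 || cfg$lambda_true > 1) {
    stop("lambda_true must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$sigma2 < 0) stop("sigma2 must be non-negative", call. = FALSE)
  if (cfg$b_true <= 0) stop("b_true must be positive", call. = FALSE)
  nonneg <- c("logA_sd", "logW0_sd", "logL_sd", "noise_cv", "host_effect_sd")
  for (p in nonneg) {
    if (cfg[[p]] < 0) stop(p, " must be non-negative", call. = FALSE)
  }
  if (cfg$body_size_cor < -1 || cfg$body_size_cor > 1) {
    stop("body_size_cor must lie in [-1, 1]", call. = FALSE)
  }
  if (cfg$root_fraction <= 0 || cfg$root_fraction >= 1) {
    stop("root_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$n_hosts < 1 || cfg$n_replicates < 1) {
    stop("n_hosts and n_replicates must be at least 1", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

# Deterministic substream seed for a named generator stage.
substream_seed <- function(seed, stage) {
  stages <- c("tree", "trait", "w0", "allocation", "hosts", "noise",
              "fixture", "reference")
  i <- match(stage, stages)
  if (is.na(i)) stop("unknown substream stage: ", stage, call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, length(stages))[i]
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Deterministic given the configuration seed; tips labelled `sp01`,
#' `sp02`, ... The Yule tree is ultrametric, standing in for an inferred
#' species tree in recovery experiments.
#'
#' @param config A [simulation_config()].
#' @return A rooted ultrametric `phylo` object with `n_species` tips.
#' @examples
#' simulate_tree(simulation_config(seed = 3, n_species = 8))
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(config$seed, "tree"))
  tr <- ape::rphylo(config$n_species, birth = config$birth_rate, death = 0)
  tr$tip.label <- sprintf("sp%03d", seq_len(config$n_species))
  tr
}

#' Simulate a trait under the lambda model
#'
#' Draws one realization of a continuous trait on the tree from the
#' multivariate normal implied by Brownian motion with rate `sigma2`, root
#' state `root_state`, and tip covariance off-diagonals scaled by
#' `lambda_true`. `lambda_true = 1` is pure Brownian motion; `lambda_true =
#' 0` gives i.i.d. tip values with the Brownian tip variances.
#'
#' @param tree A `phylo` object (e.g. from [simulate_tree()]).
#' @param config A [simulation_config()].
#' @param seed Optional override of the substream seed (so that replicate
#'   draws within a study can differ while remaining reproducible).
#' @return A named numeric vector of tip values.
#' @export
simulate_bm_trait <- function(tree, config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  check_phylo(tree)
  C <- ape::vcv(tree)
  V <- config$lambda_true * C
  diag(V) <- diag(C)
  n <- nrow(V)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(if (is.null(seed)) substream_seed(config$seed, "trait") else seed)
  z <- stats::rnorm(n)
  if (config$sigma2 == 0) {
    x <- rep(config$root_state, n)
  } else {
    U <- chol(config$sigma2 * V)
    x <- config$root_state + as.vector(t(U) %*% z)
  }
  stats::setNames(x, rownames(C))
}

#' Simulate a sporulation/colonization experiment with known ground truth
#'
#' Generates a full greenhouse-style allocation experiment from the
#' Smith-Fretwell model used generatively: per species, single-spore mass
#' `W0` and reproductive allocation `A` are lognormal, and expected spore
#' output is `R = A / W0^b_true`. Each host multiplies sporulation by a
#' lognormal host effect; each replicate applies independent multiplicative
#' lognormal noise (mean 1, CV `noise_cv`) to every measured quantity. Body
#' size is generated as a total mycelium length correlated (on the log scale,
#' correlation `body_size_cor`) with allocation, split into root and soil
#' compartments; the root compartment is re-expressed as ergosterol through
#' the forward calibration `E = 0.4 L + 0.18`, so downstream analysis must
#' invert it.
#'
#' With `noise_cv = 0`, `host_effect_sd = 0` and `logA_sd = 0`, the emitted
#' data satisfy `R = A / W0^b` exactly and the fitted trade-off slope is
#' exactly `-b_true`.
#'
#' @param config A [simulation_config()].
#' @param tree Optional `phylo` object; when supplied and
#'   `config$w0_signal = TRUE`, log10 W0 evolves on the tree (Brownian motion
#'   with `lambda_true`, rate `sigma2` scaled to `logW0_sd` at the tips)
#'   instead of being drawn i.i.d. Species names are taken from the tree tips.
#' @param constants A [conversion_constants()] list used for the forward
#'   ergosterol calibration.
#' @return A list of class `allocation_simulation`:
#'   * `colonization`: tibble in the [read_colonization()] schema
#'     (`n_species * n_hosts * n_replicates` rows),
#'   * `spore_mass`: tibble `species_id`, `mass` (ug),
#'   * `truth`: list with per-species `A`, `W0`, expected `R`, host
#'     multipliers and the full config.
#' @examples
#' sim <- simulate_allocation_experiment(simulation_config(seed = 2))
#' nrow(sim$colonization) # 14 * 4 * 5 = 280
#' @export
simulate_allocation_experiment <- function(config, tree = NULL,
                                           constants = conversion_constants()) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$b_true <= 0) stop("b_true must be positive", call. = FALSE)
  if (config$noise_cv < 0) stop("noise_cv must be non-negative", call. = FALSE)

  if (!is.null(tree)) {
    check_phylo(tree)
    species <- tree$tip.label
    if (length(species) != config$n_species) {
      stop("tree has ", length(species), " tips but config$n_species = ",
           config$n_species, call. = FALSE)
    }
  } else {
    species <- sprintf("sp%03d", seq_len(config$n_species))
  }
  n <- length(species)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  # per-species spore mass W0 (ug, log10 scale)
  set.seed(substream_seed(config$seed, "w0"))
  if (!is.null(tree) && config$w0_signal) {
    bm <- simulate_bm_trait(tree, config, seed = substream_seed(config$seed, "w0"))
    z <- if (stats::sd(bm) > 0) (bm - mean(bm)) / stats::sd(bm) else bm * 0
    log_w0 <- config$logW0_mean + config$logW0_sd * z[species]
  } else {
    log_w0 <- config$logW0_mean + config$logW0_sd * stats::rnorm(n)
  }
  w0 <- 10^log_w0

  # per-species allocation A (ug/g) and correlated body length (m/g)
  set.seed(substream_seed(config$seed, "allocation"))
  zA <- stats::rnorm(n)
  log_a <- config$logA_mean + config$logA_sd * zA
  A <- 10^log_a
  rho <- config$body_size_cor
  zL <- rho * zA + sqrt(1 - rho^2) * stats::rnorm(n)
  log_len <- config$logL_mean + config$logL_sd * zL
  total_length <- 10^log_len

  expected_R <- A / w0^config$b_true

  set.seed(substream_seed(config$seed, "hosts"))
  hosts <- c("Plantago lanceolata", "Plantago major", "Poa annua", "Poa pratensis")
  if (config$n_hosts <= 4) {
    hosts <- hosts[seq_len(config$n_hosts)]
  } else {
    hosts <- c(hosts, sprintf("host%02d", seq_len(config$n_hosts - 4)))
  }
  host_mult <- 10^stats::rnorm(config$n_hosts, 0, config$host_effect_sd)
  names(host_mult) <- hosts

  grid <- tidyr::expand_grid(
    fungal_species = species, host_species = hosts,
    replicate = seq_len(config$n_replicates)
  )
  set.seed(substream_seed(config$seed, "noise"))
  # lognormal multiplier with mean 1 and CV noise_cv
  noise_mult <- function(k) {
    if (config$noise_cv == 0) return(rep(1, k))
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    exp(stats::rnorm(k, -sdlog^2 / 2, sdlog))
  }
  m <- nrow(grid)
  sp_idx <- match(grid$fungal_species, species)
  r_rep <- expected_R[sp_idx] * host_mult[grid$host_species] * noise_mult(m)
  root_len <- total_length[sp_idx] * config$root_fraction * noise_mult(m)
  soil_len <- total_length[sp_idx] * (1 - config$root_fraction) * noise_mult(m)
  ergosterol <- constants$ergosterol_slope * root_len + constants$ergosterol_intercept

  colonization <- grid |>
    dplyr::mutate(
      root_ergosterol_ug_per_g = ergosterol,
      soil_hyphal_m_per_g = soil_len,
      spores_per_g = unname(r_rep)
    )
  structure(list(
    colonization = colonization,
    spore_mass = tibble::tibble(species_id = species, mass = w0),
    truth = list(
      species = species, A = stats::setNames(A, species),
      W0 = stats::setNames(w0, species),
      expected_R = stats::setNames(expected_R, species),
      total_length = stats::setNames(total_length, species),
      host_multipliers = host_mult, config = config
    )
  ), class = "allocation_simulation")
}

#' Small spore-trait fixture table
#'
#' Emits a deterministic trait table exercising every parser feature: globose
#' and subglobose records, inner ranges nested inside outer ranges, and one
#' dimorphic species with glomoid and acaulosporoid rows.
#'
#' @param config A [simulation_config()] (only the seed is used).
#' @param path Optional path; when given the table is also written as CSV.
#' @param species Optional character vector of species names (e.g. tree tip
#'   labels) to use instead of the built-in fixture names; the dimorphic
#'   example species is added only when `species` is `NULL`.
#' @return A tibble in the [read_spore_traits()] input schema.
#' @examples
#' make_fixture_trait_table()
#' @export
make_fixture_trait_table <- function(config = simulation_config(), path = NULL,
                                     species = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(config$seed, "fixture"))

  add_dimorphic <- is.null(species)
  if (is.null(species)) {
    species <- sprintf("Fixturea species%02d", seq_len(9))
  }
  n_total <- length(species)
  n_glob <- ceiling(n_total / 2)
  n_sub <- n_total - n_glob
  d <- round(10^stats::runif(n_total, 1.6, 2.6))  # 40-400 um
  tab <- tibble::tibble(
    species = species,
    family = rep(c("Glomeraceae", "Acaulosporaceae", "Gigasporaceae"),
                 length.out = n_glob + n_sub),
    morph = "default",
    shape = rep(c("globose", "subglobose"), times = c(n_glob, n_sub)),
    inner_low_long = 0.9 * d, inner_high_long = 1.1 * d,
    outer_low_long = 0.75 * d, outer_high_long = 1.25 * d,
    inner_low_short = NA_real_, inner_high_short = NA_real_,
    outer_low_short = NA_real_, outer_high_short = NA_real_
  )
  sub <- tab$shape == "subglobose"
  tab$inner_low_short[sub] <- 0.9 * 0.7 * d[sub]
  tab$inner_high_short[sub] <- 1.1 * 0.7 * d[sub]
  tab$outer_low_short[sub] <- 0.75 * 0.7 * d[sub]
  tab$outer_high_short[sub] <- 1.25 * 0.7 * d[sub]

  out <- tab
  if (add_dimorphic) {
    dim_d <- c(glomoid = 90, acaulosporoid = 210)
    dimo <- tibble::tibble(
      species = "Ambispora fixturensis",
      family = "Ambisporaceae",
      morph = names(dim_d),
      shape = "globose",
      inner_low_long = 0.9 * dim_d, inner_high_long = 1.1 * dim_d,
      outer_low_long = 0.75 * dim_d, outer_high_long = 1.25 * dim_d,
      inner_low_short = NA_real_, inner_high_short = NA_real_,
      outer_low_short = NA_real_, outer_high_short = NA_real_
    )
    out <- dplyr::bind_rows(tab, dimo)
  }
  if (!is.null(path)) readr::write_csv(out, path)
  out
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation config (seed ", x$seed, "): ", x$n_species, " species x ",
      x$n_hosts, " hosts x ", x$n_replicates, " replicates\n", sep = "")
  cat(sprintf("  trade-off b = %g, lambda = %g, noise CV = %g, host sd = %g\n",
              x$b_true, x$lambda_true, x$noise_cv, x$host_effect_sd))
  invisible(x)
}

#' @export
print.allocation_simulation <- function(x, ...) {
  cat("Simulated allocation experiment: ", nrow(x$colonization),
      " colonization records, ", nrow(x$spore_mass), " species\n", sep = "")
  invisible(x)
}
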