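#' Configuration for the end-to-end pipeline
#'
#' @param trait_csv Path to (or data frame of) the spore-trait table
#'   ([read_spore_traits()] schema).
#' @param colonization_csv Path to (or data frame of) the colonization table
#'   ([read_colonization()] schema).
#' @param tree_file Optional path to a rooted newick tree (or a `phylo`
#'   object); required when `run_signal = TRUE`.
#' @param range_basis `"inner"` or `"outer"` diameter ranges.
#' @param morph Morph kept for dimorphic species in the allocation analyses.
#' @param run_signal Estimate phylogenetic signal? Needs `tree_file`.
#' @param alpha Significance level.
#' @param out_dir Output directory for report files; created if absent.
#' @param constants A [conversion_constants()] list.
#' @param seed Seed recorded in the run log (the analysis itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(trait_csv, colonization_csv, tree_file = NULL,
                            range_basis = "inner", morph = "glomoid",
                            run_signal = !is.null(tree_file), alpha = 0.05,
                            out_dir = tempfile("sporetrade-run-"),
                            constants = conversion_constants(), seed = 1L) {
  for (p in list(trait_csv, colonization_csv)) {
    if (!is.data.frame(p) && !file.exists(p)) {
      stop("input file not found: ", p, call. = FALSE)
    }
  }
  if (isTRUE(run_signal) && is.null(tree_file)) {
    stop("phylogenetic-signal analysis requested but no tree supplied ",
         "(tree_file is missing)", call. = FALSE)
  }
  if (!is.null(tree_file) && !inherits(tree_file, "phylo") && !file.exists(tree_file)) {
    stop("tree file not found: ", tree_file, call. = FALSE)
  }
  structure(list(
    trait_csv = trait_csv, colonization_csv = colonization_csv,
    tree_file = tree_file, range_basis = range_basis, morph = morph,
    run_signal = isTRUE(run_signal), alpha = alpha, out_dir = out_dir,
    constants = constants, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full comparative analysis
#'
#' Executes every stage on the configured inputs: spore-size derivation,
#' cross-family size comparison, phylogenetic signal in log10 spore volume
#' (run twice when dimorphic morphs are present, once per morph set),
#' biomass/allocation conversion, the trade-off analysis in all body-size
#' correction variants, and body-size scaling. Writes one report file per
#' stage plus a run log of every constant and decision, and returns the
#' results invisibly. Outputs are deterministic for a given configuration.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list with elements `sizes`, `comparison`, `signal`
#'   (named list of `lambda_fit` per morph set, or `NULL`), `allocation`,
#'   `tradeoff`, `scaling`, and `files` (paths written).
#' @examples
#' \donttest{
#' sim <- simulate_allocation_experiment(simulation_config(seed = 9))
#' cfg <- pipeline_config(make_fixture_trait_table(), sim$colonization)
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  log_lines <- c(
    "sporetrade pipeline run",
    paste0("seed: ", config$seed),
    paste0("range basis: ", config$range_basis),
    paste0("morph for single-trait analyses: ", config$morph),
    paste0("alpha: ", config$alpha),
    paste0("constants: ",
           paste(names(unclass(config$constants)),
                 unlist(config$constants), sep = "=", collapse = ", "))
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    readr::write_csv(df, path)
    files <<- c(files, path)
    path
  }

  # -- spore sizes ------------------------------------------------------------
  sizes <- stage("spore_sizes", {
    records <- read_spore_traits(config$trait_csv)
    spore_sizes(records, range_basis = config$range_basis,
                constants = config$constants)
  })
  emit(sizes, "spore_sizes.csv")

  # -- cross-family comparison ------------------------------------------------
  comparison <- stage("taxa_comparison", {
    one_morph <- select_morph(sizes, prefer = config$morph)
    keep <- one_morph |>
      dplyr::group_by(.data$family) |>
      dplyr::filter(dplyr::n() >= 2) |>
      dplyr::ungroup()
    if (nrow(keep) >= 2 && length(unique(keep$family)) >= 1) {
      compare_taxa(keep, family, volume)
    } else {
      NULL
    }
  })
  if (!is.null(comparison)) {
    emit(comparison$groups, "taxa_comparison.csv")
  }

  # -- phylogenetic signal ----------------------------------------------------
  signal <- NULL
  if (config$run_signal) {
    signal <- stage("phylo_signal", {
      tree <- if (inherits(config$tree_file, "phylo")) config$tree_file
              else ape::read.tree(config$tree_file)
      if (is.null(tree)) stop("could not read tree: ", config$tree_file)
      morph_sets <- if (any(duplicated(sizes$species_id))) {
        c("glomoid", "acaulosporoid")
      } else {
        config$morph
      }
      fits <- lapply(morph_sets, function(m) {
        sel <- select_morph(sizes, prefer = m)
        sel <- sel[sel$species_id %in% tree$tip.label, ]
        fit_pagel_lambda(tree, stats::setNames(log10(sel$volume), sel$species_id))
      })
      names(fits) <- morph_sets
      fits
    })
    sig_tbl <- purrr::map_dfr(signal, tidy, .id = "morph_set")
    path <- file.path(config$out_dir, "lambda_report.json")
    jsonlite::write_json(sig_tbl, path, auto_unbox = TRUE, digits = NA)
    files <- c(files, path)
  }

  # -- allocation -------------------------------------------------------------
  allocation <- stage("allocation", {
    w0 <- select_morph(sizes, prefer = config$morph)
    allocation_table(config$colonization_csv,
                     dplyr::select(w0, "species_id", "mass"),
                     constants = config$constants)
  })
  emit(allocation, "allocation.csv")

  # -- trade-off --------------------------------------------------------------
  tradeoff <- stage("tradeoff", {
    tree <- NULL
    if (!is.null(config$tree_file)) {
      tree <- if (inherits(config$tree_file, "phylo")) config$tree_file
              else ape::read.tree(config$tree_file)
    }
    tradeoff_analysis(allocation, tree = tree, alpha = config$alpha)
  })
  emit(tidy(tradeoff), "tradeoff_report.csv")
  path <- file.path(config$out_dir, "tradeoff_report.json")
  jsonlite::write_json(
    list(fits = tidy(tradeoff),
         pic = if (is.null(tradeoff$pic)) NULL else tradeoff$pic),
    path, auto_unbox = TRUE, digits = NA)
  files <- c(files, path)

  # -- scaling ----------------------------------------------------------------
  scaling <- stage("scaling", scaling_analysis(allocation, alpha = config$alpha))
  emit(tidy(scaling), "scaling_report.csv")

  log_lines <- c(log_lines,
                 paste0("records: ", nrow(sizes), " spore sizes, ",
                        nrow(allocation), " allocation points"),
                 paste0("files: ", paste(basename(files), collapse = ", ")))
  log_path <- file.path(config$out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  files <- c(files, log_path)

  invisible(list(sizes = sizes, comparison = comparison, signal = signal,
                 allocation = allocation, tradeoff = tradeoff,
                 scaling = scaling, files = files))
}
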