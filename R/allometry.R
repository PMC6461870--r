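#' Offspring size-number trade-off analysis
#'
#' Fits the Smith-Fretwell trade-off `R = A / W0^b` on log10-transformed
#' variables by SMA regression, in the three body-size-correction variants:
#'
#' * `uncorrected`: log R vs log W0 (the slope estimates `-b`);
#' * `per_length`: spore output per meter of extraradical mycelium,
#'   log(R / extraradical length) vs log W0;
#' * `per_mass`: spore output per unit mycelium mass,
#'   log(R / body mass) vs log W0;
#'
#' plus the allocation-size relationship log A vs log W0. Each fit carries the
#' correlation test (slope vs 0) and the SMA test against slope -1 (inverse
#' proportionality: a fixed reproductive budget split into few large or many
#' small spores). When the uncorrected correlation is significant at `alpha`
#' and a tree is supplied, a phylogenetically independent-contrast correlation
#' of the species-level (host-averaged) log values is attached, separating a
#' physical constraint acting within every lineage from covariation inherited
#' from few evolutionary events.
#'
#' @param allocation Allocation table from [allocation_table()] (columns
#'   `fungal_species`, `host_species`, `spore_output`, `spore_mass_w0`,
#'   `allocation`, `body_mass`, `extraradical_length`). Points are species x
#'   host combinations, pooled into one fit.
#' @param tree Optional rooted `phylo` whose tips match `fungal_species`.
#' @param alpha Significance level for the PIC trigger and CIs.
#' @param correction `"ratio"` (default; divide output by the size variable,
#'   matching "spores per meter of hyphae" / "per gram of mycelium") or
#'   `"residual"` (regress log R on the log size variable by OLS and use the
#'   residuals).
#' @return An object of class `tradeoff_report`: named list of `sma_fit`
#'   objects (`uncorrected`, `per_length`, `per_mass`, `allocation_vs_size`),
#'   matching slope tests vs -1 in `$tests`, optional `$pic` tibble, and
#'   `$n_points`. See [tidy.tradeoff_report()].
#' @examples
#' sim <- simulate_allocation_experiment(simulation_config(seed = 5))
#' alloc <- allocation_table(sim$colonization, sim$spore_mass)
#' tradeoff_analysis(alloc)
#' @export
tradeoff_analysis <- function(allocation, tree = NULL, alpha = 0.05,
                              correction = c("ratio", "residual")) {
  correction <- match.arg(correction)
  d <- check_allocation(allocation)

  logs <- d |>
    dplyr::mutate(
      log_w0 = log10(.data$spore_mass_w0),
      log_r = log10(.data$spore_output),
      log_a = log10(.data$allocation),
      log_body = log10(.data$body_mass),
      log_extra = log10(.data$extraradical_length)
    )
  if (correction == "ratio") {
    logs$y_length <- logs$log_r - logs$log_extra
    logs$y_mass <- logs$log_r - logs$log_body
  } else {
    logs$y_length <- stats::resid(stats::lm(log_r ~ log_extra, data = logs))
    logs$y_mass <- stats::resid(stats::lm(log_r ~ log_body, data = logs))
  }

  if (stats::sd(logs$log_w0) == 0) stop("zero variance in spore mass W0", call. = FALSE)
  # a degenerate y axis (e.g. constant allocation) voids that variant only
  try_fit <- function(y) {
    tryCatch(sma_fit(logs, log_w0, {{ y }}, alpha = alpha),
             error = function(e) {
               message("variant skipped: ", conditionMessage(e))
               NULL
             })
  }
  fits <- list(
    uncorrected = sma_fit(logs, log_w0, log_r, alpha = alpha),
    per_length = try_fit(y_length),
    per_mass = try_fit(y_mass),
    allocation_vs_size = try_fit(log_a)
  )
  fits <- fits[!vapply(fits, is.null, logical(1))]
  tests <- lapply(fits, test_sma_slope, b0 = -1)

  pic <- NULL
  if (!is.null(tree) && fits$uncorrected$p_correlation < alpha) {
    sp <- logs |>
      dplyr::group_by(.data$fungal_species) |>
      dplyr::summarise(log_w0 = mean(.data$log_w0), log_r = mean(.data$log_r),
                       .groups = "drop")
    common <- intersect(sp$fungal_species, tree$tip.label)
    if (length(common) >= 3) {
      pic <- pic_correlation(
        tree,
        stats::setNames(sp$log_w0, sp$fungal_species),
        stats::setNames(sp$log_r, sp$fungal_species)
      )
    } else {
      message("PIC follow-up skipped: fewer than 3 species match the tree tips")
    }
  }
  structure(list(fits = fits, tests = tests, pic = pic,
                 n_points = nrow(logs), alpha = alpha, correction = correction),
            class = "tradeoff_report")
}

#' Body-size scaling of reproductive traits
#'
#' Fits, by SMA on log10 variables, the scaling of each reproductive trait
#' with total body size `Walpha`: spore size (log W0 vs log Walpha), spore
#' output (log R vs log Walpha), and total reproductive output
#' (log(R * W0) vs log Walpha), whose slope estimates the allometric exponent
#' `beta` and whose intercept estimates `log10(sigma)` in
#' `R W0 = sigma * Walpha^beta`.
#'
#' @inheritParams tradeoff_analysis
#' @return An object of class `scaling_report`: `sma_fit` objects
#'   `size_vs_body`, `output_vs_body`, `allocation_vs_body`, plus
#'   `beta_hat` and `log10_sigma_hat`.
#' @examples
#' sim <- simulate_allocation_experiment(simulation_config(seed = 5))
#' alloc <- allocation_table(sim$colonization, sim$spore_mass)
#' scaling_analysis(alloc)
#' @export
scaling_analysis <- function(allocation, alpha = 0.05) {
  d <- check_allocation(allocation)
  logs <- d |>
    dplyr::mutate(
      log_w0 = log10(.data$spore_mass_w0),
      log_r = log10(.data$spore_output),
      log_body = log10(.data$body_mass),
      log_rw0 = log10(.data$spore_output * .data$spore_mass_w0)
    )
  if (stats::sd(logs$log_body) == 0) stop("zero variance in body mass", call. = FALSE)
  try_fit <- function(y) {
    tryCatch(sma_fit(logs, log_body, {{ y }}, alpha = alpha),
             error = function(e) {
               message("relationship skipped: ", conditionMessage(e))
               NULL
             })
  }
  fits <- list(
    size_vs_body = try_fit(log_w0),
    output_vs_body = try_fit(log_r),
    allocation_vs_body = try_fit(log_rw0)
  )
  fits <- fits[!vapply(fits, is.null, logical(1))]
  ab <- fits$allocation_vs_body
  structure(list(fits = fits,
                 beta_hat = if (is.null(ab)) NA_real_ else ab$slope,
                 log10_sigma_hat = if (is.null(ab)) NA_real_ else ab$intercept,
                 n_points = nrow(logs), alpha = alpha),
            class = "scaling_report")
}

# Validate the allocation table and drop non-positive rows with a message.
check_allocation <- function(allocation) {
  req <- c("fungal_species", "host_species", "spore_output", "spore_mass_w0",
           "allocation", "body_mass", "extraradical_length")
  if (!is.data.frame(allocation) || !all(req %in% names(allocation))) {
    stop("allocation table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  d <- tibble::as_tibble(allocation)
  pos_cols <- c("spore_output", "spore_mass_w0", "allocation", "body_mass",
                "extraradical_length")
  ok <- Reduce(`&`, lapply(d[pos_cols], function(v) is.finite(v) & v > 0))
  if (!all(ok)) {
    message("excluding ", sum(!ok),
            " species x host point(s) with non-positive or missing values")
    d <- d[ok, ]
  }
  if (nrow(d) < 3) stop("need at least 3 usable species x host points", call. = FALSE)
  d
}

#' @export
print.tradeoff_report <- function(x, ...) {
  cat("Offspring size-number trade-off (", x$n_points, " species x host points, ",
      x$correction, " correction)\n\n", sep = "")
  print(tidy(x))
  if (!is.null(x$pic)) {
    cat("\nPIC correlation (uncorrected trade-off):\n")
    print(x$pic)
  }
  invisible(x)
}

#' @export
print.scaling_report <- function(x, ...) {
  cat("Body-size scaling (", x$n_points, " species x host points)\n\n", sep = "")
  print(tidy(x))
  cat(sprintf("\nbeta_hat = %.4f, log10(sigma_hat) = %.4f\n",
              x$beta_hat, x$log10_sigma_hat))
  invisible(x)
}
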