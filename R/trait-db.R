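#' Read a spore-trait table
#'
#' Reads a CSV of published spore descriptions, one row per species x spore
#' morph. Taxonomic descriptions report spore size as diameter ranges: an
#' *inner* range within which most spores fall and an optional *outer* range
#' including extreme values. Sub-globose spores additionally carry a short-axis
#' range. Dimorphic species (the Ambisporaceae with distinct "glomoid" and
#' "acaulosporoid" spore types) appear as two rows sharing the species name but
#' differing in `morph`.
#'
#' Expected columns (um units assumed): `species`, `family`, `shape`
#' (`"globose"` or `"subglobose"`), `inner_low_long`, `inner_high_long`, and
#' optionally `morph` (defaults to `"default"`), `outer_low_long`,
#' `outer_high_long`, `inner_low_short`, `inner_high_short`, `outer_low_short`,
#' `outer_high_short`.
#'
#' @param path Path to a CSV file (comma-separated, UTF-8, header row
#'   mandatory), or a data frame already in the schema above.
#' @return A tibble of validated spore records in file order, with columns
#'   `species_id`, `family`, `morph_label`, `shape_class` and the range
#'   columns.
#' @examples
#' tab <- make_fixture_trait_table()
#' read_spore_traits(tab)
#' @export
read_spore_traits <- function(path) {
  if (is.data.frame(path)) {
    raw <- tibble::as_tibble(path)
  } else {
    if (!file.exists(path)) stop("trait table not found: ", path, call. = FALSE)
    raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  }
  if (nrow(raw) == 0) stop("trait table is empty", call. = FALSE)

  required <- c("species", "family", "shape", "inner_low_long", "inner_high_long")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("trait table lacks required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"morph" %in% names(raw)) raw$morph <- "default"
  raw$morph[is.na(raw$morph) | raw$morph == ""] <- "default"

  num_cols <- c("inner_low_long", "inner_high_long", "outer_low_long", "outer_high_long",
                "inner_low_short", "inner_high_short", "outer_low_short", "outer_high_short")
  for (cc in intersect(num_cols, names(raw))) {
    val <- raw[[cc]]
    if (!is.numeric(val)) {
      parsed <- suppressWarnings(as.numeric(val))
      bad <- !is.na(val) & val != "" & is.na(parsed)
      if (any(bad)) {
        stop(sprintf("malformed numeric value in column '%s' for species: %s",
                     cc, paste(unique(raw$species[bad]), collapse = ", ")),
             call. = FALSE)
      }
      raw[[cc]] <- parsed
    }
  }
  for (cc in setdiff(num_cols, names(raw))) raw[[cc]] <- NA_real_

  shape <- tolower(trimws(raw$shape))
  bad_shape <- !shape %in% c("globose", "subglobose", "sub-globose")
  if (any(bad_shape)) {
    stop("unknown shape class for species: ",
         paste(unique(raw$species[bad_shape]), collapse = ", "),
         " (expected 'globose' or 'subglobose')", call. = FALSE)
  }
  shape[shape == "sub-globose"] <- "subglobose"

  morph <- tolower(trimws(raw$morph))
  bad_morph <- !morph %in% c("default", "glomoid", "acaulosporoid")
  if (any(bad_morph)) {
    stop("unknown morph label for species: ",
         paste(unique(raw$species[bad_morph]), collapse = ", "), call. = FALSE)
  }

  key <- paste(raw$species, morph, sep = " / ")
  if (anyDuplicated(key) > 0) {
    stop("duplicate species x morph entries: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }

  rec <- tibble::tibble(
    species_id = as.character(raw$species),
    family = as.character(raw$family),
    morph_label = morph,
    shape_class = shape,
    inner_low_long = raw$inner_low_long, inner_high_long = raw$inner_high_long,
    outer_low_long = raw$outer_low_long, outer_high_long = raw$outer_high_long,
    inner_low_short = raw$inner_low_short, inner_high_short = raw$inner_high_short,
    outer_low_short = raw$outer_low_short, outer_high_short = raw$outer_high_short
  )

  check_pair <- function(low, high, label) {
    present <- !is.na(low) | !is.na(high)
    half <- present & (is.na(low) | is.na(high))
    if (any(half)) {
      stop(sprintf("%s range has only one bound for species: %s", label,
                   paste(unique(rec$species_id[half]), collapse = ", ")), call. = FALSE)
    }
    both <- !is.na(low) & !is.na(high)
    bad <- both & (low > high | low <= 0)
    if (any(bad)) {
      stop(sprintf("invalid %s range (need 0 < low <= high) for species: %s", label,
                   paste(unique(rec$species_id[bad]), collapse = ", ")), call. = FALSE)
    }
    invisible(NULL)
  }
  check_pair(rec$inner_low_long, rec$inner_high_long, "inner long-axis")
  check_pair(rec$outer_low_long, rec$outer_high_long, "outer long-axis")
  check_pair(rec$inner_low_short, rec$inner_high_short, "inner short-axis")
  check_pair(rec$outer_low_short, rec$outer_high_short, "outer short-axis")

  if (any(is.na(rec$inner_low_long))) {
    stop("inner long-axis range is mandatory; missing for species: ",
         paste(unique(rec$species_id[is.na(rec$inner_low_long)]), collapse = ", "),
         call. = FALSE)
  }
  sub_no_short <- rec$shape_class == "subglobose" & is.na(rec$inner_low_short)
  if (any(sub_no_short)) {
    stop("subglobose records need a short-axis inner range; missing for species: ",
         paste(unique(rec$species_id[sub_no_short]), collapse = ", "), call. = FALSE)
  }
  class(rec) <- c("spore_records", class(rec))
  rec
}

#' Spore volume from diameters
#'
#' Volume of a spore modelled as a sphere (globose, one diameter) or a prolate
#' spheroid (sub-globose, long axis plus duplicated short axis):
#' `V = (pi/6) * d_long * d_short^2`. With `d_short = d_long` this reduces to
#' the sphere volume `(pi/6) d^3`.
#'
#' @param diameter_long Long-axis diameter, um.
#' @param diameter_short Short-axis diameter, um; defaults to `diameter_long`.
#' @return Volume in um^3.
#' @examples
#' spore_volume(110)       # globose, ~6.97e5 um^3
#' spore_volume(200, 100)  # prolate spheroid
#' @export
spore_volume <- function(diameter_long, diameter_short = diameter_long) {
  if (any(!is.finite(diameter_long)) || any(!is.finite(diameter_short)) ||
      any(diameter_long <= 0) || any(diameter_short <= 0)) {
    stop("diameters must be positive and finite", call. = FALSE)
  }
  if (any(diameter_short > diameter_long)) {
    stop("short-axis diameter exceeds long-axis diameter", call. = FALSE)
  }
  (pi / 6) * diameter_long * diameter_short^2
}

#' Convert spore volume to mass
#'
#' Applies the empirical density-like factor for AM fungal spores:
#' 1 um^3 weighs 3.64e-7 ug by default.
#'
#' @param volume Spore volume(s), um^3; must be non-negative.
#' @param constants A [conversion_constants()] list.
#' @return Mass in ug.
#' @examples
#' volume_to_mass(1e6) # 0.364 ug
#' @export
volume_to_mass <- function(volume, constants = conversion_constants()) {
  if (any(!is.finite(volume)) || any(volume < 0)) {
    stop("volume must be non-negative and finite", call. = FALSE)
  }
  volume * constants$spore_mass_per_volume
}

#' Derive single spore sizes from diameter-range records
#'
#' Collapses each record's diameter ranges to one diameter per axis (the
#' midpoint of the chosen range pair), then computes the spore volume (sphere
#' or prolate spheroid, see [spore_volume()]) and mass (see
#' [volume_to_mass()]). Records lacking the requested outer range fall back to
#' the inner range with a message.
#'
#' @param records Spore records from [read_spore_traits()], or a path/data
#'   frame accepted by it.
#' @param range_basis Which range pair to use: `"inner"` (default; most spores
#'   fall within it, hence the more representative estimate) or `"outer"`
#'   (extreme values).
#' @param constants A [conversion_constants()] list.
#' @return A tibble with one row per species x morph: `species_id`, `family`,
#'   `morph_label`, `range_basis`, `diameter_long`, `diameter_short` (um),
#'   `volume` (um^3), `mass` (ug).
#' @examples
#' sizes <- spore_sizes(make_fixture_trait_table())
#' head(sizes)
#' @export
spore_sizes <- function(records, range_basis = c("inner", "outer"),
                        constants = conversion_constants()) {
  range_basis <- match.arg(range_basis)
  if (!inherits(records, "spore_records")) records <- read_spore_traits(records)

  use_outer <- range_basis == "outer" & !is.na(records$outer_low_long)
  if (range_basis == "outer") {
    n_fallback <- sum(is.na(records$outer_low_long))
    if (n_fallback > 0) {
      message(n_fallback, " record(s) lack an outer range; falling back to the inner range")
    }
  }
  low_long <- ifelse(use_outer, records$outer_low_long, records$inner_low_long)
  high_long <- ifelse(use_outer, records$outer_high_long, records$inner_high_long)
  d_long <- (low_long + high_long) / 2

  sub <- records$shape_class == "subglobose"
  use_outer_s <- use_outer & !is.na(records$outer_low_short)
  low_short <- ifelse(use_outer_s, records$outer_low_short, records$inner_low_short)
  high_short <- ifelse(use_outer_s, records$outer_high_short, records$inner_high_short)
  d_short <- ifelse(sub, (low_short + high_short) / 2, d_long)
  # antecedent descriptions occasionally swap axes; keep the geometry valid
  swap <- sub & d_short > d_long
  if (any(swap)) {
    tmp <- d_long[swap]
    d_long[swap] <- d_short[swap]
    d_short[swap] <- tmp
  }
  if (any(!is.finite(d_long)) || any(d_long <= 0) || any(!is.finite(d_short)) || any(d_short <= 0)) {
    stop("non-positive computed diameter", call. = FALSE)
  }
  vol <- spore_volume(d_long, d_short)
  tibble::tibble(
    species_id = records$species_id,
    family = records$family,
    morph_label = records$morph_label,
    range_basis = range_basis,
    diameter_long = d_long,
    diameter_short = d_short,
    volume = vol,
    mass = volume_to_mass(vol, constants)
  )
}

#' Select one spore morph per species
#'
#' Dimorphic species carry two size entries (glomoid and acaulosporoid spore
#' types). Single-trait analyses need one value per species; this keeps the
#' preferred morph where two exist and the only morph otherwise.
#'
#' @param sizes Output of [spore_sizes()] (or any tibble with `species_id` and
#'   `morph_label`).
#' @param prefer Morph kept for dimorphic species: `"glomoid"` or
#'   `"acaulosporoid"`.
#' @return The filtered tibble, one row per species.
#' @export
select_morph <- function(sizes, prefer = c("glomoid", "acaulosporoid")) {
  prefer <- match.arg(prefer)
  sizes |>
    dplyr::group_by(.data$species_id) |>
    dplyr::filter(dplyr::n() == 1 | .data$morph_label == prefer) |>
    dplyr::ungroup()
}

#' Compare offspring-size distributions across taxa
#'
#' Summarizes each taxon's offspring-size distribution (quartiles, geometric
#' mean, orders of magnitude spanned) and computes pairwise fold-differences.
#' The primary fold-difference is the ratio of geometric means, the natural
#' average for quantities analyzed on a log scale; the arithmetic-mean ratio is
#' reported alongside.
#'
#' @param data A data frame with one row per species.
#' @param taxon Column (tidy-eval) naming the group/taxon label.
#' @param size Column (tidy-eval) holding offspring sizes; strictly positive,
#'   one consistent unit across all groups.
#' @param unit Optional column (tidy-eval) declaring the unit of each row; an
#'   error is raised if more than one unit is present.
#' @return A list of class `taxa_comparison` with elements `groups` (per-taxon
#'   summaries: `n`, `q25`, `median`, `q75`, `geometric_mean`,
#'   `arithmetic_mean`, `log10_span`), `pairs` (per ordered pair:
#'   `fold_geometric`, `fold_arithmetic`), and `data` (taxon/size tibble for
#'   plotting).
#' @examples
#' sizes <- spore_sizes(make_fixture_trait_table())
#' compare_taxa(sizes, family, volume)
#' @export
compare_taxa <- function(data, taxon, size, unit = NULL) {
  df <- tibble::tibble(
    taxon = as.character(rlang::eval_tidy(rlang::enquo(taxon), data)),
    size = rlang::eval_tidy(rlang::enquo(size), data)
  )
  unit_q <- rlang::enquo(unit)
  if (!rlang::quo_is_null(unit_q)) {
    units <- unique(as.character(rlang::eval_tidy(unit_q, data)))
    if (length(units) > 1) {
      stop("mixed units declared: ", paste(units, collapse = ", "), call. = FALSE)
    }
  }
  if (any(!is.finite(df$size)) || any(df$size <= 0)) {
    stop("offspring sizes must be positive and finite", call. = FALSE)
  }
  groups <- df |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(
      n = dplyr::n(),
      q25 = stats::quantile(.data$size, 0.25, names = FALSE),
      median = stats::median(.data$size),
      q75 = stats::quantile(.data$size, 0.75, names = FALSE),
      geometric_mean = exp(mean(log(.data$size))),
      arithmetic_mean = mean(.data$size),
      log10_span = log10(max(.data$size) / min(.data$size)),
      .groups = "drop"
    )
  if (any(groups$n < 2)) {
    stop("each taxon needs at least two values; too few in: ",
         paste(groups$taxon[groups$n < 2], collapse = ", "), call. = FALSE)
  }
  pairs <- tidyr::expand_grid(taxon_1 = groups$taxon, taxon_2 = groups$taxon) |>
    dplyr::left_join(dplyr::select(groups, taxon_1 = "taxon",
                                   gm1 = "geometric_mean", am1 = "arithmetic_mean"),
                     by = "taxon_1") |>
    dplyr::left_join(dplyr::select(groups, taxon_2 = "taxon",
                                   gm2 = "geometric_mean", am2 = "arithmetic_mean"),
                     by = "taxon_2") |>
    dplyr::mutate(fold_geometric = .data$gm1 / .data$gm2,
                  fold_arithmetic = .data$am1 / .data$am2) |>
    dplyr::select("taxon_1", "taxon_2", "fold_geometric", "fold_arithmetic")
  structure(list(groups = groups, pairs = pairs, data = df),
            class = "taxa_comparison")
}

#' @export
print.taxa_comparison <- function(x, ...) {
  cat("Offspring-size comparison across", nrow(x$groups), "taxa\n\n")
  print(x$groups)
  invisible(x)
}
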