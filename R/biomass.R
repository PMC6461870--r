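#' Invert the ergosterol calibration to intraradical hyphal length
#'
#' Root colonization is assayed as ergosterol (ug per g dry root); the linear
#' calibration `E = 0.4 L + 0.18` relates it to hyphal length L in meters.
#' This inverts it: `L = (E - 0.18) / 0.4`. Ergosterol values below the
#' intercept would give negative lengths, which are physically impossible; they
#' are clamped to zero with a warning.
#'
#' @param ergosterol Ergosterol content, ug (per g dry root); non-negative.
#' @param constants A [conversion_constants()] list.
#' @return Hyphal length in m (per g dry root).
#' @examples
#' ergosterol_to_hyphal_length(0.58) # 1 m
#' @export
ergosterol_to_hyphal_length <- function(ergosterol, constants = conversion_constants()) {
  if (any(!is.finite(ergosterol)) || any(ergosterol < 0)) {
    stop("ergosterol must be non-negative and finite", call. = FALSE)
  }
  len <- (ergosterol - constants$ergosterol_intercept) / constants$ergosterol_slope
  below <- len < 0
  if (any(below)) {
    warning(sum(below), " ergosterol value(s) below the calibration intercept (",
            constants$ergosterol_intercept, " ug); clamping length to 0",
            call. = FALSE)
    len[below] <- 0
  }
  len
}

#' Hyphal length to dry mass
#'
#' Treats hyphae as cylinders of constant radius (default 4 um) and applies
#' the dry density 0.23 g/cm^3: `mass = pi r^2 L * density`. One meter of
#' 4-um-radius hypha is ~5.03e-5 cm^3, i.e. ~11.56 ug dry mass.
#'
#' @param length_m Hyphal length in m; non-negative.
#' @param constants A [conversion_constants()] list.
#' @return Dry mass in ug.
#' @examples
#' hyphal_length_to_dry_mass(1) # ~11.56 ug
#' @export
hyphal_length_to_dry_mass <- function(length_m, constants = conversion_constants()) {
  if (any(!is.finite(length_m)) || any(length_m < 0)) {
    stop("hyphal length must be non-negative and finite", call. = FALSE)
  }
  r_cm <- constants$hyphal_radius * 1e-4   # um -> cm
  volume_cm3 <- pi * r_cm^2 * (length_m * 100)
  volume_cm3 * constants$hyphal_density * 1e6  # g -> ug
}

#' Total reproductive allocation
#'
#' Mass allocated to spore production: `A = R * W0`, spore output times the
#' mass of one spore.
#'
#' @param spore_output Spores per g soil (R); non-negative.
#' @param spore_mass Mass of a single spore, ug (W0); strictly positive.
#' @return Allocation in ug per g soil.
#' @examples
#' reproductive_allocation(1000, 0.364) # 364 ug/g
#' @export
reproductive_allocation <- function(spore_output, spore_mass) {
  if (any(!is.finite(spore_output)) || any(spore_output < 0)) {
    stop("spore output must be non-negative and finite", call. = FALSE)
  }
  if (any(!is.finite(spore_mass)) || any(spore_mass <= 0)) {
    stop("spore mass must be positive and finite", call. = FALSE)
  }
  spore_output * spore_mass
}

#' Read a colonization/sporulation table
#'
#' Reads per-replicate greenhouse measurements: root colonization as
#' ergosterol (ug/g dry root), soil colonization as hyphal length (m/g dry
#' soil), and sporulation as spore density (spores/g dry soil), for each
#' fungal species x host plant x replicate.
#'
#' Expected columns: `fungal_species`, `host_species`, `replicate`,
#' `root_ergosterol_ug_per_g`, `soil_hyphal_m_per_g`, `spores_per_g`.
#'
#' @param path CSV path or a data frame in the schema above.
#' @return A validated tibble.
#' @export
read_colonization <- function(path) {
  if (is.data.frame(path)) {
    raw <- tibble::as_tibble(path)
  } else {
    if (!file.exists(path)) stop("colonization table not found: ", path, call. = FALSE)
    raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  required <- c("fungal_species", "host_species", "replicate",
                "root_ergosterol_ug_per_g", "soil_hyphal_m_per_g", "spores_per_g")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("colonization table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  meas <- c("root_ergosterol_ug_per_g", "soil_hyphal_m_per_g", "spores_per_g")
  for (cc in meas) {
    v <- raw[[cc]]
    if (!is.numeric(v)) stop("column '", cc, "' is not numeric", call. = FALSE)
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("column '", cc, "' has negative or non-finite values", call. = FALSE)
    }
  }
  key <- paste(raw$fungal_species, raw$host_species, raw$replicate)
  if (anyDuplicated(key) > 0) {
    stop("duplicate replicate ids within species x host: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  tibble::as_tibble(raw[required])
}

#' Build the reproductive-allocation table
#'
#' Converts colonization measurements to common biomass units and joins
#' per-species spore masses to derive, per fungal species x host:
#' spore output `R` (spores/g soil), single-spore mass `W0` (ug), reproductive
#' allocation `A = R * W0` (ug/g), total body mass `Walpha` (ug: intraradical
#' plus extraradical mycelium, both as cylinder dry mass), and the length of
#' the extraradical mycelium (m/g soil).
#'
#' Replicates are by default averaged to species x host means before the
#' conversion chain, since the comparative fits treat a species-on-a-host as
#' one point; set `aggregate_replicates = FALSE` to keep per-replicate rows.
#'
#' @param colonization Colonization table ([read_colonization()] schema, path
#'   or data frame).
#' @param spore_mass Either a data frame with columns `species_id` and `mass`
#'   (ug; e.g. [spore_sizes()] output, one morph per species) or a named
#'   numeric vector of per-species spore masses.
#' @param constants A [conversion_constants()] list.
#' @param aggregate_replicates Average replicates before converting?
#' @return A tibble with columns `fungal_species`, `host_species` (and
#'   `replicate` if not aggregated), `spore_output`, `spore_mass_w0`,
#'   `allocation`, `body_mass`, `extraradical_length`.
#' @export
allocation_table <- function(colonization, spore_mass,
                             constants = conversion_constants(),
                             aggregate_replicates = TRUE) {
  col <- read_colonization(colonization)
  if (is.data.frame(spore_mass)) {
    if (!all(c("species_id", "mass") %in% names(spore_mass))) {
      stop("spore_mass data frame needs columns 'species_id' and 'mass'", call. = FALSE)
    }
    if (anyDuplicated(spore_mass$species_id) > 0) {
      stop("spore_mass has more than one entry per species; select one morph first ",
           "(see select_morph())", call. = FALSE)
    }
    w0 <- stats::setNames(spore_mass$mass, spore_mass$species_id)
  } else {
    w0 <- spore_mass
  }
  missing_sp <- setdiff(unique(col$fungal_species), names(w0))
  if (length(missing_sp) > 0) {
    message("excluding ", length(missing_sp),
            " species without a spore-mass entry: ",
            paste(missing_sp, collapse = ", "))
    col <- dplyr::filter(col, !.data$fungal_species %in% missing_sp)
  }
  if (nrow(col) == 0) stop("no colonization records left after matching spore masses",
                           call. = FALSE)

  if (isTRUE(aggregate_replicates)) {
    col <- col |>
      dplyr::group_by(.data$fungal_species, .data$host_species) |>
      dplyr::summarise(
        root_ergosterol_ug_per_g = mean(.data$root_ergosterol_ug_per_g),
        soil_hyphal_m_per_g = mean(.data$soil_hyphal_m_per_g),
        spores_per_g = mean(.data$spores_per_g),
        .groups = "drop"
      )
  }

  root_length <- ergosterol_to_hyphal_length(col$root_ergosterol_ug_per_g, constants)
  total_length <- root_length + col$soil_hyphal_m_per_g
  out <- col |>
    dplyr::mutate(
      spore_output = .data$spores_per_g,
      spore_mass_w0 = unname(w0[.data$fungal_species]),
      allocation = reproductive_allocation(.data$spore_output, .data$spore_mass_w0),
      body_mass = hyphal_length_to_dry_mass(total_length, constants),
      extraradical_length = .data$soil_hyphal_m_per_g
    ) |>
    dplyr::select(-dplyr::all_of(c("root_ergosterol_ug_per_g",
                                   "soil_hyphal_m_per_g", "spores_per_g")))
  out
}
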