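#' Define an array print layout
#'
#' An `array_layout` describes what is printed on one array: the allergen
#' panel (with replicate spots per allergen), control spots, and the antibody
#' standard dilution series. Every spot label on a scanned array should map to
#' exactly one layout entry; [validate_layout()] checks this.
#'
#' @param allergens Tibble or data frame with columns `name` (unique label)
#'   and `class` (allergen class used by reproducibility reports, e.g.
#'   `"surface"`, `"cytoplasm"`, `"pollen_extract"`, `"nonpollen_extract"`,
#'   `"recombinant"`).
#' @param replicates_per_allergen Spots printed per allergen (default 3).
#' @param control_names Control spot labels (default HSA and buffer).
#' @param control_replicates Spots per control (default 6).
#' @param standard_isotypes Antibody standards printed as dilution series
#'   (default IgE, IgG, IgA).
#' @param standard_concentrations Standard series in pg/spot, strictly
#'   decreasing (default 200 down to 1.5625 by twofold).
#' @param standard_replicates Spots per standard concentration (default 6).
#' @param arrays_per_slide Arrays printed per slide (default 12).
#'
#' @return An object of class `array_layout`.
#' @seealso [default_array_layout()] for the 80-allergen default panel,
#'   [layout_spots()] for the expanded per-spot grid.
#' @export
array_layout <- function(allergens,
                         replicates_per_allergen = 3,
                         control_names = c("HSA", "buffer"),
                         control_replicates = 6,
                         standard_isotypes = c("IgE", "IgG", "IgA"),
                         standard_concentrations = 200 / 2^(0:7),
                         standard_replicates = 6,
                         arrays_per_slide = 12) {
  allergens <- tibble::as_tibble(allergens)
  if (!all(c("name", "class") %in% names(allergens))) {
    stop("`allergens` needs columns `name` and `class`", call. = FALSE)
  }
  if (anyDuplicated(allergens$name)) {
    stop("allergen names must be unique", call. = FALSE)
  }
  if (length(standard_concentrations) &&
      (any(diff(standard_concentrations) >= 0) ||
       any(standard_concentrations <= 0))) {
    stop("standard_concentrations must be strictly decreasing and positive",
         call. = FALSE)
  }
  structure(
    list(
      allergens = allergens,
      replicates_per_allergen = as.integer(replicates_per_allergen),
      control_names = control_names,
      control_replicates = as.integer(control_replicates),
      standard_isotypes = standard_isotypes,
      standard_concentrations = standard_concentrations,
      standard_replicates = as.integer(standard_replicates),
      arrays_per_slide = as.integer(arrays_per_slide)
    ),
    class = "array_layout"
  )
}

#' @export
print.array_layout <- function(x, ...) {
  cat("<array_layout>\n")
  cat("  allergens: ", nrow(x$allergens), " x ", x$replicates_per_allergen,
      " replicates (classes: ",
      paste(unique(x$allergens$class), collapse = ", "), ")\n", sep = "")
  cat("  controls:  ", paste(x$control_names, collapse = ", "),
      " x ", x$control_replicates, "\n", sep = "")
  cat("  standards: ", paste(x$standard_isotypes, collapse = "/"),
      " at ", length(x$standard_concentrations), " pg/spot levels x ",
      x$standard_replicates, "\n", sep = "")
  cat("  arrays per slide:", x$arrays_per_slide, "\n")
  invisible(x)
}

#' Default 80-allergen pollen panel layout
#'
#' A panel patterned on a pollen-focused serology chip: 21 pollen species each
#' contributed as surface, cytoplasmic, and commercial-extract fractions
#' (63 spots-of-origin), 9 non-pollen commercial extracts, 5 recombinant major
#' allergens, and 3 additional extracts, for 80 allergen labels printed in
#' triplicate, alongside HSA/buffer controls and IgE/IgG/IgA standard curves
#' in six replicates.
#'
#' @return An `array_layout`.
#' @export
default_array_layout <- function() {
  pollens <- c(
    # grasses
    "Bermuda grass", "Timothy grass", "Ryegrass", "Bluegrass", "Orchard grass",
    "Fescue",
    # trees
    "Birch", "Cottonwood", "Olive", "Ash", "Elm", "Pecan", "Elder", "Oak",
    "Cedar",
    # weeds
    "Mugwort", "Ragweed", "Pigweed", "Nettle", "Plantain", "Sorrel"
  )
  allergens <- dplyr::bind_rows(
    tibble::tibble(name = paste(pollens, "surface"), class = "surface"),
    tibble::tibble(name = paste(pollens, "cytoplasm"), class = "cytoplasm"),
    tibble::tibble(name = paste(pollens, "extract"), class = "pollen_extract"),
    tibble::tibble(
      name = c("Cat extract", "Dog extract", "Mite DP extract",
               "Mite DF extract", "Cockroach G extract", "Cockroach A extract",
               "Alternaria extract", "Aspergillus extract", "Shrimp extract"),
      class = "nonpollen_extract"
    ),
    tibble::tibble(
      name = c("rBet v 1", "rAmb a 1", "rPhl p 2", "rDer p 1", "rAlt a 1"),
      class = "recombinant"
    ),
    tibble::tibble(
      name = c("Latex extract", "Egg extract", "Milk extract"),
      class = "other"
    )
  )
  array_layout(allergens)
}

#' Expand a layout into its per-spot grid
#'
#' Lays out every printed spot of one array on a 1-based grid (single block,
#' row-major), with one row per physical spot.
#'
#' @param layout An [array_layout()].
#' @param n_grid_columns Grid width in spots (default 12).
#' @return A tibble with columns `block`, `column`, `row`, `name`,
#'   `spot_type` (`"allergen"`, `"control"`, `"standard"`), `replicate_index`,
#'   and for standards `isotype` and `conc_pg` (NA elsewhere).
#' @export
layout_spots <- function(layout, n_grid_columns = 12) {
  stopifnot(inherits(layout, "array_layout"))
  allergen <- tidyr::expand_grid(
    name = layout$allergens$name,
    replicate_index = seq_len(layout$replicates_per_allergen)
  ) |>
    dplyr::mutate(spot_type = "allergen", isotype = NA_character_,
                  conc_pg = NA_real_)
  control <- tidyr::expand_grid(
    name = layout$control_names,
    replicate_index = seq_len(layout$control_replicates)
  ) |>
    dplyr::mutate(spot_type = "control", isotype = NA_character_,
                  conc_pg = NA_real_)
  standard <- tidyr::expand_grid(
    isotype = layout$standard_isotypes,
    conc_pg = layout$standard_concentrations,
    replicate_index = seq_len(layout$standard_replicates)
  ) |>
    dplyr::mutate(name = paste0(isotype, " std ", conc_pg),
                  spot_type = "standard")
  spots <- dplyr::bind_rows(allergen, control, standard)
  n <- nrow(spots)
  spots |>
    dplyr::mutate(
      block = 1L,
      column = as.integer((dplyr::row_number() - 1L) %% n_grid_columns + 1L),
      row = as.integer((dplyr::row_number() - 1L) %/% n_grid_columns + 1L)
    ) |>
    dplyr::select("block", "column", "row", "name", "spot_type",
                  "replicate_index", "isotype", "conc_pg")
}

#' Map spot labels to layout entries
#'
#' @param names Character vector of spot labels.
#' @param layout An [array_layout()].
#' @return Character vector: `"allergen"`, `"control"`, `"standard"`, or
#'   `NA` for labels absent from the layout (unmapped).
#' @keywords internal
layout_label_type <- function(names, layout) {
  spots <- layout_spots(layout)
  key <- spots |> dplyr::distinct(.data$name, .data$spot_type)
  key$spot_type[match(names, key$name)]
}
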