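#' Survey codebook: food groups, score mappings, sites, and masks
#'
#' The codebook defines the 20 survey food groups collected by the 7-day
#' recall, their mapping onto the 10 MDD-W dietary-diversity groups and the
#' 20 PDQS diet-quality groups (14 healthy, 6 unhealthy), the six study sites
#' with their country and rural/urban locality, and per-site food-group masks
#' (groups absent from a site's instrument).
#'
#' The shipped group list is a reconstruction: the source survey instrument is
#' not published, so the 20 groups are taken to coincide with the adapted PDQS
#' groups (no fried-foods-away-from-home group; dairy rather than low-fat
#' dairy; roots and tubers in place of potatoes; red/orange produce folded
#' into other vitamin A-rich fruits and vegetables; maize-flour products
#' counted as refined grains). Three groups (liquid vegetable oils,
#' sugar-sweetened beverages, desserts/sweets) have no MDD-W counterpart and
#' carry the explicit non-scoring target `"none"`.
#'
#' @return A list of class `dietshock_codebook` with elements
#'   `version`, `survey_groups` (data.frame: `id`, `label`, `mddw_group`,
#'   `pdqs_group`, `pdqs_healthy`), `mddw_groups` (data.frame: `id`, `label`),
#'   `sites` (data.frame: `site`, `country`, `locality`) and `site_masks`
#'   (named list of survey-group id vectors).
#' @export
#' @examples
#' cb <- default_codebook()
#' nrow(cb$survey_groups)  # 20
default_codebook <- function() {
  sg <- data.frame(
    id = c("dark_green_leafy_veg", "other_vit_a_fruit_veg", "cruciferous_veg",
           "other_veg", "citrus_fruits", "other_fruits", "fish", "eggs",
           "poultry", "legumes", "nuts_seeds", "dairy", "whole_grains",
           "liquid_veg_oils", "red_meat", "processed_meat", "refined_grains",
           "ssb", "desserts_sweets", "roots_tubers"),
    label = c("Dark green leafy vegetables",
              "Other vitamin A-rich fruits and vegetables (incl. red/orange produce)",
              "Cruciferous vegetables", "Other vegetables", "Whole citrus fruits",
              "Other fruits", "Fish", "Eggs", "Poultry",
              "Legumes (beans, peas, lentils)", "Nuts and seeds", "Dairy",
              "Whole grains", "Liquid vegetable oils", "Red meat",
              "Processed meats",
              "Refined grains and baked goods (incl. maize-flour products)",
              "Sugar-sweetened beverages", "Desserts and sweets",
              "Roots and tubers"),
    mddw_group = c("vit_a_dark_green_veg", "other_vit_a_fruit_veg", "other_veg",
                   "other_veg", "other_fruits", "other_fruits",
                   "meat_poultry_fish", "eggs", "meat_poultry_fish", "legumes",
                   "nuts_seeds", "dairy", "grains_roots_tubers", "none",
                   "meat_poultry_fish", "meat_poultry_fish",
                   "grains_roots_tubers", "none", "none", "grains_roots_tubers"),
    pdqs_group = NA_character_,
    pdqs_healthy = c(rep(TRUE, 14), rep(FALSE, 6)),
    stringsAsFactors = FALSE
  )
  sg$pdqs_group <- sg$id  # survey instrument coincides with the PDQS grouping

  mddw <- data.frame(
    id = c("grains_roots_tubers", "legumes", "nuts_seeds", "dairy",
           "meat_poultry_fish", "eggs", "vit_a_dark_green_veg",
           "other_vit_a_fruit_veg", "other_veg", "other_fruits"),
    label = c("Grains, white roots and tubers, and plantains",
              "Legumes (beans, peas and lentils)", "Nuts and seeds", "Dairy",
              "Meats, poultry and fish", "Eggs",
              "Vitamin A-rich dark green vegetables",
              "Other vitamin A-rich fruits and vegetables", "Other vegetables",
              "Other fruits"),
    stringsAsFactors = FALSE
  )

  sites <- data.frame(
    site = c("nouna", "ouagadougou", "kersa", "addis_ababa", "ibadan", "lagos"),
    country = c("burkina_faso", "burkina_faso", "ethiopia", "ethiopia",
                "nigeria", "nigeria"),
    locality = c("rural", "urban", "rural", "urban", "rural", "urban"),
    stringsAsFactors = FALSE
  )

  cb <- list(
    version = "1.0",
    survey_groups = sg,
    mddw_groups = mddw,
    sites = sites,
    site_masks = list(
      kersa = "other_vit_a_fruit_veg",
      addis_ababa = c("citrus_fruits", "other_fruits")
    )
  )
  class(cb) <- "dietshock_codebook"
  validate_codebook(cb)
  cb
}

#' Validate a codebook
#'
#' Checks the structural invariants: 20 survey groups each mapping to exactly
#' one MDD-W group (one of the 10 ids, or `"none"`) and one PDQS group; PDQS
#' groups partition into 14 healthy and 6 unhealthy; masks reference only
#' known survey-group ids; site/country/locality table is the fixed six-site
#' design.
#'
#' @param cb a codebook list.
#' @return `cb`, invisibly; errors with class `dietshock_codebook_error` on
#'   violation.
#' @export
validate_codebook <- function(cb) {
  sg <- cb$survey_groups
  if (!is.data.frame(sg) || nrow(sg) != 20L)
    abort("codebook must define exactly 20 survey food groups",
          "dietshock_codebook_error")
  if (anyDuplicated(sg$id))
    abort("duplicate survey food-group ids", "dietshock_codebook_error")
  ok_mddw <- c(cb$mddw_groups$id, "none")
  bad <- setdiff(sg$mddw_group, ok_mddw)
  if (length(bad))
    abort(paste0("unknown MDD-W target(s): ", paste(bad, collapse = ", ")),
          "dietshock_codebook_error")
  if (nrow(cb$mddw_groups) != 10L)
    abort("codebook must define exactly 10 MDD-W groups",
          "dietshock_codebook_error")
  if (sum(sg$pdqs_healthy) != 14L || sum(!sg$pdqs_healthy) != 6L)
    abort("PDQS groups must partition into 14 healthy + 6 unhealthy",
          "dietshock_codebook_error")
  if (anyDuplicated(sg$pdqs_group))
    abort("duplicate PDQS group assignment", "dietshock_codebook_error")
  for (site in names(cb$site_masks)) {
    if (!site %in% cb$sites$site)
      abort(paste0("mask references unknown site: ", site),
            "dietshock_codebook_error")
    bad <- setdiff(cb$site_masks[[site]], sg$id)
    if (length(bad))
      abort(paste0("mask for ", site, " references unknown group(s): ",
                   paste(bad, collapse = ", ")), "dietshock_codebook_error")
  }
  invisible(cb)
}

#' Read / write a codebook as JSON
#'
#' The codebook is a packaged, editable configuration file so that group
#' labels (which are localized per country in the field) can be adapted
#' without touching code; group ids are fixed.
#'
#' @param path file path to a codebook JSON file.
#' @return `read_codebook()` returns a validated `dietshock_codebook`.
#' @export
read_codebook <- function(path) {
  if (!file.exists(path))
    abort(paste0("codebook file not found: ", path), "dietshock_io_error")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cb <- list(
    version = raw$version %||% "unversioned",
    survey_groups = as.data.frame(raw$survey_groups, stringsAsFactors = FALSE),
    mddw_groups = as.data.frame(raw$mddw_groups, stringsAsFactors = FALSE),
    sites = as.data.frame(raw$sites, stringsAsFactors = FALSE),
    site_masks = lapply(raw$site_masks, unlist)
  )
  class(cb) <- "dietshock_codebook"
  validate_codebook(cb)
  cb
}

#' @rdname read_codebook
#' @param cb a validated codebook.
#' @export
write_codebook <- function(cb, path) {
  validate_codebook(cb)
  jsonlite::write_json(unclass(cb), path, pretty = TRUE, auto_unbox = TRUE)
  invisible(path)
}

#' Path to the packaged default codebook file
#' @export
codebook_path <- function() {
  system.file("extdata", "codebook.json", package = "dietshock", mustWork = TRUE)
}

# internal: food-group column names for a period suffix
fg_columns <- function(cb, period) paste0("fg_", cb$survey_groups$id, "_", period)

# internal: masked survey groups for one site (character(0) if none)
site_mask <- function(cb, site) {
  m <- cb$site_masks[[site]]
  if (is.null(m)) character(0) else m
}

# internal: MDD-W groups masked at a site = groups whose constituents are all masked
masked_mddw_groups <- function(cb, masked_survey_groups) {
  sg <- cb$survey_groups
  out <- character(0)
  for (g in cb$mddw_groups$id) {
    members <- sg$id[sg$mddw_group == g]
    if (length(members) && all(members %in% masked_survey_groups))
      out <- c(out, g)
  }
  out
}
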