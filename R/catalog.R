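#' Closed vocabulary of botanical family labels
#'
#' The 14 botanical families used to classify arable crops. Crop catalogs
#' must draw their `family` column from this vocabulary; the special label
#' `"Mixture"` covers multi-family species mixtures (e.g. cereal-legume
#' mixtures) that cannot be assigned to a single family.
#'
#' @return Character vector of 14 family labels.
#' @export
botanical_families <- function() {
  c("Poaceae", "Fabaceae", "Brassicaceae", "Asteraceae", "Chenopodiaceae",
    "Solanaceae", "Linaceae", "Apiaceae", "Amaryllidaceae", "Cucurbitaceae",
    "Polygonaceae", "Cannabaceae", "Boraginaceae", "Mixture")
}

#' Closed vocabulary of sowing-period categories
#'
#' Annual crops are classified by sowing period as fall, winter, spring or
#' summer crops; perennial crops form a fifth category.
#'
#' @return Character vector of the 5 category labels.
#' @export
sowing_periods <- function() {
  c("fall", "winter", "spring", "summer", "perennial")
}

#' Default catalog of the 16 main arable crops
#'
#' A built-in crop catalog covering the 16 main crops of French arable
#' cropping systems, each assigned a botanical family, a sowing-period
#' category, a cereal flag and a main-crop flag. It is the default lookup
#' for the diversity indicators and can be overridden by a user-supplied
#' `crop_catalog.csv` (see [read_dataset()]).
#'
#' @return A data.frame with columns `crop`, `family`, `sowing_period`,
#'   `is_cereal`, `is_main_crop`.
#' @export
#' @examples
#' cat <- default_catalog()
#' nrow(cat)  # 16
default_catalog <- function() {
  cat <- data.frame(
    crop = c("winter_wheat", "winter_barley", "durum_wheat", "triticale",
             "spring_oat", "maize", "ryegrass", "grassland",
             "cereal_legume_mixture", "alfalfa", "spring_pea", "soybean",
             "oilseed_rape", "sunflower", "sugar_beet", "potato"),
    family = c("Poaceae", "Poaceae", "Poaceae", "Poaceae",
               "Poaceae", "Poaceae", "Poaceae", "Poaceae",
               "Mixture", "Fabaceae", "Fabaceae", "Fabaceae",
               "Brassicaceae", "Asteraceae", "Chenopodiaceae", "Solanaceae"),
    sowing_period = c("winter", "winter", "winter", "winter",
                      "spring", "summer", "fall", "perennial",
                      "winter", "perennial", "spring", "summer",
                      "fall", "summer", "spring", "spring"),
    is_cereal = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                  FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    is_main_crop = TRUE,
    stringsAsFactors = FALSE
  )
  validate_catalog(cat)
}

#' Normalize a crop name key
#'
#' Crop names are matched case-insensitively after trimming whitespace;
#' internal spaces collapse to underscores.
#'
#' @param x character vector of raw crop names.
#' @return normalized character keys.
#' @export
normalize_crop_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", "_", x)
}

#' Validate a crop catalog
#'
#' Checks the closed vocabularies, uniqueness of crop keys and column types,
#' and normalizes crop names.
#'
#' @param catalog data.frame with columns `crop`, `family`, `sowing_period`,
#'   `is_cereal` and optionally `is_main_crop` (defaults to `TRUE`).
#' @return The validated catalog (invisibly the same shape), with normalized
#'   crop keys.
#' @export
validate_catalog <- function(catalog) {
  req <- c("crop", "family", "sowing_period", "is_cereal")
  miss <- setdiff(req, names(catalog))
  if (length(miss) > 0L)
    stop("crop catalog is missing column(s): ", paste(miss, collapse = ", "))
  catalog$crop <- normalize_crop_name(catalog$crop)
  if (anyDuplicated(catalog$crop))
    stop("duplicate crop name(s) in catalog: ",
         paste(unique(catalog$crop[duplicated(catalog$crop)]), collapse = ", "))
  bad_fam <- setdiff(unique(catalog$family), botanical_families())
  if (length(bad_fam) > 0L)
    stop("unknown botanical family label(s): ", paste(bad_fam, collapse = ", "))
  bad_per <- setdiff(unique(catalog$sowing_period), sowing_periods())
  if (length(bad_per) > 0L)
    stop("unknown sowing-period label(s): ", paste(bad_per, collapse = ", "))
  catalog$is_cereal <- as.logical(catalog$is_cereal)
  if (anyNA(catalog$is_cereal)) stop("is_cereal must be logical")
  if (is.null(catalog$is_main_crop)) catalog$is_main_crop <- TRUE
  catalog$is_main_crop <- as.logical(catalog$is_main_crop)
  rownames(catalog) <- NULL
  catalog
}

# Lookup helper: map crop keys to a catalog column, erroring on unknown crops.
catalog_lookup <- function(crops, catalog, column) {
  idx <- match(crops, catalog$crop)
  if (anyNA(idx)) {
    stop("crop(s) not present in catalog: ",
         paste(unique(crops[is.na(idx)]), collapse = ", "))
  }
  catalog[[column]][idx]
}
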