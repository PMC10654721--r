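#' Read and validate a cropping-system dataset
#'
#' Reads the four tabular inputs of the pipeline and checks referential
#' integrity; no inclusion filters are applied at this stage (see
#' [apply_inclusion_filters()]).
#'
#' Expected files:
#' \itemize{
#'   \item `fields.csv`: system_id, climatic_region, soil_type, time_point,
#'     field_id, field_area_ha, crop, cover_crop, coated_seeds
#'   \item `sprays.csv`: system_id, time_point, field_id, product_id,
#'     class (H/F/I/O), dose, treated_ha, biocontrol
#'   \item `reference_doses.csv`: product_id, crop, reference_dose
#'   \item `crop_catalog.csv` (optional; defaults to [default_catalog()]):
#'     crop, family, sowing_period, is_cereal, is_main_crop
#' }
#'
#' @param fields path to `fields.csv`, or a data.frame.
#' @param sprays path to `sprays.csv`, or a data.frame.
#' @param ref_doses path to `reference_doses.csv`, or a data.frame.
#' @param catalog path to `crop_catalog.csv`, a data.frame, or `NULL` for
#'   the built-in 16-crop catalog.
#' @return A `rotapest_dataset`: list with elements `contexts`, `fields`,
#'   `sprays`, `ref_doses`, `catalog`.
#' @export
read_dataset <- function(fields, sprays, ref_doses, catalog = NULL) {
  read_tab <- function(x, what) {
    if (is.character(x)) {
      if (!file.exists(x)) stop("missing input file for ", what, ": ", x)
      x <- utils::read.csv(x, stringsAsFactors = FALSE)
    }
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  fields <- read_tab(fields, "fields")
  sprays <- read_tab(sprays, "sprays")
  ref_doses <- read_tab(ref_doses, "reference doses")
  catalog <- if (is.null(catalog)) default_catalog()
             else validate_catalog(read_tab(catalog, "crop catalog"))
  validate_dataset(fields, sprays, ref_doses, catalog)
}

check_columns <- function(df, req, what) {
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
}

validate_dataset <- function(fields, sprays, ref_doses, catalog) {
  check_columns(fields, c("system_id", "climatic_region", "soil_type",
                          "time_point", "field_id", "field_area_ha", "crop",
                          "cover_crop", "coated_seeds"), "fields table")
  check_columns(sprays, c("system_id", "time_point", "field_id", "product_id",
                          "class", "dose", "treated_ha", "biocontrol"),
                "sprays table")
  check_columns(ref_doses, c("product_id", "crop", "reference_dose"),
                "reference-dose table")

  fields$crop <- normalize_crop_name(fields$crop)
  ref_doses$crop <- normalize_crop_name(ref_doses$crop)
  fields$cover_crop <- as.logical(fields$cover_crop)
  fields$coated_seeds <- as.logical(fields$coated_seeds)
  sprays$biocontrol <- as.logical(sprays$biocontrol)

  bad <- which(!is.finite(fields$field_area_ha) | fields$field_area_ha <= 0)
  if (length(bad) > 0L)
    stop("non-positive field area in fields row ", bad[1])
  unknown <- setdiff(unique(fields$crop), catalog$crop)
  if (length(unknown) > 0L)
    stop("crop(s) in fields table absent from catalog: ",
         paste(unknown, collapse = ", "))
  bad <- which(!is.finite(ref_doses$reference_dose) | ref_doses$reference_dose <= 0)
  if (length(bad) > 0L)
    stop("non-positive reference dose in row ", bad[1])
  bad <- which(!is.finite(sprays$dose) | sprays$dose <= 0)
  if (length(bad) > 0L && !all(sprays$biocontrol[bad]))
    stop("non-positive applied dose in sprays row ",
         bad[!sprays$biocontrol[bad]][1])

  fkey <- paste(fields$system_id, fields$time_point, fields$field_id, sep = "\r")
  if (anyDuplicated(fkey))
    stop("duplicate (system, time point, field) row in fields table")
  skey <- paste(sprays$system_id, sprays$time_point, sprays$field_id, sep = "\r")
  orphan <- which(!(skey %in% fkey))
  if (length(orphan) > 0L)
    stop("sprays row ", orphan[1], " references a field absent from fields table")

  # every non-biocontrol spray must resolve to a reference dose on its crop
  crop_of_spray <- fields$crop[match(skey, fkey)]
  rkey <- paste(ref_doses$product_id, ref_doses$crop, sep = "\r")
  want <- paste(sprays$product_id, crop_of_spray, sep = "\r")
  missing_rd <- which(!(want %in% rkey) & !sprays$biocontrol)
  if (length(missing_rd) > 0L) {
    i <- missing_rd[1]
    stop("no reference dose for product '", sprays$product_id[i],
         "' on crop '", crop_of_spray[i], "' (sprays row ", i, ")")
  }

  contexts <- unique(fields[, c("system_id", "climatic_region", "soil_type")])
  if (anyDuplicated(contexts$system_id))
    stop("system(s) with inconsistent region/soil assignment: ",
         paste(unique(contexts$system_id[duplicated(contexts$system_id)]),
               collapse = ", "))
  rownames(contexts) <- NULL

  structure(list(contexts = contexts, fields = fields, sprays = sprays,
                 ref_doses = ref_doses, catalog = catalog),
            class = "rotapest_dataset")
}

#' @export
print.rotapest_dataset <- function(x, ...) {
  cat("Cropping-system dataset:\n")
  cat("  systems:     ", nrow(x$contexts), "\n")
  cat("  field rows:  ", nrow(x$fields), "\n")
  cat("  spray rows:  ", nrow(x$sprays), "\n")
  cat("  catalog:     ", nrow(x$catalog), "crops\n")
  invisible(x)
}

#' Write a dataset to CSV files
#'
#' Inverse of [read_dataset()]; writes `fields.csv`, `sprays.csv`,
#' `reference_doses.csv` and `crop_catalog.csv` into `dir`.
#'
#' @param dataset a `rotapest_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fields = file.path(dir, "fields.csv"),
             sprays = file.path(dir, "sprays.csv"),
             ref_doses = file.path(dir, "reference_doses.csv"),
             catalog = file.path(dir, "crop_catalog.csv"))
  utils::write.csv(dataset$fields, paths["fields"], row.names = FALSE)
  utils::write.csv(dataset$sprays, paths["sprays"], row.names = FALSE)
  utils::write.csv(dataset$ref_doses, paths["ref_doses"], row.names = FALSE)
  utils::write.csv(dataset$catalog, paths["catalog"], row.names = FALSE)
  invisible(paths)
}

#' Apply the study inclusion filters
#'
#' Two filter families are applied:
#' \enumerate{
#'   \item Field count: only cropping systems described over at least
#'     `min_fields` fields (per time point) are kept. Time points of a
#'     system described on fewer fields are dropped.
#'   \item Crop-level mean pesticide use (when `tfi` is supplied): crops
#'     whose mean total TFI over the filtered dataset falls strictly below
#'     0.7 are excluded from the total- and herbicide-use model crop lists;
#'     the fungicide list additionally requires mean fungicide TFI >= 0.1,
#'     the insecticide list mean insecticide TFI >= 0.2.
#' }
#'
#' @param dataset a `rotapest_dataset`.
#' @param tfi optional TFI table from [compute_tfi()]; required to derive
#'   the per-response crop lists.
#' @param min_fields minimum number of fields per system and time point
#'   (default 8).
#' @param tfi_thresholds named numeric thresholds `total`, `fungicide`,
#'   `insecticide`.
#' @return list with elements `dataset` (filtered), `crop_lists` (per
#'   response variable, `NULL` without `tfi`) and `report` (counts removed
#'   at each step).
#' @export
apply_inclusion_filters <- function(dataset, tfi = NULL, min_fields = 8,
                                    tfi_thresholds = c(total = 0.7,
                                                       fungicide = 0.1,
                                                       insecticide = 0.2)) {
  fields <- dataset$fields
  grp <- interaction(fields$system_id, fields$time_point, drop = TRUE, sep = "\r")
  n_by_grp <- table(grp)
  keep_grp <- names(n_by_grp)[n_by_grp >= min_fields]
  keep <- as.character(grp) %in% keep_grp
  n_removed_rows <- sum(!keep)
  fields2 <- fields[keep, , drop = FALSE]
  if (nrow(fields2) == 0L)
    stop("no observations left after the minimum-fields filter")
  fkey <- paste(fields2$system_id, fields2$time_point, fields2$field_id, sep = "\r")
  sprays2 <- dataset$sprays[
    paste(dataset$sprays$system_id, dataset$sprays$time_point,
          dataset$sprays$field_id, sep = "\r") %in% fkey, , drop = FALSE]
  out <- dataset
  out$fields <- fields2
  out$sprays <- sprays2
  out$contexts <- dataset$contexts[
    dataset$contexts$system_id %in% unique(fields2$system_id), , drop = FALSE]
  rownames(out$fields) <- rownames(out$sprays) <- rownames(out$contexts) <- NULL

  crop_lists <- NULL
  crop_means <- NULL
  if (!is.null(tfi)) {
    tfi <- tfi[paste(tfi$system_id, tfi$time_point, sep = "\r") %in%
                 unique(paste(fields2$system_id, fields2$time_point, sep = "\r")), ,
               drop = FALSE]
    crop_means <- do.call(rbind, lapply(split(tfi, tfi$crop), function(d) {
      data.frame(crop = d$crop[1], mean_total = mean(d$tfi_total),
                 mean_f = mean(d$tfi_f), mean_i = mean(d$tfi_i),
                 stringsAsFactors = FALSE)
    }))
    rownames(crop_means) <- NULL
    base <- crop_means$crop[crop_means$mean_total >= tfi_thresholds[["total"]]]
    crop_lists <- list(
      total = base,
      herbicide = base,
      fungicide = intersect(base,
        crop_means$crop[crop_means$mean_f >= tfi_thresholds[["fungicide"]]]),
      insecticide = intersect(base,
        crop_means$crop[crop_means$mean_i >= tfi_thresholds[["insecticide"]]])
    )
    if (length(crop_lists$total) == 0L)
      stop("no crop passes the mean-TFI inclusion threshold")
  }
  report <- list(
    min_fields = min_fields,
    n_field_rows_removed = n_removed_rows,
    n_system_time_points_removed = length(n_by_grp) - length(keep_grp),
    n_systems_kept = nrow(out$contexts),
    crop_means = crop_means,
    n_crops_retained = if (is.null(crop_lists)) NA_integer_
                       else vapply(crop_lists, length, integer(1))
  )
  list(dataset = out, crop_lists = crop_lists, report = report)
}
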