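#' TFI contribution of a single spraying operation
#'
#' The Treatment Frequency Index counts pesticide applications at the full
#' recommended dose. One spraying operation contributes
#' \deqn{\frac{D_i \cdot S_i}{Dh_i \cdot S_t}}
#' where \eqn{D_i} is the applied dose, \eqn{Dh_i} the reference dose (the
#' lowest registered dose for the product on that crop), \eqn{S_i} the
#' treated surface and \eqn{S_t} the total field surface. Biocontrol
#' products (less hazardous / non-chemical) are excluded and contribute 0.
#'
#' @param dose applied dose per hectare (> 0).
#' @param reference_dose reference dose per hectare (> 0).
#' @param treated_ha treated surface in hectares (0 < treated_ha <= field_area_ha).
#' @param field_area_ha total field surface in hectares.
#' @param biocontrol logical; `TRUE` excludes the operation from the TFI.
#' @return Nonnegative scalar contribution.
#' @export
#' @examples
#' spray_tfi_contribution(1, 1, 10, 10)            # full dose, whole field: 1
#' spray_tfi_contribution(0.75, 1.5, 4, 10)        # 0.5 * 0.4 = 0.2
spray_tfi_contribution <- function(dose, reference_dose, treated_ha,
                                   field_area_ha, biocontrol = FALSE) {
  if (isTRUE(biocontrol)) return(0)
  if (!is.finite(dose) || dose <= 0) stop("applied dose must be > 0")
  if (!is.finite(reference_dose) || reference_dose <= 0)
    stop("reference dose must be > 0")
  if (!is.finite(treated_ha) || treated_ha <= 0)
    stop("treated surface must be > 0")
  if (treated_ha > field_area_ha + 1e-9)
    stop("treated surface (", treated_ha, " ha) exceeds field area (",
         field_area_ha, " ha)")
  (dose / reference_dose) * (treated_ha / field_area_ha)
}

# Reference-dose lookup keyed on (product_id, crop); exact match only.
ref_dose_lookup <- function(product_id, crop, ref_doses) {
  key <- paste(product_id, crop, sep = "\r")
  idx <- match(key, paste(ref_doses$product_id, ref_doses$crop, sep = "\r"))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("no reference dose for product '", product_id[bad], "' on crop '",
         crop[bad], "'")
  }
  ref_doses$reference_dose[idx]
}

#' TFI of one field-crop observation
#'
#' Sums spray contributions per pesticide class and in total, adds 1.0 TFI
#' point to the total when the crop was sown with chemically coated seeds.
#' The seed-coating point is tracked as a separate `coating` component (not
#' allocated to the herbicide/fungicide/insecticide classes); products of
#' class "O" (other, e.g. growth regulators) count in the total but in none
#' of the three class columns.
#'
#' @param sprays data.frame of the field's spray operations with columns
#'   `product_id`, `class` (one of `"H"`, `"F"`, `"I"`, `"O"`), `dose`,
#'   `treated_ha`, `biocontrol`. May have zero rows.
#' @param crop crop grown on the field (normalized name).
#' @param field_area_ha total field surface in hectares.
#' @param coated_seeds logical seed-coating flag.
#' @param ref_doses reference-dose table (`product_id`, `crop`,
#'   `reference_dose`).
#' @return Named numeric vector with components `total`, `herbicide`,
#'   `fungicide`, `insecticide`, `coating`.
#' @export
field_crop_tfi <- function(sprays, crop, field_area_ha, coated_seeds,
                           ref_doses) {
  if (!is.finite(field_area_ha) || field_area_ha <= 0)
    stop("field area must be > 0")
  out <- c(total = 0, herbicide = 0, fungicide = 0, insecticide = 0,
           coating = 0)
  if (!is.null(sprays) && nrow(sprays) > 0L) {
    bad <- setdiff(unique(sprays$class), c("H", "F", "I", "O"))
    if (length(bad) > 0L)
      stop("unknown pesticide class label(s): ", paste(bad, collapse = ", "))
    rd <- ref_dose_lookup(sprays$product_id, rep(crop, nrow(sprays)), ref_doses)
    contrib <- vapply(seq_len(nrow(sprays)), function(i) {
      spray_tfi_contribution(sprays$dose[i], rd[i], sprays$treated_ha[i],
                             field_area_ha, isTRUE(sprays$biocontrol[i]))
    }, numeric(1))
    out["herbicide"] <- sum(contrib[sprays$class == "H"])
    out["fungicide"] <- sum(contrib[sprays$class == "F"])
    out["insecticide"] <- sum(contrib[sprays$class == "I"])
    out["total"] <- sum(contrib)
  }
  if (isTRUE(coated_seeds)) {
    out["coating"] <- 1
    out["total"] <- out["total"] + 1
  }
  out
}

#' Aggregate field-level TFI to the crop x system x time point level
#'
#' When a crop is grown on several fields of a cropping system at a given
#' time point, per-class and total TFI values are averaged over those fields
#' with equal weights (area-unweighted).
#'
#' @param field_tfis matrix or data.frame with one row per field and the
#'   columns returned by [field_crop_tfi()].
#' @return Named numeric vector of averages plus `n_fields`.
#' @export
aggregate_crop_tfi <- function(field_tfis) {
  field_tfis <- as.matrix(field_tfis)
  if (nrow(field_tfis) == 0L) stop("no fields to aggregate")
  c(colMeans(field_tfis), n_fields = nrow(field_tfis))
}

#' Compute the TFI table of a dataset
#'
#' Scores every field observation with [field_crop_tfi()] and aggregates to
#' one row per (system, time point, crop) with [aggregate_crop_tfi()].
#'
#' @param dataset a validated dataset (see [read_dataset()]).
#' @return data.frame with columns `system_id`, `time_point`, `crop`,
#'   `tfi_total`, `tfi_h`, `tfi_f`, `tfi_i`, `tfi_coating`, `n_fields`.
#' @export
compute_tfi <- function(dataset) {
  fields <- dataset$fields
  sprays <- dataset$sprays
  skey <- paste(sprays$system_id, sprays$time_point, sprays$field_id, sep = "\r")
  fkey <- paste(fields$system_id, fields$time_point, fields$field_id, sep = "\r")
  spray_by_field <- split(seq_len(nrow(sprays)), factor(skey, levels = unique(fkey)))
  per_field <- t(vapply(seq_len(nrow(fields)), function(i) {
    sp <- sprays[spray_by_field[[fkey[i]]], , drop = FALSE]
    field_crop_tfi(sp, fields$crop[i], fields$field_area_ha[i],
                   fields$coated_seeds[i], dataset$ref_doses)
  }, numeric(5)))
  grp <- interaction(fields$system_id, fields$time_point, fields$crop,
                     drop = TRUE, sep = "\r")
  rows <- lapply(split(seq_len(nrow(fields)), grp), function(idx) {
    agg <- aggregate_crop_tfi(per_field[idx, , drop = FALSE])
    data.frame(
      system_id = fields$system_id[idx[1]],
      time_point = fields$time_point[idx[1]],
      crop = fields$crop[idx[1]],
      tfi_total = agg[["total"]], tfi_h = agg[["herbicide"]],
      tfi_f = agg[["fungicide"]], tfi_i = agg[["insecticide"]],
      tfi_coating = agg[["coating"]], n_fields = agg[["n_fields"]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$system_id, out$time_point, out$crop), , drop = FALSE]
  rownames(out) <- NULL
  out
}
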