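#' Hill number of order 1 (effective number of categories)
#'
#' Computes the exponential of Shannon entropy,
#' \deqn{{}^1D = \exp\left(-\sum_i p_i \ln p_i\right),}
#' the number of equally abundant categories required to yield the same
#' entropy. Order 1 gives similar weight to rare and abundant categories.
#' Zero proportions contribute nothing (0 * log(0) := 0).
#'
#' @param p numeric vector of nonnegative proportions summing to 1.
#' @param tol tolerance on the sum-to-one check.
#' @return Effective number, a scalar in `[1, sum(p > 0)]`.
#' @export
#' @examples
#' hill_shannon(c(0.25, 0.25, 0.25, 0.25))  # 4
#' hill_shannon(c(0.5, 0.3, 0.2))           # 2.80012
hill_shannon <- function(p, tol = 1e-9) {
  p <- as.numeric(p)
  if (length(p) == 0L || all(p == 0)) stop("at least one positive proportion required")
  if (any(p < 0)) stop("proportions must be nonnegative")
  if (abs(sum(p) - 1) > tol) stop("proportions must sum to 1 (got ", format(sum(p)), ")")
  p <- p[p > 0]
  exp(-sum(p * log(p)))
}

#' Decompose crop diversity into functional and taxonomic components
#'
#' Splits the effective number of crops into the effective number of
#' botanical families (functional diversity, FD) and the average effective
#' number of crops per family (taxonomic diversity, TD). Family proportions
#' \eqn{p_k} sum the proportions of member crops; a family-specific Hill
#' number \eqn{{}^1D_k} is computed on the renormalized within-family
#' proportions. TD is reported with two weightings:
#' \itemize{
#'   \item arithmetic: \eqn{{}^1D_{TD} = \sum_k p_k \, {}^1D_k} (the
#'     standard reported indicator);
#'   \item geometric: \eqn{\prod_k ({}^1D_k)^{p_k}}, for which the product
#'     \eqn{FD \times TD} recovers the effective number of crops exactly
#'     (additivity of Shannon entropy).
#' }
#'
#' @param comp named numeric vector of crop proportions (a composition).
#' @param catalog crop catalog (see [default_catalog()]).
#' @return list with elements `fd`, `td_arith`, `td_geom`, `family_hills`
#'   (named vector of \eqn{{}^1D_k}) and `family_props` (named \eqn{p_k}).
#' @export
#' @examples
#' comp <- c(winter_wheat = 0.5, winter_barley = 0.25, spring_pea = 0.25)
#' d <- decompose_diversity(comp, default_catalog())
#' d$fd * d$td_geom  # equals hill_shannon(comp)
decompose_diversity <- function(comp, catalog = default_catalog()) {
  comp <- validate_composition(comp)
  fam <- catalog_lookup(names(comp), catalog, "family")
  p_k <- tapply(comp, fam, sum)
  p_k <- p_k[p_k > 0]
  fd <- hill_shannon(as.numeric(p_k) / sum(p_k))
  hills <- vapply(names(p_k), function(k) {
    w <- comp[fam == k]
    hill_shannon(w / sum(w))
  }, numeric(1))
  td_arith <- sum(as.numeric(p_k) * hills)
  td_geom <- exp(sum(as.numeric(p_k) * log(hills)))
  list(fd = fd, td_arith = td_arith, td_geom = td_geom,
       family_hills = hills, family_props = as.numeric(p_k))
}

#' Effective number of sowing periods
#'
#' Hill number of order 1 over the proportions of the five sowing-period
#' categories (fall, winter, spring, summer, perennial) implied by a crop
#' composition.
#'
#' @inheritParams decompose_diversity
#' @return Effective number of sowing periods in `[1, 5]`.
#' @export
sowing_period_diversity <- function(comp, catalog = default_catalog()) {
  comp <- validate_composition(comp)
  per <- catalog_lookup(names(comp), catalog, "sowing_period")
  p_j <- tapply(comp, per, sum)
  hill_shannon(as.numeric(p_j) / sum(p_j))
}

#' Effective number of cereal crop species
#'
#' Hill number of order 1 over the renormalized proportions of cereal crops
#' in a composition. Returns 1 by convention (with a message) when the
#' composition contains no cereal crop.
#'
#' @inheritParams decompose_diversity
#' @return Effective number of cereal species (>= 1).
#' @export
cereal_effective_number <- function(comp, catalog = default_catalog()) {
  comp <- validate_composition(comp)
  cer <- catalog_lookup(names(comp), catalog, "is_cereal")
  w <- comp[cer & comp > 0]
  if (length(w) == 0L) {
    message("composition has no cereal crop; cereal effective number set to 1")
    return(1)
  }
  hill_shannon(w / sum(w))
}

#' Cover-crop frequency of a field set
#'
#' Proportion of fields (of one cropping system at one time point) whose
#' crop was preceded by a cover crop. The definition is field-count based:
#' field areas do not enter.
#'
#' @param cover_crop logical vector, one element per field.
#' @return Proportion in `[0, 1]`.
#' @export
cover_crop_frequency <- function(cover_crop) {
  if (length(cover_crop) == 0L) stop("empty field set")
  cover_crop <- as.logical(cover_crop)
  if (anyNA(cover_crop)) stop("cover_crop flags must be TRUE/FALSE")
  mean(cover_crop)
}

#' Build a crop composition from field observations
#'
#' The composition of a cropping system at a time point is the frequency of
#' each crop over its fields (area-unweighted field counts).
#'
#' @param crops character vector of (normalized) crop names, one per field.
#' @return Named numeric vector of proportions summing to 1.
#' @export
composition_from_fields <- function(crops) {
  if (length(crops) == 0L) stop("empty field set")
  tab <- table(crops)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

validate_composition <- function(comp, tol = 1e-9) {
  if (is.null(names(comp)) || any(names(comp) == ""))
    stop("composition must be a named vector of crop proportions")
  comp <- vapply(split(as.numeric(comp), names(comp)), sum, numeric(1))
  if (any(comp < 0)) stop("composition proportions must be nonnegative")
  if (abs(sum(comp) - 1) > tol)
    stop("composition proportions must sum to 1 (got ", format(sum(comp)), ")")
  comp[comp > 0]
}

#' Compute the five diversity indicators per cropping system and time point
#'
#' For each (system, time point) group of field observations, builds the
#' field-count composition and computes: the effective number of crops
#' (`hill_d`), functional diversity (`fd`), taxonomic diversity under both
#' weightings (`td_arith`, `td_geom`), the effective number of sowing
#' periods (`sowing_div`), cover-crop frequency (`cover_crop_freq`) and the
#' effective number of cereal species (`cereal_hill`). Indicators are not
#' rarefied by field count.
#'
#' @param fields data.frame of field observations with columns `system_id`,
#'   `time_point`, `crop`, `cover_crop` (see [read_dataset()]).
#' @param catalog crop catalog.
#' @return data.frame with one row per (system, time point).
#' @export
diversity_profiles <- function(fields, catalog = default_catalog()) {
  key <- interaction(fields$system_id, fields$time_point, drop = TRUE, sep = "\r")
  rows <- lapply(split(seq_len(nrow(fields)), key), function(idx) {
    f <- fields[idx, , drop = FALSE]
    comp <- composition_from_fields(f$crop)
    dec <- decompose_diversity(comp, catalog)
    data.frame(
      system_id = f$system_id[1], time_point = f$time_point[1],
      n_fields = nrow(f),
      hill_d = hill_shannon(comp),
      fd = dec$fd, td_arith = dec$td_arith, td_geom = dec$td_geom,
      sowing_div = sowing_period_diversity(comp, catalog),
      cover_crop_freq = cover_crop_frequency(f$cover_crop),
      cereal_hill = suppressMessages(cereal_effective_number(comp, catalog)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$system_id, out$time_point), , drop = FALSE]
  rownames(out) <- NULL
  out
}
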