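# Hand-built three-file fixture: two systems, one time point each, a
# handful of sprays with known TFI arithmetic.
tiny_fields <- function(n_fields_a = 8, n_fields_b = 8) {
  rbind(
    data.frame(system_id = "sysA", climatic_region = "oceanic",
               soil_type = "soil01", time_point = "tp01",
               field_id = sprintf("f%02d", seq_len(n_fields_a)),
               field_area_ha = 10,
               crop = rep(c("winter_wheat", "spring_pea"),
                          length.out = n_fields_a),
               cover_crop = rep(c(TRUE, FALSE), length.out = n_fields_a),
               coated_seeds = FALSE, stringsAsFactors = FALSE),
    data.frame(system_id = "sysB", climatic_region = "mountain",
               soil_type = "soil02", time_point = "tp01",
               field_id = sprintf("f%02d", seq_len(n_fields_b)),
               field_area_ha = 5,
               crop = "maize", cover_crop = FALSE, coated_seeds = FALSE,
               stringsAsFactors = FALSE)
  )
}

tiny_sprays <- function() {
  data.frame(
    system_id = c("sysA", "sysA", "sysB"),
    time_point = "tp01",
    field_id = c("f01", "f01", "f01"),
    product_id = c("H_winter_wheat", "F_winter_wheat", "H_maize"),
    class = c("H", "F", "H"),
    dose = c(2, 0.5, 1.5),
    treated_ha = c(10, 5, 5),
    biocontrol = FALSE,
    stringsAsFactors = FALSE
  )
}

tiny_ref_doses <- function() {
  data.frame(
    product_id = c("H_winter_wheat", "F_winter_wheat", "H_maize"),
    crop = c("winter_wheat", "winter_wheat", "maize"),
    reference_dose = c(2, 1, 1.5),
    stringsAsFactors = FALSE
  )
}

tiny_dataset <- function(...) {
  read_dataset(tiny_fields(...), tiny_sprays(), tiny_ref_doses())
}

# random composition over k crops of the default catalog
random_composition <- function(k, crops = default_catalog()$crop) {
  nm <- sample(crops, k)
  p <- rgamma(k, shape = 0.8)
  stats::setNames(p / sum(p), nm)
}

# Weiszfeld spatial median in raw Euclidean coordinates (independent of the
# package's PCoA route)
spatial_median_direct <- function(X, tol = 1e-10) {
  m <- colMeans(X)
  for (i in 1:1000) {
    dd <- sqrt(rowSums(sweep(X, 2, m)^2))
    dd[dd < 1e-12] <- 1e-12
    m_new <- colSums(X / dd) / sum(1 / dd)
    if (sqrt(sum((m_new - m)^2)) < tol) return(m_new)
    m <- m_new
  }
  m
}
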