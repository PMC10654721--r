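#' Default class mix of spray operations per crop
#'
#' Fractions of herbicide / fungicide / insecticide / other products used
#' when decomposing a simulated crop-level TFI into spray operations,
#' reflecting typical arable-crop profiles (herbicide-dominated feed crops,
#' fungicide-heavy potato, insecticide-heavy oilseed rape).
#'
#' @return Matrix with crops as rows and columns `H`, `F`, `I`, `O`.
#' @export
default_class_mix <- function() {
  m <- rbind(
    winter_wheat          = c(.45, .35, .10, .10),
    winter_barley         = c(.45, .35, .10, .10),
    durum_wheat           = c(.45, .35, .10, .10),
    triticale             = c(.60, .25, .05, .10),
    spring_oat            = c(.60, .25, .05, .10),
    maize                 = c(.75, .05, .15, .05),
    ryegrass              = c(.90, .05, .05, .00),
    grassland             = c(.90, .05, .05, .00),
    cereal_legume_mixture = c(.80, .10, .10, .00),
    alfalfa               = c(.80, .10, .10, .00),
    spring_pea            = c(.40, .20, .35, .05),
    soybean               = c(.75, .10, .10, .05),
    oilseed_rape          = c(.30, .20, .45, .05),
    sunflower             = c(.75, .10, .10, .05),
    sugar_beet            = c(.55, .20, .20, .05),
    potato                = c(.15, .60, .20, .05)
  )
  colnames(m) <- c("H", "F", "I", "O")
  m
}

#' Simulation configuration with study-like defaults
#'
#' Assembles the configuration of the synthetic cropping-system network:
#' 6 climatic regions, 16 soil types, systems described over at least 8
#' fields (default 10), 1 to 11 time points per system with half of the
#' systems described only once, Dirichlet crop compositions over
#' region-specific pools of the 16 main crops, and crop-level TFI responses
#' drawn from a compound Poisson-Gamma (Tweedie, 1 < p < 2) model
#' \deqn{\log\mu = a_{crop} + b_{region} + \beta_{FD} z_{FD} +
#'   \beta_{TD} z_{TD} + \beta_{cover} z_{cover} + u_{system}}
#' on the indicators scaled within the generated dataset. Defaults give
#' feed crops (grassland, ryegrass, alfalfa, cereal-legume mixture) very
#' low pesticide use and potato the highest, mirroring observed contrasts.
#'
#' @param n_systems number of cropping systems.
#' @param fields_per_system fields per system and time point (>= 8).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param ... overrides for any default element (see Details in the
#'   package vignette): `n_regions`, `n_soil_types`, `pool_size`,
#'   `time_point_weights`, `dirichlet_concentration`, `composition_drift`,
#'   `coated_prob`, `biocontrol_prob`, `cover_beta_shapes`, `intercepts`,
#'   `region_effects`, `beta_fd`, `beta_td`, `beta_cover`, `sigma_system`,
#'   `phi`, `p`, `class_mix`, `catalog`.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_systems = 300, fields_per_system = 10,
                              seed = 1, ...) {
  catalog <- default_catalog()
  intercepts <- log(c(
    winter_wheat = 2.6, winter_barley = 2.4, durum_wheat = 2.3,
    triticale = 1.7, spring_oat = 1.6, maize = 1.9,
    ryegrass = 0.15, grassland = 0.1, cereal_legume_mixture = 0.2,
    alfalfa = 0.15, spring_pea = 2.2, soybean = 1.0,
    oilseed_rape = 4.5, sunflower = 1.3, sugar_beet = 4.5, potato = 9
  ))
  cfg <- list(
    n_systems = n_systems,
    fields_per_system = fields_per_system,
    n_regions = 6,
    n_soil_types = 16,
    pool_size = 10,
    time_point_weights = c(0.50, 0.20, 0.10, 0.06, 0.04, 0.03,
                           0.02, 0.02, 0.015, 0.01, 0.005),
    dirichlet_concentration = 0.5,
    composition_drift = 0.3,
    coated_prob = 0.15,
    biocontrol_prob = 0.05,
    cover_beta_shapes = c(1.5, 4),
    intercepts = intercepts,
    region_effects = c(0.15, -0.10, 0.05, -0.05, 0.10, -0.15),
    beta_fd = -0.05, beta_td = -0.05, beta_cover = 0.04,
    beta_fd_crop = NULL, beta_td_crop = NULL,
    sigma_system = 0.3, phi = 0.8, p = 1.6,
    class_mix = default_class_mix(),
    catalog = catalog,
    seed = seed
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L) stop("unknown config element(s): ",
                             paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$fields_per_system < 8)
    stop("fields_per_system must be >= 8")
  if (cfg$p <= 1 || cfg$p >= 2) stop("index power p must lie in (1, 2)")
  if (cfg$phi <= 0) stop("dispersion phi must be > 0")
  if (abs(sum(cfg$time_point_weights) - 1) > 1e-9)
    stop("time_point_weights must sum to 1")
  class(cfg) <- "sim_config"
  cfg
}

# largest-remainder apportionment of n fields to composition p (deterministic)
apportion_fields <- function(p, n) {
  k <- floor(p * n)
  r <- p * n - k
  left <- n - sum(k)
  if (left > 0) {
    ord <- order(r, decreasing = TRUE)
    k[ord[seq_len(left)]] <- k[ord[seq_len(left)]] + 1
  }
  k
}

region_labels <- function(n) {
  lab <- c("altered_oceanic", "deteriorated_oceanic", "mountain",
           "oceanic", "semi_continental", "southwest_basin")
  lab[seq_len(n)]
}

#' Generate a synthetic cropping-system network with known ground truth
#'
#' Draws the full input dataset of the pipeline (field observations with
#' spray operations, reference doses, crop catalog) from the generative
#' model of [simulation_config()], and exports the realized parameters and
#' per-observation latent means. Crop-level TFI is drawn first and then
#' decomposed exactly into spray operations (full-dose applications plus
#' one partial application; a 1.0-point seed coating replaces one TFI point
#' when drawn), so re-scoring the generated sprays with [compute_tfi()]
#' reproduces the drawn values to machine precision. Occasional biocontrol
#' sprays (contribution 0) exercise the exclusion rule.
#'
#' @param config a `sim_config` from [simulation_config()].
#' @return list with `dataset` (a `rotapest_dataset`) and `truth` (list:
#'   the model coefficients, scaling constants, per-system random
#'   intercepts, and the crop-level observation table with latent `mu` and
#'   drawn TFI).
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cat <- config$catalog
  crops <- cat$crop
  regions <- region_labels(config$n_regions)
  soils <- sprintf("soil%02d", seq_len(config$n_soil_types))
  nf <- config$fields_per_system

  # region-specific crop pools (drawn once per dataset)
  pools <- lapply(seq_len(config$n_regions), function(r)
    sort(sample(crops, min(config$pool_size, length(crops)))))

  sys_id <- sprintf("sys%04d", seq_len(config$n_systems))
  sys_region <- sample(regions, config$n_systems, replace = TRUE)
  sys_soil <- sample(soils, config$n_systems, replace = TRUE)
  sys_ntp <- sample(seq_along(config$time_point_weights), config$n_systems,
                    replace = TRUE, prob = config$time_point_weights)
  u_sys <- stats::rnorm(config$n_systems, 0, config$sigma_system)

  rdirichlet1 <- function(k, conc) {
    g <- stats::rgamma(k, shape = conc)
    if (all(g == 0)) g[1] <- 1
    g / sum(g)
  }

  f_sys <- f_tp <- f_field <- f_crop <- character(0)
  f_cc <- logical(0)
  f_list <- vector("list", config$n_systems)
  for (s in seq_len(config$n_systems)) {
    pool <- pools[[match(sys_region[s], regions)]]
    p0 <- rdirichlet1(length(pool), config$dirichlet_concentration)
    per_tp <- vector("list", sys_ntp[s])
    for (t in seq_len(sys_ntp[s])) {
      p <- if (t == 1 || stats::runif(1) >= config$composition_drift) p0
           else rdirichlet1(length(pool), config$dirichlet_concentration)
      counts <- apportion_fields(p, nf)
      crop_vec <- rep(pool, counts)
      cc_target <- stats::rbeta(1, config$cover_beta_shapes[1],
                                config$cover_beta_shapes[2])
      per_tp[[t]] <- data.frame(
        system_id = sys_id[s], time_point = sprintf("tp%02d", t),
        field_id = sprintf("f%02d", seq_len(nf)),
        crop = crop_vec,
        cover_crop = stats::runif(nf) < cc_target,
        stringsAsFactors = FALSE
      )
    }
    f_list[[s]] <- do.call(rbind, per_tp)
  }
  fields <- do.call(rbind, f_list)
  fields$climatic_region <- sys_region[match(fields$system_id, sys_id)]
  fields$soil_type <- sys_soil[match(fields$system_id, sys_id)]
  fields$field_area_ha <- round(stats::rlnorm(nrow(fields), log(8), 0.4), 2)
  fields$coated_seeds <- FALSE  # set below from the drawn TFI

  # crop-level observation table with indicators
  stp <- interaction(fields$system_id, fields$time_point, drop = TRUE,
                     sep = "\r")
  ind_rows <- lapply(split(seq_len(nrow(fields)), stp), function(idx) {
    f <- fields[idx, , drop = FALSE]
    comp <- composition_from_fields(f$crop)
    dec <- decompose_diversity(comp, cat)
    data.frame(system_id = f$system_id[1], time_point = f$time_point[1],
               fd = dec$fd, td = dec$td_arith,
               cover = cover_crop_frequency(f$cover_crop),
               stringsAsFactors = FALSE)
  })
  ind <- do.call(rbind, ind_rows)

  obs <- unique(fields[, c("system_id", "time_point", "crop")])
  ii <- match(paste(obs$system_id, obs$time_point),
              paste(ind$system_id, ind$time_point))
  obs$fd_raw <- ind$fd[ii]; obs$td_raw <- ind$td[ii]
  obs$cover_raw <- ind$cover[ii]
  sc <- data.frame(
    var = c("fd", "td", "cover_crop_freq"),
    mean = c(mean(obs$fd_raw), mean(obs$td_raw), mean(obs$cover_raw)),
    sd = c(stats::sd(obs$fd_raw), stats::sd(obs$td_raw),
           stats::sd(obs$cover_raw)),
    stringsAsFactors = FALSE
  )
  sc$sd[sc$sd == 0 | !is.finite(sc$sd)] <- 1
  z_fd <- (obs$fd_raw - sc$mean[1]) / sc$sd[1]
  z_td <- (obs$td_raw - sc$mean[2]) / sc$sd[2]
  z_cc <- (obs$cover_raw - sc$mean[3]) / sc$sd[3]

  a_c <- config$intercepts[obs$crop]
  if (anyNA(a_c)) stop("missing intercept for crop(s): ",
                       paste(unique(obs$crop[is.na(a_c)]), collapse = ", "))
  b_r <- config$region_effects[match(sys_region[match(obs$system_id, sys_id)],
                                     regions)]
  u <- u_sys[match(obs$system_id, sys_id)]
  # crop-specific indicator slopes (zero unless configured)
  bfd_c <- btd_c <- rep(0, nrow(obs))
  if (!is.null(config$beta_fd_crop)) {
    v <- config$beta_fd_crop[obs$crop]
    bfd_c <- ifelse(is.na(v), 0, v)
  }
  if (!is.null(config$beta_td_crop)) {
    v <- config$beta_td_crop[obs$crop]
    btd_c <- ifelse(is.na(v), 0, v)
  }
  obs$mu <- exp(a_c + b_r + (config$beta_fd + bfd_c) * z_fd +
                  (config$beta_td + btd_c) * z_td +
                  config$beta_cover * z_cc + u)
  obs$tfi_drawn <- rtweedie_cp(nrow(obs), obs$mu, config$phi, config$p)

  # seed coating replaces 1.0 TFI point when the drawn total allows it
  obs$coated <- obs$tfi_drawn >= 1 &
    stats::runif(nrow(obs)) < config$coated_prob
  obs$spray_tfi <- obs$tfi_drawn - as.numeric(obs$coated)

  fi <- match(paste(fields$system_id, fields$time_point, fields$crop),
              paste(obs$system_id, obs$time_point, obs$crop))
  fields$coated_seeds <- obs$coated[fi]

  # reference doses: one product per crop x class, plus a biocontrol product
  rd_grid <- expand.grid(crop = crops, class = c("H", "F", "I", "O"),
                         stringsAsFactors = FALSE)
  rd_grid$product_id <- paste(rd_grid$class, rd_grid$crop, sep = "_")
  rd_grid$reference_dose <- round(stats::rlnorm(nrow(rd_grid), 0, 0.5), 3)
  bio <- data.frame(crop = crops, class = "B",
                    product_id = "bioctl",
                    reference_dose = 1, stringsAsFactors = FALSE)
  ref_doses <- rbind(rd_grid[, c("product_id", "crop", "reference_dose")],
                     bio[, c("product_id", "crop", "reference_dose")])

  # decompose each field's spray TFI: floor(s) full-dose + one partial
  s_field <- obs$spray_tfi[fi]
  n_full <- floor(s_field + 1e-9)
  frac <- pmax(s_field - n_full, 0)
  frac[frac < 1e-9] <- 0
  n_spray <- n_full + (frac > 0)
  has_bio <- stats::runif(nrow(fields)) < config$biocontrol_prob
  total_rows <- n_spray + has_bio
  fidx <- rep(seq_len(nrow(fields)), total_rows)
  within <- sequence(total_rows)
  is_bio <- within > rep(n_spray, total_rows)
  is_partial <- !is_bio & within == rep(n_full, total_rows) + 1L
  dose_frac <- ifelse(is_bio, 1, ifelse(is_partial, rep(frac, total_rows), 1))

  sp_crop <- fields$crop[fidx]
  cls <- character(length(fidx))
  mix <- config$class_mix
  for (cr in unique(sp_crop)) {
    w <- which(sp_crop == cr & !is_bio)
    pr <- if (cr %in% rownames(mix)) mix[cr, ] else c(.5, .25, .15, .1)
    if (length(w) > 0)
      cls[w] <- sample(c("H", "F", "I", "O"), length(w), replace = TRUE,
                       prob = pr)
  }
  cls[is_bio] <- "O"
  product <- ifelse(is_bio, "bioctl", paste(cls, sp_crop, sep = "_"))
  rd <- ref_doses$reference_dose[match(paste(product, sp_crop),
                                       paste(ref_doses$product_id,
                                             ref_doses$crop))]
  sprays <- data.frame(
    system_id = fields$system_id[fidx],
    time_point = fields$time_point[fidx],
    field_id = fields$field_id[fidx],
    product_id = product,
    class = cls,
    dose = dose_frac * rd,
    treated_ha = fields$field_area_ha[fidx],
    biocontrol = is_bio,
    stringsAsFactors = FALSE
  )
  sprays <- sprays[sprays$dose > 0, , drop = FALSE]
  rownames(sprays) <- NULL

  fields <- fields[, c("system_id", "climatic_region", "soil_type",
                       "time_point", "field_id", "field_area_ha", "crop",
                       "cover_crop", "coated_seeds")]
  dataset <- validate_dataset(fields, sprays, ref_doses, cat)

  truth <- list(
    intercepts = config$intercepts,
    region_effects = stats::setNames(config$region_effects, regions),
    beta_fd = config$beta_fd, beta_td = config$beta_td,
    beta_cover = config$beta_cover,
    beta_fd_crop = config$beta_fd_crop, beta_td_crop = config$beta_td_crop,
    sigma_system = config$sigma_system, phi = config$phi, p = config$p,
    scaling = sc,
    system_random_intercepts = stats::setNames(u_sys, sys_id),
    observations = obs,
    seed = config$seed
  )
  list(dataset = dataset, truth = truth)
}
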