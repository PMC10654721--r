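# Averaged linear-predictor contrast vector: model-matrix row at the values
# pinned in `at`, averaged with equal weights over the levels of every
# factor not pinned, with unpinned continuous covariates at their mean.
lp_vector <- function(fit, at = list()) {
  mf <- fit$model_frame
  vars <- names(mf)[-1]
  grid_vals <- lapply(vars, function(v) {
    if (v %in% names(at)) return(at[[v]])
    if (v %in% names(fit$xlevels)) return(fit$xlevels[[v]])
    mean(mf[[v]])
  })
  names(grid_vals) <- vars
  grid <- do.call(expand.grid, c(grid_vals, stringsAsFactors = FALSE))
  colMeans(model_matrix_for(fit, grid))
}

#' Type III Wald chi-square test for a model term
#'
#' With sum-to-zero contrast coding (as used by [fit_tweedie_glm()]), the
#' joint Wald statistic of a term's coefficient block,
#' \eqn{W = \beta_T^\top V_T^{-1} \beta_T}, is the type III chi-square test
#' of that term in the presence of all others.
#'
#' @param fit a `tweedie_fit`.
#' @param term term label as it appears in the model formula (e.g.
#'   `"crop"`, `"crop:fd"`); `NULL` tests every term and returns a table.
#' @return data.frame with columns `term`, `chisq`, `df`, `p_value`.
#' @export
type3_wald <- function(fit, term = NULL) {
  labels <- attr(fit$terms, "term.labels")
  if (is.null(term)) term <- labels
  rows <- lapply(term, function(tm) {
    k <- match(tm, labels)
    if (is.na(k)) stop("term '", tm, "' not in the model")
    idx <- which(fit$assign == k)
    b <- fit$coefficients[idx]
    V <- fit$vcov[idx, idx, drop = FALSE]
    Vi <- tryCatch(solve(V), error = function(e)
      stop("singular covariance block for term '", tm, "'"))
    W <- drop(t(b) %*% Vi %*% b)
    data.frame(term = tm, chisq = W, df = length(idx),
               p_value = stats::pchisq(W, length(idx), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Marginalized (estimated marginal) means
#'
#' For each level of a focal factor, the linear predictor is averaged with
#' equal weights over the levels of every non-focal factor (e.g. climatic
#' region), with continuous covariates held at their means unless pinned
#' via `at`; the average is back-transformed through the log link. Standard
#' errors follow from \eqn{c^\top V c} and Wald 95% confidence intervals
#' are computed on the link scale and exponentiated (the delta method for a
#' monotone transform). With `simultaneous = TRUE` the intervals are
#' Bonferroni-adjusted across the focal levels.
#'
#' @param fit a `tweedie_fit`.
#' @param focal name of the focal factor.
#' @param at named list pinning covariate values (e.g. `list(fd = 1.5)`).
#' @param level confidence level.
#' @param simultaneous logical; Bonferroni-adjust the intervals.
#' @return data.frame of class `effect_estimates` with columns `label`,
#'   `estimate` (response scale), `se_link`, `ci_low`, `ci_high`,
#'   and attributes `contrast_matrix` and `fit` for downstream contrasts.
#' @export
marginal_means <- function(fit, focal, at = list(), level = 0.95,
                           simultaneous = FALSE) {
  if (!(focal %in% names(fit$xlevels)))
    stop("focal factor '", focal, "' not in the model")
  lev <- fit$xlevels[[focal]]
  C <- t(vapply(lev, function(l) lp_vector(fit, at = c(stats::setNames(list(l), focal), at)),
                numeric(length(fit$coefficients))))
  eta <- drop(C %*% fit$coefficients)
  se <- sqrt(rowSums((C %*% fit$vcov) * C))
  alpha <- 1 - level
  if (simultaneous) alpha <- alpha / length(lev)
  z <- stats::qnorm(1 - alpha / 2)
  out <- data.frame(label = lev, estimate = exp(eta), eta = eta, se_link = se,
                    ci_low = exp(eta - z * se), ci_high = exp(eta + z * se),
                    stringsAsFactors = FALSE)
  attr(out, "contrast_matrix") <- C
  attr(out, "fit") <- fit
  class(out) <- c("effect_estimates", "data.frame")
  out
}

# compact letter display by the insert-and-absorb algorithm on a logical
# "significantly different" matrix
compact_letters <- function(labels, sig) {
  cols <- list(rep(TRUE, length(labels)))
  for (i in seq_along(labels)) for (j in seq_len(i - 1L)) {
    if (!sig[i, j]) next
    for (k in seq_along(cols)) {
      if (cols[[k]][i] && cols[[k]][j]) {
        a <- cols[[k]]; b <- cols[[k]]
        a[i] <- FALSE; b[j] <- FALSE
        cols[[k]] <- a
        cols[[length(cols) + 1L]] <- b
      }
    }
    # absorb columns contained in another
    drop <- rep(FALSE, length(cols))
    for (k in seq_along(cols)) for (m in seq_along(cols)) {
      if (k != m && !drop[m] && !drop[k] && all(cols[[k]] <= cols[[m]]))
        drop[k] <- TRUE
    }
    cols <- cols[!drop]
  }
  letters_used <- letters[seq_along(cols)]
  vapply(seq_along(labels), function(i)
    paste0(letters_used[vapply(cols, `[`, logical(1), i)], collapse = ""),
    character(1))
}

#' Pairwise contrasts with FDR adjustment and a compact letter display
#'
#' All pairwise link-scale differences between marginalized means, tested
#' with two-tailed Wald z tests, p-values adjusted by the Benjamini-Hochberg
#' false discovery rate procedure. Levels are annotated with compact
#' letters (insert-and-absorb algorithm): levels sharing a letter are not
#' significantly different at the adjusted threshold.
#'
#' @param means an `effect_estimates` table from [marginal_means()].
#' @param alpha significance threshold on adjusted p-values.
#' @return list with `contrasts` (data.frame: `level_1`, `level_2`,
#'   `delta_eta`, `se`, `z`, `p_value`, `p_adjusted`) and `letters`
#'   (data.frame `label`, `letters`).
#' @export
pairwise_contrasts_fdr <- function(means, alpha = 0.05) {
  C <- attr(means, "contrast_matrix")
  fit <- attr(means, "fit")
  if (is.null(C) || is.null(fit)) stop("means must come from marginal_means()")
  k <- nrow(means)
  if (k < 2L) stop("need at least 2 levels")
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(ij) {
    cvec <- C[ij[1], ] - C[ij[2], ]
    d <- sum(cvec * fit$coefficients)
    se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
    z <- d / se
    c(d = d, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  ct <- data.frame(level_1 = means$label[pairs[1, ]],
                   level_2 = means$label[pairs[2, ]],
                   delta_eta = rows["d", ], se = rows["se", ],
                   z = rows["z", ], p_value = rows["p", ],
                   p_adjusted = stats::p.adjust(rows["p", ], method = "BH"),
                   stringsAsFactors = FALSE)
  sig <- matrix(FALSE, k, k)
  sig[t(pairs)] <- ct$p_adjusted < alpha
  sig <- sig | t(sig)
  list(contrasts = ct,
       letters = data.frame(label = means$label,
                            letters = compact_letters(means$label, sig),
                            stringsAsFactors = FALSE))
}

#' Per-crop slopes of a diversity indicator
#'
#' The slope of the (scaled) indicator for each crop is the derivative of
#' the linear predictor with respect to the indicator at that crop,
#' averaged over climatic regions, with the other continuous covariates at
#' their means (so with an indicator-by-indicator interaction the slope is
#' evaluated at the mean of the partner indicator). Each slope is tested
#' against zero with a two-tailed Wald z test.
#'
#' @param fit a `tweedie_fit`.
#' @param indicator name of the continuous indicator (scaled scale).
#' @param by name of the crop factor (default `"crop"`); `NULL` for a
#'   single overall slope.
#' @return data.frame with columns `crop`, `slope`, `se`, `z`, `p_value`.
#' @export
slope_tests <- function(fit, indicator, by = "crop") {
  if (!(indicator %in% names(fit$model_frame)))
    stop("indicator '", indicator, "' not in the model")
  h <- 0.5
  slope_vec <- function(at0) {
    cp <- lp_vector(fit, at = c(at0, stats::setNames(list(+h), indicator)))
    cm <- lp_vector(fit, at = c(at0, stats::setNames(list(-h), indicator)))
    (cp - cm) / (2 * h)  # exact for a linear predictor
  }
  groups <- if (is.null(by)) list(NULL) else
    lapply(fit$xlevels[[by]], function(l) stats::setNames(list(l), by))
  rows <- lapply(groups, function(at0) {
    cvec <- slope_vec(if (is.null(at0)) list() else at0)
    s <- sum(cvec * fit$coefficients)
    se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
    data.frame(crop = if (is.null(at0)) "(all)" else at0[[1]],
               slope = s, se = se, z = s / se,
               p_value = 2 * stats::pnorm(-abs(s / se)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percent change of the response over a raw-scale indicator change
#'
#' Converts a slope on the scaled indicator into the percent change of the
#' expected response when the raw indicator moves from `from_raw` to
#' `to_raw`:
#' \eqn{\Delta\eta = \beta_{scaled} (to - from)/sd} and
#' \eqn{\%\Delta = 100(e^{\Delta\eta} - 1)}, with a delta-method Wald
#' confidence interval computed on \eqn{\Delta\eta} and exponentiated.
#'
#' @param fit a `tweedie_fit` carrying a scaling record.
#' @param indicator indicator name (as scaled in the model).
#' @param from_raw,to_raw raw-scale endpoints (e.g. functional diversity
#'   1 to 4, or cover-crop frequency 0 to 1).
#' @param crop crop level at which to evaluate the slope; `NULL` averages
#'   over crops.
#' @param by name of the crop factor.
#' @param level confidence level.
#' @return data.frame with `crop`, `percent_change`, `ci_low`, `ci_high`,
#'   `p_value`.
#' @export
percent_change_effect <- function(fit, indicator, from_raw, to_raw,
                                  crop = NULL, by = "crop", level = 0.95) {
  if (is.null(fit$scaling) || !(indicator %in% fit$scaling$var))
    stop("no scaling record for indicator '", indicator, "'")
  sdv <- fit$scaling$sd[fit$scaling$var == indicator]
  if (sdv <= 0) stop("indicator standard deviation must be > 0")
  st <- slope_tests(fit, indicator, by = if (is.null(crop)) NULL else by)
  if (!is.null(crop)) {
    st <- st[st$crop == crop, , drop = FALSE]
    if (nrow(st) == 0L) stop("crop '", crop, "' not in the model")
  }
  mult <- (to_raw - from_raw) / sdv
  z <- stats::qnorm(1 - (1 - level) / 2)
  deta <- st$slope * mult
  se <- st$se * abs(mult)
  data.frame(crop = st$crop,
             percent_change = 100 * (exp(deta) - 1),
             ci_low = 100 * (exp(deta - z * se) - 1),
             ci_high = 100 * (exp(deta + z * se) - 1),
             p_value = st$p_value,
             stringsAsFactors = FALSE)
}
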