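#' Candidate model formulas for the regulation analysis
#'
#' Builds the five candidate fixed-effect structures compared by AIC for
#' the regulation models: a baseline with climatic region, crop, the two
#' diversity indicators, their interaction and cover-crop frequency, then
#' four elaborations adding crop-by-indicator interactions while respecting
#' marginality. With `sowing_alternative = TRUE` the functional-diversity
#' indicator is replaced by the diversity of sowing periods and the
#' indicator-by-indicator interaction is dropped, giving four candidates.
#'
#' @param response response column name (e.g. `"tfi_total"`).
#' @param fd,td,cover,sowing column names of the scaled indicators.
#' @param sowing_alternative logical; build the sowing-period variant.
#' @return Named list of formulas, ordered from simplest to most complex.
#' @export
regulation_candidates <- function(response, fd = "fd", td = "td",
                                  cover = "cover_crop_freq",
                                  sowing = "sowing_div",
                                  sowing_alternative = FALSE) {
  f <- function(rhs) stats::as.formula(paste(response, "~", rhs))
  if (sowing_alternative) {
    base <- paste("climatic_region + crop +", sowing, "+", td, "+", cover)
    list(
      baseline = f(base),
      crop_sowing = f(paste(base, "+ crop:", sowing)),
      crop_td = f(paste(base, "+ crop:", td)),
      crop_sowing_td = f(paste(base, "+ crop:", sowing, "+ crop:", td))
    )
  } else {
    base <- paste("climatic_region + crop +", fd, "*", td, "+", cover)
    list(
      baseline = f(base),
      crop_fd = f(paste(base, "+ crop:", fd)),
      crop_td = f(paste(base, "+ crop:", td)),
      crop_fd_td = f(paste(base, "+ crop:", fd, "+ crop:", td)),
      crop_fd_td_fdtd = f(paste(base, "+ crop:", fd, "+ crop:", td,
                                "+ crop:", fd, ":", td))
    )
  }
}

#' Select the most parsimonious Tweedie model by AIC
#'
#' Fits each candidate on the same rows and returns the lowest-AIC fit.
#' Ties (within `tie_tol`) are broken toward the candidate with fewer
#' parameters, and among equal-complexity ties toward the earlier (simpler)
#' candidate in the list. Candidates that fail to converge are excluded
#' with a warning and flagged in the table.
#'
#' @param candidates named list of model formulas, ordered from simplest to
#'   most complex.
#' @param data data.frame with all model columns.
#' @param p index power passed to [fit_tweedie_glm()] (a common fixed value
#'   keeps the AIC comparison on identical footing; `"profile"` profiles it
#'   per candidate).
#' @param tie_tol AIC difference treated as a tie (default 0: strict
#'   lowest AIC).
#' @param ... further arguments to [fit_tweedie_glm()].
#' @return list with `best` (a `tweedie_fit`), `best_name` and `table`
#'   (data.frame `model`, `n_par`, `aic`, `converged`).
#' @export
select_model_aic <- function(candidates, data, p = "profile", tie_tol = 0,
                             ...) {
  if (length(candidates) < 2L) stop("need at least 2 candidate models")
  if (is.null(names(candidates)))
    names(candidates) <- paste0("model_", seq_along(candidates))
  fits <- vector("list", length(candidates))
  tab <- data.frame(model = names(candidates), n_par = NA_integer_,
                    aic = NA_real_, converged = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(candidates)) {
    fit <- tryCatch(fit_tweedie_glm(candidates[[i]], data, p = p, ...),
                    error = function(e) {
                      warning("candidate '", names(candidates)[i],
                              "' excluded: ", conditionMessage(e))
                      NULL
                    })
    if (!is.null(fit)) {
      fits[[i]] <- fit
      tab$n_par[i] <- fit$n_par
      tab$aic[i] <- fit$aic
      tab$converged[i] <- TRUE
    }
  }
  ok <- which(tab$converged)
  if (length(ok) == 0L) stop("no candidate model converged")
  best_aic <- min(tab$aic[ok])
  tied <- ok[tab$aic[ok] <= best_aic + tie_tol]
  tied <- tied[order(tab$n_par[tied], tied)]
  best <- tied[1]
  list(best = fits[[best]], best_name = tab$model[best], table = tab)
}
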