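#' Tweedie regression with approximate random intercepts
#'
#' An approximate extension of [fit_tweedie_glm()] with Gaussian random
#' intercepts for one or more grouping factors, estimated by penalized
#' IRLS: the group indicator blocks enter the working least-squares problem
#' with a ridge penalty \eqn{\phi/\sigma_g^2}, and each variance component
#' is updated by Schall's moment step
#' \eqn{\sigma_g^2 = u_g^\top u_g / (q_g - \mathrm{tr}_g)} until joint
#' convergence. This is a quasi-likelihood approximation: it does not
#' reproduce Laplace-approximation mixed-model estimates and all outputs
#' are flagged `approximate`. On non-convergence the fixed-effects fit is
#' returned with a warning.
#'
#' @param formula fixed-effects formula.
#' @param data data.frame.
#' @param groups character vector of grouping-factor column names.
#' @param p index power in (1, 2) (profiling is not supported here).
#' @param max_outer outer iteration cap.
#' @param tol convergence tolerance on fixed effects and variance
#'   components.
#' @param ... passed to the internal fixed-effect machinery.
#' @return A `tweedie_fit` (fixed-effect block only in `coefficients` and
#'   `vcov`) with extra elements `variance_components` (named
#'   \eqn{\sigma_g^2}), `random_effects` (list of BLUP-like group
#'   deviations) and `approximate = TRUE`. Predictions with random effects
#'   at zero equal the population-level predictions.
#' @export
fit_random_intercepts <- function(formula, data, groups, p = 1.6,
                                  max_outer = 50, tol = 1e-6, ...) {
  if (!is.numeric(p) || p <= 1 || p >= 2)
    stop("p must be a fixed number in (1, 2)")
  data <- as.data.frame(data)
  chr <- vapply(data, is.character, logical(1))
  data[chr] <- lapply(data[chr], factor)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  contrasts <- sum_contrasts(mf[-1])
  X <- stats::model.matrix(stats::terms(mf), mf, contrasts.arg = contrasts)
  Zs <- lapply(groups, function(g) {
    f <- factor(data[[g]][as.integer(rownames(mf))])
    stats::model.matrix(~ f - 1)
  })
  q <- vapply(Zs, ncol, integer(1))
  Z <- do.call(cbind, Zs)
  blk <- rep(seq_along(groups), q)
  XZ <- cbind(X, Z)
  nb <- ncol(X)

  sigma2 <- rep(stats::var(log(y + mean(y) / 2)) / 4, length(groups))
  phi <- 1
  mu <- pmax(y, mean(y) / 10) + mean(y) / 10
  eta <- log(mu)
  beta_u <- rep(0, ncol(XZ))
  converged <- FALSE
  for (outer in seq_len(max_outer)) {
    old <- c(beta_u[seq_len(nb)], sigma2)
    for (inner in seq_len(50)) {
      w <- mu^(2 - p)
      z <- eta + (y - mu) / mu
      pen <- c(rep(0, nb), phi / sigma2[blk])
      A <- crossprod(XZ * sqrt(w)) + diag(pen)
      b <- crossprod(XZ, w * z)
      new_bu <- solve(A, b)
      eta <- drop(XZ %*% new_bu)
      mu <- exp(eta)
      if (max(abs(new_bu - beta_u)) < 1e-8) { beta_u <- drop(new_bu); break }
      beta_u <- drop(new_bu)
    }
    phi <- sum((y - mu)^2 / mu^p) / max(1, length(y) - nb)
    Ainv <- solve(A)
    for (g in seq_along(groups)) {
      idx <- nb + which(blk == g)
      u <- beta_u[idx]
      trg <- sum(diag(Ainv)[idx]) * phi / sigma2[g]
      denom <- max(q[g] - trg, 0.5)
      sigma2[g] <- max(sum(u^2) / denom, 1e-10)
    }
    if (max(abs(c(beta_u[seq_len(nb)], sigma2) - old)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("approximate random-intercept fit did not converge; ",
            "falling back to the fixed-effects fit")
    return(fit_tweedie_glm(formula, data, p = p, ...))
  }
  beta <- beta_u[seq_len(nb)]
  names(beta) <- colnames(X)
  Vfull <- phi * solve(crossprod(XZ * sqrt(mu^(2 - p))) +
                         diag(c(rep(0, nb), phi / sigma2[blk])))
  ll <- sum(dtweedie_cp(y, mu, phi, p))
  fit <- structure(list(
    coefficients = beta, vcov = Vfull[seq_len(nb), seq_len(nb), drop = FALSE],
    phi = phi, p = p,
    log_likelihood = ll, aic = NA_real_, n_par = nb + 2L + length(groups),
    fitted = mu, linear_predictor = eta, y = y,
    n_obs = length(y), iterations = outer,
    formula = formula, terms = stats::terms(mf), contrasts = contrasts,
    xlevels = stats::.getXlevels(stats::terms(mf), mf),
    assign = attr(X, "assign"), model_frame = mf,
    scaling = NULL,
    variance_components = stats::setNames(sigma2, groups),
    random_effects = stats::setNames(
      lapply(seq_along(groups), function(g) beta_u[nb + which(blk == g)]),
      groups),
    approximate = TRUE
  ), class = "tweedie_fit")
  fit
}
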