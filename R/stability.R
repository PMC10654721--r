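#' Crop composition table of a dataset
#'
#' One row per (system, time point), one column per crop, entries the
#' field-count proportions (each row sums to 1).
#'
#' @param fields field-observation table of a dataset.
#' @return list with `comp` (numeric matrix), `system_id`, `time_point`,
#'   `region` (row metadata vectors).
#' @export
composition_table <- function(fields) {
  grp <- interaction(fields$system_id, fields$time_point, drop = TRUE, sep = "\r")
  crops <- sort(unique(fields$crop))
  rows <- split(seq_len(nrow(fields)), grp)
  comp <- matrix(0, nrow = length(rows), ncol = length(crops),
                 dimnames = list(NULL, crops))
  meta_sys <- character(length(rows)); meta_tp <- character(length(rows))
  meta_reg <- character(length(rows))
  for (i in seq_along(rows)) {
    f <- fields[rows[[i]], , drop = FALSE]
    p <- composition_from_fields(f$crop)
    comp[i, names(p)] <- p
    meta_sys[i] <- as.character(f$system_id[1])
    meta_tp[i] <- as.character(f$time_point[1])
    meta_reg[i] <- as.character(f$climatic_region[1])
  }
  list(comp = comp, system_id = meta_sys, time_point = meta_tp,
       region = meta_reg)
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, computed with
#' \code{vegan::vegdist}. For composition rows summing to 1 the values lie
#' in `[0, 1]` with 0 on the diagonal.
#'
#' @param comp numeric matrix of nonnegative rows (compositions).
#' @return A symmetric dissimilarity matrix.
#' @export
bray_curtis_matrix <- function(comp) {
  comp <- as.matrix(comp)
  if (any(comp < 0)) stop("composition entries must be nonnegative")
  as.matrix(vegan::vegdist(comp, method = "bray"))
}

#' PERMANOVA with restricted permutations
#'
#' Partitions the sum of squared dissimilarities among groups and assesses
#' significance by permuting group labels, optionally restricted within
#' strata (e.g. climatic regions). With \eqn{n} rows and \eqn{a} groups:
#' \deqn{SS_{total} = \frac{1}{n}\sum_{i<j} d_{ij}^2,\quad
#'       SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2,}
#' \eqn{SS_{between} = SS_{total} - SS_{within}},
#' \eqn{F = (SS_{between}/(a-1)) / (SS_{within}/(n-a))} and
#' \eqn{R^2 = SS_{between}/SS_{total}}. The permutation p-value uses the
#' +1 convention (observed configuration counted in the reference set).
#'
#' @param dist square symmetric dissimilarity matrix (or `dist`).
#' @param groups group labels, one per row.
#' @param strata optional stratum labels restricting permutations.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed for the permutation stream.
#' @return Object of class `rotapest_permanova`: list with `ss_between`,
#'   `ss_within`, `ss_total`, `df_between`, `df_within`, `pseudo_f`,
#'   `r_squared`, `p_value`, `n_permutations`.
#' @export
permanova <- function(dist, groups, strata = NULL, n_perm = 1000,
                      seed = NULL) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n != ncol(d) || any(abs(d - t(d)) > 1e-8))
    stop("dist must be a square symmetric matrix")
  groups <- as.factor(as.character(groups))
  if (length(groups) != n) stop("groups length must match dist")
  a <- nlevels(groups)
  if (a < 2L) stop("need at least 2 groups")
  if (n - a < 1L) stop("no within-group degrees of freedom (n - a = 0)")
  if (!is.null(strata)) {
    strata <- as.factor(as.character(strata))
    if (length(strata) != n) stop("strata length must match dist")
  }
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within_of <- function(g) {
    idx <- split(seq_len(n), g)
    sum(vapply(idx, function(i) sum(d2[i, i]) / (2 * length(i)), numeric(1)))
  }
  ss_within <- ss_within_of(groups)
  ss_between <- ss_total - ss_within
  f_of <- function(ssw) ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  f_obs <- f_of(ss_within)

  if (!is.null(seed)) set.seed(seed)
  perm_idx <- function() {
    idx <- seq_len(n)
    if (is.null(strata)) return(sample(idx))
    for (s in levels(strata)) {
      w <- which(strata == s)
      if (length(w) > 1L) idx[w] <- w[sample(length(w))]
    }
    idx
  }
  n_ge <- 0L
  for (b in seq_len(n_perm)) {
    gp <- groups[perm_idx()]
    n_ge <- n_ge + (f_of(ss_within_of(gp)) >= f_obs - 1e-12)
  }
  structure(list(
    ss_between = ss_between, ss_within = ss_within, ss_total = ss_total,
    df_between = a - 1L, df_within = n - a,
    pseudo_f = f_obs, r_squared = ss_between / ss_total,
    p_value = (n_ge + 1) / (n_perm + 1), n_permutations = n_perm
  ), class = "rotapest_permanova")
}

#' @export
print.rotapest_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: F(%d,%d) = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$df_between, x$df_within, x$pseudo_f, x$r_squared, x$p_value,
              x$n_permutations))
  invisible(x)
}

#' Multivariate homogeneity of group dispersions
#'
#' Embeds the dissimilarity matrix by principal coordinates (double
#' centering and eigendecomposition; axes with negative eigenvalues are
#' retained as an imaginary block), computes each group's spatial median by
#' iteratively reweighted least squares separately in the real and
#' imaginary blocks, and forms each point's distance to its group median as
#' \eqn{d^2 = d^2_{real} - d^2_{imag}} clamped at 0. The distances are then
#' compared between groups with a one-way ANOVA. Groups of size 1 have
#' distance 0 and are excluded from the ANOVA with a warning.
#'
#' @inheritParams permanova
#' @return list with `distances` (per point), `groups`, `group_medians_dist`
#'   (mean distance per group), `anova_f`, `df`, `p_value`, `excluded`
#'   (singleton group labels).
#' @export
dispersion_test <- function(dist, groups, seed = NULL) {
  d <- as.matrix(dist)
  n <- nrow(d)
  groups <- as.factor(as.character(groups))

  # PCoA: double-centered Gower matrix, full eigendecomposition
  A <- -0.5 * d^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  eig <- eigen(G, symmetric = TRUE)
  keep <- abs(eig$values) > max(abs(eig$values)) * 1e-10
  val <- eig$values[keep]
  vec <- eig$vectors[, keep, drop = FALSE]
  pos <- val > 0
  Vr <- sweep(vec[, pos, drop = FALSE], 2, sqrt(val[pos]), `*`)
  Vi <- if (any(!pos)) sweep(vec[, !pos, drop = FALSE], 2, sqrt(-val[!pos]), `*`)
        else matrix(0, n, 0)

  dist2_block <- function(V, idx, tol = 1e-8, max_iter = 500) {
    # squared distances of rows idx to their spatial (geometric) median
    if (ncol(V) == 0L) return(rep(0, length(idx)))
    X <- V[idx, , drop = FALSE]
    m <- colMeans(X)
    for (it in seq_len(max_iter)) {
      dd <- sqrt(rowSums(sweep(X, 2, m)^2))
      at_point <- dd < 1e-12
      if (any(at_point)) dd[at_point] <- 1e-12  # perturbation for ties at a data point
      w <- 1 / dd
      m_new <- colSums(X * w) / sum(w)
      if (sqrt(sum((m_new - m)^2)) < tol) { m <- m_new; break }
      m <- m_new
    }
    rowSums(sweep(X, 2, m)^2)
  }

  dist2 <- numeric(n)
  for (g in levels(groups)) {
    idx <- which(groups == g)
    dist2[idx] <- pmax(dist2_block(Vr, idx) - dist2_block(Vi, idx), 0)
  }
  dists <- sqrt(dist2)

  sizes <- table(groups)
  singles <- names(sizes)[sizes < 2]
  if (length(singles) > 0L)
    warning("group(s) of size 1 excluded from the dispersion ANOVA: ",
            paste(singles, collapse = ", "))
  keep_rows <- !(as.character(groups) %in% singles)
  g2 <- droplevels(groups[keep_rows])
  if (nlevels(g2) < 2L) stop("fewer than 2 groups with >= 2 members")
  fit <- stats::anova(stats::lm(dists[keep_rows] ~ g2))
  structure(list(
    distances = dists, groups = groups,
    group_mean_dist = tapply(dists, groups, mean),
    anova_f = fit[["F value"]][1],
    df = c(fit[["Df"]][1], fit[["Df"]][2]),
    p_value = fit[["Pr(>F)"]][1],
    excluded = singles
  ), class = "rotapest_dispersion")
}

#' @export
print.rotapest_dispersion <- function(x, ...) {
  cat(sprintf("Dispersion ANOVA: F(%d,%d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$anova_f, x$p_value))
  invisible(x)
}

#' Balanced-subset PERMANOVA robustness analysis
#'
#' Splits the rows by the number of observations available per group (e.g.
#' 2, 3, ..., 11 time points per cropping system) and runs one PERMANOVA
#' per observation-count class, so that each sub-analysis is balanced and
#' insensitive to dispersion heterogeneity. Classes holding fewer than two
#' groups are skipped with a warning.
#'
#' @param comp composition matrix (rows = system x time point).
#' @param groups group labels (cropping system ids).
#' @param strata stratum labels (climatic regions).
#' @param n_perm permutations per PERMANOVA.
#' @param seed integer seed.
#' @return data.frame with one row per observation-count class `k`:
#'   `k`, `n_groups`, `n_rows`, `r_squared`, `pseudo_f`, `p_value`.
#' @export
balanced_subset_analysis <- function(comp, groups, strata = NULL,
                                     n_perm = 1000, seed = NULL) {
  groups <- as.character(groups)
  counts <- table(groups)
  ks <- sort(unique(as.integer(counts)))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (k in ks) {
    gk <- names(counts)[counts == k]
    if (length(gk) < 2L) {
      warning("observation-count class k = ", k,
              " has fewer than 2 groups; skipped")
      next
    }
    idx <- which(groups %in% gk)
    d <- bray_curtis_matrix(comp[idx, , drop = FALSE])
    res <- permanova(d, groups[idx],
                     strata = if (is.null(strata)) NULL else strata[idx],
                     n_perm = n_perm)
    rows[[length(rows) + 1L]] <- data.frame(
      k = k, n_groups = length(gk), n_rows = length(idx),
      r_squared = res$r_squared, pseudo_f = res$pseudo_f,
      p_value = res$p_value
    )
  }
  if (length(rows) == 0L) stop("no observation-count class with >= 2 groups")
  do.call(rbind, rows)
}
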