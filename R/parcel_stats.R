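#' Gray-matter median of a map
#'
#' @param map 3D numeric array.
#' @param gm_mask 3D logical mask.
#' @return Median of the finite in-mask voxels (non-finite voxels are
#'   excluded; their count is in attribute `n_excluded`).
#' @export
gm_median <- function(map, gm_mask) {
  gm_mask <- array(as.logical(gm_mask), dim(map))
  if (!any(gm_mask)) stop("empty gray-matter mask")
  v <- map[gm_mask]
  ok <- is.finite(v)
  if (!any(ok)) stop("all in-mask voxels are non-finite")
  structure(stats::median(v[ok]), n_excluded = sum(!ok))
}

#' Parcel means of a map
#'
#' @param map 3D numeric array.
#' @param atlas 3D integer label array (positive labels; 0 = background)
#'   or a `synthetic_atlas`.
#' @param map_kind Optional label recorded with the table.
#' @return Data frame of class `parcel_table` with `parcel_id`,
#'   `parcel_mean` (mean of finite voxels) and `n_voxels`; empty parcels
#'   are dropped with a warning.
#' @export
parcel_means <- function(map, atlas, map_kind = NULL) {
  if (inherits(atlas, "synthetic_atlas")) atlas <- atlas$atlas
  if (!all(dim(map) == dim(atlas)))
    stop("map grid ", paste(dim(map), collapse = "x"),
         " does not match atlas grid ", paste(dim(atlas), collapse = "x"))
  sel <- atlas > 0L & is.finite(map)
  labs <- atlas[sel]
  means <- tapply(map[sel], labs, mean)
  counts <- tapply(map[sel], labs, length)
  all_ids <- sort(unique(atlas[atlas > 0L]))
  got <- as.integer(names(means))
  if (length(got) < length(all_ids))
    warning("dropping ", length(all_ids) - length(got),
            " parcel(s) with no finite voxels")
  out <- data.frame(parcel_id = got, parcel_mean = as.numeric(means),
                    n_voxels = as.integer(counts))
  attr(out, "map_kind") <- map_kind
  class(out) <- c("parcel_table", "data.frame")
  out
}

#' Cook's distance for a simple linear regression
#'
#' Influence of each observation on the OLS fit of `y` on `x`, from the
#' standard leverage/residual formula with p = 2 parameters. The usual
#' screening threshold in this pipeline is `4/n`.
#'
#' @param x,y Numeric vectors (n >= 4, `x` non-constant).
#' @return Numeric vector of Cook's distances.
#' @export
cooks_distance <- function(x, y) {
  n <- length(x)
  if (n < 4 || length(y) != n) stop("need n >= 4 paired observations")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("zero variance in x")
  h <- 1 / n + (x - mean(x))^2 / sxx
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  e <- y - (mean(y) + b * (x - mean(x)))
  s2 <- sum(e^2) / (n - 2)
  if (s2 == 0) return(rep(0, n))
  e^2 * h / (2 * s2 * (1 - h)^2)
}

#' Fisher Z transformation
#' @param r Correlation coefficient(s), |r| < 1.
#' @param n Optional sample size; when given, the standardized form
#'   `atanh(r) * sqrt(n - 3)` is returned instead of raw `atanh(r)`.
#' @return Numeric vector.
#' @export
fisher_z <- function(r, n = NULL) {
  z <- atanh(r)
  if (!is.null(n)) z <- z * sqrt(n - 3)
  z
}

#' Critical values for Fisher-Z screening of a single correlation
#'
#' The standardized Fisher Z statistic `atanh(r) * sqrt(n - 3)` is compared
#' to the two-tailed normal critical value (1.96 at alpha = 0.05). The
#' corresponding threshold on |r| itself, `tanh(z_crit / sqrt(n_used - 3))`,
#' rises as observations (e.g. outlier parcels) are removed.
#'
#' @param n_used Number of retained observations (>= 4).
#' @param alpha Two-tailed significance level (default 0.05).
#' @return List with `z_crit`, `r_threshold`, `n_used`, `alpha`.
#' @export
adjusted_critical_value <- function(n_used, alpha = 0.05) {
  stopifnot(n_used >= 4, alpha > 0, alpha < 1)
  z_crit <- stats::qnorm(1 - alpha / 2)
  list(z_crit = z_crit,
       r_threshold = tanh(z_crit / sqrt(n_used - 3)),
       n_used = n_used, alpha = alpha)
}

.correlation_result <- function(method, r, p, n_used, removed, rule, alpha,
                                unscreened = NULL) {
  z_raw <- if (abs(r) < 1) atanh(r) else sign(r) * Inf
  z_std <- if (n_used > 3) z_raw * sqrt(n_used - 3) else NA_real_
  crit <- stats::qnorm(1 - alpha / 2)
  structure(list(method = method, r = r, p = p,
                 fisher_z = z_raw, fisher_z_std = z_std,
                 n_used = n_used, removed_indices = removed,
                 removal_rule = rule, critical_value = crit,
                 significant = !is.na(z_std) && abs(z_std) > crit,
                 alpha = alpha, unscreened = unscreened),
            class = "correlation_result")
}

#' Between-subject Pearson correlation with influence screening
#'
#' Pearson correlation of two per-subject scalars (e.g. gray-matter median
#' CBF and CVR). When `remove_influential = TRUE`, points with Cook's
#' distance above `4/n` on the regression of `y` on `x` are removed in a
#' single pass and the correlation is recomputed on the retained points;
#' the unscreened result is kept alongside.
#'
#' @param x,y Per-subject values (n >= 4).
#' @param remove_influential Apply the 4/n Cook's rule (default TRUE).
#' @param alpha Significance level (default 0.05).
#' @return A `correlation_result`; the full-sample fit is in
#'   `$unscreened` when screening removed anything.
#' @export
correlate_between_subjects <- function(x, y, remove_influential = TRUE,
                                       alpha = 0.05) {
  n <- length(x)
  if (n < 4 || length(y) != n) stop("need n >= 4 paired subjects")
  ct_full <- stats::cor.test(x, y)
  full <- list(r = unname(ct_full$estimate), p = ct_full$p.value, n = n)
  removed <- integer(0)
  if (remove_influential) {
    D <- cooks_distance(x, y)
    removed <- which(D > 4 / n)
  }
  if (length(removed)) {
    if (n - length(removed) < 3)
      stop("fewer than 3 subjects remain after influence removal")
    ct <- stats::cor.test(x[-removed], y[-removed])
    .correlation_result("pearson", unname(ct$estimate), ct$p.value,
                        n - length(removed), removed,
                        "cooks_4_over_n", alpha, unscreened = full)
  } else {
    .correlation_result("pearson", full$r, full$p, n, removed,
                        if (remove_influential) "cooks_4_over_n" else "none",
                        alpha, unscreened = full)
  }
}

#' Within-subject spatial rank correlation across parcels
#'
#' Spearman correlation between two parcel tables (e.g. CVR and baseline
#' CBF parcel means). Outlier parcels are screened once by Cook's distance
#' above `4/n` on the rank-rank regression (consistent with the rank
#' correlation), then the correlation, its Fisher Z, and significance
#' against the standardized normal critical value are computed on the
#' retained parcels.
#'
#' @param x,y `parcel_table`s (or numeric vectors of matched parcel
#'   values).
#' @param remove_outlier_parcels Apply the 4/n rule (default TRUE).
#' @param alpha Significance level (default 0.05).
#' @return A `correlation_result` (method `"spearman"`). Removing more
#'   than 25% of parcels triggers a warning but still returns the result.
#' @export
correlate_spatial <- function(x, y, remove_outlier_parcels = TRUE,
                              alpha = 0.05) {
  if (inherits(x, "parcel_table") && inherits(y, "parcel_table")) {
    m <- merge(as.data.frame(x)[c("parcel_id", "parcel_mean")],
               as.data.frame(y)[c("parcel_id", "parcel_mean")],
               by = "parcel_id")
    xv <- m$parcel_mean.x; yv <- m$parcel_mean.y
  } else {
    xv <- as.numeric(x); yv <- as.numeric(y)
    if (length(xv) != length(yv)) stop("parcel vectors differ in length")
  }
  n <- length(xv)
  if (n < 10) stop("need at least 10 matched parcels")
  rho_full <- stats::cor(xv, yv, method = "spearman")
  removed <- integer(0)
  if (remove_outlier_parcels) {
    rx <- rank(xv); ry <- rank(yv)
    D <- cooks_distance(rx, ry)
    removed <- which(D > 4 / n)
    if (length(removed) > 0.25 * n)
      warning("more than 25% of parcels flagged as outliers (",
              length(removed), "/", n, ")")
  }
  keep <- setdiff(seq_len(n), removed)
  rho <- stats::cor(xv[keep], yv[keep], method = "spearman")
  .correlation_result("spearman", rho, NA_real_, length(keep), removed,
                      if (remove_outlier_parcels) "cooks_4_over_n" else "none",
                      alpha,
                      unscreened = list(r = rho_full, p = NA_real_, n = n))
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.3f (n = %d%s)\n",
              x$method, x$r, x$n_used,
              if (length(x$removed_indices))
                sprintf(", %d removed by %s", length(x$removed_indices),
                        x$removal_rule) else ""))
  cat(sprintf("  Fisher Z = %.3f (standardized %.2f vs critical %.2f): %s\n",
              x$fisher_z, x$fisher_z_std, x$critical_value,
              if (isTRUE(x$significant)) "significant" else "not significant"))
  if (!is.na(x$p)) cat(sprintf("  p = %.4g\n", x$p))
  invisible(x)
}
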