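#' Fit voxelwise CVR with or without hemodynamic lag optimization
#'
#' Mass-univariate multiple regression of every in-mask voxel series on an
#' end-tidal CO2 regressor plus nuisance terms (intercept, polynomial
#' drift, six motion parameters). With `optimize = "none"` only the
#' unshifted (lag 0) regressor is used. With `optimize = "lag"` the model
#' is refit for every shifted regressor in the set and, per voxel, the lag
#' with the largest full-model R-squared wins; ties are broken toward the
#' smallest absolute lag (negative before positive). CVR amplitude is
#' `100 * beta_petco2 / beta_mean` in %BOLD/mmHg, where `beta_mean` is the
#' fitted intercept. Voxels whose fitted mean is within
#' `beta_mean_eps` times the grand mean absolute signal of zero get `NaN`
#' amplitude and a flag. Lags selected at the edge of the grid are flagged
#' as boundary voxels (and additionally censored when
#' `censor_boundary = TRUE`).
#'
#' @param bold 4D BOLD array; the trailing volumes must cover the
#'   regressor's analyzed window (an initial discard prefix is dropped
#'   automatically).
#' @param regressors A [build_regressors()] set.
#' @param mask 3D logical (or 0/1) analysis mask.
#' @param motion Optional motion matrix with one row per bold volume (or
#'   per analyzed volume).
#' @param drift_order Polynomial drift order; default one order per 150 s
#'   of analyzed scan time (minimum 1).
#' @param optimize `"lag"` or `"none"`.
#' @param censor_boundary Censor boundary-lag voxels (default FALSE).
#' @param beta_mean_eps Relative threshold guarding the %BOLD division.
#' @return Object of class `cvr_fit` with 3D maps `cvr_amp`, `lag_s`,
#'   `r_squared`, `beta_mean`, logical `boundary_flag` and `mean_flag`,
#'   plus fitting metadata.
#' @seealso [summary.cvr_fit()], [coef.cvr_fit()]
#' @export
cvr_fit <- function(bold, regressors, mask, motion = NULL,
                    drift_order = NULL, optimize = c("lag", "none"),
                    censor_boundary = FALSE, beta_mean_eps = 1e-6) {
  optimize <- match.arg(optimize)
  stopifnot(inherits(regressors, "regressor_set"), length(dim(bold)) == 4)
  sp <- dim(bold)[1:3]
  if (!all(dim(mask) == sp)) {
    stop("mask grid ", paste(dim(mask), collapse = "x"),
         " does not match bold grid ", paste(sp, collapse = "x"))
  }
  mask <- array(as.logical(mask), sp)
  vox <- which(mask)
  if (!length(vox)) stop("empty mask")
  nv <- ncol(regressors$regressors)
  n_total <- dim(bold)[4]
  n_discard <- n_total - nv
  if (n_discard < 0)
    stop("bold has fewer volumes than the regressor set expects")
  if (any(!is.finite(regressors$regressors)))
    stop("regressor rows contain non-finite values")

  flat <- matrix(bold, prod(sp), n_total)
  Y <- t(flat[vox, (n_discard + 1L):n_total, drop = FALSE]) # nv x nvox
  nvox <- ncol(Y)
  if (any(!is.finite(Y))) stop("non-finite values inside the mask")

  if (is.null(drift_order))
    drift_order <- max(1L, floor(nv * regressors$tr_s / 150))
  tv <- (seq_len(nv) - 1) * regressors$tr_s
  N <- if (drift_order >= 1)
    unclass(stats::poly(tv, degree = drift_order)) else NULL
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) == n_total)
      motion <- motion[(n_discard + 1L):n_total, , drop = FALSE]
    if (nrow(motion) != nv) stop("motion rows do not match bold volumes")
    m <- scale(motion, center = TRUE, scale = FALSE)
    m <- m[, colSums(abs(m)) > 0, drop = FALSE]
    if (ncol(m)) N <- cbind(N, m)
  }

  ## centered formulation: solve for non-intercept betas on demeaned data,
  ## recover the intercept as ybar - beta_pet * xbar (nuisances are mean-free)
  ybar <- colMeans(Y)
  Yc <- sweep(Y, 2, ybar)
  ss_tot <- colSums(Yc^2)
  p0 <- if (is.null(N)) 0L else ncol(N)
  NtN <- if (p0) crossprod(N) else matrix(0, 0, 0)
  NtY <- if (p0) crossprod(N, Yc) else matrix(0, 0, nvox)

  lag_order <- order(abs(regressors$lags_s), regressors$lags_s)
  if (optimize == "none")
    lag_order <- which(abs(regressors$lags_s) < regressors$lag_step_s / 100)

  best_r2 <- rep(-Inf, nvox)
  best_i <- rep(NA_integer_, nvox)
  best_bpet <- numeric(nvox)
  best_bmean <- numeric(nvox)
  for (i in lag_order) {
    x <- regressors$regressors[i, ]
    xbar <- mean(x)
    xc <- x - xbar
    xtx <- sum(xc^2)
    xtY <- crossprod(xc, Yc)                    # 1 x nvox
    if (p0) {
      Ntx <- crossprod(N, xc)
      XtX <- rbind(cbind(NtN, Ntx), cbind(t(Ntx), xtx))
      XtY <- rbind(NtY, xtY)
    } else {
      XtX <- matrix(xtx, 1, 1)
      XtY <- xtY
    }
    B <- tryCatch(solve(XtX, XtY),
                  error = function(e) stop("rank-deficient model at lag ",
                                           regressors$lags_s[i], " s: ",
                                           conditionMessage(e)))
    ss_res <- pmax(ss_tot - colSums(B * XtY), 0)
    r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, 0)
    upd <- r2 > best_r2
    if (any(upd)) {
      best_r2[upd] <- r2[upd]
      best_i[upd] <- i
      best_bpet[upd] <- B[p0 + 1L, upd]
      best_bmean[upd] <- ybar[upd] - B[p0 + 1L, upd] * xbar
    }
  }
  best_r2[!is.finite(best_r2)] <- 0
  best_r2 <- pmin(pmax(best_r2, 0), 1)

  eps <- beta_mean_eps * mean(abs(Y))
  mean_flag <- abs(best_bmean) < eps
  cvr <- ifelse(mean_flag, NaN, 100 * best_bpet / best_bmean)
  lag_sel <- regressors$lags_s[best_i]
  boundary <- abs(lag_sel) >= max(abs(regressors$lags_s)) - 1e-9
  if (optimize == "none") boundary <- rep(FALSE, nvox)
  if (censor_boundary) {
    cvr[boundary] <- NA_real_
    lag_sel[boundary] <- NA_real_
  }

  to_map <- function(v, init = NA_real_) {
    a <- array(init, sp); a[vox] <- v; a
  }
  structure(list(cvr_amp = to_map(cvr),
                 lag_s = to_map(if (optimize == "none") rep(0, nvox) else lag_sel),
                 r_squared = to_map(best_r2),
                 beta_mean = to_map(best_bmean),
                 boundary_flag = to_map(boundary, FALSE),
                 mean_flag = to_map(mean_flag, FALSE),
                 mask = mask, lags_s = regressors$lags_s,
                 optimize = optimize, drift_order = drift_order,
                 n_volumes = nv, n_discard = n_discard,
                 censor_boundary = censor_boundary,
                 call = match.call()),
            class = "cvr_fit")
}

#' CVR without lag optimization (unshifted regressor)
#' @inheritParams cvr_fit
#' @param ... Passed to [cvr_fit()].
#' @return A `cvr_fit` with `lag_s = 0` everywhere.
#' @export
cvr_no_opt <- function(bold, regressors, mask, ...)
  cvr_fit(bold, regressors, mask, optimize = "none", ...)

#' CVR with hemodynamic lag optimization
#' @inheritParams cvr_fit
#' @param ... Passed to [cvr_fit()].
#' @return A `cvr_fit` with per-voxel optimal lags.
#' @export
cvr_lag_opt <- function(bold, regressors, mask, ...)
  cvr_fit(bold, regressors, mask, optimize = "lag", ...)

#' @export
print.cvr_fit <- function(x, ...) {
  nvox <- sum(x$mask)
  cat(sprintf("CVR fit (%s): %d voxels, %d volumes, drift order %d\n",
              if (x$optimize == "lag") "lag-optimized" else "no lag optimization",
              nvox, x$n_volumes, x$drift_order))
  cat(sprintf("  median CVR %.3f %%BOLD/mmHg, median R^2 %.3f\n",
              stats::median(x$cvr_amp[x$mask], na.rm = TRUE),
              stats::median(x$r_squared[x$mask], na.rm = TRUE)))
  if (x$optimize == "lag")
    cat(sprintf("  median |lag| %.2f s, %d boundary voxel(s)\n",
                stats::median(abs(x$lag_s[x$mask]), na.rm = TRUE),
                sum(x$boundary_flag)))
  invisible(x)
}

#' @export
summary.cvr_fit <- function(object, ...) {
  m <- object$mask
  qs <- function(v) stats::quantile(v[m], c(.05, .25, .5, .75, .95), na.rm = TRUE)
  out <- list(optimize = object$optimize,
              n_voxels = sum(m),
              cvr = qs(object$cvr_amp),
              lag = qs(object$lag_s),
              r_squared = qs(object$r_squared),
              n_boundary = sum(object$boundary_flag),
              n_mean_flag = sum(object$mean_flag))
  class(out) <- "summary.cvr_fit"
  out
}

#' @export
print.summary.cvr_fit <- function(x, ...) {
  cat(sprintf("CVR fit summary (%s), %d voxels\n", x$optimize, x$n_voxels))
  tab <- rbind(`CVR (%BOLD/mmHg)` = x$cvr, `lag (s)` = x$lag,
               `R^2` = x$r_squared)
  print(round(tab, 3))
  cat(sprintf("boundary-lag voxels: %d; near-zero-mean voxels: %d\n",
              x$n_boundary, x$n_mean_flag))
  invisible(x)
}

#' @export
coef.cvr_fit <- function(object, ...) {
  idx <- which(object$mask, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3],
             cvr_amp = object$cvr_amp[object$mask],
             lag_s = object$lag_s[object$mask],
             r_squared = object$r_squared[object$mask],
             beta_mean = object$beta_mean[object$mask],
             boundary = object$boundary_flag[object$mask])
}

#' @export
plot.cvr_fit <- function(x, map = c("cvr_amp", "lag_s", "r_squared"),
                         slice = NULL, ...) {
  map <- match.arg(map)
  a <- x[[map]]
  if (is.null(slice)) slice <- ceiling(dim(a)[3] / 2)
  graphics::image(a[, , slice], main = sprintf("%s (slice %d)", map, slice),
                  useRaster = TRUE, ...)
  invisible(x)
}
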