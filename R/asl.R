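#' Kinetic parameters for single-PLD pCASL quantification
#'
#' Defaults follow the consensus single-compartment model for a
#' pseudo-continuous labeling scheme with post-label delay and bolus
#' duration of 1.8 s each (inflow time 3.6 s) and inversion efficiency
#' 0.85. Both the tissue T1 used by Bayesian kinetic tools and the blood
#' T1 used by the closed-form formula are carried; the formula uses
#' `t1_blood_s`.
#'
#' @param lambda_partition Blood-brain partition coefficient (ml/g).
#' @param alpha_inv_eff Labeling (inversion) efficiency, in (0, 1].
#' @param tau_bolus_s Label (bolus) duration in seconds.
#' @param pld_s Post-label delay in seconds.
#' @param t1_s Tissue T1 in seconds (metadata; not used by the formula).
#' @param t1_blood_s Arterial blood T1 in seconds.
#' @return List of class `asl_params`.
#' @export
asl_params <- function(lambda_partition = 0.9, alpha_inv_eff = 0.85,
                       tau_bolus_s = 1.8, pld_s = 1.8, t1_s = 1.3,
                       t1_blood_s = 1.65) {
  vals <- c(lambda_partition, alpha_inv_eff, tau_bolus_s, pld_s, t1_s,
            t1_blood_s)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all ASL parameters must be positive")
  if (alpha_inv_eff > 1) stop("'alpha_inv_eff' must be in (0, 1]")
  structure(list(lambda_partition = lambda_partition,
                 alpha_inv_eff = alpha_inv_eff,
                 tau_bolus_s = tau_bolus_s, pld_s = pld_s, t1_s = t1_s,
                 t1_blood_s = t1_blood_s),
            class = "asl_params")
}

# forward kinetic model: CBF (ml/100 g/min) -> delta-M signal
.cbf_forward <- function(cbf, m0, params) {
  with(params,
       cbf * 2 * alpha_inv_eff * t1_blood_s * m0 *
         (1 - exp(-tau_bolus_s / t1_blood_s)) * exp(-pld_s / t1_blood_s) /
         (6000 * lambda_partition))
}

#' Average tag/control difference of a pCASL series
#'
#' @param series 4D array of tag/control volumes plus one M0 volume.
#' @param order `"tc"` (tag first, default) or `"ct"`.
#' @param m0_index Index of the M0 volume (default: the `m0_index`
#'   attribute of the series, else the last volume).
#' @return List with `delta_m` (mean control - tag, 3D), `m0` (3D) and
#'   `n_pairs`.
#' @export
tag_control_diff <- function(series, order = c("tc", "ct"), m0_index = NULL) {
  order <- if (missing(order) && !is.null(attr(series, "order")))
    attr(series, "order") else match.arg(order)
  stopifnot(length(dim(series)) == 4)
  if (is.null(m0_index))
    m0_index <- if (!is.null(attr(series, "m0_index")))
      attr(series, "m0_index") else dim(series)[4]
  nvol <- dim(series)[4]
  m0 <- series[, , , m0_index]
  rest <- setdiff(seq_len(nvol), m0_index)
  if (length(rest) %% 2L != 0L)
    stop("odd number of tag/control volumes after removing M0")
  n_pairs <- length(rest) %/% 2L
  tag_idx <- rest[seq(if (order == "tc") 1L else 2L, by = 2L,
                      length.out = n_pairs)]
  ctl_idx <- rest[seq(if (order == "tc") 2L else 1L, by = 2L,
                      length.out = n_pairs)]
  dm <- array(0, dim(series)[1:3])
  for (p in seq_len(n_pairs))
    dm <- dm + (series[, , , ctl_idx[p]] - series[, , , tag_idx[p]])
  list(delta_m = dm / n_pairs, m0 = m0, n_pairs = n_pairs)
}

#' Quantify cerebral blood flow from a mean tag/control difference
#'
#' Single-compartment consensus formula:
#' `cbf = 6000 * lambda * dM * exp(PLD/T1b) /
#'  (2 * alpha * T1b * M0 * (1 - exp(-tau/T1b)))` in ml/100 g/min.
#'
#' @param delta_m Mean control-minus-tag volume.
#' @param m0 Calibration volume (positive inside the mask).
#' @param params [asl_params()].
#' @param mask 3D logical brain mask.
#' @param n_pairs Number of averaged pairs (metadata).
#' @return Object of class `cbf_map`: `cbf` (3D; `NaN` where M0 is
#'   non-positive inside the mask, flagged), `m0`, `mask`, `n_pairs_used`,
#'   `params`, `n_excluded`.
#' @export
quantify_cbf <- function(delta_m, m0, params = asl_params(), mask,
                         n_pairs = NULL) {
  stopifnot(inherits(params, "asl_params"))
  mask <- array(as.logical(mask), dim(delta_m))
  bad <- mask & !(m0 > 0)
  if (any(bad))
    warning(sum(bad), " voxel(s) with non-positive M0 excluded from CBF")
  cbf <- array(NA_real_, dim(delta_m))
  ok <- mask & !bad
  p <- params
  cbf[ok] <- 6000 * p$lambda_partition * delta_m[ok] *
    exp(p$pld_s / p$t1_blood_s) /
    (2 * p$alpha_inv_eff * p$t1_blood_s * m0[ok] *
       (1 - exp(-p$tau_bolus_s / p$t1_blood_s)))
  cbf[bad] <- NaN
  structure(list(cbf = cbf, m0 = m0, mask = mask,
                 n_pairs_used = n_pairs, params = params,
                 n_excluded = sum(bad)),
            class = "cbf_map")
}

#' @export
print.cbf_map <- function(x, ...) {
  cat(sprintf("CBF map: %d voxels, median %.1f ml/100g/min (%d excluded)\n",
              sum(x$mask), stats::median(x$cbf[x$mask], na.rm = TRUE),
              x$n_excluded))
  invisible(x)
}

#' Mask-aware Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian kernel with `sigma = fwhm / (2*sqrt(2*log(2)))` per
#' axis (in mm), renormalized by the smoothed mask so values near mask
#' edges are proper weighted averages of in-mask neighbours (a constant
#' image is unchanged inside the mask). `fwhm_mm = 0` is the identity.
#'
#' @param vol 3D numeric array.
#' @param fwhm_mm Full width at half maximum in mm.
#' @param voxel_mm Isotropic voxel size in mm.
#' @param mask Optional 3D logical mask (default: finite voxels).
#' @return Smoothed 3D array (`NA` outside the mask).
#' @export
smooth_volume <- function(vol, fwhm_mm, voxel_mm = 2, mask = NULL) {
  stopifnot(length(dim(vol)) == 3, fwhm_mm >= 0)
  if (is.null(mask)) mask <- is.finite(vol)
  mask <- array(as.logical(mask), dim(vol))
  if (fwhm_mm == 0) {
    out <- vol; out[!mask] <- NA_real_
    return(out)
  }
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = sigma_vox)
  k <- k / sum(k)
  kernel_mat <- function(n) {
    K <- matrix(0, n, n)
    for (o in -r:r) {
      idx <- seq_len(n)
      tgt <- idx + o
      okk <- tgt >= 1 & tgt <= n
      K[cbind(idx[okk], tgt[okk])] <- K[cbind(idx[okk], tgt[okk])] +
        k[o + r + 1]
    }
    K
  }
  conv_axis <- function(a, axis) {
    d <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, d[axis], prod(d[-axis]))
    m <- kernel_mat(d[axis]) %*% m
    aperm(array(m, d[perm]), order(perm))
  }
  w <- array(as.numeric(mask), dim(vol))
  v0 <- vol; v0[!mask] <- 0
  for (ax in 1:3) {
    v0 <- conv_axis(v0, ax)
    w <- conv_axis(w, ax)
  }
  out <- array(NA_real_, dim(vol))
  out[mask] <- v0[mask] / w[mask]
  out
}

#' Smooth a CBF map
#' @param cbf_map A [quantify_cbf()] result.
#' @param fwhm_mm FWHM in mm (0 = identity).
#' @param voxel_mm Voxel size in mm.
#' @return A `cbf_map` with smoothed values and an `fwhm_mm` field.
#' @export
smooth_cbf <- function(cbf_map, fwhm_mm, voxel_mm = 2) {
  stopifnot(inherits(cbf_map, "cbf_map"))
  sm <- smooth_volume(cbf_map$cbf, fwhm_mm, voxel_mm,
                      cbf_map$mask & is.finite(cbf_map$cbf))
  out <- cbf_map
  out$cbf <- sm
  out$fwhm_mm <- fwhm_mm
  out
}
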