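#' Build a synthetic hemispheric cortical parcellation
#'
#' Creates an ellipsoidal brain on the given grid, a cortical gray-matter
#' shell (a partial-volume profile thresholded at `gm_threshold`), and a
#' parcellation of the shell into `n_regions` regions per hemisphere,
#' mirroring a maximum-probability cortical atlas split at the midline:
#' 48 regions yield 96 hemispheric parcels. Regions are equal-count
#' quantile blocks in the anterior-posterior and inferior-superior
#' directions, so every parcel is non-empty and lies inside the GM mask.
#'
#' @param grid_shape Integer vector of 3 voxel dimensions
#'   (default `c(24, 24, 12)`).
#' @param n_regions Regions per hemisphere (default 48).
#' @param voxel_mm Isotropic voxel size in mm (default 2).
#' @param gm_threshold Partial-volume threshold defining the GM mask
#'   (default 0.5).
#' @return Object of class `synthetic_atlas`: list with `atlas` (3D integer
#'   array, labels 1..2*n_regions; left hemisphere 1..n_regions), `gm_mask`,
#'   `brain_mask` (3D logical), `gm_pv` (partial volume), `affine`,
#'   `n_parcels`, `grid_shape`, `voxel_mm`.
#' @export
make_atlas <- function(grid_shape = c(24, 24, 12), n_regions = 48,
                       voxel_mm = 2, gm_threshold = 0.5) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 2), n_regions >= 1)
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  ax <- 0.46 * nx; ay <- 0.46 * ny; az <- 0.46 * nz
  ii <- slice.index(array(0, grid_shape), 1)
  jj <- slice.index(array(0, grid_shape), 2)
  kk <- slice.index(array(0, grid_shape), 3)
  rho <- sqrt(((ii - cx) / ax)^2 + ((jj - cy) / ay)^2 + ((kk - cz) / az)^2)
  brain <- rho <= 1
  # partial-volume profile: cortex occupies the outer shell of the ellipsoid
  gm_pv <- array(0, grid_shape)
  gm_pv[brain] <- stats::plogis((rho[brain] - 0.5) / 0.06)
  gm <- gm_pv >= gm_threshold

  atlas <- array(0L, grid_shape)
  # factor n_regions into (anterior-posterior) x (inferior-superior) blocks
  divs <- which(n_regions %% seq_len(n_regions) == 0)
  nz_bins <- divs[which.min(abs(divs - sqrt(n_regions * 0.75)))]
  ny_bins <- n_regions / nz_bins
  for (hemi in 1:2) {
    hvox <- which(gm & (if (hemi == 1) ii <= cx else ii > cx))
    if (length(hvox) < n_regions)
      stop("grid too small for ", n_regions, " regions per hemisphere")
    yv <- jj[hvox]; zv <- kk[hvox]
    ord <- order(yv, zv, ii[hvox])
    ybin <- .equal_count_bins(length(hvox), ny_bins)[order(ord)]
    lab <- integer(length(hvox))
    for (b in seq_len(ny_bins)) {
      sel <- which(ybin == b)
      ord_z <- order(zv[sel], yv[sel], ii[hvox][sel])
      zbin <- .equal_count_bins(length(sel), nz_bins)[order(ord_z)]
      lab[sel] <- (b - 1L) * nz_bins + zbin
    }
    atlas[hvox] <- as.integer(lab + (hemi - 1L) * n_regions)
  }
  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  affine[1:3, 4] <- -voxel_mm * c(cx, cy, cz)
  structure(list(atlas = atlas, gm_mask = gm, brain_mask = brain,
                 gm_pv = gm_pv, affine = affine,
                 n_parcels = 2L * as.integer(n_regions),
                 grid_shape = grid_shape, voxel_mm = voxel_mm),
            class = "synthetic_atlas")
}

# assign n items (in order) to k near-equal consecutive bins
.equal_count_bins <- function(n, k) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(k), times = sizes)
}

#' Paint per-parcel values into a volume
#' @param atlas_obj A `synthetic_atlas`.
#' @param values Numeric vector of length `n_parcels` (parcel 1..P order).
#' @param background Value outside the parcellation (default 0).
#' @return 3D numeric array.
#' @export
parcel_paint <- function(atlas_obj, values, background = 0) {
  stopifnot(inherits(atlas_obj, "synthetic_atlas"),
            length(values) == atlas_obj$n_parcels)
  out <- array(background, atlas_obj$grid_shape)
  lab <- atlas_obj$atlas
  sel <- lab > 0L
  out[sel] <- values[lab[sel]]
  out
}

#' Generate a field with a planted rank correlation to a base field
#'
#' Given per-parcel base values, returns standardized partner values whose
#' population Spearman correlation with the base is `rho`. The base values
#' are mapped to normal scores and mixed with independent Gaussian noise at
#' a Pearson coefficient of `2*sin(pi*rho/6)`, the Gaussian-copula value
#' whose induced Spearman correlation equals `rho` (exactly 1 at
#' `rho = 1`). Individual draws fluctuate around the target; the planted
#' value is recovered in expectation over seeds.
#'
#' @param base_field Numeric vector of per-parcel values.
#' @param rho Target Spearman correlation, in `[-1, 1]`.
#' @param seed Integer seed.
#' @return Numeric vector of standardized partner values (z-scores).
#' @export
couple_fields <- function(base_field, rho, seed) {
  if (!is.numeric(rho) || length(rho) != 1L || abs(rho) > 1)
    stop("'rho' must be a single value in [-1, 1]")
  n <- length(base_field)
  set.seed(seed)
  zb <- stats::qnorm((rank(base_field, ties.method = "average") - 0.5) / n)
  rho_p <- 2 * sin(pi * rho / 6)
  as.numeric(rho_p * zb + sqrt(1 - rho_p^2) * stats::rnorm(n))
}
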