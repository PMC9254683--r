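#' Assemble a voxelwise regression design
#'
#' Columns are ordered blocks: intercept, orthonormal polynomial drift over
#' scan time, six demeaned motion parameters, and the end-tidal CO2
#' regressor (kept un-demeaned so that the ratio of its beta to the fitted
#' intercept is the percent signal change per mmHg). All-zero or constant
#' motion columns are dropped with a message. Rank deficiency raises an
#' error naming the offending column.
#'
#' @param n_volumes Number of analyzed volumes.
#' @param tr_s Repetition time in seconds.
#' @param drift_order Polynomial drift order (>= 0); the package default
#'   elsewhere is one order per 150 s of scan.
#' @param motion Optional motion-parameter matrix (`n_volumes` x 6).
#' @param regressor The end-tidal regressor (length `n_volumes`).
#' @return Object of class `cvr_design`: `X`, `blocks` (column indices per
#'   block), `condition_number`, `tr_s`.
#' @export
build_design <- function(n_volumes, tr_s, drift_order, motion = NULL,
                         regressor) {
  stopifnot(n_volumes > 2, tr_s > 0, drift_order >= 0)
  if (length(regressor) != n_volumes)
    stop("'regressor' must have length n_volumes")
  tv <- (seq_len(n_volumes) - 1) * tr_s
  cols <- list(intercept = matrix(1, n_volumes, 1))
  if (drift_order >= 1)
    cols$drift <- unclass(stats::poly(tv, degree = drift_order))
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_volumes || ncol(motion) != 6)
      stop("'motion' must be an n_volumes x 6 matrix")
    m <- scale(motion, center = TRUE, scale = FALSE)
    keep <- colSums(abs(m)) > 0
    if (!all(keep))
      message("dropping ", sum(!keep), " constant motion column(s): ",
              paste(which(!keep), collapse = ", "))
    if (any(keep)) cols$motion <- m[, keep, drop = FALSE]
  }
  cols$petco2 <- matrix(as.numeric(regressor), n_volumes, 1)
  X <- do.call(cbind, cols)
  nm <- unlist(mapply(function(b, k) if (k == 1) b else paste0(b, seq_len(k)),
                      names(cols), vapply(cols, ncol, 1L)))
  colnames(X) <- nm
  blocks <- split(seq_len(ncol(X)), rep(names(cols), vapply(cols, ncol, 1L)))

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- setdiff(seq_len(ncol(X)), sort(qrX$pivot[seq_len(qrX$rank)]))
    stop("design is rank deficient: column(s) ",
         paste(colnames(X)[bad], collapse = ", "), " collinear")
  }
  Xs <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  sv <- svd(Xs, nu = 0, nv = 0)$d
  structure(list(X = X, blocks = blocks,
                 condition_number = sv[1] / sv[length(sv)],
                 tr_s = tr_s),
            class = "cvr_design")
}

#' Ordinary least squares for one voxel
#'
#' @param y Numeric response (finite).
#' @param X A `cvr_design` or numeric design matrix.
#' @return List with `betas` (named), `r_squared` (about the mean) and
#'   `fitted`. An all-zero response returns zero betas and `r_squared = 0`
#'   with a warning.
#' @export
fit_voxel <- function(y, X) {
  if (inherits(X, "cvr_design")) X <- X$X
  if (length(y) != nrow(X)) stop("length(y) must match nrow(X)")
  if (any(!is.finite(y))) stop("'y' must be finite")
  if (all(y == 0)) {
    warning("all-zero voxel series: returning zero fit")
    return(list(betas = stats::setNames(numeric(ncol(X)), colnames(X)),
                r_squared = 0, fitted = numeric(length(y))))
  }
  fit <- stats::lm.fit(X, y)
  betas <- fit$coefficients
  betas[is.na(betas)] <- 0
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else max(0, min(1, 1 - ss_res / ss_tot))
  list(betas = betas, r_squared = r2, fitted = y - fit$residuals)
}
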