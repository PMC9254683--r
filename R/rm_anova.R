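#' Arrange long-format correlation data into a repeated-measures design
#'
#' @param data Data frame with columns `subject`, `scheme` (factor A, e.g.
#'   lag-optimization scheme), `segment` (factor B, e.g. data segment) and
#'   `value` (e.g. Fisher-Z spatial correlation).
#' @return Object of class `rm_design`: response matrix `Y` (subjects x
#'   cells, cell order A-major), level labels and sizes.
#' @export
rm_design <- function(data) {
  stopifnot(all(c("subject", "scheme", "segment", "value") %in% names(data)))
  subj <- factor(data$subject)
  fa <- factor(data$scheme)
  fb <- factor(data$segment)
  a <- nlevels(fa); b <- nlevels(fb); S <- nlevels(subj)
  tab <- table(subj, fa, fb)
  if (any(tab != 1L))
    stop("design must be fully crossed with one observation per cell")
  cell <- (as.integer(fa) - 1L) * b + as.integer(fb)
  Y <- matrix(NA_real_, S, a * b)
  Y[cbind(as.integer(subj), cell)] <- data$value
  colnames(Y) <- paste(rep(levels(fa), each = b), rep(levels(fb), a),
                       sep = ":")
  rownames(Y) <- levels(subj)
  structure(list(Y = Y, a = a, b = b, S = S,
                 levels_a = levels(fa), levels_b = levels(fb)),
            class = "rm_design")
}

# indicator matrices averaging cells into factor levels (columns A-major)
.rm_groups <- function(a, b) {
  ga <- rep(seq_len(a), each = b)
  gb <- rep(seq_len(b), a)
  GA <- matrix(0, a * b, a); GA[cbind(seq_len(a * b), ga)] <- 1 / b
  GB <- matrix(0, a * b, b); GB[cbind(seq_len(a * b), gb)] <- 1 / a
  list(ga = ga, gb = gb, GA = GA, GB = GB)
}

# two-way within-subject F statistics from the cell matrix (S x a*b),
# columns A-major; returns c(FA, FB, FAB)
.rm_f <- function(Y, a, b, g = .rm_groups(a, b)) {
  S <- nrow(Y)
  cm <- colMeans(Y)
  mu <- mean(cm)
  ms <- rowMeans(Y)
  ga <- g$ga; gb <- g$gb
  Ai <- as.numeric(cm %*% g$GA)
  Bj <- as.numeric(cm %*% g$GB)
  Ysa <- Y %*% g$GA
  Ysb <- Y %*% g$GB
  ss_a <- S * b * sum((Ai - mu)^2)
  ss_b <- S * a * sum((Bj - mu)^2)
  ss_ab <- S * sum((cm - Ai[ga] - Bj[gb] + mu)^2)
  ss_subj <- a * b * sum((ms - mu)^2)
  ss_sa <- b * sum((Ysa - matrix(Ai, S, a, byrow = TRUE) - ms + mu)^2)
  ss_sb <- a * sum((Ysb - matrix(Bj, S, b, byrow = TRUE) - ms + mu)^2)
  ss_tot <- sum((Y - mu)^2)
  ss_sab <- max(ss_tot - ss_a - ss_b - ss_ab - ss_subj - ss_sa - ss_sb, 0)
  fr <- function(ss_eff, df_eff, ss_err, df_err) {
    if (ss_err <= .Machine$double.eps * max(1, ss_tot)) {
      if (ss_eff <= .Machine$double.eps * max(1, ss_tot)) 0 else Inf
    } else (ss_eff / df_eff) / (ss_err / df_err)
  }
  c(A = fr(ss_a, a - 1, ss_sa, (a - 1) * (S - 1)),
    B = fr(ss_b, b - 1, ss_sb, (b - 1) * (S - 1)),
    AB = fr(ss_ab, (a - 1) * (b - 1), ss_sab, (a - 1) * (b - 1) * (S - 1)))
}

#' Classical two-way within-subject ANOVA F statistics
#'
#' Sum-of-squares decomposition with subject, subject-by-A, subject-by-B
#' and subject-by-A-by-B error strata. A constant response yields F = 0
#' with a warning.
#'
#' @param design An [rm_design()] (or long data frame accepted by it).
#' @return Data frame with one row per effect (`scheme`, `segment`,
#'   `scheme:segment`): `F`, `df1`, `df2`, and the parametric `p_param`.
#' @export
rm_anova_f <- function(design) {
  if (!inherits(design, "rm_design")) design <- rm_design(design)
  a <- design$a; b <- design$b; S <- design$S
  if (stats::var(as.vector(design$Y)) == 0)
    warning("constant response: all F statistics set to 0")
  f <- .rm_f(design$Y, a, b)
  df1 <- c(a - 1, b - 1, (a - 1) * (b - 1))
  df2 <- df1 * (S - 1)
  data.frame(effect = c("scheme", "segment", "scheme:segment"),
             F = as.numeric(f), df1 = df1, df2 = df2,
             p_param = stats::pf(as.numeric(f), df1, df2, lower.tail = FALSE))
}

# all permutations of 1..n (used only for exhaustive enumeration guards)
.all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in .all_perms(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Permutation repeated-measures ANOVA
#'
#' Null distributions for the two main effects and the interaction are
#' built by permuting the cell labels independently within each subject
#' (observations are exchangeable within the subject stratum under the
#' global null), recomputing all three F statistics for each permutation.
#' P-values are `(1 + #[F_perm >= F_obs]) / (1 + n_perm)`, so no Gaussian
#' or sphericity assumption is used. If the number of distinct
#' within-subject relabelings does not exceed `n_perm`, the null is
#' enumerated exhaustively instead (with a message).
#'
#' @param data Long data frame (see [rm_design()]) or an `rm_design`.
#' @param n_perm Number of permutations (default 100000; must be >= 999).
#' @param seed Integer seed.
#' @return Object of class `perm_rm_anova`: `table` (effects with F, df,
#'   permutation and parametric p), `n_perm`, `exhaustive`, `seed`,
#'   `design`.
#' @export
perm_rm_anova <- function(data, n_perm = 100000, seed) {
  design <- if (inherits(data, "rm_design")) data else rm_design(data)
  if (n_perm < 999) stop("'n_perm' must be at least 999")
  if (missing(seed)) stop("'seed' is required")
  Y <- design$Y; a <- design$a; b <- design$b; S <- design$S
  ab <- a * b
  f_obs <- .rm_f(Y, a, b)

  n_distinct <- factorial(ab)^S
  exhaustive <- is.finite(n_distinct) && n_distinct <= n_perm
  set.seed(seed)
  if (exhaustive) {
    message("enumerating all ", n_distinct, " within-subject relabelings")
    perms <- .all_perms(ab)
    grid <- do.call(expand.grid, rep(list(seq_along(perms)), S))
    n_eff <- nrow(grid)
    count <- c(A = 0, B = 0, AB = 0)
    for (g in seq_len(n_eff)) {
      Yp <- Y
      for (s in seq_len(S)) Yp[s, ] <- Y[s, perms[[grid[g, s]]]]
      count <- count + (.rm_f(Yp, a, b) >= f_obs - 1e-12)
    }
    p <- count / n_eff
    p <- pmax(p, 1 / n_eff)
  } else {
    g <- .rm_groups(a, b)
    count <- c(A = 0, B = 0, AB = 0)
    Yp <- Y
    for (k in seq_len(n_perm)) {
      for (s in seq_len(S)) Yp[s, ] <- Y[s, sample.int(ab)]
      count <- count + (.rm_f(Yp, a, b, g) >= f_obs - 1e-12)
    }
    p <- (1 + count) / (1 + n_perm)
  }

  df1 <- c(a - 1, b - 1, (a - 1) * (b - 1))
  df2 <- df1 * (S - 1)
  tab <- data.frame(effect = c("scheme", "segment", "scheme:segment"),
                    F = as.numeric(f_obs), df1 = df1, df2 = df2,
                    p_perm = as.numeric(p),
                    p_param = stats::pf(as.numeric(f_obs), df1, df2,
                                        lower.tail = FALSE))
  structure(list(table = tab, n_perm = if (exhaustive) NA_integer_ else n_perm,
                 exhaustive = exhaustive, seed = seed, design = design),
            class = "perm_rm_anova")
}

#' @export
print.perm_rm_anova <- function(x, ...) {
  cat("Permutation repeated-measures ANOVA",
      if (x$exhaustive) "(exhaustive null)" else
        sprintf("(%d permutations)", x$n_perm), "\n")
  tab <- x$table
  tab$F <- round(tab$F, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.perm_rm_anova <- function(object, ...) {
  print(object)
  cat(sprintf("design: %d subjects x %d x %d cells\n",
              object$design$S, object$design$a, object$design$b))
  invisible(object$table)
}

#' Pairwise simple main effects with FDR correction
#'
#' For each pair of levels of the chosen factor, the per-subject mean
#' difference (averaged over the other factor) is tested: by default with a
#' within-subject sign-flip permutation test on the mean difference
#' (enumerated exhaustively when `2^S <= n_perm`), or parametrically with a
#' paired t-test. P-values are Benjamini-Hochberg corrected across the
#' contrast family and compared against `alpha`.
#'
#' @param data Long data frame or `rm_design`.
#' @param factor Which factor: `"scheme"` or `"segment"`.
#' @param n_perm Permutations per contrast (default 10000).
#' @param seed Integer seed (required for `method = "permutation"`).
#' @param method `"permutation"` (default) or `"parametric"`.
#' @param alpha Significance level after FDR (default 0.05).
#' @return Data frame: `contrast`, `estimate`, `p_raw`, `p_fdr`,
#'   `significant`.
#' @export
simple_main_effects <- function(data, factor = c("scheme", "segment"),
                                n_perm = 10000, seed = NULL,
                                method = c("permutation", "parametric"),
                                alpha = 0.05) {
  design <- if (inherits(data, "rm_design")) data else rm_design(data)
  factor <- match.arg(factor)
  method <- match.arg(method)
  Y <- design$Y; a <- design$a; b <- design$b; S <- design$S
  ga <- rep(seq_len(a), each = b)
  gb <- rep(seq_len(b), a)
  if (factor == "scheme") {
    levs <- design$levels_a
    M <- vapply(seq_len(a), function(i)
      rowMeans(Y[, ga == i, drop = FALSE]), numeric(S))
  } else {
    levs <- design$levels_b
    M <- vapply(seq_len(b), function(j)
      rowMeans(Y[, gb == j, drop = FALSE]), numeric(S))
  }
  k <- ncol(M)
  if (k < 2) stop("factor has fewer than 2 levels")
  pairs <- utils::combn(k, 2)
  if (method == "permutation" && is.null(seed))
    stop("'seed' required for permutation tests")
  res <- apply(pairs, 2, function(pr) {
    d <- M[, pr[1]] - M[, pr[2]]
    est <- mean(d)
    if (method == "parametric") {
      p <- stats::t.test(d)$p.value
    } else {
      if (2^S <= n_perm) {
        signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), S)))
        null_stat <- abs(as.numeric(signs %*% d) / S)
        p <- mean(null_stat >= abs(est) - 1e-15)
      } else {
        set.seed(seed + pr[1] * 131L + pr[2])
        null_stat <- replicate(n_perm,
                               abs(mean(d * sample(c(-1, 1), S, TRUE))))
        p <- (1 + sum(null_stat >= abs(est) - 1e-15)) / (1 + n_perm)
      }
    }
    c(est = est, p = p)
  })
  out <- data.frame(contrast = paste(levs[pairs[1, ]], "-", levs[pairs[2, ]]),
                    estimate = res["est", ], p_raw = res["p", ])
  out$p_fdr <- stats::p.adjust(out$p_raw, method = "BH")
  out$significant <- out$p_fdr < alpha
  out
}

#' Screen for extreme outliers and rerun the ANOVA three ways
#'
#' Values more than `3 x IQR` below the first quartile or above the third
#' (within each cell of the design; type-7 quantiles) are flagged. Three
#' sensitivity analyses are then run: the full data, the data with flagged
#' subjects removed, and the data with flagged values replaced by the mean
#' of the remaining values in that cell.
#'
#' @param data Long data frame (see [rm_design()]).
#' @param multiplier IQR multiplier (default 3 = extreme outliers).
#' @return Data frame of flags: one row per observation with `flag` set.
#' @export
extreme_outlier_screen <- function(data, multiplier = 3) {
  stopifnot(all(c("subject", "scheme", "segment", "value") %in% names(data)))
  cell <- interaction(data$scheme, data$segment, drop = TRUE)
  flag <- logical(nrow(data))
  for (cl in levels(cell)) {
    idx <- which(cell == cl)
    if (length(idx) < 4)
      stop("fewer than 4 values in cell ", cl, ": cannot screen")
    q <- stats::quantile(data$value[idx], c(0.25, 0.75), type = 7)
    iqr <- q[2] - q[1]
    flag[idx] <- data$value[idx] < q[1] - multiplier * iqr |
      data$value[idx] > q[2] + multiplier * iqr
  }
  out <- data
  out$flag <- flag
  out
}

#' @rdname extreme_outlier_screen
#' @param n_perm,seed Passed to [perm_rm_anova()].
#' @param multiplier IQR multiplier (default 3).
#' @return For `sensitivity_anova`: list with `flags` and the three
#'   `perm_rm_anova` results (`full`, `subjects_removed`,
#'   `values_replaced`).
#' @export
sensitivity_anova <- function(data, n_perm = 100000, seed,
                              multiplier = 3) {
  flags <- extreme_outlier_screen(data, multiplier)
  full <- perm_rm_anova(data, n_perm, seed)
  removed <- NULL
  bad_subj <- unique(flags$subject[flags$flag])
  if (length(bad_subj)) {
    keep <- !(data$subject %in% bad_subj)
    if (length(unique(data$subject[keep])) >= 3)
      removed <- perm_rm_anova(data[keep, ], n_perm, seed)
  } else removed <- full
  repl <- data
  if (any(flags$flag)) {
    cell <- interaction(data$scheme, data$segment, drop = TRUE)
    for (i in which(flags$flag)) {
      same <- which(cell == cell[i] & !flags$flag)
      repl$value[i] <- mean(data$value[same])
    }
    replaced <- perm_rm_anova(repl, n_perm, seed)
  } else replaced <- full
  list(flags = flags, full = full, subjects_removed = removed,
       values_replaced = replaced)
}
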