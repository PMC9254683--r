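test_that("within-subject F statistics match aov with Error strata", {
  # small 2x2, 3 subjects
  set.seed(16)
  Y <- matrix(rnorm(12), 3, 4)
  long <- rm_long(Y, schemes = c("none", "lag"), segments = c("s1", "s2"))
  aov_f <- function(long) {
    ao <- summary(aov(value ~ scheme * segment +
                        Error(factor(subject) / (scheme * segment)),
                      data = long))
    vapply(c("Error: factor(subject):scheme",
             "Error: factor(subject):segment",
             "Error: factor(subject):scheme:segment"),
           function(nm) ao[[nm]][[1]][1, "F value"], numeric(1))
  }
  f <- rm_anova_f(long)
  expect_equal(f$F, unname(aov_f(long)), tolerance = 1e-10)
  expect_equal(f$df1, c(1, 1, 1))
  expect_equal(f$df2, c(2, 2, 2))

  # the study's 2x5, 9 subjects
  set.seed(17)
  long9 <- rm_long(matrix(rnorm(90), 9, 10))
  f9 <- rm_anova_f(long9)
  expect_equal(f9$F, unname(aov_f(long9)), tolerance = 1e-10)
  expect_equal(f9$df2, c(8, 32, 32))
})

test_that("constant responses give zero F with a warning; location shifts change nothing", {
  Y <- matrix(5, 4, 10)
  expect_warning(f <- rm_anova_f(rm_long(Y)), "constant")
  expect_equal(f$F, c(0, 0, 0))
  set.seed(18)
  Y2 <- matrix(rnorm(40), 4, 10)
  f1 <- rm_anova_f(rm_long(Y2))
  f2 <- rm_anova_f(rm_long(Y2 + 100))
  expect_equal(f1$F, f2$F, tolerance = 1e-8)
})

test_that("permutation ANOVA is seeded-deterministic and saturates under a huge effect", {
  set.seed(19)
  Y <- matrix(rnorm(90), 9, 10)
  long <- rm_long(Y)
  a1 <- perm_rm_anova(long, n_perm = 999, seed = 42)
  a2 <- perm_rm_anova(long, n_perm = 999, seed = 42)
  expect_identical(a1$table$p_perm, a2$table$p_perm)
  expect_true(all(a1$table$p_perm >= 1 / 1000 & a1$table$p_perm <= 1))
  # overwhelming scheme effect -> p at the floor 1/(n_perm+1)
  Yb <- matrix(rnorm(90, 0, 0.01), 9, 10)
  Yb[, 1:5] <- Yb[, 1:5] + 100
  ab <- perm_rm_anova(rm_long(Yb), n_perm = 999, seed = 1)
  expect_equal(ab$table$p_perm[1], 1 / 1000)
  expect_error(perm_rm_anova(long, n_perm = 100, seed = 1), "999")
})

test_that("small designs switch to exhaustive enumeration", {
  set.seed(20)
  Y <- matrix(rnorm(8), 2, 4) # (4!)^2 = 576 < 999 relabelings
  long <- rm_long(Y, segments = c("s1", "s2"))
  expect_message(a <- perm_rm_anova(long, n_perm = 999, seed = 3),
                 "enumerating")
  expect_true(a$exhaustive)
  expect_true(all(a$table$p_perm > 0 & a$table$p_perm <= 1))
})

test_that("incomplete designs are rejected", {
  long <- rm_long(matrix(rnorm(40), 4, 10))
  expect_error(rm_design(long[-1, ]), "fully crossed")
})

test_that("Benjamini-Hochberg FDR equals the step-up formula", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  # step-up oracle: p_(i) * m / i, cumulative minimum from the largest
  step_up <- function(p) {
    m <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(p[o] * m / (m:1)))[ro]
  }
  expect_equal(p.adjust(p, method = "BH"), rep(0.05, 5))
  expect_equal(p.adjust(p, method = "BH"), step_up(p))
  set.seed(21)
  q <- runif(20)
  expect_equal(p.adjust(q, method = "BH"), step_up(q))
  expect_equal(p.adjust(rep(1, 6), method = "BH"), rep(1, 6))
  perm <- sample(20)
  expect_equal(p.adjust(q[perm], method = "BH"), step_up(q)[perm])
})

test_that("simple main effects find a planted scheme difference and adjust p-values", {
  set.seed(22)
  Y <- matrix(rnorm(90, 0, 0.3), 9, 10)
  Y[, 1:5] <- Y[, 1:5] + 2 # scheme 'none' columns elevated
  long <- rm_long(Y)
  sme <- simple_main_effects(long, "scheme", seed = 5)
  expect_equal(nrow(sme), 1L)
  expect_lt(sme$p_raw, 0.01)
  expect_true(sme$significant)
  sseg <- simple_main_effects(long, "segment", seed = 5)
  expect_equal(nrow(sseg), choose(5, 2))
  expect_true(all(sseg$p_fdr >= sseg$p_raw - 1e-12))
  spar <- simple_main_effects(long, "scheme", method = "parametric")
  expect_lt(spar$p_raw, 0.01)
})

test_that("extreme-outlier screening follows the 3xIQR quartile rule", {
  set.seed(23)
  base <- data.frame(subject = rep(1:9, 2),
                     scheme = rep(c("none", "lag"), each = 9),
                     segment = "seg1",
                     value = rep(seq(-1, 1, length.out = 9), 2))
  sc <- extreme_outlier_screen(base)
  expect_false(any(sc$flag)) # symmetric data, no extremes
  out <- base
  out$value[5] <- 10 # beyond 3xIQR of the contaminated cell quartiles
  q <- quantile(out$value[1:9], c(0.25, 0.75), type = 7)
  expect_gt(out$value[5], q[2] + 3 * (q[2] - q[1]))
  sc2 <- extreme_outlier_screen(out)
  expect_true(sc2$flag[5])
  expect_equal(sum(sc2$flag), 1L)
  # brute-force quantile oracle with the same convention, milder rule
  set.seed(24)
  rnd <- base; rnd$value <- rnorm(18)
  sc3 <- extreme_outlier_screen(rnd, multiplier = 1)
  for (s in c("none", "lag")) {
    idx <- which(rnd$scheme == s)
    qq <- quantile(rnd$value[idx], c(0.25, 0.75), type = 7)
    expect_equal(sc3$flag[idx],
                 rnd$value[idx] < qq[1] - (qq[2] - qq[1]) |
                   rnd$value[idx] > qq[2] + (qq[2] - qq[1]))
  }
})

test_that("sensitivity reruns cover removal and cell-mean replacement", {
  set.seed(25)
  Y <- matrix(rnorm(90, 1, 0.3), 9, 10)
  Y[3, 2] <- 15 # gross extreme value
  long <- rm_long(Y)
  sa <- sensitivity_anova(long, n_perm = 999, seed = 9)
  expect_true(any(sa$flags$flag))
  expect_s3_class(sa$full, "perm_rm_anova")
  expect_s3_class(sa$subjects_removed, "perm_rm_anova")
  expect_s3_class(sa$values_replaced, "perm_rm_anova")
  expect_equal(sa$subjects_removed$design$S, 8)
  # replaced value equals the mean of the other subjects in that cell
  # (rm_design orders factor levels alphabetically, so look up by name)
  repl_design <- sa$values_replaced$design
  expect_equal(repl_design$Y[3, "none:seg2"], mean(Y[-3, 2]),
               tolerance = 1e-12)
})
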