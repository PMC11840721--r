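# independent brute-force oracles --------------------------------------------

# two-sided exact Mann-Whitney p by enumerating every labeling of the
# pooled sample (tie-free); uses the symmetry of U about n1*n2/2
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  cmb <- utils::combn(n, na)
  u_all <- apply(cmb, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  centre <- na * (n - na) / 2
  mean(abs(u_all - centre) >= abs(u_obs - centre) - 1e-9)
}

test_that("median and IQR follow the linear-interpolation quartile rule", {
  m <- median_iqr(c(1, 2, 3, 4, 5))
  expect_equal(m, list(median = 3, q1 = 2, q3 = 4))
  expect_equal(median_iqr(7), list(median = 7, q1 = 7, q3 = 7))
  v <- c(2.3, 9.1, 4.4, 0.7, 5.5, 8.2)
  shifted <- median_iqr(v + 11)
  base <- median_iqr(v)
  expect_equal(shifted$median, base$median + 11)
  expect_equal(shifted$q1, base$q1 + 11)
  expect_equal(shifted$q3, base$q3 + 11)
  expect_error(median_iqr(numeric(0)), "empty")
})

test_that("Mann-Whitney: worked example, symmetry, exact = enumeration", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  expect_identical(r$p_method, "exact")

  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 8)  # n_a * n_b / 2

  set.seed(3)
  for (na in c(2, 3, 4)) {
    x <- rnorm(na); y <- rnorm(7 - na)
    expect_equal(mann_whitney(x, y)$p_value, mw_enum_p(x, y))
  }
  expect_error(mann_whitney(numeric(0), 1:3), "empty group")
  expect_error(mann_whitney(c(1, 1, 2), c(2, 3, 4), mode = "exact"),
               "tie-free")
})

test_that("Kruskal-Wallis: hand-formula example and degenerate cases", {
  k <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(k$statistic, 32 / 7, tolerance = 1e-9)  # 4.571 at 3 d.p.
  expect_equal(round(k$statistic, 3), 4.571)

  ident <- kruskal_wallis(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(ident$statistic, 0, tolerance = 1e-12)

  expect_error(kruskal_wallis(list(1:3)), "fewer than 2 groups")
})

test_that("Kruskal-Wallis exact enumeration agrees with an independent oracle", {
  set.seed(8)
  g <- list(rnorm(2), rnorm(2), rnorm(2))
  ex <- kruskal_wallis(g, exact = TRUE)
  # independent oracle: permute the pooled values over all 6! orderings
  pooled <- unlist(g)
  kstat <- function(v) kruskal.test(list(v[1:2], v[3:4], v[5:6]))$statistic
  h_obs <- kstat(pooled)
  perms <- combinat_perms(pooled)
  h_all <- vapply(perms, kstat, numeric(1))
  expect_equal(ex$p_value, mean(h_all >= h_obs - 1e-9))
  expect_error(kruskal_wallis(list(rnorm(5), rnorm(5)), exact = TRUE),
               "n <= 8")
})

test_that("Dunn-Bonferroni: monotone adjustment, null groups, clipping", {
  set.seed(11)
  g2 <- list(a = rnorm(4), b = rnorm(4) + 2)
  d2 <- dunn_bonferroni(g2)
  expect_gte(d2$p_adjusted["a", "b"], d2$p_raw["a", "b"])

  ident <- dunn_bonferroni(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_true(all(ident$p_adjusted[upper.tri(ident$p_adjusted)] == 1))
  expect_true(all(abs(ident$z[upper.tri(ident$z)]) < 1e-12))

  g4 <- list(rnorm(3), rnorm(3), rnorm(3), rnorm(3))
  d4 <- dunn_bonferroni(g4)
  expect_true(all(d4$p_adjusted[upper.tri(d4$p_adjusted)] <= 1))
  expect_true(all(d4$p_adjusted[upper.tri(d4$p_adjusted)] >=
                    d4$p_raw[upper.tri(d4$p_raw)]))
})

test_that("Spearman: perfect monotone, permutation p, transform invariance", {
  x <- c(1.2, 3.4, 5.1, 7.7, 9.0)
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, -sqrt(x))$rho, -1)

  set.seed(17)
  a <- rnorm(5); b <- rnorm(5)
  mine <- spearman_cor(a, b)
  oracle <- cor.test(a, b, method = "spearman", exact = TRUE)
  expect_equal(mine$rho, unname(oracle$estimate))
  expect_equal(mine$p_value, oracle$p.value)
  expect_identical(mine$p_method, "exact permutation")

  # rho invariant under strictly monotone transforms of either margin
  big <- rnorm(20)
  yy <- rnorm(20)
  expect_equal(spearman_cor(exp(big), yy)$rho, spearman_cor(big, yy)$rho)
  expect_equal(spearman_cor(big, qlogis(plogis(yy)))$rho,
               spearman_cor(big, yy)$rho)

  expect_warning(r0 <- spearman_cor(rep(1, 5), rnorm(5)), "constant")
  expect_true(is.na(r0$rho))
  expect_error(spearman_cor(1:4, 1:5), "length mismatch")
})

test_that("longitudinal delta: subtraction, additivity, missing timepoints", {
  df <- data.frame(subject_id = rep(c("s1", "s2"), each = 3),
                   group = "BLM", day = rep(c(8, 15, 22), 2),
                   uptake = c(2.1, 4.0, 5.3, 1.0, 1.5, 1.8))
  d <- delta_longitudinal(df, "uptake", 8, 22)
  expect_equal(d$delta[d$subject_id == "s1"], 3.2)
  d1 <- delta_longitudinal(df, "uptake", 8, 15)
  d2 <- delta_longitudinal(df, "uptake", 15, 22)
  expect_equal(d$delta, d1$delta + d2$delta)
  expect_equal(delta_longitudinal(
    data.frame(subject_id = "s", group = "g", day = c(8, 22),
               uptake = c(3, 3)), "uptake")$delta, 0)
  expect_error(delta_longitudinal(df[df$day != 22, ], "uptake", 8, 22),
               "missing timepoint")
})

test_that("predictive correlation recovers constructed effect directions", {
  set.seed(29)
  mult <- exp(rnorm(8, 0, 0.25))
  # progressive arm: change proportional to baseline severity
  prog <- data.frame(
    subject_id = rep(paste0("p", 1:8), each = 2), group = "BLM",
    day = rep(c(8, 22), 8),
    uptake = as.vector(rbind(2 * mult, 5 * mult)),
    mld = as.vector(rbind(-600 + 100 * mult, -600 + 250 * mult)))
  # treated arm: regression proportional to baseline severity
  trt <- data.frame(
    subject_id = rep(paste0("t", 1:8), each = 2), group = "treated",
    day = rep(c(8, 22), 8),
    uptake = as.vector(rbind(2 * mult, 1.2 * mult)),
    mld = as.vector(rbind(-600 + 100 * mult, -600 + 40 * mult)))
  res <- predictive_correlation(rbind(prog, trt))
  expect_gt(res$BLM$rho, 0)
  expect_lt(res$treated$rho, 0)

  small <- prog[prog$subject_id %in% c("p1", "p2"), ]
  expect_warning(out <- predictive_correlation(small), "skipped")
  expect_length(out, 0)
})
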