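test_that("SPAD conversion and averaging protocol match the meter calibration", {
  expect_equal(spad_to_lcc(50), 50.476)  # 1.4498*50 - 22.014
  expect_equal(spad_to_lcc(22.014 / 1.4498), 0)
  a <- 13; b <- 29
  expect_equal(spad_to_lcc(a) + spad_to_lcc(b) - spad_to_lcc(0),
               spad_to_lcc(a + b))  # affine identity

  expect_equal(plant_mean_spad(matrix(40, 3, 3)), 40)
  leaves <- rbind(c(30, 30, 30), c(40, 40, 40), c(50, 50, 50))
  expect_equal(plant_mean_spad(leaves), 40)
  set.seed(2)
  r <- matrix(stats::runif(9, 20, 60), 3, 3)
  expect_equal(plant_mean_spad(r), mean(r))  # balanced: grand mean
  expect_error(plant_mean_spad(1:8), "9 finite")
})

test_that("canopy chlorophyll applies the microgram/cm2 to g/m2 factor", {
  expect_equal(canopy_chl(0, 2), 0)
  expect_equal(canopy_chl(41.94, 3), 1.2582)
  season <- generate_season(SceneConfig(rows = 4, cols = 4), n_plots = 4,
                            seed = 29)
  expect_true(all(season$plots$ccc > 0 & season$plots$ccc < 4.2))
})

test_that("Spearman R2 matches brute-force rank correlation, with and without ties", {
  r <- spearman_r2(1:4, c(2, 1, 4, 3))
  expect_equal(r$spearman_rho, 0.6)
  expect_equal(r$r2_spearman, 0.36)
  expect_equal(spearman_r2(1:10, (1:10)^3)$spearman_rho, 1)
  expect_equal(spearman_r2(1:10, -(1:10))$spearman_rho, -1)
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    x <- sample(1:6, n, replace = TRUE)  # heavy ties
    y <- x + stats::rnorm(n, 0, 2)
    got <- spearman_r2(x, y)
    rho_oracle <- stats::cor(rank(x), rank(y), method = "pearson")
    expect_equal(got$spearman_rho, rho_oracle, tolerance = 1e-12)
    expect_equal(got$r2_spearman, rho_oracle^2, tolerance = 1e-12)
    t_oracle <- rho_oracle * sqrt((n - 2) / (1 - rho_oracle^2))
    expect_equal(got$p_value, 2 * stats::pt(-abs(t_oracle), n - 2),
                 tolerance = 1e-10)
  }
  expect_error(spearman_r2(rep(1, 5), 1:5), "zero variance")
})

test_that("paired t-test agrees with the closed-form statistic", {
  expect_equal(paired_ttest(1:5, 1:5), list(t = 0, p_value = 1))
  set.seed(23)
  a <- stats::rnorm(10, 5, 1); b <- stats::rnorm(10, 4, 1)
  got <- paired_ttest(a, b)
  d <- a - b
  t_oracle <- mean(d) / (stats::sd(d) / sqrt(10))
  expect_equal(got$t, t_oracle, tolerance = 1e-12)
  expect_equal(got$p_value, 2 * stats::pt(-abs(t_oracle), 9),
               tolerance = 1e-12)
  shifted <- a + 3 + stats::rnorm(10, 0, 1e-4)
  expect_lt(paired_ttest(shifted, a)$p_value, 1e-10)
  expect_error(paired_ttest(c(1, 2), c(0, 1)), "zero-variance")
})

test_that("z-scores have exact moments and affine invariance", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))  # sample sd is 1
  set.seed(31)
  v <- stats::rnorm(40, 10, 4)
  z <- zscore(v)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore(3 * v - 7), z, tolerance = 1e-12)
  expect_error(zscore(rep(2, 5)), "constant")
})

test_that("linear fits recover exact lines and match the sums-of-squares oracle", {
  x <- seq(0, 5, by = 0.5)
  fit <- fit_linear(x, 2 * x + 1)
  expect_equal(unname(fit$coefficients), c(1, 2), tolerance = 1e-10)
  expect_equal(fit$r2, 1)
  set.seed(3)
  y <- stats::rnorm(length(x))      # independent of x
  fit2 <- fit_linear(x, y)
  expect_lt(fit2$r2, 0.3)
  pred <- fit2$coefficients[1] + fit2$coefficients[2] * x
  r2_oracle <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_equal(fit2$r2, r2_oracle, tolerance = 1e-12)
  expect_equal(predict(fit2, x), unname(pred), tolerance = 1e-12)
  expect_error(fit_linear(rep(1, 5), 1:5), "zero variance")
})

test_that("exponential fits recover parameters and reduce to the log-linear fit", {
  x <- seq(-2, 3, length.out = 30)
  fit <- fit_exponential(x, 2 * exp(0.5 * x))
  expect_equal(unname(fit$coefficients["a"]), 2, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["b"]), 0.5, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)

  flat <- fit_exponential(x, rep(3, 30) * exp(stats::rnorm(30, 0, 1e-8)))
  expect_equal(unname(flat$coefficients["b"]), 0, tolerance = 1e-4)

  # parameter recovery within 5% at n = 60 under 10% multiplicative noise
  set.seed(17)
  x <- stats::runif(60, 0, 4)
  y <- 2 * exp(0.5 * x) * exp(stats::rnorm(60, 0, 0.1))
  noisy <- fit_exponential(x, y)
  expect_lt(abs(noisy$coefficients["a"] - 2) / 2, 0.05)
  expect_lt(abs(noisy$coefficients["b"] - 0.5) / 0.5, 0.05)

  # zero-noise log-linear equivalence
  loglin <- stats::lm(log(2 * exp(0.5 * x)) ~ x)
  noiseless_fit <- fit_exponential(x, 2 * exp(0.5 * x))
  expect_equal(log(unname(noiseless_fit$coefficients["a"])),
               unname(stats::coef(loglin)[1]), tolerance = 1e-6)
  expect_equal(unname(noiseless_fit$coefficients["b"]),
               unname(stats::coef(loglin)[2]), tolerance = 1e-6)
  expect_error(fit_exponential(1:5, c(1, 2, -1, 3, 4)), "positive")
})

test_that("group comparison reports the 4x3x2 grid and the constructed identity", {
  # exact linear VI-CCC link in both groups: all linear R2 equal 1
  scenes <- 12
  ccc <- seq(0.5, 3, length.out = scenes)
  sv <- rbind(
    data.frame(scene = 1:scenes, class = "SL", ccc = ccc,
               ndvi = 0.5 + 0.1 * ccc, tcari = 0.3 - 0.05 * ccc,
               pri = 0.02 + 0.01 * ccc, cire = 1 + 0.5 * ccc),
    data.frame(scene = 1:scenes, class = "SHL", ccc = ccc,
               ndvi = 0.6 + 0.1 * ccc, tcari = 0.2 - 0.05 * ccc,
               pri = 0.05 + 0.01 * ccc, cire = 1.2 + 0.5 * ccc))
  tab <- compare_groups(sv)
  expect_equal(nrow(tab), 4 * 3 * 2)
  lin <- tab[tab$model == "linear", ]
  expect_true(all(abs(lin$r2 - 1) < 1e-10))

  # a group-specific offset: pooling destroys raw R2, z-scoring restores it
  sv2 <- sv
  set.seed(41)
  sv2$tcari <- sv2$tcari + ifelse(sv2$class == "SL", 0.3, 0) +
    stats::rnorm(nrow(sv2), 0, 0.005)
  raw <- compare_groups(sv2, indices = "tcari", normalize = FALSE)
  norm <- compare_groups(sv2, indices = "tcari", normalize = TRUE)
  r2_of <- function(tab, g) tab$r2[tab$group == g & tab$model == "linear"]
  expect_lt(r2_of(raw, "Combined"), min(r2_of(raw, "SL"), r2_of(raw, "SHL")))
  expect_gt(r2_of(norm, "Combined"), r2_of(raw, "Combined"))
  gap_raw <- min(r2_of(raw, "SL"), r2_of(raw, "SHL")) - r2_of(raw, "Combined")
  gap_norm <- min(r2_of(norm, "SL"), r2_of(norm, "SHL")) -
    r2_of(norm, "Combined")
  expect_lt(gap_norm, gap_raw)
  expect_error(compare_groups(sv[sv$class == "SL", ]), "SHL")
})
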