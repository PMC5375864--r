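test_that("spectral angle behaves as an amplitude-blind metric", {
  s <- Spectrum(c(500, 600), c(0.3, 0.6))
  expect_equal(sam(s, s), 0, tolerance = 1e-6)
  expect_equal(sam(s, Spectrum(c(500, 600), c(0.15, 0.3))), 0,
               tolerance = 1e-6)  # 0.5x scale, up to acos rounding
  e1 <- Spectrum(c(500, 600), c(1, 0))
  e2 <- Spectrum(c(500, 600), c(0, 1))
  expect_equal(sam(e1, e2), pi / 2)
  expect_error(sam(e1, Spectrum(c(500, 600), c(0, 0))), "zero")
  set.seed(4)
  for (rep in 1:20) {
    x <- stats::runif(30, 0.01, 1); y <- stats::runif(30, 0.01, 1)
    a <- sam(x, y)
    expect_gte(a, 0); expect_lte(a, pi)
    expect_equal(sam(x * stats::runif(1, 0.1, 9), y), a, tolerance = 1e-10)
  }
})

test_that("spectral information divergence matches hand arithmetic and is symmetric", {
  x <- Spectrum(c(500, 600), c(0.5, 0.5))
  y <- Spectrum(c(500, 600), c(0.25, 0.75))
  hand <- 0.5 * log(4 / 3) + (0.25 * log(0.5) + 0.75 * log(1.5))
  expect_equal(sid(x, y), hand, tolerance = 1e-12)  # ~0.2746
  expect_equal(sid(x, x), 0)
  set.seed(8)
  for (rep in 1:20) {
    a <- stats::runif(25, 0.01, 1); b <- stats::runif(25, 0.01, 1)
    expect_equal(sid(a, b), sid(b, a), tolerance = 1e-12)
    expect_gte(sid(a, b), 0)
    # amplitude-invariant by construction (sum normalisation)
    expect_equal(sid(a * 3, b), sid(a, b), tolerance = 1e-10)
  }
})

test_that("matching assigns the metric-minimising class with fixed tie order", {
  wl <- seq(400, 900, by = 10)
  set.seed(6)
  refs <- lapply(stats::setNames(COMPONENT_CLASSES, COMPONENT_CLASSES),
                 function(cl) Spectrum(wl, stats::runif(length(wl), 0.05, 1)))
  expect_equal(match_classify(refs$SHL, refs, "sam"), "SHL")
  expect_equal(match_classify(refs$SP, refs, "sid"), "SP")
  doubled <- Spectrum(wl, refs$SL$value * 2)
  expect_equal(match_classify(doubled, refs, "sam"), "SL")
  # all references identical: the tie goes to the first class in order
  same <- lapply(refs, function(r) refs$SHP)
  expect_equal(match_classify(refs$SHP, same, "sam"), "SL")
})

test_that("well-separated class models are recovered at >= 95% by SAM on CR spectra", {
  grid <- default_grid()
  mods <- default_component_models("HD", amplitude_sd = 0.05, tilt_sd = 0.03)
  set.seed(42)
  lib_rows <- list(); cls <- character(0)
  for (cl in COMPONENT_CLASSES) {
    for (i in 1:50) {
      lib_rows[[length(lib_rows) + 1L]] <-
        component_spectrum(mods[[cl]], grid)$value
      cls <- c(cls, cl)
    }
  }
  lib <- SpectralLibrary(grid, do.call(rbind, lib_rows), cls,
                         rep("HD", length(cls)))
  acc <- match_classify_library(lib, "sam", "continuum_removed")$accuracy
  expect_gte(acc, 0.95)
})

test_that("class distance tables match a brute-force loop and separate classes", {
  wl <- c(500, 600, 700)
  vals <- rbind(c(0.2, 0.4, 0.6), c(0.2, 0.4, 0.6),
                c(0.6, 0.3, 0.1), c(0.6, 0.3, 0.1))
  lib <- SpectralLibrary(wl, vals, c("SL", "SL", "SP", "SP"),
                         rep("HD", 4))
  tab <- class_distance_table(lib, "sam", "reflectance")
  expect_equal(diag(tab), c(SL = 0, SP = 0), tolerance = 1e-6)
  expect_true(all(tab[row(tab) != col(tab)] > 0))

  set.seed(19)
  vals2 <- matrix(stats::runif(6 * 3, 0.05, 1), 6, 3)
  lib2 <- SpectralLibrary(wl, vals2, c("SL", "SL", "SHL", "SHL", "SP", "SP"),
                          rep("HD", 6))
  tab2 <- class_distance_table(lib2, "sid", "reflectance")
  for (ci in rownames(tab2)) for (cj in colnames(tab2)) {
    ref <- class_mean_spectrum(lib2, cj)
    rows <- which(lib2$class == ci)
    expect_equal(tab2[ci, cj],
                 mean(vapply(rows, function(r)
                   sid(library_spectrum(lib2, r), ref), numeric(1))),
                 tolerance = 1e-12)
  }
  # single spectrum per class: entry (i, j) is the plain pairwise metric
  lib3 <- SpectralLibrary(wl, vals2[c(1, 3), ], c("SL", "SP"),
                          rep("HD", 2))
  tab3 <- class_distance_table(lib3, "sam", "reflectance")
  expect_equal(tab3["SL", "SP"],
               sam(library_spectrum(lib3, 1), library_spectrum(lib3, 2)))
})

test_that("threshold derivation takes midpoints of season-averaged class means", {
  vi <- expand.grid(class = COMPONENT_CLASSES, stage = c("HD", "FL"),
                    rep = 1:3, stringsAsFactors = FALSE)
  base_pri <- c(SL = 0.10, SHL = 0.10, SP = -0.02, SHP = -0.02)
  base_tcari <- c(SL = 0.30, SHL = 0.10, SP = 0.08, SHP = 0.02)
  vi$pri <- base_pri[vi$class]
  vi$tcari <- base_tcari[vi$class]
  th <- derive_thresholds(vi)
  expect_equal(th$pri_split, (0.10 + -0.02) / 2)      # = 0.04
  expect_equal(th$tcari_leaf_split, (0.30 + 0.10) / 2)  # = 0.20
  expect_equal(th$tcari_panicle_split, (0.08 + 0.02) / 2)

  # stage weighting: an unbalanced stage must not dominate the class mean
  vi2 <- data.frame(class = rep(COMPONENT_CLASSES, each = 4),
                    stage = rep(c("HD", "HD", "HD", "FL"), 4),
                    pri = 0, tcari = 0)
  vi2$pri[vi2$class == "SL"] <- c(0.2, 0.2, 0.2, 0.4)
  vi2$pri[vi2$class == "SHL"] <- c(0.2, 0.2, 0.2, 0.4)
  th2 <- derive_thresholds(vi2)
  # stage means: HD 0.2, FL 0.4 -> class mean 0.3 (not the pooled 0.25)
  expect_equal(th2$pri_split, (0.3 + 0) / 2)
  th2p <- derive_thresholds(vi2, stage_weighting = "pooled")
  expect_equal(th2p$pri_split, (0.25 + 0) / 2)

  expect_error(derive_thresholds(vi[vi$class != "SP", ]), "SP")
  # identical class means: splits collapse to that mean (legal degenerate)
  vi3 <- vi; vi3$pri <- 0.1; vi3$tcari <- 0.2
  th3 <- derive_thresholds(vi3)
  expect_equal(th3$pri_split, 0.1)
  expect_equal(th3$tcari_leaf_split, 0.2)
})

test_that("the decision tree follows its truth table with ties to leaf/sunlit", {
  th <- structure(list(pri_split = 0.04, tcari_leaf_split = 0.2,
                       tcari_panicle_split = 0.05), class = "Thresholds")
  expect_equal(decision_tree_classify(0.10, 0.30, th), "SL")
  expect_equal(decision_tree_classify(0.10, 0.10, th), "SHL")
  expect_equal(decision_tree_classify(0.00, 0.08, th), "SP")
  expect_equal(decision_tree_classify(0.00, 0.01, th), "SHP")
  # boundary equality goes to the leaf branch, then the sunlit branch
  expect_equal(decision_tree_classify(0.04, 0.2, th), "SL")
  expect_equal(decision_tree_classify(0.04, 0.199, th), "SHL")
  expect_equal(decision_tree_classify(0.0399, 0.05, th), "SP")
})

test_that("image classification equals the per-pixel loop and honours the mask", {
  sc <- generate_scene(SceneConfig(rows = 10, cols = 10, stage = "HD",
                                   seed = 3))
  season <- list(scenes = list(c(sc, list(stage = "HD", plot_id = 1))))
  lib <- roi_library(list(list(cube = sc$cube, labels = sc$labels,
                               stage = "HD")), n_per_class = 15, seed = 3)
  th <- derive_thresholds(library_vi_table(lib))
  mask <- evi_mask(sc$cube)
  out <- classify_image(sc$cube, th, mask)
  nm <- label_names(out)
  pmap <- vi_image(sc$cube, "pri")
  tmap <- vi_image(sc$cube, "tcari")
  for (r in 1:10) for (co in 1:10) {
    expected <- if (!mask[r, co]) "NONVEG"
                else decision_tree_classify(pmap[r, co], tmap[r, co], th)
    expect_identical(nm[r, co], expected)
  }
  all_masked <- classify_image(sc$cube, th, matrix(FALSE, 10, 10))
  expect_true(all(label_names(all_masked) == "NONVEG"))
})

test_that("cross-validation is perfect on separated classes and deterministic", {
  vi <- expand.grid(class = COMPONENT_CLASSES, stage = c("HD", "FL"),
                    rep = 1:10, stringsAsFactors = FALSE)
  base_pri <- c(SL = 0.10, SHL = 0.12, SP = -0.02, SHP = -0.03)
  base_tcari <- c(SL = 0.30, SHL = 0.10, SP = 0.08, SHP = 0.02)
  set.seed(55)
  vi$pri <- base_pri[vi$class] + stats::rnorm(nrow(vi), 0, 0.002)
  vi$tcari <- base_tcari[vi$class] + stats::rnorm(nrow(vi), 0, 0.002)
  cv <- cross_validate(vi, folds = 10, seed = 2)
  expect_equal(cv$accuracy, 1.0)
  expect_equal(sum(cv$confusion), nrow(vi))
  cv2 <- cross_validate(vi, folds = 10, seed = 2)
  expect_identical(cv$confusion, cv2$confusion)
  expect_error(cross_validate(vi[1:20, ], folds = 10), "stratification")
})

test_that("cross-validation on permuted labels collapses to the chance rate", {
  set.seed(99)
  n_per <- 100
  vi <- data.frame(class = rep(COMPONENT_CLASSES, each = n_per),
                   stage = "HD",
                   pri = stats::rnorm(4 * n_per, 0.05, 0.03),
                   tcari = stats::rnorm(4 * n_per, 0.15, 0.05))
  vi$class <- sample(vi$class)  # sever any label-feature link
  cv <- cross_validate(vi, folds = 10, seed = 3)
  n <- nrow(vi)
  expect_lt(abs(cv$accuracy - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("sunlit/shaded pixel ratio counts leaves only", {
  lab <- LabelMap(matrix(c(rep(1L, 10), rep(2L, 20), rep(5L, 6)), 6, 6),
                  c(SL = 1L, SHL = 2L, NONVEG = 5L))
  expect_equal(sunlit_shaded_ratio(lab), 0.5)
  no_shl <- LabelMap(matrix(1L, 2, 2), c(SL = 1L, SHL = 2L))
  expect_true(is.na(sunlit_shaded_ratio(no_shl)))
  # invariant to background pixels
  lab2 <- LabelMap(matrix(c(rep(1L, 10), rep(2L, 20), rep(5L, 70)), 10, 10),
                   c(SL = 1L, SHL = 2L, NONVEG = 5L))
  expect_equal(sunlit_shaded_ratio(lab2), 0.5)
})
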