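test_that("feature vectors have the frozen 32-element layout", {
  fv <- extract_features(random_cddm())
  expect_length(fv, 32)
  expect_true(all(is.finite(fv)))
  expect_equal(names(fv)[1:4],
               c("Q1_mag_mean", "Q1_mag_variance", "Q1_mag_kurtosis",
                 "Q1_mag_skewness"))
  expect_equal(names(fv)[29:32],
               c("Q4_ang_mean", "Q4_ang_variance", "Q4_ang_kurtosis",
                 "Q4_ang_skewness"))
  # any even-shaped map works; odd shapes fail at construction already
  expect_length(extract_features(random_cddm(4, 6)), 32)
})

test_that("quadrant moments match the brute-force oracle", {
  # 2x2 quadrants (0,0,1,1): mean .5, variance .25, kurtosis 1, skewness 0
  m <- cddm(matrix(c(0, 0, 1, 1,
                     1, 1, 1, 1,
                     1, 1, 1, 1,
                     1, 1, 1, 1), 4, 4, byrow = TRUE),
            matrix(0.3, 4, 4))
  fv <- extract_features(m)
  expect_equal(unname(fv["Q1_mag_mean"]), 0.5)
  expect_equal(unname(fv["Q1_mag_variance"]), 0.25)
  expect_equal(unname(fv["Q1_mag_kurtosis"]), 1)
  expect_equal(unname(fv["Q1_mag_skewness"]), 0)
  # constant channel convention: (mean, var, kurt, skew) = (value, 0, 0, 0)
  expect_equal(unname(fv[c("Q2_mag_mean", "Q2_mag_variance",
                           "Q2_mag_kurtosis", "Q2_mag_skewness")]),
               c(1, 0, 0, 0))
  expect_equal(unname(fv[c("Q1_ang_mean", "Q1_ang_variance")]), c(0.3, 0))

  # random quadrants against direct moment formulas
  set.seed(83)
  for (i in 1:10) {
    mm <- random_cddm()
    q <- split_quadrants(mm)
    fv <- extract_features(mm)
    om <- oracle_moments(as.vector(q$Q3$magnitude))
    expect_equal(unname(fv[c("Q3_mag_mean", "Q3_mag_variance",
                             "Q3_mag_kurtosis", "Q3_mag_skewness")]),
                 om, tolerance = 1e-12)
    oa <- oracle_moments(as.vector(q$Q2$angle))
    expect_equal(unname(fv[c("Q2_ang_mean", "Q2_ang_variance",
                             "Q2_ang_kurtosis", "Q2_ang_skewness")]),
                 oa, tolerance = 1e-12)
  }
})

test_that("normalization affects only magnitude mean/variance predictably", {
  set.seed(89)
  raw <- matrix(runif(100, 0, 7), 10, 10)
  ang <- matrix(runif(100, -3, 3), 10, 10)
  a <- cddm(raw, ang)                      # normalized by max
  b <- cddm(raw / max(raw), ang, normalize = FALSE)
  expect_equal(extract_features(a), extract_features(b))
  # scaling is affine with zero offset: skewness and kurtosis of each
  # magnitude channel are scale-free
  s <- max(raw)
  fn <- extract_features(a)
  fu <- local({
    q <- split_quadrants(a)
    unlist(lapply(q, function(x) oracle_moments(as.vector(x$magnitude * s))))
  })
  for (qi in 1:4) {
    expect_equal(unname(fn[(qi - 1) * 8 + 3]), unname(fu[(qi - 1) * 4 + 3]),
                 tolerance = 1e-10)  # kurtosis
    expect_equal(unname(fn[(qi - 1) * 8 + 4]), unname(fu[(qi - 1) * 4 + 4]),
                 tolerance = 1e-10)  # skewness
    expect_equal(unname(fn[(qi - 1) * 8 + 1]) * s,
                 unname(fu[(qi - 1) * 4 + 1]), tolerance = 1e-10)  # mean
    expect_equal(unname(fn[(qi - 1) * 8 + 2]) * s^2,
                 unname(fu[(qi - 1) * 4 + 2]), tolerance = 1e-8)   # variance
  }
})

test_that("distances match direct evaluation and reject bad input", {
  x <- c(1, 2, 3); y <- c(2, 4, 0)
  expect_equal(feature_distance(x, y, "cityblock"), 6)
  expect_equal(feature_distance(x, y, "chebyshev"), 3)
  expect_equal(feature_distance(x, y, "euclidean"), sqrt(14))
  expect_equal(feature_distance(x, x, "cityblock"), 0)
  expect_equal(feature_distance(x, x, "euclidean"), 0)
  expect_equal(feature_distance(x, x, "chebyshev"), 0)
  # metric aliases normalize
  expect_equal(feature_distance(x, y, "Manhattan"), 6)
  expect_equal(feature_distance(x, y, "Eucledian"), sqrt(14))
  expect_equal(feature_distance(x, y, "Chebychev"), 3)
  expect_error(feature_distance(x, y, "hamming"), "unknown metric")
  expect_error(feature_distance(x, c(1, 2), "cityblock"), "mismatch")
  set.seed(97)
  for (i in 1:30) {
    n <- sample(2:64, 1)
    u <- rnorm(n); v <- rnorm(n)
    for (mt in c("cityblock", "euclidean", "chebyshev"))
      expect_equal(feature_distance(u, v, mt), oracle_distance(u, v, mt),
                   tolerance = 1e-12)
    # permutation symmetry
    p <- sample(n)
    for (mt in c("cityblock", "euclidean", "chebyshev"))
      expect_equal(feature_distance(u[p], v[p], mt),
                   feature_distance(u, v, mt), tolerance = 1e-12)
  }
})

test_that("metric ordering, symmetry and triangle inequality hold", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(2:40, 1)
    a <- rnorm(n); b <- rnorm(n); c <- rnorm(n)
    dch <- feature_distance(a, b, "chebyshev")
    deu <- feature_distance(a, b, "euclidean")
    dcb <- feature_distance(a, b, "cityblock")
    expect_lte(dch, deu + 1e-12)
    expect_lte(deu, dcb + 1e-12)
    for (mt in c("cityblock", "euclidean", "chebyshev")) {
      expect_gte(feature_distance(a, b, mt), 0)
      expect_equal(feature_distance(a, b, mt), feature_distance(b, a, mt))
      expect_lte(feature_distance(a, c, mt),
                 feature_distance(a, b, mt) + feature_distance(b, c, mt) +
                   1e-12)
    }
  }
})

test_that("knn_vote agrees with the brute-force oracle", {
  set.seed(103)
  for (mt in c("cityblock", "euclidean", "chebyshev")) {
    for (i in 1:30) {
      n <- sample(6:30, 1)
      train <- matrix(rnorm(n * 5), n, 5)
      labels <- sample(c("A", "B"), n, replace = TRUE)
      if (length(unique(labels)) < 2) labels[1:2] <- c("A", "B")
      q <- rnorm(5)
      for (k in c(1, 3, 5)) {
        expect_equal(knn_vote(q, train, labels, k, mt),
                     oracle_knn(q, train, labels, k, mt))
      }
    }
  }
})

test_that("knn_vote rules: k=1 recovery, majority, even-k tie, validation", {
  train <- rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3))
  labels <- c("A", "A", "B", "B")
  # query at a training point with k=1 returns that point's label
  expect_equal(knn_vote(c(2, 2), train, labels, 1, "euclidean"), "B")
  # majority among (A, A, B) in distance order
  expect_equal(knn_vote(c(0.4, 0.4), train, labels, 3, "euclidean"), "A")
  # even k split resolves to the single nearest neighbor
  expect_equal(knn_vote(c(1.4, 1.4), train, labels, 2, "euclidean"), "A")
  expect_equal(knn_vote(c(1.6, 1.6), train, labels, 2, "euclidean"), "B")
  expect_error(knn_vote(c(0, 0), train, labels, 5, "euclidean"), "k must be")
  expect_error(knn_vote(c(0, 0), train, c("A", "B", "C", "A"), 1,
                        "euclidean"), "binary")
})

test_that("the packaged pair registry reproduces the published parameters", {
  reg <- pair_registry()
  p <- lookup_pair_params("CAD2", "LVH3", reg)
  expect_equal(p$metric, "cityblock"); expect_equal(p$k, 3L)
  p <- lookup_pair_params("CAD1", "CAD2", reg)
  expect_equal(p$metric, "chebyshev"); expect_equal(p$k, 7L)
  p <- lookup_pair_params("CAD1", "NORM2", reg)
  expect_equal(p$metric, "euclidean"); expect_equal(p$k, 5L)
  # symmetric lookup
  expect_equal(lookup_pair_params("LVH3", "CAD2", reg)[c("metric", "k")],
               lookup_pair_params("CAD2", "LVH3", reg)[c("metric", "k")])
  # unlisted pairs fall back to the default row
  p <- lookup_pair_params("CAD5", "NORM1", reg)
  expect_equal(p$metric, "cityblock"); expect_equal(p$k, 1L)
  # alias-based lookup works
  p <- lookup_pair_params("IHD2", "DIFFf", reg)
  expect_equal(p$metric, "cityblock"); expect_equal(p$k, 10L)
  expect_error(lookup_pair_params("CAD1", "CAD1", reg), "distinct")
})

test_that("classify_pair runs the duel on reference features", {
  co <- tiny_cohort(n_per = 4, seed = 107L)
  # query identical to a reference map with k = 1 returns its own label
  q <- co$maps[[co$groups$LVH1[1]]]
  expect_equal(classify_pair(q, co, c("LVH1", "MDAM"),
                             params = list(metric = "cityblock", k = 1L)),
               "LVH1")
  # low-noise query of a class wins its own pair duel
  cfg <- generator_config(magnitude_noise_sd = 0.02, angle_noise_sd = 0.05,
                          per_group_count = 1, seed = 109L, separation = 1)
  set.seed(110)
  q2 <- sample_map(default_templates(1)$LVH1, cfg, map_id = "p")
  ref <- tiny_cohort(n_per = 5, separation = 1, mag_noise = 0.03,
                     ang_noise = 0.1, seed = 111L)
  expect_equal(classify_pair(q2, ref, c("LVH1", "MDAM")), "LVH1")
  # oracle equivalence on synthetic queries, k = 3
  co2 <- tiny_cohort(n_per = 6, seed = 113L, separation = 0.6,
                     mag_noise = 0.1, ang_noise = 0.5)
  ids <- unlist(co2$groups[c("CAD2", "LVH3")], use.names = FALSE)
  train <- t(vapply(co2$maps[ids], extract_features, numeric(32)))
  tl <- vapply(co2$maps[ids], function(m) m$label, "")
  set.seed(115)
  for (i in 1:50) {
    tpl <- default_templates(0.6)[[sample(c("CAD2", "LVH3"), 1)]]
    cfg2 <- generator_config(per_group_count = 1, seed = 1L)
    q3 <- sample_map(tpl, cfg2, map_id = "x")
    got <- classify_pair(q3, co2, c("CAD2", "LVH3"),
                         params = list(metric = "cityblock", k = 3L))
    expect_equal(got, oracle_knn(extract_features(q3), train, tl, 3,
                                 "cityblock"))
  }
  expect_error(classify_pair(q, co, c("LVH1", "MDAM"),
                             params = list(metric = "cityblock", k = 99L)),
               "insufficient")
})
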