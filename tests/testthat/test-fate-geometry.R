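test_that("normalization divides by the maximum and rejects bad input", {
  n <- normalize_triple(70.3, 50, 50)
  expect_equal(unlist(n), c(x = 1, a = 50 / 70.3, b = 50 / 70.3))
  expect_equal(unlist(normalize_triple(100, 100, 100)), c(x = 1, a = 1, b = 1))
  n2 <- normalize_triple(76.5, 70.3, 200)
  expect_equal(unlist(n2), c(x = 0.3825, a = 0.3515, b = 1))
  expect_error(normalize_triple(0, 0, 0), "unclassifiable")
  expect_error(normalize_triple(-1, 2, 3), "nonnegative")
})

test_that("feature-plane transform is duplicate-order invariant", {
  p <- to_feature_point(1, 0.71124, 0.71124)
  expect_equal(unlist(p), c(u = 0.28876, v = 0.28876))
  p2 <- to_feature_point(0.3825, 0.3515, 1)
  expect_equal(unlist(p2), c(u = -0.6175, v = 0.031))
  expect_equal(to_feature_point(1, 1, 1), tibble::tibble(u = 0, v = 0))
  expect_identical(to_feature_point(0.4, 0.2, 0.9),
                   to_feature_point(0.4, 0.9, 0.2))
})

test_that("point-to-segment distance handles foot-inside and endpoint cases", {
  segs <- fate_segments()
  sf <- segs[segs$fate == "SF", ]
  nf <- segs[segs$fate == "NF", ]
  # frozen values from a dense-sampling oracle (1e5 points per segment)
  expect_equal(point_segment_distance(0.28876, 0.28876,
                                      sf$u0, sf$v0, sf$u1, sf$v1),
               0.298738, tolerance = 1e-5)
  expect_equal(point_segment_distance(0.28876, 0.28876,
                                      nf$u0, nf$v0, nf$u1, nf$v1),
               0.839955, tolerance = 1e-5)
  # endpoint lies on the segment
  expect_equal(point_segment_distance(0.5, 0.5, sf$u0, sf$v0, sf$u1, sf$v1),
               0)
  # foot of perpendicular inside: distance to the line u + v = 1
  expect_equal(point_segment_distance(0.25, 0.65, sf$u0, sf$v0, sf$u1, sf$v1),
               abs(0.25 + 0.65 - 1) / sqrt(2))
  # foot outside: distance to the nearer endpoint (0, 1)
  expect_equal(point_segment_distance(-0.2, 0.9, sf$u0, sf$v0, sf$u1, sf$v1),
               sqrt(0.2^2 + 0.1^2))
})

test_that("the two in-text worked examples are reproduced", {
  c1 <- classify_fate(70.3, 50, 50)
  expect_equal(round(c1$p_sf, 2), 0.48)
  expect_identical(c1$label, "SF")
  c2 <- classify_fate(76.5, 70.3, 200)
  expect_equal(round(c2$p_nf, 2), 0.91)
  expect_identical(c2$label, "NF")
})

test_that("points on a pure-fate segment get probability one for that fate", {
  expect_equal(classify_fate(100, 50, 50)$p_sf, 1)   # (0.5, 0.5) on SF
  expect_equal(classify_fate(100, 100, 200)$p_nf, 1) # (-0.5, 0) on NF
  expect_equal(classify_fate(7, 7, 7)$p_cf, 1)       # (0, 0) on CF
  # generated pure rules, random parameters
  withr::with_seed(7, {
    s <- runif(50, 10, 400)
    p <- runif(50)
    m <- runif(50, 2, 6)
    sf <- classify_fate(s, p * s, (1 - p) * s)
    expect_true(all(sf$p_sf > 1 - 1e-9))
    cf <- classify_fate(s, s, s)
    expect_true(all(cf$p_cf == 1))
    nf <- classify_fate(s, s, m * s)
    expect_true(all(nf$p_nf > 1 - 1e-9))
  })
})

test_that("probabilities normalize, and the classifier is symmetric and scale-free", {
  tr <- random_triples(2000, seed = 42)
  res <- classify_fates(tr)
  expect_true(all(abs(res$p_sf + res$p_cf + res$p_nf - 1) < 1e-12))
  # trapezoid invariant
  expect_true(all(res$u >= -1 - 1e-12 & res$u <= res$v & res$v <= 1 + 1e-12))
  # swap symmetry is exact
  swapped <- classify_fate(tr$x, tr$b, tr$a)
  expect_identical(res$p_sf, swapped$p_sf)
  expect_identical(res$p_cf, swapped$p_cf)
  expect_identical(res$p_nf, swapped$p_nf)
  # scale invariance up to round-off in the normalization
  k <- withr::with_seed(1, runif(2000, 0.01, 100))
  scaled <- classify_fate(k * tr$x, k * tr$a, k * tr$b)
  expect_equal(res$p_sf, scaled$p_sf, tolerance = 1e-12)
  expect_equal(res$p_nf, scaled$p_nf, tolerance = 1e-12)
})

test_that("corner flags and NA propagation behave as documented", {
  # complete expression loss: (x, a, b) = (1, eps, eps) maps near (1, 1)
  expect_true(classify_fate(100, 1, 1)$near_corner)
  # complete gain: (x, x, x) is (0, 0); far from both corners
  expect_false(classify_fate(100, 100, 100)$near_corner)
  expect_true(classify_fate(1, 40, 40)$near_corner) # near (-1, -1)
  r <- classify_fate(c(10, 0), c(5, 0), c(5, 0), on_zero = "na")
  expect_false(r$unclassifiable[1])
  expect_true(r$unclassifiable[2])
  expect_true(is.na(r$label[2]))
  expect_error(classify_fate(0, 0, 0), "unclassifiable")
})
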