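# geometric primitives, distance set, the 29 features, regional subsets

test_that("angle_deg follows the inclination-from-horizontal convention", {
  expect_equal(angle_deg(c(0, 0), c(5, 0)), 0)
  expect_equal(abs(angle_deg(c(0, 0), c(0, 5))), 90)
  expect_equal(angle_deg(c(0, 0), c(1, 1)), 45)
  # endpoint order must not matter for a segment's inclination
  set.seed(3)
  for (i in 1:20) {
    a <- stats::runif(2, -10, 10); b <- stats::runif(2, -10, 10)
    expect_equal(angle_deg(a, b), angle_deg(b, a), tolerance = 1e-12)
  }
  expect_error(angle_deg(c(1, 2), c(1, 2)), "degenerate")
})

test_that("slope is the literal difference quotient", {
  expect_equal(slope(c(0, 0), c(2, 1)), 0.5)
  expect_equal(slope(c(0, 3), c(4, 3)), 0)
  set.seed(4)
  for (i in 1:20) {
    a <- stats::runif(2); b <- stats::runif(2)
    expect_equal(slope(a, b), (a[2] - b[2]) / (a[1] - b[1]))
  }
  expect_error(slope(c(1, 0), c(1, 5)), "vertical")
})

test_that("euclid and perimeter match their oracles", {
  expect_equal(euclid(c(0, 0), c(3, 4)), 5)
  expect_equal(euclid(c(2, 2), c(2, 2)), 0)
  expect_equal(euclid(c(1, 9), c(-4, 2)), euclid(c(-4, 2), c(1, 9)))

  expect_equal(perimeter(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 4)
  tri <- rbind(c(0, 0), c(2, 0), c(1, sqrt(3)))
  expect_equal(perimeter(tri), 6)
  expect_error(perimeter(rbind(c(0, 0), c(1, 1))), "3 points")
  set.seed(6)
  for (i in 1:20) {
    poly <- matrix(stats::runif(2 * sample(3:9, 1), -5, 5), ncol = 2)
    expect_equal(perimeter(poly), oracle_perimeter(poly), tolerance = 1e-12)
  }
})

test_that("distance set has 28 distances + 2 averages and mirrors pair up", {
  ds <- compute_distances(make_template())
  expect_length(unclass(ds), 30L)
  expect_length(attr(ds, "perimeters"), 2L)
  pairs <- list(c("Bl", "Br"), c("D", "E"), c("H", "I"), c("Nl", "Nr"),
                c("Ol", "Or"), c("Pl", "Ql"), c("Pu", "Qu"), c("Vl", "Vr"),
                c("R", "S"), c("T", "U"), c("F", "G"), c("J", "K"),
                c("L", "M"))
  for (p in pairs) expect_equal(ds[[p[1]]], ds[[p[2]]],
                                info = paste(p, collapse = "="))
  per <- attr(ds, "perimeters")
  expect_equal(per[["Wl"]], per[["Wr"]])
  expect_true(all(unclass(ds) >= 0))
  expect_gt(ds[["A"]], 0); expect_gt(ds[["W"]], 0)
})

test_that("uniform scaling doubles every distance", {
  set.seed(8)
  lm <- tilt_correct(random_landmarks(sd = 2))
  lm2 <- landmarks51(lm$points * 2, tilt_corrected = TRUE)
  d1 <- compute_distances(lm)
  d2 <- compute_distances(lm2)
  expect_equal(as.numeric(d2), 2 * as.numeric(d1), tolerance = 1e-9)
  expect_identical(names(unclass(d2)), names(unclass(d1)))
  expect_equal(attr(compute_distances(lm2), "perimeters"),
               2 * attr(compute_distances(lm), "perimeters"),
               tolerance = 1e-9)
})

test_that("distances demand tilt correction and complete definitions", {
  lm <- random_landmarks(sd = 1)
  expect_error(compute_distances(lm), "tilt")
  expect_silent(compute_distances(lm, require_tilt = FALSE))
  defs <- distance_definitions()
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  utils::write.csv(defs[defs$name != "A", c("name", "kind", "points")],
                   f, row.names = FALSE)
  expect_error(distance_definitions(path = f), "lacks entries")
})

test_that("the symmetric template is the feature fixed point", {
  fv <- extract_features(make_template())
  expect_length(fv, 29L)
  expect_equal(unname(unclass(fv)[PAIRED_MAX]), rep(1, length(PAIRED_MAX)))
  expect_equal(unname(unclass(fv)[HORIZONTAL_ANGLES]),
               rep(0, length(HORIZONTAL_ANGLES)))
  expect_equal(unname(unclass(fv)[SLOPES]), rep(0, 3))
  expect_equal(fv[["f23"]], 90)
  # the left/right arguments of the normalized Max features coincide
  ds <- compute_distances(make_template())
  expect_equal(ds[["Vl"]], ds[["Vr"]])
  per <- attr(ds, "perimeters")
  expect_equal(per[["Wl"]], per[["Wr"]])
  # recomputation after tilt correction reproduces it bit-for-bit
  fv2 <- extract_features(tilt_correct(make_template()))
  expect_identical(as.numeric(fv), as.numeric(fv2))
})

test_that("a drooping left mouth corner registers in the mouth features", {
  t <- make_template()
  lm <- t
  p <- lm$points
  p[29, 2] <- p[29, 2] + 8   # P28 down 8 px
  drooped <- landmarks51(p)
  fv <- extract_features(drooped)
  expect_gt(fv[["f14"]], 0)
  expect_gt(max(unclass(fv)[paste0("f", 15:21)] -
                  unclass(extract_features(t))[paste0("f", 15:21)]), 0)
})

test_that("features are invariant to translation and uniform scale", {
  set.seed(9)
  for (i in 1:10) {
    lm <- random_landmarks(sd = 2)
    f0 <- as.numeric(extract_features(lm))
    s <- stats::runif(1, 0.2, 5)
    off <- stats::runif(2, -300, 300)
    lm2 <- landmarks51(sweep(lm$points * s, 2, -off))
    expect_equal(as.numeric(extract_features(lm2)), f0, tolerance = 1e-9)
  }
})

test_that("paired Max features are >= 1, equal 1 iff arguments agree", {
  set.seed(10)
  for (i in 1:50) {
    fv <- extract_features(random_landmarks(sd = 3))
    expect_true(all(unclass(fv)[PAIRED_MAX] >= 1))
    expect_true(all(unclass(fv)[HORIZONTAL_ANGLES] >= 0 &
                      unclass(fv)[HORIZONTAL_ANGLES] <= 180))
  }
  expect_equal(extract_features(make_template())[["f8"]], 1)
})

test_that("mirroring with relabelling preserves the feature set", {
  t <- make_template()
  d <- apply_palsy(t, palsy_perturbation("left", brow = 6, eye = 5,
                                         mouth = 10))
  fl <- unclass(extract_features(d))
  fm <- unclass(extract_features(mirror_landmarks(d)))
  keep <- setdiff(seq_len(29), c(SLOPES, 13, 14))  # drop f4-f6, f12, f13
  expect_equal(fm[keep], fl[keep], tolerance = 1e-9)
  expect_equal(fm[SLOPES], -fl[SLOPES], tolerance = 1e-9)   # slopes negate
  expect_equal(unname(fm[13:14]), unname(fl[14:13]),
               tolerance = 1e-9)                             # f12/f13 swap
})

test_that("optimized features equal the literal transliteration oracle", {
  set.seed(12)
  for (i in 1:100) {
    lm <- tilt_correct(random_landmarks(sd = 3))
    fv <- as.numeric(compute_features(compute_distances(lm), lm))
    expect_equal(fv, unname(oracle_features(lm$points)), tolerance = 1e-12)
  }
})

test_that("regional subsets project 29/19/15 features in order", {
  fv <- extract_features(random_landmarks(sd = 1))
  expect_length(select_region(fv, "face"), 29L)
  eyes <- select_region(fv, "eyes")
  mouth <- select_region(fv, "mouth")
  expect_length(eyes, 19L)
  expect_length(mouth, 15L)
  expect_named(eyes, paste0("f", c(0:13, 22, 23, 25, 26, 27)))
  expect_named(mouth, paste0("f", c(14:22, 23:28)))
  expect_error(select_region(fv, "nose"), "arg")
  # matrix projection agrees
  m <- matrix(unclass(fv), 1, dimnames = list(NULL, names(fv)))
  expect_identical(as.numeric(select_region(m, "eyes")),
                   as.numeric(eyes))
})

test_that("degenerate geometry is reported, not silently clamped", {
  pts <- make_template()$points
  pts[11, ] <- pts[20, ] <- c(0, 0)  # P10 == P19 -> A == 0
  expect_error(extract_features(landmarks51(pts)), "degenerate")
})
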