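test_that("polar radius implements rounded Euclidean distance", {
  expect_identical(polar_radius(0, 0, c(0, 0)), 0L)
  expect_identical(polar_radius(3, 4, c(0, 0)), 5L)
  expect_identical(polar_radius(2, 1, c(0, 0)), 2L) # sqrt(5) ~ 2.236
  # half-away-from-zero at the .5 boundary: distance 2.5 -> 3
  expect_identical(polar_radius(2.5, 0, c(0, 0)), 3L)
  expect_identical(polar_radius(c(0, 3, 2), c(0, 4, 1), c(0, 0)),
                   c(0L, 5L, 2L))
})

test_that("radial profiles of delta rings step where the ring sits", {
  size <- 101L
  ctr <- 50
  x <- matrix(rep(0:(size - 1L), each = size), size, size)
  y <- matrix(rep(0:(size - 1L), times = size), size, size)
  r <- sqrt((x - ctr)^2 + (y - ctr)^2)

  # all intensity in the r = 0 bin
  img0 <- matrix(0, size, size); img0[ctr + 1, ctr + 1] <- 100
  pr0 <- radial_profile(img0, c(ctr, ctr), 40)
  expect_equal(pr0$cumulative[1], 1)

  # single uniform ring at r = 10: cumulative steps 0 -> 1 there
  img1 <- 700 * (round(r) == 10)
  pr1 <- radial_profile(img1, c(ctr, ctr), 40)
  expect_equal(pr1$cumulative[10], 0) # radius 9
  expect_equal(pr1$cumulative[11], 1) # radius 10
  expect_true(all(diff(pr1$cumulative) >= 0))
  expect_equal(pr1$cumulative[41], 1)

  # two equal-brightness rings at r = 5 and 15: per-pixel mean normalisation
  # cancels circumference, cumulative is exactly 0.5 between them
  img2 <- 700 * (round(r) == 5) + 700 * (round(r) == 15)
  pr2 <- radial_profile(img2, c(ctr, ctr), 40)
  expect_equal(pr2$cumulative[7], 0.5)  # r = 6
  expect_equal(pr2$cumulative[15], 0.5) # r = 14
  expect_equal(pr2$cumulative[16], 1)   # r = 15

  expect_warning(pr_zero <- radial_profile(matrix(0, 32, 32), c(15, 15), 10),
                 "all-zero")
  expect_true(pr_zero$zero_signal)
  expect_true(all(pr_zero$cumulative == 0))
})

test_that("radial_profile matches the naive per-pixel double loop bit-for-bit", {
  naive_profile <- function(proj, com, r_max) {
    sums <- numeric(r_max + 1); cnts <- numeric(r_max + 1)
    for (i in seq_len(nrow(proj))) for (j in seq_len(ncol(proj))) {
      r <- floor(sqrt((j - 1 - com[1])^2 + (i - 1 - com[2])^2) + 0.5)
      if (r <= r_max) {
        sums[r + 1] <- sums[r + 1] + proj[i, j]
        cnts[r + 1] <- cnts[r + 1] + 1
      }
    }
    means <- ifelse(cnts > 0, sums / pmax(cnts, 1), 0)
    list(means = means, cum = cumsum(means) / sum(means))
  }
  withr::with_seed(11, {
    for (k in 1:8) {
      proj <- matrix(sample(0:1000, 64 * 64, TRUE), 64, 64)
      com <- c(runif(1, 24, 40), runif(1, 24, 40))
      r_max <- sample(15:30, 1)
      pr <- radial_profile(proj, com, r_max)
      ref <- naive_profile(proj, com, r_max)
      expect_identical(pr$mean_intensity, ref$means)
      expect_identical(pr$cumulative, ref$cum)
    }
  })
})

test_that("radius_at_fraction interpolates and is monotone in the fraction", {
  # delta ring at relative radius 0.4: every fraction reads 0.4
  size <- 101L; ctr <- 50
  x <- matrix(rep(0:(size - 1L), each = size), size, size)
  y <- matrix(rep(0:(size - 1L), times = size), size, size)
  img <- 500 * (round(sqrt((x - ctr)^2 + (y - ctr)^2)) == 16)
  pr <- radial_profile(img, c(ctr, ctr), 40)
  # interpolation between the bracketing bins reads one bin width low on a
  # pure step, so the ring position is recovered to within 1/r_max
  expect_equal(radius_at_fraction(pr, 0.6), 0.4, tolerance = 1 / 40 + 1e-12)

  # hand interpolation: cumulative 0.5 at rel 0.30, 0.7 at 0.35 -> 0.325
  prof <- structure(list(
    mean_intensity = rep(1, 21),
    cumulative = c(seq(0, 0.5, length.out = 7), 0.7,
                   seq(0.75, 1, length.out = 13)),
    rel_radius = (0:20) / 20, r_max = 20L, zero_signal = FALSE),
    class = "radial_profile")
  expect_equal(radius_at_fraction(prof, 0.6), 0.325, tolerance = 1e-12)

  # exactly linear cumulative: fraction f reads f
  lin <- structure(list(mean_intensity = rep(1, 21),
                        cumulative = (0:20) / 20,
                        rel_radius = (0:20) / 20, r_max = 20L,
                        zero_signal = FALSE), class = "radial_profile")
  expect_equal(radius_at_fraction(lin, 0.6), 0.6, tolerance = 1e-12)
  fr <- seq(0.05, 0.95, by = 0.05)
  vals <- vapply(fr, radius_at_fraction, numeric(1), profile = pr)
  expect_true(all(diff(vals) >= 0))
  expect_error(radius_at_fraction(structure(list(zero_signal = TRUE),
                                            class = "radial_profile"), 0.6),
               "no signal")
})

test_that("nuclear initial slope reads the chord at the cutoff", {
  size <- 101L; ctr <- 50
  x <- matrix(rep(0:(size - 1L), each = size), size, size)
  y <- matrix(rep(0:(size - 1L), times = size), size, size)
  r <- round(sqrt((x - ctr)^2 + (y - ctr)^2))
  # no signal inside 0.3 * r_max (ring at 0.875 * 40 = 35)
  pr_out <- radial_profile(500 * (r == 35), c(ctr, ctr), 40)
  expect_equal(nuclear_initial_slope(pr_out, 0.3), 0, tolerance = 1e-12)
  # all signal well inside the cutoff
  pr_in <- radial_profile(500 * (r == 2), c(ctr, ctr), 40)
  expect_equal(nuclear_initial_slope(pr_in, 0.3), 1 / 0.3, tolerance = 1e-12)
  # half inside: rings at r = 4 and r = 35 with equal per-pixel intensity
  pr_half <- radial_profile(500 * (r == 4) + 500 * (r == 35), c(ctr, ctr), 40)
  expect_equal(nuclear_initial_slope(pr_half, 0.3), 0.5 / 0.3, tolerance = 1e-12)
})

test_that("marker deltas carry the polarity sign convention", {
  d <- marker_deltas(c(basolateral = 0.9, apical = 0.5, actin = 0.5))
  expect_equal(unname(d["f1_delta_gp58_gp135"]), 0.4)
  d2 <- marker_deltas(c(basolateral = 0.5, apical = 0.9, actin = 0.9))
  expect_equal(unname(d2["f1_delta_gp58_gp135"]), -0.4)
  d3 <- marker_deltas(c(basolateral = 0.7, apical = 0.5, actin = 0.5))
  expect_equal(unname(d3["f2_delta_actin_gp135"]), 0)
})

test_that("feature vector ties its identities and matches generator geometry", {
  pz <- small_params(noise = FALSE)
  f1s <- feature_vector(equatorial_projection(generate_spheroid("1_regular", pz, 21)$stack))
  expect_identical(f1s[["f1_delta_gp58_gp135"]],
                   f1s[["f3_relpos60_gp58"]] - f1s[["f4_relpos60_gp135"]])
  expect_identical(f1s[["f2_delta_actin_gp135"]],
                   f1s[["f5_relpos60_actin"]] - f1s[["f4_relpos60_gp135"]])
  expect_gt(f1s[["f1_delta_gp58_gp135"]], 0)
  expect_lt(abs(f1s[["f2_delta_actin_gp135"]]), 0.1)
  expect_lt(f1s[["f9_nuclear_initial_slope"]], 0.3)

  f2s <- feature_vector(equatorial_projection(generate_spheroid("2_inverse", pz, 22)$stack))
  expect_lt(f2s[["f1_delta_gp58_gp135"]], 0)

  f3s <- feature_vector(equatorial_projection(generate_spheroid("3a_aggregate", pz, 23)$stack))
  expect_gt(f3s[["f9_nuclear_initial_slope"]], 1)

  expect_identical(names(f1s), feature_names())
  expect_true(all(is.finite(f1s)))
})

test_that("feature table extraction and CSV round trip are lossless", {
  p <- small_params()
  ds <- generate_dataset(c("1_regular" = 2L, "2_inverse" = 2L), p, seed = 8)
  feats <- extract_features(ds)
  expect_identical(nrow(feats), 4L)
  expect_identical(feats$coarse_label, c("1", "1", "2", "2"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(feats, path)
  back <- read_features_csv(path)
  for (fn in feature_names())
    expect_equal(back[[fn]], feats[[fn]], tolerance = 1e-15)
})
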