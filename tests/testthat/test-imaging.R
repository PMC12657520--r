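test_that("Otsu threshold separates a two-level image exactly", {
  vals <- c(rep(10, 50), rep(200, 50))
  thr <- otsuThreshold(vals)
  expect_gt(thr, 10)
  expect_lte(thr, 200)
  expect_equal(sum(vals > thr), 50L)
  expect_error(otsuThreshold(rep(7, 20)), "no threshold")
})

test_that("Otsu equals the exhaustive between-class-variance oracle", {
  for (s in 1:30) {
    vals <- withr::with_seed(s, {
      n <- sample(50:400, 1)
      round(c(rnorm(n, 80, 20), rnorm(n / 2, 180, 30)))
    })
    vals <- pmin(pmax(vals, 0), 255)
    if (length(unique(vals)) < 2) next
    thr <- otsuThreshold(vals)
    expect_equal(vals > thr, naiveOtsuPartition(vals))
  }
})

test_that("nuclei are segmented with high overlap and split when touching", {
  g <- generateNucleusImage(seed = 3)
  lab <- segmentNuclei(g$image)
  expect_equal(max(lab), 5L)
  for (i in 1:5) {
    gtm <- g$nucleusMask == i
    k <- as.integer(names(which.max(table(lab[gtm & lab > 0]))))
    jac <- sum(lab == k & gtm) / sum(lab == k | gtm)
    expect_gte(jac, 0.9)
  }
  expect_warning(blank <- segmentNuclei(matrix(100, 64, 64)), "blank")
  expect_equal(max(blank), 0L)
  ## two overlapping ellipses with distinct centres are separated
  ov <- generateNucleusImage(centers = rbind(c(100, 128), c(140, 128)),
                             radiusRange = c(24, 24), fociPerNucleus = 0,
                             seed = 4)
  labs <- segmentNuclei(ov$image)
  expect_equal(max(labs), 2L)
})

test_that("i80/i20 follows the linear-interpolation percentile convention", {
  m <- matrix(100, 10, 10)
  expect_equal(i80i20(m, m > 0), 1)
  v <- matrix(c(10, 20, 30, 40, 50), 1)
  expect_equal(i80i20(v, v > 0, minPixels = 5), 42 / 18)
  expect_equal(i80i20(v * 7, v > 0, minPixels = 5), 42 / 18)
  expect_error(i80i20(v, v > 0), "fewer than")
  ## ratio >= 1 on random nuclei
  for (s in 1:10) {
    px <- withr::with_seed(s, matrix(rnorm(400, 5000, 1500), 20))
    expect_gte(i80i20(px, px > -Inf), 1)
  }
  ## zero 20th percentile is reported missing
  z <- matrix(c(rep(0, 40), rep(10, 10)), 5)
  expect_message(r <- i80i20(z, z > -Inf), "missing")
  expect_true(is.na(r))
})

test_that("heterochromatin foci are recovered in count and area", {
  hits <- 0L; tot <- 0L
  for (s in 1:6) {
    g <- generateNucleusImage(seed = s)
    for (i in 1:5) {
      f <- heterochromatinFoci(g$image, g$nucleusMask == i)
      tot <- tot + 1L
      if (f$focus_count == g$params$fociPerNucleus) hits <- hits + 1L
    }
    measured <- sum(vapply(1:5, function(i)
      heterochromatinFoci(g$image, g$nucleusMask == i)$total_focus_area,
      integer(1)))
    planted <- sum(g$focusMask > 0)
    expect_lt(abs(measured - planted) / planted, 0.1)
  }
  expect_gte(hits / tot, 0.9)
  ## a featureless nucleus yields no foci
  flat <- matrix(5000, 40, 40)
  expect_equal(heterochromatinFoci(flat, flat > 0)$focus_count, 0L)
})

test_that("peripheral fraction partitions focus pixels exactly", {
  d <- sqrt((row(matrix(0, 61, 61)) - 31)^2 + (col(matrix(0, 61, 61)) - 31)^2)
  nucleus <- d <= 25
  shellFoci <- d > 22.5 & d <= 24.5
  coreFoci <- d <= 5
  expect_equal(peripheralFraction(shellFoci, nucleus, shellWidth = 3), 1)
  expect_equal(peripheralFraction(coreFoci, nucleus, shellWidth = 3), 0)
  both <- shellFoci | coreFoci
  pf <- peripheralFraction(both, nucleus, shellWidth = 3)
  expect_equal(pf + (1 - pf), 1)
  expect_equal(pf, sum(shellFoci) / sum(both))
  expect_warning(
    expect_equal(peripheralFraction(coreFoci, nucleus, shellWidth = 40), 1),
    "wider")
})

test_that("peripheral bias in the generator raises the measured fraction", {
  measure <- function(bias, s) {
    g <- generateNucleusImage(peripheralBias = bias, seed = s)
    mean(vapply(seq_len(g$params$nNuclei), function(i) {
      f <- heterochromatinFoci(g$image, g$nucleusMask == i)
      peripheralFraction(f$focusMask, g$nucleusMask == i)
    }, numeric(1)), na.rm = TRUE)
  }
  expect_gt(measure(0.9, 5), measure(0.1, 5))
})

test_that("spheroid spread area is accurate and monotone in migration", {
  disc <- generateSpheroidImage(coreRadius = 50, migrationRadius = 50,
                                nCells = 0, seed = 11)
  m <- spheroidSpreadArea(disc$dapi)
  expect_lt(abs(m$spread_area - pi * 50^2) / (pi * 50^2), 0.05)
  expect_lte(m$core_area, m$spread_area)
  sweep <- vapply(c(60, 90, 120), function(r)
    spheroidSpreadArea(
      generateSpheroidImage(migrationRadius = r, seed = 11)$dapi
    )$spread_area, numeric(1))
  expect_true(all(diff(sweep) > 0))
  expect_error(spheroidSpreadArea(matrix(0, 32, 32)), "no foreground")
})

test_that("cytoskeleton area ratio matches planted geometry", {
  sz <- 256
  d <- sqrt((row(matrix(0, sz, sz)) - 128)^2 +
            (col(matrix(0, sz, sz)) - 128)^2)
  core <- d <= 40
  ring <- d > 50 & d <= 70
  actin <- matrix(300, sz, sz)
  actin[core | ring] <- 8000
  expect_lt(abs(cytoskeletonAreaRatio(actin, core) -
                sum(ring) / sum(core)), 0.1 * sum(ring) / sum(core))
  expect_equal(cytoskeletonAreaRatio(actin * 7, core),
               cytoskeletonAreaRatio(actin, core))
  confined <- matrix(300, sz, sz); confined[core] <- 8000
  expect_equal(cytoskeletonAreaRatio(confined, core), 0)
  expect_error(cytoskeletonAreaRatio(actin, matrix(FALSE, sz, sz)), "core")
})

test_that("per-nucleus metric tables are complete and consistent", {
  g <- generateNucleusImage(seed = 6)
  met <- nucleiMetrics(g$image, mask = g$nucleusMask)
  expect_equal(nrow(met), 5L)
  expect_true(all(met$i80_i20 >= 1, na.rm = TRUE))
  expect_true(all(met$total_focus_area <= met$nucleus_area))
  expect_true(all(met$peripheral_fraction >= 0 &
                  met$peripheral_fraction <= 1, na.rm = TRUE))
})
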