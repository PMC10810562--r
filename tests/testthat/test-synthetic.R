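# Generative model: truth sampling, calibration properties, rendering,
# determinism and conservation.

test_that("empty gonad yields a truth table with only the DTC", {
  tr <- generateTruth(smallGeometry(0), BiologyModel(1), seed = 1)
  expect_equal(nrow(truthCells(tr)), 0)
  expect_equal(nrow(truthAts(tr)), 0)
  expect_true(truthDtc(tr)$drift >= 0)
})

test_that("drift law reproduces the published Day-1 and Day-4 anchors", {
  set.seed(10)
  d1 <- sampleDrift(20000, BiologyModel(1))
  expect_gt(mean(d1), 1.85); expect_lt(mean(d1), 2.15)
  expect_gte(mean(d1 <= 5), 0.95)
  d4 <- sampleDrift(20000, BiologyModel(4))
  expect_gt(mean(d4), 10.8); expect_lt(mean(d4), 13.2)
  expect_gt(mean(d4 <= 5), 0.33); expect_lt(mean(d4 <= 5), 0.43)
  expect_gt(max(d4), 40)          # long tail reaching ~42 um
  expect_true(all(d4 >= 0))
})

test_that("per-locus probability solves the 4-locus Bernoulli model", {
  bio <- BiologyModel(1)
  d <- c(0, 1.25, 5, 12, 25)
  q <- perLocusProbability(d, bio)
  # closed form check: 1 - (1-q)^4 == p
  expect_equal(1 - (1 - q)^bio@nLoci, activationProbability(d, bio),
               tolerance = 1e-12)
  # Monte-Carlo of the Bernoulli model at the distal-most bin
  set.seed(4)
  act <- replicate(20000, any(rbinom(bio@nLoci, 1, q[2]) > 0))
  expect_equal(mean(act), activationProbability(1.25, bio),
               tolerance = 0.035)
})

test_that("truth-level calibration: boundary beyond 25 um and distal peak", {
  # pooled over >= 10,000 cells, detection bypassed
  geo <- GonadGeometry()
  cells <- do.call(rbind, lapply(1:52, function(i) {
    tr <- generateTruth(geo, BiologyModel(1), seed = 5000 + i)
    truthCells(tr)[, c("axial_distance", "n_ats")]
  }))
  expect_gte(nrow(cells), 10000)
  prof <- oracle_profile(cells$axial_distance, cells$n_ats >= 1, 2.5, 60)
  beyond <- prof$percent[which(seq(0, 57.5, 2.5) >= 25)]
  expect_true(all(beyond[!is.na(beyond)] < 2.5))
  peak_mid <- seq(1.25, by = 2.5, length.out = length(prof$percent))[
    which.max(prof$percent)]
  expect_gte(peak_mid, 3); expect_lte(peak_mid, 7)
  # distal-most region ~70%
  expect_gt(prof$percent[1], 62); expect_lt(prof$percent[1], 78)
})

test_that("aging monotonicity: drift mean and activation peak move proximally", {
  means <- vapply(1:4, function(day) {
    b <- BiologyModel(day)
    exp(b@driftMeanlog + b@driftSdlog^2 / 2)   # untruncated lognormal mean
  }, 0)
  expect_true(all(diff(means) > 0))
  peaks <- vapply(1:4, function(day) {
    a <- BiologyModel(day)@activationAnchors
    a[which.max(a[, 2]), 1]
  }, 0)
  expect_true(all(diff(peaks) > 0))
})

test_that("truth conservation: ATS rows equal active loci", {
  tr <- generateTruth(smallGeometry(18), BiologyModel(1), seed = 77)
  cells <- truthCells(tr)
  expect_equal(sum(vapply(cells$locus_states, sum, 1L)), nrow(truthAts(tr)))
  expect_equal(sum(cells$n_ats), nrow(truthAts(tr)))
  # every ATS inside its nuclear sphere
  ats <- truthAts(tr)
  if (nrow(ats) > 0) {
    i <- match(ats$cell_id, cells$cell_id)
    dd <- sqrt((ats$x - cells$x[i])^2 + (ats$y - cells$y[i])^2 +
               (ats$z - cells$z[i])^2)
    expect_true(all(dd < cells$r[i]))
  }
  # every mRNA inside the tube and outside nuclear spheres
  mr <- truthMrna(tr)
  if (nrow(mr) > 0) {
    expect_true(all(mr$x >= 0 & mr$x <= tr@geometry@tubeLength))
    expect_true(all(mr$y^2 + mr$z^2 <= tr@geometry@tubeRadius^2))
    for (k in seq_len(nrow(mr))) {
      dd <- sqrt((cells$x - mr$x[k])^2 + (cells$y - mr$y[k])^2 +
                 (cells$z - mr$z[k])^2)
      expect_true(all(dd >= cells$r))
    }
  }
})

test_that("nuclei are packed without overlap and inside the tube", {
  tr <- generateTruth(smallGeometry(18), BiologyModel(1), seed = 3)
  cells <- truthCells(tr)
  m <- as.matrix(cells[, c("x", "y", "z")])
  d <- as.matrix(dist(m)); diag(d) <- Inf
  rsum <- outer(cells$r, cells$r, "+")
  expect_true(all(d >= 0.9 * rsum - 1e-9))
  expect_true(all(cells$y^2 + cells$z^2 <=
                    (tr@geometry@tubeRadius - cells$r)^2 + 1e-9))
})

test_that("packing failure names the achievable maximum", {
  expect_error(generateTruth(GonadGeometry(tubeLength = 8, tubeRadius = 4,
                                           nCells = 500), BiologyModel(1),
                             seed = 1),
               "packing failed.*reduce nCells", ignore.case = TRUE)
})

test_that("truth and render are deterministic for a fixed seed", {
  geo <- smallGeometry(12)
  t1 <- generateTruth(geo, BiologyModel(2), seed = 11)
  t2 <- generateTruth(geo, BiologyModel(2), seed = 11)
  expect_identical(truthCells(t1), truthCells(t2))
  expect_identical(truthAts(t1), truthAts(t2))
  s1 <- renderStack(t1, OpticsModel(), seed = 12)
  s2 <- renderStack(t2, OpticsModel(), seed = 12)
  expect_identical(s1@img, s2@img)
  s3 <- renderStack(t1, OpticsModel(), seed = 13)
  expect_false(identical(s1@img, s3@img))
})

test_that("a single noise-free mRNA renders with its argmax at the spot", {
  geo <- smallGeometry(0)
  mrna <- data.frame(mrna_id = 1L, cell_id = 1L, x = 10.4, y = 1.3,
                     z = -0.9, intensity_au = 1)
  tr <- makeTruthFixture(mrna = mrna, geometry = geo)
  st <- renderStack(tr, OpticsModel(shotNoise = FALSE), seed = 1,
                    channels = "exon")
  arr <- getChannel(st, "exon")
  pk <- arrayInd(which.max(arr), dim(arr))
  w <- nicheQuant:::.stack_world(st, pk - 1)
  expect_lt(abs(w[1] - 10.4), 0.14)
  expect_lt(abs(w[2] - 1.3), 0.14)
  expect_lt(abs(w[3] + 0.9), 0.31)
})

test_that("integrated spot signal is proportional to intensity (5x = 5x)", {
  geo <- smallGeometry(0)
  ats <- data.frame(ats_id = 1L, cell_id = 1L, x = 5, y = 0, z = 0,
                    intensity_au = 5)
  mrna <- data.frame(mrna_id = 1L, cell_id = 1L, x = 15, y = 0, z = 0,
                     intensity_au = 1)
  tr <- makeTruthFixture(ats = ats, mrna = mrna, geometry = geo)
  st <- renderStack(tr, OpticsModel(shotNoise = FALSE,
                                    background = c(dapi = 0, intron = 0,
                                                   exon = 0, membrane = 0)),
                    seed = 1, channels = "exon")
  arr <- getChannel(st, "exon")
  xs <- (seq_len(dim(arr)[1]) - 0.5) * st@pixelSizeXY
  s_ats <- sum(arr[xs < 10, , ])
  s_mrna <- sum(arr[xs >= 10, , ])
  expect_equal(s_ats / s_mrna, 5, tolerance = 0.02)
})

test_that("cohorts derive per-gonad seeds deterministically", {
  s1 <- gonadSeeds(42, 5); s2 <- gonadSeeds(42, 5)
  expect_identical(s1, s2)
  expect_true(all(s1 < 2^31) && length(unique(s1)) == 5)
  co <- generateCohort(1, smallGeometry(8), BiologyModel(1), OpticsModel(),
                       masterSeed = 4)
  expect_length(co, 1)
  expect_s4_class(co[[1]]$stack, "GonadStack")
  expect_s4_class(co[[1]]$truth, "GonadTruth")
})
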