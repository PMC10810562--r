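# Spatial statistics: cell table, profiles, boundary/peak, NND, DTC
# distances, correlations, region centers and extents.

cells_fixture <- function() {
  data.frame(cell_id = 1:6, nucleus_id = 1:6,
             x = c(1, 4, 7, 12, 20, 30), y = c(0, 1, -1, 2, 0, 0),
             z = c(0, 0, 1, -1, 0, 0), r = 1.8,
             morphology = c(rep("mitotic", 5), "crescent"),
             axial_distance = c(1, 4, 7, 12, 20, 30),
             dtc_distance = c(2, 5, 8, 13, 21, 31),
             n_ats = c(2L, 1L, 0L, 1L, 0L, 0L),
             summed_ats_au = c(2.1, 1.2, 0, 1.0, 0, 0),
             n_mrna = c(15L, 12L, 8L, 3L, 0L, 0L))
}

test_that("cell table aggregates spots and excludes the DTC", {
  nuc <- data.frame(nucleus_id = 1:3, x = c(1, 5, 9), y = 0, z = c(0, 0, 1),
                    r = 1.8, morphology = c("mitotic", "mitotic",
                                            "dtc_candidate"))
  spots <- data.frame(
    spot_class = c("true_ats", "true_ats", "mrna_cyto", "mrna_cyto"),
    cell_id = c(1L, 1L, 2L, 2L), nucleus_id = c(1L, 1L, NA, NA),
    intensity_au = c(1.2, 0.9, 1, 1))
  cells <- buildCellTable(nuc, spots, dtcId = 3L)
  expect_equal(nrow(cells), 2)
  expect_equal(cells$summed_ats_au[1], 2.1)
  expect_equal(cells$n_ats, c(2L, 0L))
  expect_equal(cells$n_mrna, c(0L, 2L))
  expect_equal(cells$dtc_distance[1], sqrt(64 + 1))
  # conservation: table totals equal spot-file totals
  expect_equal(sum(cells$n_ats),
               sum(spots$spot_class == "true_ats" & !is.na(spots$cell_id)))
  expect_equal(sum(cells$n_mrna), sum(spots$spot_class == "mrna_cyto"))
  # zero spots -> all counts zero; absent DTC -> flagged NA distances
  c0 <- buildCellTable(nuc, spots[0, ], dtcId = NA)
  expect_true(all(c0$n_ats == 0) && all(c0$n_mrna == 0))
  expect_true(all(is.na(c0$dtc_distance)))
})

test_that("percent profile matches hand binning and sums its cells", {
  set.seed(2)
  cells <- data.frame(axial_distance = runif(20, 0, 24),
                      n_ats = rbinom(20, 2, 0.4))
  prof <- percentProfile(cells, binWidth = 2.5, maxDistance = 24)
  want <- oracle_profile(cells$axial_distance, cells$n_ats >= 1, 2.5, 24)
  expect_equal(prof$percent, want$percent)
  expect_equal(prof$n_cells, want$n)
  expect_equal(sum(prof$n_cells), 20)
  allpos <- percentProfile(data.frame(axial_distance = c(1, 2, 9),
                                      n_ats = 1L), binWidth = 2.5)
  expect_true(all(allpos$percent[allpos$n_cells > 0] == 100))
})

test_that("profile averaging weights gonads equally", {
  p1 <- percentProfile(data.frame(axial_distance = c(1, 1, 6), n_ats = c(1L, 1L, 0L)),
                       binWidth = 5, maxDistance = 10)
  p2 <- percentProfile(data.frame(axial_distance = c(2, 7), n_ats = c(0L, 1L)),
                       binWidth = 5, maxDistance = 10)
  avg <- averageProfiles(list(p1, p2))
  expect_equal(avg$percent[1], mean(c(100, 0)))
  expect_equal(avg$percent[2], mean(c(0, 100)))
  expect_equal(avg$n_gonads, c(2, 2))
})

test_that("pool boundary follows the 2.5% rule with smoothing", {
  prof5 <- data.frame(bin_lo = seq(0, 20, 5), bin_hi = seq(5, 25, 5),
                      bin_mid = seq(2.5, 22.5, 5),
                      n_cells = 10, n_positive = 0,
                      percent = c(70, 40, 10, 2, 1))
  expect_equal(poolBoundary(prof5, 2.5), 15)
  # identically zero profile: boundary at the first bin edge
  z <- prof5; z$percent <- 0
  expect_equal(poolBoundary(z), 0)
  # a single above-threshold bin beyond the crossing does not reset it
  bump <- data.frame(bin_lo = seq(0, 30, 5), bin_hi = seq(5, 35, 5),
                     bin_mid = seq(2.5, 32.5, 5), n_cells = 10,
                     n_positive = 0,
                     percent = c(70, 40, 10, 2, 4, 1, 0))
  expect_equal(poolBoundary(bump, 2.5), 15)
  # two consecutive above-threshold bins do reset it
  plateau <- bump; plateau$percent <- c(70, 40, 10, 2, 4, 6, 1)
  expect_equal(poolBoundary(plateau, 2.5), 30)
  # monotone nonincreasing in the threshold
  th <- c(1.5, 2.5, 5, 12, 45)
  bounds <- vapply(th, function(t) poolBoundary(prof5, t), 0)
  expect_true(all(diff(bounds) <= 0))
})

test_that("profile peak picks the maximum bin, distal on ties", {
  prof <- data.frame(bin_mid = c(1.25, 3.75, 6.25),
                     percent = c(50, 70, 70), n_cells = 5)
  expect_equal(profilePeak(prof), 3.75)
  one <- data.frame(bin_mid = 8.75, percent = 12, n_cells = 3)
  expect_equal(profilePeak(one), 8.75)
  none <- data.frame(bin_mid = 1, percent = NA_real_, n_cells = 0)
  expect_error(profilePeak(none), "occupied")
})

test_that("NND equals the all-pairs oracle and is monotone", {
  cells <- cells_fixture()
  two <- cells[1:2, ]; two$n_ats <- 1L
  expect_equal(nndDistances(two),
               rep(sqrt(9 + 1), 2), ignore_attr = TRUE)
  set.seed(9)
  big <- data.frame(x = runif(100, 0, 40), y = runif(100, -8, 8),
                    z = runif(100, -8, 8), n_ats = 1L)
  expect_equal(unname(nndDistances(big)),
               oracle_nnd(as.matrix(big[, 1:3])))
  # adding a distant cell never decreases existing NNDs
  plus <- rbind(big, data.frame(x = 500, y = 0, z = 0, n_ats = 1L))
  expect_true(all(unname(nndDistances(plus))[1:100] >=
                    unname(nndDistances(big)) - 1e-12))
  expect_error(nndDistances(big[1, ]), "at least 2")
})

test_that("DTC shift is Euclidean and DTC distances average correctly", {
  expect_equal(dtcShift(c(0, 0, 0)), 0)
  expect_equal(dtcShift(c(3, 4, 0)), 5)
  cells <- cells_fixture()
  expect_equal(meanDtcDistance(cells), mean(c(2, 5, 13)))
  one <- cells[4, ]
  expect_equal(meanDtcDistance(one), 13)
  expect_error(meanDtcDistance(cells[cells$n_ats > 5, ]), "qualifying")
})

test_that("correlation with distance is exact on linear data and invariant", {
  cells <- cells_fixture()
  cells$n_ats <- 1L
  cells$summed_ats_au <- -2 * cells$dtc_distance + 10
  fit <- corrVsDistance(cells, "summed_ats_au")
  expect_equal(fit$r, -1)
  expect_equal(fit$slope, -2)
  expect_equal(fit$intercept, 10)
  perm <- cells[sample(nrow(cells)), ]
  expect_equal(corrVsDistance(perm, "summed_ats_au")$r, fit$r)
  flat <- cells; flat$summed_ats_au <- 1
  expect_error(corrVsDistance(flat, "summed_ats_au"), "variance")
})

test_that("mRNA region centers and their distance behave geometrically", {
  cells <- cells_fixture()
  ctr <- mrnaRegionCenter(cells, threshold = 10)   # cells 1 and 2
  expect_equal(unname(ctr), c(2.5, 0.5, 0))
  single <- mrnaRegionCenter(cells, threshold = 14)
  expect_equal(unname(single), c(1, 0, 0))
  expect_true(all(is.na(mrnaRegionCenter(cells, threshold = 99))))
  expect_equal(regionCenterDistance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_true(is.na(regionCenterDistance(c(NA, NA, NA), c(1, 1, 1))))
  # symmetric pair -> midpoint
  pair <- data.frame(x = c(2, 6), y = c(1, -1), z = 0, n_mrna = 20L)
  expect_equal(unname(mrnaRegionCenter(pair)), c(4, 0, 0))
})

test_that("PZ extent follows the more-than-one-crescent rule", {
  mkc <- function(ax) data.frame(axial_distance = ax,
                                 morphology = "crescent")
  mito <- data.frame(axial_distance = seq(1, 50, 2),
                     morphology = "mitotic")
  # crescents only beyond 35 um, clustered -> extent ~ 35
  cl <- rbind(mito, mkc(c(35.5, 36.8, 38, 40)))
  expect_equal(as.numeric(pzExtent(cl)), 35.5)
  expect_false(attr(pzExtent(cl), "flagged"))
  # one isolated crescent at 20, next at 35: not triggered at 20
  iso <- rbind(mito, mkc(c(20, 35)))
  out <- pzExtent(iso, windowLength = 60)
  expect_equal(as.numeric(out), 60)
  expect_true(attr(out, "flagged"))
  # no crescents at all -> flagged full length
  out2 <- pzExtent(mito, windowLength = 60)
  expect_equal(as.numeric(out2), 60)
  expect_true(attr(out2, "flagged"))
})

test_that("region extent is a span, duplication-invariant", {
  cells <- data.frame(axial_distance = c(5, 12, 25), n_ats = 1L)
  expect_equal(regionExtent(cells), 20)
  expect_equal(regionExtent(cells[2, , drop = FALSE]), 0)
  dup <- rbind(cells, cells[2, ])
  expect_equal(regionExtent(dup), 20)
})
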