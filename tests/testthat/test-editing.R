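pileRow <- function(A, G, feature = "f", position = 0L, ref = "A",
                    inDna = FALSE, C = 0L, T = 0L) {
  data.frame(feature = feature, position = position, ref = ref,
             A = A, C = C, G = G, T = T, inDnaVariants = inDna,
             stringsAsFactors = FALSE)
}

test_that("editing-site calling reproduces the threshold semantics exactly", {
  # boundary enumeration around coverage 10/11 and G 2/3
  expect_identical(nrow(callEditingSites(pileRow(A = 8, G = 3))), 1L)  # 11, 3
  expect_identical(nrow(callEditingSites(pileRow(A = 5, G = 5))), 0L)  # 10
  expect_identical(nrow(callEditingSites(pileRow(A = 9, G = 2))), 0L)  # G=2
  expect_identical(nrow(callEditingSites(pileRow(A = 97, G = 3,
                                                 inDna = TRUE))), 0L)
  expect_identical(nrow(callEditingSites(pileRow(A = 8, G = 3,
                                                 ref = "C"))), 0L)
  called <- callEditingSites(pileRow(A = 8, G = 3))
  expect_equal(called$gFraction, 3 / 11)
  # coverage counts all four bases
  withCT <- pileRow(A = 5, G = 3, C = 2, T = 1)  # total 11
  expect_identical(nrow(callEditingSites(withCT)), 1L)
  expect_equal(callEditingSites(withCT)$gFraction, 3 / 8)  # G/(A+G)
})

test_that("site calling is monotone in its thresholds", {
  set.seed(12)
  pile <- do.call(rbind, lapply(1:200, function(i)
    pileRow(A = sample(0:30, 1), G = sample(0:10, 1),
            position = i, inDna = runif(1) < 0.1)))
  n <- nrow(callEditingSites(pile))
  expect_true(nrow(callEditingSites(pile, minCoverage = 15)) <= n)
  expect_true(nrow(callEditingSites(pile, minG = 5)) <= n)
})

test_that("editing index is total G over total A+G at reference-A positions", {
  one <- pileRow(A = 90, G = 10)
  expect_equal(unname(editingIndex(one)), 0.1)
  two <- rbind(pileRow(A = 50, G = 0, position = 0),
               pileRow(A = 30, G = 20, position = 1))
  expect_equal(unname(editingIndex(two)), 20 / 100)
  noG <- rbind(pileRow(A = 50, G = 0), pileRow(A = 10, G = 0, position = 1))
  expect_equal(unname(editingIndex(noG)), 0)
  # equals the coverage-weighted mean of per-site G fractions
  set.seed(13)
  pile <- do.call(rbind, lapply(1:50, function(i)
    pileRow(A = sample(1:100, 1), G = sample(0:20, 1), position = i)))
  w <- pile$A + pile$G
  expect_equal(unname(editingIndex(pile)),
               sum(w * (pile$G / w)) / sum(w))
})

test_that("editing index recovers a planted fraction at high coverage", {
  cfg <- SyntheticConfig(nGenes = 5, nMirnas = 2,
                         editedSiteFraction = 1,
                         editingFractionRange = c(0.1, 0.1),
                         dnaVariantFraction = 0,
                         pileupCoverage = 10000L, rngSeed = 21)
  utrs <- c(u1 = paste(rep("A", 50), collapse = ""))
  pe <- generateEditingPileups(cfg, utrs)
  idx <- unname(editingIndex(pe$pileups))
  se <- sqrt(0.1 * 0.9 / (50 * 10000))
  expect_lt(abs(idx - 0.1), 3 * se)
})

test_that("DNA variants are excluded regardless of counts", {
  cfg <- SyntheticConfig(nGenes = 2, nMirnas = 1, editedSiteFraction = 1,
                         editingFractionRange = c(0.3, 0.3),
                         dnaVariantFraction = 1, pileupCoverage = 100L,
                         rngSeed = 3)
  pe <- generateEditingPileups(cfg, c(u = "AAAAAAAAAA"))
  expect_true(all(pe$pileups$inDnaVariants))
  expect_identical(nrow(callEditingSites(pe$pileups)), 0L)
})

test_that("seed editing reports the max G proportion over covered seed As", {
  bc <- data.frame(mirna = "m1", position = 1:9, ref = "A",
                   A = 960, C = 0, G = 40, T = 0)
  # planted 4% at every position; only positions 2-8 count
  expect_equal(unname(mirnaSeedEditing(bc)), 0.04)
  # no A in the seed -> undefined
  bcNoA <- data.frame(mirna = "m2", position = 2:8, ref = "C",
                      A = 0, C = 100, G = 0, T = 0)
  expect_true(is.na(mirnaSeedEditing(bcNoA)))
  # coverage exactly 10 at the only seed A -> undefined (strict > 10)
  bc10 <- data.frame(mirna = "m3", position = 5, ref = "A",
                     A = 9, C = 0, G = 1, T = 0)
  expect_true(is.na(mirnaSeedEditing(bc10)))
  bc11 <- data.frame(mirna = "m3", position = 5, ref = "A",
                     A = 10, C = 0, G = 1, T = 0)
  expect_equal(unname(mirnaSeedEditing(bc11)), 1 / 11)
})

test_that("MRE/editing intersection applies the window coverage filter", {
  mres <- data.frame(feature = c("u1", "u2"), position = c(0L, 0L))
  covTrack <- data.frame(
    feature = rep(c("u1", "u2"), each = 8),
    position = rep(0:7, 2),
    depth = c(rep(50, 8), rep(10, 8)))  # u2 fails the > 10 filter
  sites <- data.frame(feature = "u1", position = 3L,
                      gFraction = 0.2)
  res <- mreEditingOverlap(mres, sites, covTrack)
  expect_identical(res$nConsidered, 1L)
  expect_identical(res$nEdited, 1L)
  expect_equal(res$fraction, 1)
  # no editing sites in the windows -> fraction 0
  res0 <- mreEditingOverlap(mres,
                            data.frame(feature = "u1", position = 20L,
                                       gFraction = 0.2),
                            covTrack)
  expect_equal(res0$fraction, 0)
})

test_that("one-off conservation comparison builds the three 8-mer classes", {
  set.seed(30)
  alns <- lapply(1:5, function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
               collapse = "")
    UtrAlignment(s, s, paste0("g", i), paste0("g", i, "o"))
  })
  res <- oneOffConservationComparison(alns, c("CTGCCTCA", "GGACGTCA"),
                                      seed = 2)
  expect_named(res$tables, c("oneOff", "shuffled", "gToA"))
  expect_true("CTACCTCA" %in% res$tables$oneOff$octamer)
  # an MRE with no G contributes nothing to the one-off panel
  resNoG <- oneOffConservationComparison(alns, "CTACCTCA", seed = 2)
  expect_null(resNoG$tables$oneOff)
  expect_length(resNoG$ratePanels$oneOff, 0)
})
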