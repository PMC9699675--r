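test_that("config validity enforces probability ranges and effect direction", {
  expect_error(SyntheticConfig(substitutionRate = 1.2), "probabilities")
  expect_error(SyntheticConfig(nGenes = 0), "nGenes")
  expect_error(SyntheticConfig(editingFractionRange = c(0.5, 0.1)),
               "interval")
  expect_error(SyntheticConfig(plantedConservationCoexpressed = 0.3,
                               plantedConservationNoncoexpressed = 0.5),
               "allowInvertedEffect")
  inv <- SyntheticConfig(plantedConservationCoexpressed = 0.3,
                         plantedConservationNoncoexpressed = 0.5,
                         allowInvertedEffect = TRUE)
  expect_s4_class(inv, "SyntheticConfig")
})

test_that("miRNA generation is reproducible, sized and typed correctly", {
  cfg <- SyntheticConfig(nMirnas = 1, rngSeed = 7)
  one <- generateMirnas(cfg)
  expect_identical(nrow(one), 1L)
  expect_true(nchar(one$matureSeq) %in% 20:23)
  expect_identical(generateMirnas(cfg), one)  # same seed, same output
  none <- generateMirnas(SyntheticConfig(nMirnas = 0))
  expect_identical(nrow(none), 0L)
  many <- generateMirnas(SyntheticConfig(nMirnas = 50, rngSeed = 1))
  expect_false(anyDuplicated(many$name) > 0)
  expect_true(all(grepl("^[ACGU]+$", many$matureSeq)))
  expect_true(all(many$ageClass %in%
                    c("bilaterian", "protostome", "coleoid", "octopus")))
  other <- generateMirnas(SyntheticConfig(nMirnas = 50, rngSeed = 2))
  expect_false(identical(many$matureSeq, other$matureSeq))
})

test_that("generated pairs are byte-identical across runs with one seed", {
  cfg <- SyntheticConfig(nGenes = 30, nMirnas = 3, rngSeed = 9)
  m <- generateMirnas(cfg)
  p1 <- generateOrthologPairs(cfg, m)
  p2 <- generateOrthologPairs(cfg, m)
  expect_identical(p1$refSeqs, p2$refSeqs)
  expect_identical(p1$orthSeqs, p2$orthSeqs)
  expect_identical(p1$truth, p2$truth)
})

test_that("truth table round-trips exactly under zero mutation and {0,1} rates", {
  base <- list(nGenes = 80, nMirnas = 4, substitutionRate = 0,
               indelRate = 0, rngSeed = 13)
  for (p in c(0, 1)) {
    cfg <- do.call(SyntheticConfig,
                   c(base, plantedConservationCoexpressed = p,
                     plantedConservationNoncoexpressed = p))
    m <- generateMirnas(cfg)
    pairs <- generateOrthologPairs(cfg, m)
    expect_true(all(pairs$truth$conserved == (p == 1)))
    # downstream conservation calls match the truth labels exactly
    byGene <- split(pairs$truth, pairs$truth$gene)
    alnByGene <- setNames(pairs$alignments,
                          vapply(pairs$alignments, slot, "", "geneRef"))
    for (g in names(byGene)[1:20]) {
      for (k in seq_len(nrow(byGene[[g]]))) {
        expect_identical(
          isConservedOccurrence(alnByGene[[g]],
                                byGene[[g]]$position[k],
                                byGene[[g]]$octamer[k]),
          byGene[[g]]$conserved[k])
      }
    }
  }
})

test_that("alignments embed the planted site gap-free when indels are on", {
  cfg <- SyntheticConfig(nGenes = 40, nMirnas = 2, substitutionRate = 0,
                         indelRate = 0.05,
                         plantedConservationCoexpressed = 1,
                         plantedConservationNoncoexpressed = 1,
                         rngSeed = 15)
  m <- generateMirnas(cfg)
  pairs <- generateOrthologPairs(cfg, m)
  sites <- scanConservedSites(pairs$alignments, deriveMre(m$matureSeq))
  truthKey <- paste(pairs$truth$gene, pairs$truth$position)
  planted <- paste(sites$gene, sites$position) %in% truthKey
  expect_true(all(sites$conserved[planted]))
})

test_that("planted conservation rates are recovered within 3 binomial SE", {
  cfg <- SyntheticConfig(nGenes = 1100, nMirnas = 8, sitesPerGene = 4,
                         rngSeed = 17)
  m <- generateMirnas(cfg)
  pairs <- generateOrthologPairs(cfg, m)
  truth <- pairs$truth
  for (arm in c(TRUE, FALSE)) {
    sub <- truth[truth$codetected == arm, ]
    expect_gte(nrow(sub), 2000)
    p <- if (arm) 0.6 else 0.4
    se <- sqrt(p * (1 - p) / nrow(sub))
    expect_lt(abs(mean(sub$conserved) - p), 3 * se)
  }
})

test_that("expression matrices realise every codetection label", {
  for (nt in c(1L, 4L)) {
    cfg <- SyntheticConfig(nGenes = 60, nMirnas = 4, nTissues = nt,
                           rngSeed = 19)
    m <- generateMirnas(cfg)
    pairs <- generateOrthologPairs(cfg, m)
    expr <- generateExpression(cfg, m, pairs$truth)
    expect_true(all(expr$mirnaCpm >= 0) && all(expr$mrnaCpm >= 0))
    pairTab <- unique(pairs$truth[, c("gene", "mirna", "codetected")])
    got <- vapply(seq_len(nrow(pairTab)), function(i)
      classifyCodetection(expr$mirnaCpm[pairTab$mirna[i], ],
                          expr$mrnaCpm[pairTab$gene[i], ]), logical(1))
    expect_identical(got, pairTab$codetected)
  }
})

test_that("editing pileups plant the requested fractions and variants", {
  cfg <- SyntheticConfig(editedSiteFraction = 0.3,
                         editingFractionRange = c(0.1, 0.1),
                         dnaVariantFraction = 0, pileupCoverage = 100L,
                         rngSeed = 25)
  set.seed(1)
  utrs <- setNames(randomDna(20, 200, 300), paste0("u", 1:20))
  pe <- generateEditingPileups(cfg, utrs)
  expect_true(all(pe$pileups$ref == "A"))
  edited <- pe$truth$plantedFraction > 0
  # unedited positions carry no G
  expect_true(all(pe$pileups$G[!edited] == 0))
  # pooled G fraction at edited positions approximates the planted level
  gFrac <- sum(pe$pileups$G[edited]) / (100 * sum(edited))
  se <- sqrt(0.1 * 0.9 / (100 * sum(edited)))
  expect_lt(abs(gFrac - 0.1), 3 * se)
  # fraction of edited positions close to the planted site fraction
  expect_lt(abs(mean(edited) - 0.3),
            3 * sqrt(0.3 * 0.7 / length(edited)))
})
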