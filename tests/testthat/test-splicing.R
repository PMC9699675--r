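test_that("triplet construction yields ES and IR junction sets", {
  set.seed(14)
  contig <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                  collapse = "")
  ann3 <- data.frame(transcript = "t1", contig = "c1",
                     start = c(1, 101, 301), end = c(60, 200, 400))
  tr <- buildTriplets(ann3, c(c1 = contig))
  expect_identical(sum(tr$kind == "ES"), 1L)
  expect_identical(sum(tr$kind == "IR"), 2L)  # two introns
  es <- tr[tr$kind == "ES", ]
  # E1E2 junction: last 42 of exon1 + first 42 of exon2
  expect_identical(es$J1, paste0(substr(contig, 19, 60),
                                 substr(contig, 101, 142)))
  expect_identical(es$J3, paste0(substr(contig, 19, 60),
                                 substr(contig, 301, 342)))
  # 2-exon transcript: no ES triplet, one IR triplet
  ann2 <- data.frame(transcript = "t2", contig = "c1",
                     start = c(1, 101), end = c(60, 200))
  tr2 <- buildTriplets(ann2, c(c1 = contig))
  expect_identical(tr2$kind, "IR")
  # shared triplets across transcripts are reported once
  shared <- rbind(ann3, transform(ann3, transcript = "t1b"))
  expect_identical(nrow(buildTriplets(shared, c(c1 = contig))), nrow(tr))
  # malformed input
  expect_error(buildTriplets(
    data.frame(transcript = "t", contig = "c1", start = 10, end = 5),
    c(c1 = contig)), "malformed")
  expect_error(buildTriplets(
    data.frame(transcript = "t", contig = "c1", start = c(1, 30),
               end = c(50, 80)), c(c1 = contig)), "overlapping")
})

test_that("effective mappability matches the brute-force 50-mer dictionary", {
  set.seed(15)
  junctions <- vapply(1:100, function(i)
    paste(sample(c("A", "C", "G", "T"),
                 sample(c(55, 60, 84), 1), replace = TRUE),
          collapse = ""), character(1))
  # plant exact duplicates and a short junction
  junctions[5] <- junctions[9]
  junctions[20] <- paste(rep("A", 40), collapse = "")
  m <- effectiveMappability(junctions)
  expect_identical(m, bruteForceMappability(junctions))
  expect_identical(m[5], 0L)   # duplicated junction: nothing unique
  expect_identical(m[20], 0L)  # shorter than 50: no contained 50-mer
})

test_that("mappability of unique junctions equals contained 50-mer counts", {
  set.seed(16)
  j84 <- paste(sample(c("A", "C", "G", "T"), 84, replace = TRUE),
               collapse = "")
  j60 <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
  m <- effectiveMappability(c(j84, j60))
  expect_identical(m, c(35L, 11L))
})

test_that("rES and rIR match their closed forms on hand-computable triplets", {
  expect_equal(rateES(c(10, 10, 10)), 0.5)
  expect_equal(rateES(c(10, 10, 0)), 0)
  # adjusted-count case: skip junction 10 reads at m=20 -> 17.5
  expect_equal(rateES(c(35, 35, 10), c(35, 35, 20)), 17.5 / 52.5)
  expect_equal(rateIR(c(4, 4, 4)), 0.5)
  expect_equal(rateIR(c(0, 0, 10)), 0)
  expect_equal(rateIR(c(6, 2, 4)), 0.5)  # mean(6,2) = 4
  # rIR = 1 when the spliced junction has no reads
  expect_equal(rateIR(c(5, 5, 0)), 1)
  expect_true(is.na(rateES(c(0, 0, 0))))
  expect_error(rateES(c(-1, 5, 5)), "negative")
})

test_that("rates are scale-invariant and monotone; m = 35 adjustment is identity", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(1:50, 3)
    expect_equal(rateES(n), rateES(n * 7))
    expect_equal(rateIR(n), rateIR(n * 3))
  }
  expect_equal(adjustCounts(c(10, 20), c(35L, 35L)), c(10, 20))
  # monotone in the skip / intron junctions
  es <- vapply(0:20, function(k) rateES(c(10, 10, k)), numeric(1))
  expect_true(all(diff(es) > 0))
  ir <- vapply(0:20, function(k) rateIR(c(k, k, 10)), numeric(1))
  expect_true(all(diff(ir[-1]) > 0))
})

test_that("planted splicing rates are recovered from multinomial counts", {
  cfg <- SyntheticConfig(rngSeed = 23)
  tj <- generateJunctionCounts(cfg, nTriplets = 1, readsPerTriplet = 10000,
                               kind = "ES", plantedRates = 0.5)
  got <- rateES(c(tj$N1, tj$N2, tj$N3), c(tj$m1, tj$m2, tj$m3))
  # binomial-scale error on the skip-read share s = r/(2-r) at n = 10,000
  expect_lt(abs(got - 0.5), 3 * sqrt(0.25 / 10000) * 4)
  tz <- generateJunctionCounts(cfg, nTriplets = 5, readsPerTriplet = 100,
                               kind = "ES", plantedRates = 0)
  expect_true(all(tz$N3 == 0))
  ti <- generateJunctionCounts(cfg, nTriplets = 5, readsPerTriplet = 100,
                               kind = "IR", plantedRates = 1)
  expect_true(all(ti$N3 == 0))
  expect_true(all(vapply(seq_len(5), function(i)
    rateIR(c(ti$N1[i], ti$N2[i], ti$N3[i])), numeric(1)) == 1))
})

test_that("subsampling is deterministic and enforces eligibility", {
  cfg <- SyntheticConfig(rngSeed = 31)
  tis <- list(a = generateJunctionCounts(cfg, nTriplets = 300,
                                         seedOffset = 0))
  s1 <- subsampleTissueRates(tis, "ES", nTriplets = 200, nReads = 5000,
                             nReps = 3, seed = 5)
  s2 <- subsampleTissueRates(tis, "ES", nTriplets = 200, nReads = 5000,
                             nReps = 3, seed = 5)
  expect_identical(s1, s2)
  expect_error(subsampleTissueRates(tis, "ES", nTriplets = 1000,
                                    nReads = 5000, nReps = 2, seed = 1),
               "eligible")
})
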