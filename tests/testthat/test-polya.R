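tagDf <- function(position, count, contig = "c1", strand = "+") {
  data.frame(contig = contig, position = position, strand = strand,
             count = count, stringsAsFactors = FALSE)
}

test_that("tag clustering follows the 20 bp / 40 nt merge semantics", {
  # 10 bp apart: merged, representative is the strongest tag
  cl <- clusterTags(tagDf(c(100, 110), c(5, 3)))
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$position, 100)
  expect_identical(cl$count, 8)
  # 50 bp apart: two clusters survive both passes
  cl2 <- clusterTags(tagDf(c(100, 150), c(5, 3)))
  expect_identical(nrow(cl2), 2L)
  # pass 2: representatives 35 nt apart merge (35 < 40)
  cl3 <- clusterTags(tagDf(c(100, 135), c(5, 3)))
  expect_identical(nrow(cl3), 1L)
  expect_identical(cl3$position, 100)
  expect_identical(cl3$count, 8)
  # exactly 20 bp apart: pass 1 keeps them separate ("closer than 20"),
  # but pass 2 still merges the two representatives (20 < 40)
  expect_identical(nrow(clusterTags(tagDf(c(100, 120), c(5, 3)))), 1L)
  # exactly 40 nt apart: neither pass merges
  expect_identical(nrow(clusterTags(tagDf(c(100, 140), c(5, 3)))), 2L)
  expect_identical(nrow(clusterTags(tagDf(c(100, 139), c(5, 3)))), 1L)
})

test_that("clustering conserves counts and spaces representatives apart", {
  set.seed(18)
  tags <- tagDf(sort(sample(1:2000, 120)),
                sample(1:20, 120, replace = TRUE))
  cl <- clusterTags(tags)
  expect_identical(sum(cl$count), sum(tags$count))
  expect_true(all(diff(cl$position) >= 40))
  # ties broken toward the 3'-most position on the strand
  tiePlus <- clusterTags(tagDf(c(100, 105), c(5, 5)))
  expect_identical(tiePlus$position, 105)
  tieMinus <- clusterTags(tagDf(c(100, 105), c(5, 5), strand = "-"))
  expect_identical(tieMinus$position, 100)
})

test_that("re-clustering representatives is idempotent", {
  set.seed(19)
  tags <- tagDf(sort(sample(1:5000, 80)), sample(1:9, 80, replace = TRUE))
  cl <- clusterTags(tags)
  again <- clusterTags(cl[, c("contig", "position", "strand", "count")])
  expect_identical(again$position, cl$position)
  expect_identical(again$count, cl$count)
})

test_that("strands and contigs are clustered independently", {
  tags <- rbind(tagDf(c(100, 110), c(5, 3), strand = "+"),
                tagDf(c(100, 110), c(2, 7), strand = "-"),
                tagDf(c(100, 110), c(1, 1), contig = "c2"))
  cl <- clusterTags(tags)
  expect_identical(nrow(cl), 3L)
})

test_that("cluster filtering needs continuous coverage or stop-codon overlap", {
  clusters <- data.frame(contig = "c1", strand = "+", position = 120,
                         count = 8, members = "118,120",
                         stopCodon = 100, stringsAsFactors = FALSE)
  fullCov <- data.frame(contig = "c1", position = 100:120, depth = 5)
  expect_identical(nrow(filterClusters(clusters, fullCov)), 1L)
  brokenCov <- fullCov
  brokenCov$depth[10] <- 4  # one base below 5 breaks continuity
  expect_identical(nrow(filterClusters(clusters, brokenCov)), 0L)
  # a member read overlapping the stop codon rescues the cluster
  noCov <- data.frame(contig = character(0), position = integer(0),
                      depth = numeric(0))
  expect_identical(nrow(filterClusters(clusters, noCov,
                                       readLength = 25)), 1L)
  expect_identical(nrow(filterClusters(clusters, noCov,
                                       readLength = 10)), 0L)
  # unassignable clusters are dropped with a message
  na <- clusters; na$stopCodon <- NA
  expect_message(out <- filterClusters(na, fullCov), "no assignable")
  expect_identical(nrow(out), 0L)
})

test_that("PAS assignment scans 50 nt and breaks ties by dataset abundance", {
  expect_identical(assignPas("GGGAATAAAGG"), "AATAAA")
  expect_true(is.na(assignPas("GGGGGGGGGG")))
  # both motifs present; AATAAA more abundant in the dataset
  windows <- c("CCAATAAACCATTAAACC", "GGAATAAAGG", "GGAATAAAGG")
  got <- assignPas(windows)
  expect_identical(got[1], "AATAAA")
  # force the other motif to dominate the dataset
  got2 <- assignPas("CCAATAAACCATTAAACC",
                    datasetFrequencies = c(AATAAA = 1, ATTAAA = 10))
  expect_identical(got2, "ATTAAA")
  # only the 50 nt upstream window is searched
  far <- paste0("AATAAA", paste(rep("C", 60), collapse = ""))
  expect_true(is.na(assignPas(far)))
})

test_that("synthetic tags cluster back to the planted cleavage sites", {
  cfg <- SyntheticConfig(rngSeed = 33)
  tg <- generateTags(cfg, nSites = 40)
  cl <- clusterTags(tg$tags)
  expect_identical(nrow(cl), 40L)
  expect_identical(cl$position, tg$truth$position)
  expect_identical(sum(cl$count), sum(tg$tags$count))
})
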