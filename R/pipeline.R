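#' End-to-end MRE conservation / codetection analysis
#'
#' Chains the full target-site conservation analysis on synthetic data:
#' generate miRNAs, orthologous UTR pairs and expression matrices; derive
#' MRE octamers and scan the alignments; classify each site's codetection
#' from the CPM matrices; build per-miRNA codetection-by-conservation
#' tables and scores; score dinucleotide-shuffled control octamers;
#' standardise the panel to Z scores; and test the coexpressed,
#' non-coexpressed and control rate groups against each other
#' (Mann-Whitney, Bonferroni).
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param nControlsPerMirna shuffled control octamers per miRNA.
#' @param minOccurrences occurrence filter for control rates.
#' @return list with components \code{mirnas}, \code{truth}, \code{sites}
#'   (per-site calls), \code{scores} (per-miRNA data.frame),
#'   \code{controlRates}, \code{zPanel}, \code{groupTests},
#'   \code{armRates} (pooled conservation per codetection arm) and
#'   \code{ageClassRates}.
#' @export
runConservationAnalysis <- function(config, nControlsPerMirna = 2L,
                                    minOccurrences = 10L) {
  stopifnot(is(config, "SyntheticConfig"))
  mirnas <- generateMirnas(config)
  if (nrow(mirnas) == 0L)
    stop("miRNA stage: empty miRNA set, nothing to analyse",
         call. = FALSE)
  pairs <- generateOrthologPairs(config, mirnas)
  expr <- generateExpression(config, mirnas, pairs$truth)

  octamers <- deriveMre(mirnas$matureSeq)
  octToMirna <- mirnas$name[!duplicated(octamers)]
  names(octToMirna) <- octamers[!duplicated(octamers)]

  sites <- scanConservedSites(pairs$alignments, names(octToMirna))
  if (nrow(sites) == 0L)
    stop("conservation stage: no MRE occurrences found", call. = FALSE)
  sites$mirna <- unname(octToMirna[sites$octamer])

  detM <- expr$mirnaCpm >= 100
  detG <- expr$mrnaCpm >= 10
  codetMat <- (detM %*% t(detG)) > 0
  sites$codetected <- codetMat[cbind(match(sites$mirna, rownames(detM)),
                                     match(sites$gene, rownames(detG)))]

  byMirna <- split(sites, sites$mirna)
  scores <- do.call(rbind, lapply(names(byMirna), function(m) {
    tab <- buildConservationTable(byMirna[[m]], label = m)
    sc <- conservationScores(tab)
    data.frame(mirna = m, nSites = length(tab),
               scoreCodetected = sc$codetected,
               scoreNoncodetected = sc$noncodetected,
               stringsAsFactors = FALSE)
  }))

  controls <- unlist(lapply(seq_along(octToMirna), function(i)
    suppressWarnings(dinucleotideShuffle(
      names(octToMirna)[i], n = nControlsPerMirna,
      annotatedMres = names(octToMirna),
      seed = config@rngSeed + 100L + i))))
  controlTab <- conservationRates(pairs$alignments, unique(controls),
                                  minOccurrences = minOccurrences)
  okCtl <- !controlTab$excluded & !is.na(controlTab$rate)
  controlRates <- stats::setNames(controlTab$rate[okCtl],
                                  controlTab$octamer[okCtl])

  panel <- stats::setNames(scores$scoreCodetected,
                           paste0(scores$mirna, ":codet"))
  if (length(controlRates))
    panel <- c(panel, stats::setNames(controlRates,
                                      paste0("ctrl:", names(controlRates))))
  zPanel <- suppressWarnings(zscorePanel(panel))

  groups <- list(
    coexpressed = scores$scoreCodetected[!is.na(scores$scoreCodetected)],
    noncoexpressed =
      scores$scoreNoncodetected[!is.na(scores$scoreNoncodetected)])
  if (length(controlRates) >= 1L) groups$control <- unname(controlRates)
  groupTests <- compareGroups(groups)

  armRates <- c(
    codetected = mean(sites$conserved[sites$codetected]),
    noncodetected = mean(sites$conserved[!sites$codetected]))

  siteAge <- mirnas$ageClass[match(sites$mirna, mirnas$name)]
  ageClassRates <- stats::aggregate(
    sites$conserved, by = list(ageClass = siteAge),
    FUN = function(x) mean(x))
  names(ageClassRates)[2L] <- "conservationRate"

  list(mirnas = mirnas, truth = pairs$truth, sites = sites,
       scores = scores, controlRates = controlRates, zPanel = zPanel,
       groupTests = groupTests, armRates = armRates,
       ageClassRates = ageClassRates)
}

#' Run every analysis stage on synthetic data and write a report
#'
#' Executes the conservation/codetection analysis, the editing-site and
#' editing-index stage (including the MRE/editing intersection), the
#' splicing-rate stage with the cross-tissue subsampling protocol, and the
#' 3'-end tag clustering stage with PAS assignment, all driven by one
#' configuration, and writes tables plus a machine-readable JSON report
#' into \code{outdir}.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param outdir output directory (created if needed).
#' @param subsampleTriplets,subsampleReads,subsampleReps sizes for the
#'   cross-tissue subsampling stage.
#' @return the report, a named list, invisibly.
#' @export
runAll <- function(config, outdir = tempfile("cephamir_run_"),
                   subsampleTriplets = 500L, subsampleReads = 25000L,
                   subsampleReps = 50L) {
  stopifnot(is(config, "SyntheticConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config@rngSeed

  cons <- runConservationAnalysis(config)
  writeTableWithProvenance(cons$scores,
                           file.path(outdir, "mre_scores.tsv"),
                           seed, config)
  writeTableWithProvenance(cons$sites,
                           file.path(outdir, "mre_sites.tsv"),
                           seed, config)
  writeTableWithProvenance(cons$groupTests,
                           file.path(outdir, "group_tests.tsv"),
                           seed, config)

  # editing stage on the reference UTRs (regenerated deterministically
  # from the same config)
  pairs <- generateOrthologPairs(config, cons$mirnas)
  pe <- generateEditingPileups(config, pairs$refSeqs)
  calls <- callEditingSites(pe$pileups)
  idx <- editingIndex(pe$pileups)
  coverageTrack <- data.frame(feature = pe$pileups$feature,
                              position = pe$pileups$position,
                              depth = pe$pileups$A + pe$pileups$C +
                                pe$pileups$G + pe$pileups$T,
                              stringsAsFactors = FALSE)
  consSites <- cons$sites[cons$sites$conserved,
                          c("gene", "position"), drop = FALSE]
  names(consSites)[1L] <- "feature"
  overlap <- mreEditingOverlap(consSites, calls, coverageTrack)
  writeTableWithProvenance(calls,
                           file.path(outdir, "editing_sites.tsv"),
                           seed, config)

  # splicing stage: two tissues with identical planted parameters
  tissues <- list(
    tissueA = generateJunctionCounts(config, seedOffset = 0L),
    tissueB = generateJunctionCounts(config, seedOffset = 1L))
  subs <- subsampleTissueRates(tissues, kind = "ES",
                               nTriplets = subsampleTriplets,
                               nReads = subsampleReads,
                               nReps = subsampleReps,
                               seed = seed + 20L)
  writeTableWithProvenance(as.data.frame(subs),
                           file.path(outdir, "splicing_subsample.tsv"),
                           seed, config)

  # 3'-end stage
  tg <- generateTags(config)
  clusters <- clusterTags(tg$tags)
  restore <- .localRNG(seed + 30L)
  contig <- paste(sample(c("A", "C", "G", "T"),
                         max(clusters$position) + 1L, replace = TRUE),
                  collapse = "")
  restore()
  upstream <- substring(contig, pmax(1L, clusters$position - 49L),
                        clusters$position)
  clusters$pas <- assignPas(upstream)
  writeTableWithProvenance(clusters,
                           file.path(outdir, "polya_clusters.tsv"),
                           seed, config)

  report <- list(
    seed = seed,
    conservation = list(
      armRates = as.list(cons$armRates),
      groupTests = cons$groupTests),
    editing = list(nSitesCalled = nrow(calls),
                   meanEditingIndex = mean(idx, na.rm = TRUE),
                   mreOverlap = overlap),
    splicing = list(meanRateByTissue = as.list(colMeans(subs))),
    polya = list(nClusters = nrow(clusters),
                 nWithPas = sum(!is.na(clusters$pas))))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
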