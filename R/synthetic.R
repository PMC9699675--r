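#' Generate synthetic mature miRNAs
#'
#' Draws \code{nMirnas} mature sequences of 20-23 nt over the RNA alphabet,
#' with unique names, a family label, and a phylogenetic age class drawn
#' from the supplied set (by default the four broad strata relevant to
#' octopus miRNA evolution).
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param ageClasses character vector of age-class labels to sample from.
#' @return data.frame with columns \code{name}, \code{matureSeq} (RNA),
#'   \code{family}, \code{ageClass}.
#' @examples
#' generateMirnas(SyntheticConfig(nMirnas = 3, rngSeed = 7))
#' @export
generateMirnas <- function(config,
                           ageClasses = c("bilaterian", "protostome",
                                          "coleoid", "octopus")) {
  stopifnot(is(config, "SyntheticConfig"))
  n <- config@nMirnas
  if (n == 0L)
    return(data.frame(name = character(0), matureSeq = character(0),
                      family = character(0), ageClass = character(0),
                      stringsAsFactors = FALSE))
  restore <- .localRNG(config@rngSeed)
  on.exit(restore())
  lens <- sample(20:23, n, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
          collapse = ""), character(1))
  name <- sprintf("syn-mir-%03d", seq_len(n))
  data.frame(name = name, matureSeq = seqs,
             family = sub("-[0-9]+$", "", name),
             ageClass = sample(ageClasses, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Generate orthologous 3'UTR pairs with planted MREs
#'
#' Simulates, for each gene, a reference 3'UTR (length log-normal around
#' the configured median) and an orthologous UTR derived from it by
#' background substitutions and single-nucleotide indels. Each gene is
#' assigned one miRNA (round-robin) and a codetection label (fair coin);
#' \code{sitesPerGene} copies of the miRNA's MRE octamer are planted at
#' non-overlapping positions. Each planted site is independently copied
#' intact into the ortholog ("conserved") with the arm's planted
#' probability; non-conserved sites receive one forced substitution inside
#' the octamer. Background mutations and indels are placed outside planted
#' windows, so the realised conservation of planted sites is exactly the
#' planted Bernoulli rate. Because the generator knows every mutation, it
#' emits the true alignment alongside the sequences.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param mirnas data.frame as from \code{\link{generateMirnas}} (nonempty).
#' @return list with \code{alignments} (list of
#'   \linkS4class{UtrAlignment}), \code{refSeqs} and \code{orthSeqs}
#'   (named character vectors), and \code{truth} (data.frame: \code{gene},
#'   \code{mirna}, \code{octamer}, \code{position} 0-based,
#'   \code{conserved}, \code{codetected}).
#' @export
generateOrthologPairs <- function(config, mirnas) {
  stopifnot(is(config, "SyntheticConfig"))
  if (nrow(mirnas) == 0L)
    stop("mirnas must be nonempty", call. = FALSE)
  octamers <- deriveMre(mirnas$matureSeq)
  restore <- .localRNG(config@rngSeed + 1L)
  on.exit(restore())
  bases <- c("A", "C", "G", "T")
  nG <- config@nGenes
  lens <- pmax(30L, as.integer(round(stats::rlnorm(
    nG, meanlog = log(config@utrLengthMedian),
    sdlog = config@utrLengthSdlog))))
  mirnaIdx <- rep_len(seq_len(nrow(mirnas)), nG)
  codet <- stats::runif(nG) < 0.5
  pCons <- ifelse(codet, config@plantedConservationCoexpressed,
                  config@plantedConservationNoncoexpressed)

  alignments <- vector("list", nG)
  refSeqs <- orthSeqs <- character(nG)
  geneNames <- sprintf("gene%05d", seq_len(nG))
  truthRows <- vector("list", nG)
  kept <- logical(nG)
  for (g in seq_len(nG)) {
    L <- lens[g]
    refChars <- sample(bases, L, replace = TRUE)
    # plant non-overlapping sites, redrawing on collision
    nSites <- config@sitesPerGene
    starts0 <- integer(0)  # 0-based
    candidates <- sample.int(L - 7L, min(L - 7L, 50L * nSites)) - 1L
    for (p in candidates) {
      if (length(starts0) == nSites) break
      if (all(abs(p - starts0) >= 8L)) starts0 <- c(starts0, p)
    }
    if (length(starts0) < nSites) {
      warning("gene ", geneNames[g], ": UTR too short to place ",
              nSites, " sites; skipped", call. = FALSE)
      next
    }
    kept[g] <- TRUE
    oct <- octamers[mirnaIdx[g]]
    octChars <- strsplit(oct, "", fixed = TRUE)[[1]]
    for (p in starts0) refChars[(p + 1L):(p + 8L)] <- octChars
    protected <- logical(L)
    for (p in starts0) protected[(p + 1L):(p + 8L)] <- TRUE

    orthChars <- refChars
    subMask <- !protected & stats::runif(L) < config@substitutionRate
    if (any(subMask)) {
      shift <- sample.int(3L, sum(subMask), replace = TRUE)
      orthChars[subMask] <- bases[
        (match(orthChars[subMask], bases) - 1L + shift) %% 4L + 1L]
    }
    conserved <- stats::runif(length(starts0)) < pCons[g]
    for (k in which(!conserved)) {
      pos <- starts0[k] + sample.int(8L, 1L)
      orthChars[pos] <- bases[
        (match(orthChars[pos], bases) - 1L +
           sample.int(3L, 1L)) %% 4L + 1L]
    }
    indelDraw <- stats::runif(L)
    del <- !protected & indelDraw < config@indelRate / 2
    ins <- !protected & indelDraw >= config@indelRate / 2 &
      indelDraw < config@indelRate
    insBase <- sample(bases, L, replace = TRUE)

    refRow <- paste0(refChars, ifelse(ins, "-", ""))
    orthRow <- paste0(ifelse(del, "-", orthChars),
                      ifelse(ins, insBase, ""))
    aRef <- paste(refRow, collapse = "")
    aOrth <- paste(orthRow, collapse = "")
    alignments[[g]] <- UtrAlignment(aRef, aOrth,
                                    geneRef = geneNames[g],
                                    geneOrth = paste0(geneNames[g],
                                                      "_orth"))
    refSeqs[g] <- gsub("-", "", aRef, fixed = TRUE)
    orthSeqs[g] <- gsub("-", "", aOrth, fixed = TRUE)
    truthRows[[g]] <- data.frame(
      gene = geneNames[g], mirna = mirnas$name[mirnaIdx[g]],
      octamer = oct, position = sort(starts0),
      conserved = conserved[order(starts0)], codetected = codet[g],
      stringsAsFactors = FALSE)
  }
  names(refSeqs) <- geneNames
  names(orthSeqs) <- paste0(geneNames, "_orth")
  list(alignments = alignments[kept],
       refSeqs = refSeqs[kept], orthSeqs = orthSeqs[kept],
       truth = do.call(rbind, truthRows[kept]))
}

#' Generate tissue CPM matrices realising the planted codetection labels
#'
#' Builds miRNA x tissue and gene x tissue CPM matrices such that every
#' truth-table codetection label is realised under the default thresholds:
#' each miRNA is highly expressed (>= 100 CPM) in exactly one tissue;
#' genes of codetected pairs are expressed >= 10 CPM in that tissue, genes
#' of non-codetected pairs stay below 10 CPM everywhere. Works for any
#' number of tissues, including one.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param mirnas data.frame from \code{\link{generateMirnas}}.
#' @param truth truth table from \code{\link{generateOrthologPairs}}.
#' @return list with matrices \code{mirnaCpm} and \code{mrnaCpm}.
#' @export
generateExpression <- function(config, mirnas, truth) {
  stopifnot(is(config, "SyntheticConfig"))
  restore <- .localRNG(config@rngSeed + 2L)
  on.exit(restore())
  nT <- config@nTissues
  tissues <- sprintf("tissue%02d", seq_len(nT))
  nM <- nrow(mirnas)
  mirnaCpm <- matrix(stats::runif(nM * nT, 0, 50), nM, nT,
                     dimnames = list(mirnas$name, tissues))
  highTissue <- sample.int(nT, nM, replace = TRUE)
  mirnaCpm[cbind(seq_len(nM), highTissue)] <-
    stats::runif(nM, 150, 1000)
  names(highTissue) <- mirnas$name

  genes <- unique(truth$gene)
  mrnaCpm <- matrix(stats::runif(length(genes) * nT, 0, 5),
                    length(genes), nT,
                    dimnames = list(genes, tissues))
  pairTab <- unique(truth[, c("gene", "mirna", "codetected")])
  codetPairs <- pairTab[pairTab$codetected, , drop = FALSE]
  if (nrow(codetPairs)) {
    rows <- match(codetPairs$gene, genes)
    cols <- highTissue[codetPairs$mirna]
    mrnaCpm[cbind(rows, cols)] <- stats::runif(nrow(codetPairs), 20, 500)
  }
  list(mirnaCpm = mirnaCpm, mrnaCpm = mrnaCpm)
}

#' Generate editing pileups with planted editing fractions
#'
#' For every reference-adenosine position of the supplied UTRs, emits a
#' pileup row at the configured coverage. A fraction
#' \code{editedSiteFraction} of A positions receives planted editing: a
#' per-site level drawn uniformly from \code{editingFractionRange}, with G
#' reads binomial at that level. A further \code{dnaVariantFraction} of
#' the edited positions is also written into the DNA-variant exclusion set
#' (emulating genomic A/G SNPs that RNA-only evidence would miscall as
#' editing).
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param utrs named character vector of DNA sequences.
#' @return list with \code{pileups} (data.frame: \code{feature},
#'   \code{position} 0-based, \code{ref}, \code{A}, \code{C}, \code{G},
#'   \code{T}, \code{inDnaVariants}), \code{dnaVariants} (feature,
#'   position) and \code{truth} (feature, position, plantedFraction).
#' @export
generateEditingPileups <- function(config, utrs) {
  stopifnot(is(config, "SyntheticConfig"))
  restore <- .localRNG(config@rngSeed + 3L)
  on.exit(restore())
  cov <- config@pileupCoverage
  rows <- lapply(names(utrs), function(f) {
    chars <- strsplit(utrs[[f]], "", fixed = TRUE)[[1]]
    aPos <- which(chars == "A") - 1L
    if (!length(aPos)) return(NULL)
    data.frame(feature = f, position = aPos, ref = "A",
               stringsAsFactors = FALSE)
  })
  pile <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  n <- nrow(pile)
  edited <- stats::runif(n) < config@editedSiteFraction
  frac <- ifelse(edited,
                 stats::runif(n, config@editingFractionRange[1L],
                              config@editingFractionRange[2L]), 0)
  g <- stats::rbinom(n, cov, frac)
  pile$A <- cov - g
  pile$C <- 0L
  pile$G <- g
  pile$T <- 0L
  pile$inDnaVariants <- edited & stats::runif(n) < config@dnaVariantFraction
  list(pileups = pile,
       dnaVariants = pile[pile$inDnaVariants, c("feature", "position")],
       truth = data.frame(feature = pile$feature,
                          position = pile$position,
                          plantedFraction = frac,
                          inDnaVariants = pile$inDnaVariants,
                          stringsAsFactors = FALSE))
}

#' Generate junction triplets with planted splicing rates
#'
#' Synthesises \code{nTriplets} junction triplets whose read counts are
#' multinomial with junction probabilities chosen so that the expected
#' splicing rate equals the planted rate: for exon skipping the skip
#' junction receives probability \code{r/(2-r)} (inclusion reads split
#' evenly over E1E2 and E2E3); for intron retention the two intron
#' junctions share \code{2r/(1+r)}. Junction sequences are random 42+42 nt
#' concatenations, so mappability is maximal (35) with overwhelming
#' probability.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param nTriplets number of triplets.
#' @param readsPerTriplet reads drawn per triplet.
#' @param kind \code{"ES"} or \code{"IR"}.
#' @param plantedRates planted rate(s), recycled over triplets.
#' @param seedOffset added to the config seed (use distinct offsets for
#'   independent tissues).
#' @return data.frame with \code{tripletId}, \code{kind}, junction
#'   sequences \code{J1..J3}, raw counts \code{N1..N3}, mappabilities
#'   \code{m1..m3}, and \code{plantedRate}.
#' @export
generateJunctionCounts <- function(config, nTriplets = 1200L,
                                   readsPerTriplet = 50L,
                                   kind = c("ES", "IR"),
                                   plantedRates = 0.1,
                                   seedOffset = 0L) {
  stopifnot(is(config, "SyntheticConfig"))
  kind <- match.arg(kind)
  restore <- .localRNG(config@rngSeed + 4L + seedOffset)
  on.exit(restore())
  r <- rep_len(plantedRates, nTriplets)
  probs <- if (kind == "ES") {
    s <- r / (2 - r)
    rbind((1 - s) / 2, (1 - s) / 2, s)
  } else {
    q <- 2 * r / (1 + r)
    rbind(q / 2, q / 2, 1 - q)
  }
  counts <- vapply(seq_len(nTriplets), function(i)
    as.integer(stats::rmultinom(1L, readsPerTriplet, probs[, i])),
    integer(3))
  junc <- function() vapply(seq_len(nTriplets), function(i)
    paste(sample(c("A", "C", "G", "T"), 84L, replace = TRUE),
          collapse = ""), character(1))
  out <- data.frame(
    tripletId = sprintf("%s%05d", tolower(kind), seq_len(nTriplets)),
    kind = kind, J1 = junc(), J2 = junc(), J3 = junc(),
    N1 = counts[1L, ], N2 = counts[2L, ], N3 = counts[3L, ],
    plantedRate = r, stringsAsFactors = FALSE)
  m <- effectiveMappability(c(out$J1, out$J2, out$J3))
  out$m1 <- m[seq_len(nTriplets)]
  out$m2 <- m[nTriplets + seq_len(nTriplets)]
  out$m3 <- m[2L * nTriplets + seq_len(nTriplets)]
  out[, c("tripletId", "kind", "J1", "J2", "J3",
          "N1", "N2", "N3", "m1", "m2", "m3", "plantedRate")]
}

#' Generate clustered 3'-end tag positions
#'
#' Emits tag positions grouped around true cleavage sites: each site gets
#' a dominant tag plus satellite tags within a few bases, and sites are
#' spaced far enough apart that clustering should recover them.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param nSites number of true cleavage sites.
#' @param tagsPerSite satellite tags per site (in addition to the
#'   dominant tag).
#' @param spacing distance between consecutive true sites (default 200).
#' @return list with \code{tags} (contig, position, strand, count) and
#'   \code{truth} (the true site positions).
#' @export
generateTags <- function(config, nSites = 50L, tagsPerSite = 3L,
                         spacing = 200L) {
  stopifnot(is(config, "SyntheticConfig"))
  restore <- .localRNG(config@rngSeed + 5L)
  on.exit(restore())
  sitePos <- 100L + spacing * (seq_len(nSites) - 1L)
  rows <- lapply(seq_len(nSites), function(i) {
    sat <- unique(sitePos[i] +
                    sample(c(-10:-1, 1:10), tagsPerSite))
    data.frame(contig = "contig1",
               position = c(sitePos[i], sat),
               strand = "+",
               count = c(sample(10:30, 1L),
                         sample(1:5, length(sat), replace = TRUE)),
               stringsAsFactors = FALSE)
  })
  tags <- do.call(rbind, rows)
  tags <- tags[order(tags$position), , drop = FALSE]
  rownames(tags) <- NULL
  list(tags = tags,
       truth = data.frame(contig = "contig1", position = sitePos,
                          stringsAsFactors = FALSE))
}
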