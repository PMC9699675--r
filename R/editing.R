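#' Call A-to-I editing sites from per-position pileups
#'
#' An editing site is a reference-adenosine position with more than 10
#' mapping reads of which at least 3 are guanosine, that is absent from the
#' DNA-variant set (a variant seen in genomic DNA is a SNP, not editing).
#' "More than 10" is strict everywhere: coverage must be at least
#' \code{minCoverage} (default 11).
#'
#' @param pileups data.frame with columns \code{feature}, \code{position}
#'   (0-based), \code{ref}, \code{A}, \code{C}, \code{G}, \code{T} and
#'   logical \code{inDnaVariants}.
#' @param minCoverage minimum total read count at the position (default 11,
#'   i.e. strictly more than 10 reads).
#' @param minG minimum guanosine read count (default 3).
#' @return data.frame of called sites: \code{feature}, \code{position},
#'   \code{gFraction} (G / (A + G)).
#' @examples
#' p <- data.frame(feature = "u1", position = 5, ref = "A",
#'                 A = 8, C = 0, G = 3, T = 0, inDnaVariants = FALSE)
#' callEditingSites(p)
#' @export
callEditingSites <- function(pileups, minCoverage = 11L, minG = 3L) {
  .checkPileups(pileups)
  cov <- pileups$A + pileups$C + pileups$G + pileups$T
  called <- pileups$ref == "A" &
    cov >= minCoverage &
    pileups$G >= minG &
    !pileups$inDnaVariants
  out <- pileups[called, c("feature", "position"), drop = FALSE]
  out$gFraction <- pileups$G[called] /
    (pileups$A[called] + pileups$G[called])
  rownames(out) <- NULL
  out
}

.checkPileups <- function(pileups) {
  required <- c("feature", "position", "ref", "A", "C", "G", "T",
                "inDnaVariants")
  if (!all(required %in% names(pileups)))
    stop("pileups must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  counts <- as.matrix(pileups[, c("A", "C", "G", "T")])
  if (any(counts < 0)) stop("negative read counts", call. = FALSE)
  invisible(TRUE)
}

#' Per-feature A-to-I editing index
#'
#' The editing index of a feature is the total number of guanosines
#' sequenced at its reference-adenosine positions divided by the total
#' number of sequenced adenosines plus guanosines there: a
#' coverage-weighted editing level. C/T reads at reference-A positions are
#' treated as sequencing errors and excluded from the denominator
#' (\code{denominator = "AG"}); set \code{denominator = "all"} to divide by
#' all reads instead.
#'
#' @inheritParams callEditingSites
#' @param denominator \code{"AG"} (default) or \code{"all"}.
#' @return named numeric vector, one index per feature; \code{NA} for
#'   features with no covered reference-A position.
#' @examples
#' p <- data.frame(feature = "u1", position = 0:1, ref = "A",
#'                 A = c(50, 30), C = 0, G = c(0, 20), T = 0,
#'                 inDnaVariants = FALSE)
#' editingIndex(p)  # 20/100 = 0.2
#' @export
editingIndex <- function(pileups, denominator = c("AG", "all")) {
  .checkPileups(pileups)
  denominator <- match.arg(denominator)
  refA <- pileups[pileups$ref == "A", , drop = FALSE]
  den <- if (denominator == "AG") refA$A + refA$G
         else refA$A + refA$C + refA$G + refA$T
  g <- tapply(refA$G, refA$feature, sum)
  d <- tapply(den, refA$feature, sum)
  idx <- ifelse(d > 0, g / d, NA_real_)
  # preserve the feature order of the input
  idx[unique(refA$feature)]
}

#' Maximum seed-editing level per miRNA
#'
#' For each miRNA, over reference-adenosine positions 2-8 (1-based; the
#' seed) with strictly more than 10 mapped reads, reports the maximum
#' guanosine proportion — the highest apparent A-to-I editing level within
#' the seed. miRNAs with no qualifying position are reported \code{NA}.
#'
#' @param baseCounts data.frame of per-position base counts over mature
#'   miRNA references: columns \code{mirna}, \code{position} (1-based),
#'   \code{ref}, \code{A}, \code{C}, \code{G}, \code{T}.
#' @param minCoverage minimum total reads at a position (default 11).
#' @return named numeric vector of maximum seed G proportions.
#' @export
mirnaSeedEditing <- function(baseCounts, minCoverage = 11L) {
  required <- c("mirna", "position", "ref", "A", "C", "G", "T")
  if (!all(required %in% names(baseCounts)))
    stop("baseCounts must have columns ",
         paste(required, collapse = ", "), call. = FALSE)
  cov <- baseCounts$A + baseCounts$C + baseCounts$G + baseCounts$T
  eligible <- baseCounts$ref == "A" &
    baseCounts$position >= 2L & baseCounts$position <= 8L &
    cov >= minCoverage
  mirnas <- unique(baseCounts$mirna)
  prop <- baseCounts$G / cov
  out <- vapply(mirnas, function(m) {
    sel <- eligible & baseCounts$mirna == m
    if (!any(sel)) NA_real_ else max(prop[sel])
  }, numeric(1))
  names(out) <- mirnas
  out
}

#' Intersect conserved MREs with called editing sites
#'
#' Among conserved MRE windows with sufficient RNA-seq coverage (strictly
#' more than 10 reads, summarised over the 8 positions), counts how many
#' overlap at least one called editing site. Windows failing the coverage
#' filter are excluded from the denominator so that absence of editing is
#' never an artefact of missing data.
#'
#' @param mreSites data.frame of conserved MRE windows: \code{feature},
#'   \code{position} (0-based start; the window spans 8 nt).
#' @param editingSites data.frame as returned by
#'   \code{\link{callEditingSites}}.
#' @param coverage data.frame of per-position read depth: \code{feature},
#'   \code{position}, \code{depth}. Positions absent from the track count
#'   as depth 0.
#' @param minCoverage coverage threshold (default 11).
#' @param summarise how to summarise depth over the 8 window positions:
#'   \code{"mean"} (default) or \code{"min"}.
#' @return list with \code{nConsidered}, \code{nEdited} and
#'   \code{fraction}.
#' @export
mreEditingOverlap <- function(mreSites, editingSites, coverage,
                              minCoverage = 11L,
                              summarise = c("mean", "min")) {
  summarise <- match.arg(summarise)
  if (nrow(mreSites) == 0L)
    return(list(nConsidered = 0L, nEdited = 0L, fraction = NA_real_))
  covKey <- paste(coverage$feature, coverage$position)
  winDepth <- vapply(seq_len(nrow(mreSites)), function(i) {
    pos <- mreSites$position[i] + 0:7
    d <- coverage$depth[match(paste(mreSites$feature[i], pos), covKey)]
    d[is.na(d)] <- 0
    if (summarise == "mean") mean(d) else min(d)
  }, numeric(1))
  considered <- winDepth >= minCoverage
  editKey <- paste(editingSites$feature, editingSites$position)
  edited <- vapply(seq_len(nrow(mreSites)), function(i) {
    any(paste(mreSites$feature[i], mreSites$position[i] + 0:7) %in% editKey)
  }, logical(1))
  nCons <- sum(considered)
  nEd <- sum(considered & edited)
  list(nConsidered = nCons, nEdited = nEd,
       fraction = if (nCons > 0L) nEd / nCons else NA_real_)
}

#' Conservation of one-off MREs against their controls
#'
#' Compares the conservation rates of one-off MREs (8-mers one A-to-I
#' editing event away from an MRE) with two control classes: dinucleotide
#' shuffles of the one-off 8-mers, and 8-mers convertible to the MRE by a
#' G-to-A substitution. If functional selection acted on one-off sites,
#' their rates would exceed the controls'.
#'
#' @param alignments list of \linkS4class{UtrAlignment} objects.
#' @param mreOctamers character vector of MRE octamers.
#' @param nShufflesPerOctamer shuffled controls drawn per one-off octamer.
#' @param minOccurrences occurrence filter passed to
#'   \code{\link{conservationRates}}.
#' @param seed integer seed for the shuffles.
#' @return list with per-class rate tables (\code{tables}) and the defined,
#'   non-excluded rate vectors (\code{ratePanels}) ready for
#'   \code{\link{compareGroups}}.
#' @export
oneOffConservationComparison <- function(alignments, mreOctamers,
                                         nShufflesPerOctamer = 5L,
                                         minOccurrences = 10L,
                                         seed = 1L) {
  mreOctamers <- unique(toupper(mreOctamers))
  oneOff <- unique(unlist(lapply(mreOctamers, function(o)
    oneOffPrecursors(o)$precursors)))
  gToA <- unique(unlist(lapply(mreOctamers, function(o)
    oneOffPrecursors(o)$gToAControls)))
  shuffled <- if (length(oneOff)) unique(unlist(lapply(
    seq_along(oneOff), function(i)
      suppressWarnings(dinucleotideShuffle(
        oneOff[i], n = nShufflesPerOctamer,
        annotatedMres = c(mreOctamers, oneOff),
        seed = seed + i))))) else character(0)
  classes <- list(oneOff = oneOff, shuffled = shuffled, gToA = gToA)
  tables <- lapply(classes, function(set) {
    if (length(set) == 0L) return(NULL)
    conservationRates(alignments, set, minOccurrences = minOccurrences)
  })
  panels <- lapply(tables, function(tab) {
    if (is.null(tab)) return(numeric(0))
    ok <- !tab$excluded & !is.na(tab$rate)
    stats::setNames(tab$rate[ok], tab$octamer[ok])
  })
  list(tables = tables, ratePanels = panels)
}
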