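#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Configuration for the synthetic-data generator
#'
#' Holds every tunable parameter of the synthetic transcriptome generator:
#' numbers of genes, miRNAs and tissues, the log-normal 3'UTR length model,
#' inter-species mutation rates, the planted site-conservation probabilities
#' for the codetected and non-codetected arms, and the per-site A-to-I
#' editing level range. All downstream generators consume one of these
#' objects, so a config plus a seed fully determines every synthetic input.
#'
#' @slot nGenes number of genes (orthologous 3'UTR pairs) to simulate.
#' @slot utrLengthMedian median 3'UTR length in nucleotides; lengths are
#'   drawn from a log-normal centred on this median.
#' @slot utrLengthSdlog log-scale standard deviation of the UTR length
#'   distribution.
#' @slot substitutionRate per-site substitution probability between the
#'   reference and ortholog UTR, outside planted sites.
#' @slot indelRate per-site probability of a single-nucleotide insertion or
#'   deletion, placed outside planted sites.
#' @slot nMirnas number of mature miRNAs to simulate.
#' @slot sitesPerGene number of target sites planted per gene.
#' @slot plantedConservationCoexpressed probability that a planted site of a
#'   codetected miRNA-mRNA pair is copied intact into the ortholog.
#' @slot plantedConservationNoncoexpressed same for non-codetected pairs.
#' @slot nTissues number of tissues in the expression matrices.
#' @slot editingFractionRange length-2 numeric, the interval from which
#'   per-site planted editing levels (G fractions) are drawn.
#' @slot editedSiteFraction fraction of reference-A positions that carry
#'   planted editing.
#' @slot dnaVariantFraction fraction of edited positions additionally
#'   recorded as genomic (DNA) variants, which site calling must reject.
#' @slot pileupCoverage read coverage used for simulated pileups.
#' @slot rngSeed integer seed recorded with all generated outputs.
#'
#' @section Validity:
#' All probabilities must lie in [0, 1]; \code{nGenes >= 1}; the planted
#' conservation of the codetected arm must be at least that of the
#' non-codetected arm (the expected direction of selection on functional
#' sites) unless \code{allowInvertedEffect = TRUE} is given to
#' \code{\link{SyntheticConfig}}.
#'
#' @seealso \code{\link{SyntheticConfig}}, \code{\link{generateMirnas}},
#'   \code{\link{generateOrthologPairs}}
#' @name SyntheticConfig-class
#' @rdname SyntheticConfig-class
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(
    nGenes = "integer",
    utrLengthMedian = "numeric",
    utrLengthSdlog = "numeric",
    substitutionRate = "numeric",
    indelRate = "numeric",
    nMirnas = "integer",
    sitesPerGene = "integer",
    plantedConservationCoexpressed = "numeric",
    plantedConservationNoncoexpressed = "numeric",
    nTissues = "integer",
    editingFractionRange = "numeric",
    editedSiteFraction = "numeric",
    dnaVariantFraction = "numeric",
    pileupCoverage = "integer",
    rngSeed = "integer",
    allowInvertedEffect = "logical"
  )
)

setValidity("SyntheticConfig", function(object) {
  msgs <- character(0)
  probs <- c(
    substitutionRate = object@substitutionRate,
    indelRate = object@indelRate,
    plantedConservationCoexpressed = object@plantedConservationCoexpressed,
    plantedConservationNoncoexpressed =
      object@plantedConservationNoncoexpressed,
    editedSiteFraction = object@editedSiteFraction,
    dnaVariantFraction = object@dnaVariantFraction
  )
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad))
    msgs <- c(msgs, paste0("probabilities outside [0,1]: ",
                           paste(bad, collapse = ", ")))
  if (object@nGenes < 1L) msgs <- c(msgs, "nGenes must be >= 1")
  if (object@nMirnas < 0L) msgs <- c(msgs, "nMirnas must be >= 0")
  if (object@nTissues < 1L) msgs <- c(msgs, "nTissues must be >= 1")
  if (length(object@editingFractionRange) != 2L ||
      any(object@editingFractionRange < 0) ||
      any(object@editingFractionRange > 1) ||
      diff(object@editingFractionRange) < 0)
    msgs <- c(msgs, "editingFractionRange must be an interval within [0,1]")
  if (!object@allowInvertedEffect &&
      object@plantedConservationCoexpressed <
        object@plantedConservationNoncoexpressed)
    msgs <- c(msgs, paste0(
      "plantedConservationCoexpressed < plantedConservationNoncoexpressed; ",
      "set allowInvertedEffect = TRUE to simulate an inverted effect"))
  if (length(msgs)) msgs else TRUE
})

#' Create a synthetic-data configuration
#'
#' @param nGenes number of orthologous 3'UTR pairs.
#' @param utrLengthMedian median UTR length (nt).
#' @param utrLengthSdlog log-scale SD of UTR lengths.
#' @param substitutionRate per-site substitution probability.
#' @param indelRate per-site indel probability.
#' @param nMirnas number of mature miRNAs.
#' @param sitesPerGene planted sites per gene.
#' @param plantedConservationCoexpressed planted conservation probability
#'   for sites of codetected pairs.
#' @param plantedConservationNoncoexpressed planted conservation probability
#'   for sites of non-codetected pairs.
#' @param nTissues number of tissues.
#' @param editingFractionRange interval of planted per-site editing levels.
#' @param editedSiteFraction fraction of reference-A positions edited.
#' @param dnaVariantFraction fraction of edited positions also recorded as
#'   DNA variants.
#' @param pileupCoverage simulated read coverage per pileup position.
#' @param rngSeed integer seed.
#' @param allowInvertedEffect allow the codetected arm to be planted less
#'   conserved than the non-codetected arm.
#' @return A validated \linkS4class{SyntheticConfig} object.
#' @examples
#' cfg <- SyntheticConfig(nGenes = 10, nMirnas = 2, rngSeed = 1)
#' cfg
#' @export
SyntheticConfig <- function(nGenes = 500L,
                            utrLengthMedian = 350,
                            utrLengthSdlog = 0.4,
                            substitutionRate = 0.05,
                            indelRate = 0.01,
                            nMirnas = 10L,
                            sitesPerGene = 2L,
                            plantedConservationCoexpressed = 0.6,
                            plantedConservationNoncoexpressed = 0.4,
                            nTissues = 5L,
                            editingFractionRange = c(0.02, 0.2),
                            editedSiteFraction = 0.05,
                            dnaVariantFraction = 0.05,
                            pileupCoverage = 50L,
                            rngSeed = 1L,
                            allowInvertedEffect = FALSE) {
  new("SyntheticConfig",
      nGenes = as.integer(nGenes),
      utrLengthMedian = as.numeric(utrLengthMedian),
      utrLengthSdlog = as.numeric(utrLengthSdlog),
      substitutionRate = as.numeric(substitutionRate),
      indelRate = as.numeric(indelRate),
      nMirnas = as.integer(nMirnas),
      sitesPerGene = as.integer(sitesPerGene),
      plantedConservationCoexpressed =
        as.numeric(plantedConservationCoexpressed),
      plantedConservationNoncoexpressed =
        as.numeric(plantedConservationNoncoexpressed),
      nTissues = as.integer(nTissues),
      editingFractionRange = as.numeric(editingFractionRange),
      editedSiteFraction = as.numeric(editedSiteFraction),
      dnaVariantFraction = as.numeric(dnaVariantFraction),
      pileupCoverage = as.integer(pileupCoverage),
      rngSeed = as.integer(rngSeed),
      allowInvertedEffect = isTRUE(allowInvertedEffect))
}

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig\n",
      "  genes: ", object@nGenes,
      "  miRNAs: ", object@nMirnas,
      "  tissues: ", object@nTissues, "\n",
      "  UTR length: lognormal(median = ", object@utrLengthMedian,
      ", sdlog = ", object@utrLengthSdlog, ")\n",
      "  mutation: subst = ", object@substitutionRate,
      ", indel = ", object@indelRate, "\n",
      "  planted conservation (codetected / non-codetected): ",
      object@plantedConservationCoexpressed, " / ",
      object@plantedConservationNoncoexpressed, "\n",
      "  seed: ", object@rngSeed, "\n", sep = "")
})

#' Gapped pairwise alignment of two orthologous 3'UTRs
#'
#' Represents one global alignment between a reference-species 3'UTR and its
#' ortholog: the two gapped rows plus column-to-sequence coordinate maps
#' used to decide positional homology of target sites.
#'
#' @slot geneRef,geneOrth identifiers of the two orthologs.
#' @slot alignedRef,alignedOrth gapped alignment rows (equal width; gap is
#'   \code{-}).
#' @slot colmapRef,colmapOrth integer vectors, one entry per alignment
#'   column, giving the 0-based sequence coordinate in the respective
#'   ungapped sequence, or \code{NA} at gap columns.
#' @slot score alignment score (\code{NA} for externally supplied
#'   alignments).
#'
#' @section Validity:
#' Both rows have equal width; ungapping each row must reproduce the
#' coordinate maps (one non-NA entry per residue, in order).
#' @seealso \code{\link{alignUtrPair}}, \code{\link{isConservedOccurrence}}
#' @name UtrAlignment-class
#' @rdname UtrAlignment-class
#' @exportClass UtrAlignment
setClass("UtrAlignment",
  representation(
    geneRef = "character",
    geneOrth = "character",
    alignedRef = "character",
    alignedOrth = "character",
    colmapRef = "integer",
    colmapOrth = "integer",
    score = "numeric"
  )
)

setValidity("UtrAlignment", function(object) {
  msgs <- character(0)
  if (nchar(object@alignedRef) != nchar(object@alignedOrth))
    msgs <- c(msgs, "aligned rows differ in width")
  w <- nchar(object@alignedRef)
  if (length(object@colmapRef) != w || length(object@colmapOrth) != w)
    msgs <- c(msgs, "coordinate maps must have one entry per column")
  refChars <- strsplit(object@alignedRef, "", fixed = TRUE)[[1]]
  orthChars <- strsplit(object@alignedOrth, "", fixed = TRUE)[[1]]
  if (w > 0) {
    if (!identical(is.na(object@colmapRef), refChars == "-"))
      msgs <- c(msgs, "colmapRef gaps disagree with alignedRef gaps")
    if (!identical(is.na(object@colmapOrth), orthChars == "-"))
      msgs <- c(msgs, "colmapOrth gaps disagree with alignedOrth gaps")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a UtrAlignment from two gapped rows
#'
#' Coordinate maps are derived from the gap structure. Use this to wrap
#' externally produced (e.g. aligned-FASTA) alignments.
#'
#' @param alignedRef,alignedOrth gapped rows of equal width (gap \code{-}).
#' @param geneRef,geneOrth sequence identifiers.
#' @param score optional alignment score.
#' @return A \linkS4class{UtrAlignment}.
#' @examples
#' UtrAlignment("ACG-T", "ACGGT", "gRef", "gOrth")
#' @export
UtrAlignment <- function(alignedRef, alignedOrth,
                         geneRef = "ref", geneOrth = "orth",
                         score = NA_real_) {
  new("UtrAlignment",
      geneRef = as.character(geneRef), geneOrth = as.character(geneOrth),
      alignedRef = toupper(alignedRef), alignedOrth = toupper(alignedOrth),
      colmapRef = .gappedColmap(toupper(alignedRef)),
      colmapOrth = .gappedColmap(toupper(alignedOrth)),
      score = as.numeric(score))
}

# alignment column -> 0-based ungapped coordinate (NA at gaps)
.gappedColmap <- function(row) {
  chars <- strsplit(row, "", fixed = TRUE)[[1]]
  isRes <- chars != "-"
  map <- rep(NA_integer_, length(chars))
  map[isRes] <- seq_len(sum(isRes)) - 1L
  map
}

setMethod("show", "UtrAlignment", function(object) {
  w <- nchar(object@alignedRef)
  ident <- if (w > 0) {
    a <- strsplit(object@alignedRef, "")[[1]]
    b <- strsplit(object@alignedOrth, "")[[1]]
    sprintf("%.1f%%", 100 * sum(a == b & a != "-") / w)
  } else "NA"
  cat("UtrAlignment ", object@geneRef, " | ", object@geneOrth,
      "  width ", w, "  identity ", ident,
      if (!is.na(object@score)) paste0("  score ", object@score) else "",
      "\n", sep = "")
  if (w > 0) {
    show_w <- min(w, 60L)
    cat("  ", substr(object@alignedRef, 1, show_w),
        if (w > show_w) "..." else "", "\n", sep = "")
    cat("  ", substr(object@alignedOrth, 1, show_w),
        if (w > show_w) "..." else "", "\n", sep = "")
  }
})

#' Codetection-by-conservation contingency table for target sites
#'
#' The 2x2 partition of a miRNA's target sites by whether the miRNA and
#' host mRNA are codetected in at least one tissue, and whether the site is
#' matched exactly at the homologous position of the orthologous 3'UTR.
#' Per-cell distinct host-gene counts are carried alongside the site counts.
#'
#' @slot label an identifier for the site set (e.g. the miRNA name).
#' @slot sites integer cell counts, named
#'   \code{noCodetectMismatch, noCodetectMatch, codetectMismatch,
#'   codetectMatch}.
#' @slot genes integer distinct-gene counts for the same four cells.
#' @seealso \code{\link{buildConservationTable}},
#'   \code{\link{conservationScores}}
#' @name ConservationTable-class
#' @rdname ConservationTable-class
#' @exportClass ConservationTable
setClass("ConservationTable",
  representation(label = "character", sites = "integer", genes = "integer"))

.ctCells <- c("noCodetectMismatch", "noCodetectMatch",
              "codetectMismatch", "codetectMatch")

setValidity("ConservationTable", function(object) {
  msgs <- character(0)
  if (!identical(names(object@sites), .ctCells))
    msgs <- c(msgs, paste0("sites must be named ",
                           paste(.ctCells, collapse = ", ")))
  if (!identical(names(object@genes), .ctCells))
    msgs <- c(msgs, "genes must be named like sites")
  if (any(object@sites < 0L) || any(object@genes < 0L))
    msgs <- c(msgs, "counts must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' @rdname ConservationTable-class
#' @param label identifier for the site set.
#' @param sites,genes length-4 counts in the order no-codetection/mismatch,
#'   no-codetection/match, codetection/mismatch, codetection/match.
#' @return \code{ConservationTable()} returns a
#'   \linkS4class{ConservationTable}.
#' @examples
#' ConservationTable("let-7", sites = c(4, 5, 29, 39),
#'                   genes = c(4, 4, 27, 39))
#' @export
ConservationTable <- function(label, sites, genes = sites) {
  sites <- as.integer(sites); genes <- as.integer(genes)
  names(sites) <- .ctCells; names(genes) <- .ctCells
  new("ConservationTable", label = as.character(label),
      sites = sites, genes = genes)
}

#' @describeIn ConservationTable-class total number of sites in the table.
#' @param x a \code{ConservationTable}.
#' @export
setMethod("length", "ConservationTable", function(x) sum(x@sites))

#' Accessors for ConservationTable cell counts
#'
#' @param x a \linkS4class{ConservationTable}.
#' @return \code{siteCounts} and \code{geneCounts} return the named length-4
#'   integer vectors of site and distinct-gene counts.
#' @name ConservationTable-accessors
#' @export
siteCounts <- function(x) {
  stopifnot(is(x, "ConservationTable"))
  x@sites
}

#' @rdname ConservationTable-accessors
#' @export
geneCounts <- function(x) {
  stopifnot(is(x, "ConservationTable"))
  x@genes
}

setMethod("show", "ConservationTable", function(object) {
  m <- matrix(object@sites, 2, 2, byrow = TRUE,
              dimnames = list(c("no codetection", "codetection"),
                              c("mismatch", "exact match")))
  cat("ConservationTable for ", object@label, " (",
      sum(object@sites), " sites)\n", sep = "")
  print(m)
})
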