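#' Positional k-mer conservation rates across ortholog alignments
#'
#' For every octamer in \code{octamerSet}, scans the ungapped reference row
#' of every alignment for exact occurrences (overlaps included, windows
#' containing N excluded) and computes the fraction of occurrences matched
#' by the identical octamer at the homologous (same alignment columns,
#' gap-free) position of the ortholog. Every occurrence is evaluated
#' independently, so one gene can contribute several occurrences of the
#' same octamer. Octamers observed fewer than \code{minOccurrences} times
#' across the whole alignment set are flagged \code{excluded}: rates from a
#' handful of sites are too noisy to compare.
#'
#' @param alignments list of \linkS4class{UtrAlignment} objects.
#' @param octamerSet character vector of 8 nt octamers (deduplicated;
#'   set \code{deduplicate = FALSE} to keep repeated entries, e.g. when
#'   identical MREs from paralogous miRNAs should be scored once each).
#' @param minOccurrences minimum occurrence count for a usable rate
#'   (default 10).
#' @param deduplicate drop duplicated octamers before scanning.
#' @return a data.frame with one row per octamer: \code{octamer},
#'   \code{nOccurrences}, \code{nConserved}, \code{rate} (NA when there are
#'   no occurrences), \code{excluded}.
#' @seealso \code{\link{isConservedOccurrence}} for the per-occurrence
#'   rule, \code{\link{scanConservedSites}} for the per-site table.
#' @export
conservationRates <- function(alignments, octamerSet, minOccurrences = 10L,
                              deduplicate = TRUE) {
  if (length(octamerSet) == 0L)
    stop("octamerSet must be nonempty", call. = FALSE)
  octamerSet <- toupper(octamerSet)
  if (deduplicate) octamerSet <- unique(octamerSet)
  stopifnot(all(nchar(octamerSet) == 8L))
  sites <- scanConservedSites(alignments, octamerSet)
  nOcc <- nCons <- integer(length(octamerSet))
  if (nrow(sites)) {
    occTab <- table(factor(sites$octamer, levels = octamerSet))
    consTab <- table(factor(sites$octamer[sites$conserved],
                            levels = octamerSet))
    nOcc <- as.integer(occTab)
    nCons <- as.integer(consTab)
  }
  data.frame(
    octamer = octamerSet,
    nOccurrences = nOcc,
    nConserved = nCons,
    rate = ifelse(nOcc > 0L, nCons / nOcc, NA_real_),
    excluded = nOcc < minOccurrences,
    stringsAsFactors = FALSE)
}

#' Scan alignments for octamer occurrences and their conservation
#'
#' The site-level companion of \code{\link{conservationRates}}: one row per
#' occurrence of any octamer of the set in any reference UTR, with the
#' conservation call for that occurrence.
#'
#' @inheritParams conservationRates
#' @return a data.frame with columns \code{gene} (reference gene id),
#'   \code{octamer}, \code{position} (0-based start in the ungapped
#'   reference UTR) and \code{conserved}.
#' @export
scanConservedSites <- function(alignments, octamerSet) {
  octamerSet <- unique(toupper(octamerSet))
  res <- lapply(alignments, function(aln) {
    index <- .alignmentIndex(aln)
    L <- nchar(index$refSeq)
    if (L < 8L) return(NULL)
    starts <- seq_len(L - 7L)
    windows <- substring(index$refSeq, starts, starts + 7L)
    hit <- match(windows, octamerSet)
    keep <- which(!is.na(hit))
    if (!length(keep)) return(NULL)
    data.frame(
      gene = aln@geneRef,
      octamer = octamerSet[hit[keep]],
      position = keep - 1L,
      conserved = vapply(keep - 1L, function(p)
        .conservedAt(index, p, octamerSet[hit[p + 1L]]), logical(1)),
      stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(gene = character(0), octamer = character(0),
                      position = integer(0), conserved = logical(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, res)
}
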