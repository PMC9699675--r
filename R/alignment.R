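#' @importFrom Rcpp sourceCpp
#' @useDynLib cephamir, .registration = TRUE
NULL

#' Globally align two orthologous 3'UTRs
#'
#' Computes a deterministic global pairwise alignment with affine gap
#' penalties (Needleman-Wunsch-Gotoh). A gap of length k costs
#' \code{gapOpen + k * gapExt}. Traceback tie-breaking is fixed (diagonal,
#' then gap-in-ortholog, then gap-in-reference), so identical inputs always
#' yield the identical alignment. Alignments produced by an external
#' aligner can be supplied instead via \code{\link{readAlignedFasta}} or
#' \code{\link{UtrAlignment}}.
#'
#' @param refUtr,orthUtr DNA sequences (nonempty character scalars).
#' @param geneRef,geneOrth identifiers stored in the result.
#' @param match,mismatch,gapOpen,gapExt scoring parameters; defaults
#'   +1/-1/-10/-0.5.
#' @return a \linkS4class{UtrAlignment}.
#' @examples
#' alignUtrPair("ACGTACGT", "ACGTCGT")
#' @export
alignUtrPair <- function(refUtr, orthUtr, geneRef = "ref", geneOrth = "orth",
                         match = 1, mismatch = -1,
                         gapOpen = -10, gapExt = -0.5) {
  refUtr <- toupper(refUtr); orthUtr <- toupper(orthUtr)
  if (!nzchar(refUtr) || !nzchar(orthUtr))
    stop("cannot align an empty sequence", call. = FALSE)
  res <- .nwGotohAlign(refUtr, orthUtr, match, mismatch, gapOpen, gapExt)
  UtrAlignment(res$alignedRef, res$alignedOrth, geneRef, geneOrth,
               score = res$score)
}

#' Ungapped sequences of an alignment
#'
#' @param aln a \linkS4class{UtrAlignment}.
#' @return the reference (or ortholog) sequence with gaps removed.
#' @export
refSequence <- function(aln) gsub("-", "", aln@alignedRef, fixed = TRUE)

#' @rdname refSequence
#' @export
orthSequence <- function(aln) gsub("-", "", aln@alignedOrth, fixed = TRUE)

#' Read pairwise alignments from aligned FASTA
#'
#' Expects records in pairs: each consecutive (reference, ortholog) pair of
#' gapped sequences of equal width becomes one \linkS4class{UtrAlignment}.
#'
#' @param path aligned-FASTA file.
#' @return list of \linkS4class{UtrAlignment} objects.
#' @export
readAlignedFasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) %% 2L != 0L)
    stop("aligned FASTA must contain an even number of records",
         call. = FALSE)
  idx <- seq(1L, length(seqs), by = 2L)
  lapply(idx, function(i) {
    UtrAlignment(as.character(seqs[[i]]), as.character(seqs[[i + 1L]]),
                 geneRef = names(seqs)[i], geneOrth = names(seqs)[i + 1L])
  })
}

#' Write pairwise alignments as aligned FASTA
#'
#' @param alignments list of \linkS4class{UtrAlignment} objects.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAlignedFasta <- function(alignments, path) {
  rows <- unlist(lapply(alignments, function(a)
    c(a@alignedRef, a@alignedOrth)))
  nms <- unlist(lapply(alignments, function(a) c(a@geneRef, a@geneOrth)))
  out <- Biostrings::BStringSet(rows)
  names(out) <- nms
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Is a site occurrence conserved at the homologous aligned position?
#'
#' A site occurrence in the reference 3'UTR counts as conserved only when
#' its 8 positions map to 8 consecutive gap-free alignment columns whose
#' ortholog row spells exactly the same octamer. Any gap in either row
#' inside the window, or any mismatch, breaks positional identity and the
#' occurrence is not conserved.
#'
#' @param aln a \linkS4class{UtrAlignment}.
#' @param posRef 0-based start of the occurrence in the ungapped reference.
#' @param octamer the 8 nt site sequence.
#' @return \code{TRUE} or \code{FALSE}.
#' @examples
#' aln <- UtrAlignment("GGCTACCTCAGG", "GGCTACCTCAGG")
#' isConservedOccurrence(aln, 2, "CTACCTCA")
#' @export
isConservedOccurrence <- function(aln, posRef, octamer) {
  stopifnot(is(aln, "UtrAlignment"))
  octamer <- toupper(octamer)
  k <- nchar(octamer)
  refLen <- sum(!is.na(aln@colmapRef))
  if (posRef < 0L || posRef + k > refLen)
    stop("occurrence window [", posRef, ", ", posRef + k,
         ") out of range for reference of length ", refLen, call. = FALSE)
  env <- .alignmentIndex(aln)
  .conservedAt(env, posRef, octamer)
}

# per-alignment lookup tables used by the conservation scan
.alignmentIndex <- function(aln) {
  refCols <- which(!is.na(aln@colmapRef))       # column of each ref residue
  list(refCols = refCols,
       orthRow = aln@alignedOrth,
       refSeq = gsub("-", "", aln@alignedRef, fixed = TRUE))
}

.conservedAt <- function(index, posRef, octamer) {
  k <- nchar(octamer)
  colFirst <- index$refCols[posRef + 1L]
  colLast <- index$refCols[posRef + k]
  if (colLast - colFirst != k - 1L) return(FALSE)  # insertion in window
  window <- substr(index$orthRow, colFirst, colLast)
  # a gap character in the window makes the comparison fail automatically
  window == octamer
}
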