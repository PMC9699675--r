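#' @importFrom Biostrings matchPattern
NULL

#' Derive the 8mer miRNA response element (MRE) of a mature miRNA
#'
#' The canonical strong-effect target site of a miRNA is the 8mer: the
#' Watson-Crick complement of miRNA seed positions 2-8, written 5'->3' on
#' the mRNA, followed by an adenosine opposite miRNA position 1. The
#' trailing A is a positional feature recognised by Argonaute, not a
#' base-pairing one.
#'
#' @param matureSeq character vector of mature miRNA sequences in the RNA
#'   alphabet (A, C, G, U), each at least 8 nt.
#' @return character vector of 8 nt DNA octamers (seed match + trailing A).
#' @examples
#' deriveMre("UGAGGUAGUAGGUUGUAUAGUU")  # let-7 -> "CTACCTCA"
#' @export
deriveMre <- function(matureSeq) {
  matureSeq <- toupper(matureSeq)
  if (any(nchar(matureSeq) < 8L))
    stop("mature miRNA sequences must be at least 8 nt", call. = FALSE)
  .checkAlphabet(matureSeq, c("A", "C", "G", "U"), "mature miRNA sequence")
  seed <- substr(matureSeq, 2L, 8L)
  paste0(.revcompDna(rnaToDna(seed)), "A")
}

#' Scan a 3'UTR for exact occurrences of an octamer
#'
#' Reports every (possibly overlapping) exact occurrence of an 8 nt site on
#' the sense strand. Windows containing \code{N} never match: assembly gaps
#' are treated conservatively as non-sites.
#'
#' @param utrSeq a single DNA sequence over \{A,C,G,T,N\}.
#' @param octamer an 8 nt DNA string.
#' @return integer vector of 0-based start positions (empty if none).
#' @examples
#' scanUtr("GGCTACCTCAGG", "CTACCTCA")  # 2
#' scanUtr("TATATATATA", "TATATATA")    # 0 2 (overlaps reported)
#' @export
scanUtr <- function(utrSeq, octamer) {
  stopifnot(length(utrSeq) == 1L, length(octamer) == 1L)
  utrSeq <- toupper(utrSeq); octamer <- toupper(octamer)
  if (nchar(octamer) != 8L) stop("octamer must be 8 nt", call. = FALSE)
  .checkAlphabet(utrSeq, c("A", "C", "G", "T", "N"), "UTR sequence")
  .checkAlphabet(octamer, c("A", "C", "G", "T"), "octamer")
  if (nchar(utrSeq) < 8L) return(integer(0))
  hits <- matchPattern(octamer, Biostrings::DNAString(utrSeq), fixed = TRUE)
  as.integer(BiocGenerics::start(hits)) - 1L
}

# all length-8 strings over the dinucleotide multigraph of `octamer`:
# vertices are bases, edges are the 7 observed dinucleotides; every Euler
# path (an ordering that uses each dinucleotide exactly once) spells a
# permutation with identical dinucleotide counts.
.enumerateDinucPermutations <- function(octamer) {
  chars <- strsplit(octamer, "", fixed = TRUE)[[1]]
  stopifnot(length(chars) == 8L)
  edges <- table(from = chars[-8], to = chars[-1])
  vertices <- union(rownames(edges), colnames(edges))
  out <- character(0)
  walk <- function(v, remaining, path) {
    if (sum(remaining) == 0L) {
      out[[length(out) + 1L]] <<- paste(path, collapse = "")
      return(invisible(NULL))
    }
    if (!v %in% rownames(remaining)) return(invisible(NULL))
    nxt <- colnames(remaining)[remaining[v, ] > 0L]
    for (u in nxt) {
      remaining[v, u] <- remaining[v, u] - 1L
      walk(u, remaining, c(path, u))
      remaining[v, u] <- remaining[v, u] + 1L
    }
  }
  m <- matrix(as.integer(edges), nrow = nrow(edges),
              dimnames = dimnames(edges))
  for (v0 in vertices) walk(v0, m, v0)
  unique(out)
}

#' Dinucleotide-preserving control octamers
#'
#' Generates control 8-mers for conservation analyses by permuting the
#' source octamer while preserving its exact dinucleotide multiset (an
#' Euler-path shuffle over the de Bruijn multigraph of dinucleotides), then
#' keeping only permutations that end in adenosine (to match the trailing A
#' of 8mer MREs), are distinct from the source, and are not themselves
#' annotated MREs. Controls are drawn without replacement from this
#' feasible set.
#'
#' @param octamer source 8 nt DNA octamer.
#' @param n number of controls requested.
#' @param annotatedMres character vector of octamers to exclude (the full
#'   annotated MRE set).
#' @param seed integer seed; sampling is deterministic given the seed.
#' @return character vector of control octamers (possibly shorter than
#'   \code{n}, with a warning, if the feasible set is smaller; empty, with a
#'   warning, if no valid permutation exists).
#' @examples
#' dinucleotideShuffle("CTACCTCA", n = 3, seed = 1)
#' dinucleotideShuffle("AAAAAAAA", n = 1, seed = 1)  # empty: no permutation
#' @export
dinucleotideShuffle <- function(octamer, n = 1L, annotatedMres = character(0),
                                seed = 1L) {
  stopifnot(n >= 1L)
  octamer <- toupper(octamer)
  .checkAlphabet(octamer, c("A", "C", "G", "T"), "octamer")
  feasible <- .enumerateDinucPermutations(octamer)
  feasible <- setdiff(feasible, c(octamer, toupper(annotatedMres)))
  feasible <- feasible[endsWith(feasible, "A")]
  if (length(feasible) == 0L) {
    warning("no valid dinucleotide permutation for ", octamer,
            call. = FALSE)
    return(character(0))
  }
  feasible <- sort(feasible)
  if (length(feasible) < n) {
    warning("only ", length(feasible), " of ", n,
            " requested controls exist for ", octamer, call. = FALSE)
    n <- length(feasible)
  }
  rng <- .localRNG(seed)
  on.exit(rng())
  sample(feasible, n, replace = FALSE)
}

# run code under a locally-seeded RNG; returns a restore function
.localRNG <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Enumerate one-off MRE precursors and substitution controls
#'
#' A "one-off MRE" is a genomic 8-mer that would become an MRE if a single
#' A-to-I editing event (read as G) occurred within it: each precursor is
#' obtained from the MRE by replacing exactly one G with an A. The control
#' direction replaces one non-terminal A of the MRE with G (8-mers
#' convertible to the MRE by a G-to-A substitution); the trailing A is a
#' positional feature whose editing cannot create or destroy seed pairing
#' and is therefore never substituted.
#'
#' @param octamer an MRE octamer (8 nt DNA, trailing A).
#' @return a list with components \code{precursors} (one-off MREs, one per
#'   G of the source) and \code{gToAControls} (one per non-terminal A).
#' @examples
#' oneOffPrecursors("CTGCCTCA")$precursors  # "CTACCTCA"
#' oneOffPrecursors("CTACCTCA")$precursors  # none: no G to un-edit
#' @export
oneOffPrecursors <- function(octamer) {
  octamer <- toupper(octamer)
  .checkAlphabet(octamer, c("A", "C", "G", "T"), "octamer")
  stopifnot(nchar(octamer) == 8L)
  chars <- strsplit(octamer, "", fixed = TRUE)[[1]]
  sub1 <- function(positions, replacement) {
    vapply(positions, function(i) {
      x <- chars; x[i] <- replacement; paste(x, collapse = "")
    }, character(1))
  }
  list(
    precursors = unique(sub1(which(chars == "G"), "A")),
    gToAControls = unique(sub1(setdiff(which(chars == "A"), 8L), "G"))
  )
}
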