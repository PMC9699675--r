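#' Build exon-skipping and intron-retention junction triplets
#'
#' From exon coordinates and contig sequences, constructs the junction
#' sequences used for splicing-rate estimation. For exon skipping, every
#' internal exon of a transcript yields a triplet with junctions E1E2,
#' E2E3 and the skip junction E1E3; for intron retention, every intron
#' yields E1I, IE2 and the spliced junction E1E2. Each junction
#' concatenates up to \code{flank} nt (default 42) from each side (shorter
#' exons/introns contribute their full length). Triplets sharing all three
#' junction coordinate keys are reported once (nonredundant).
#'
#' @param annotation data.frame of exons with columns \code{transcript},
#'   \code{contig}, \code{start}, \code{end} (1-based, inclusive); exons of
#'   a transcript must be ordered and non-overlapping.
#' @param contigSeqs named character vector (or DNAStringSet) of contig
#'   sequences.
#' @param flank nucleotides taken from each side of a junction.
#' @return data.frame with one row per triplet: \code{tripletId},
#'   \code{kind} (\code{"ES"} or \code{"IR"}), junction sequences
#'   \code{J1}, \code{J2}, \code{J3} (for ES: E1E2, E2E3, E1E3; for IR:
#'   E1I, IE2, E1E2).
#' @export
buildTriplets <- function(annotation, contigSeqs, flank = 42L) {
  required <- c("transcript", "contig", "start", "end")
  if (!all(required %in% names(annotation)))
    stop("annotation must have columns ",
         paste(required, collapse = ", "), call. = FALSE)
  if (!is.character(contigSeqs))
    contigSeqs <- stats::setNames(as.character(contigSeqs),
                                  names(contigSeqs))
  bad <- annotation$start > annotation$end |
    !(annotation$contig %in% names(contigSeqs))
  if (any(bad))
    stop("malformed exon record(s): ",
         paste(utils::head(which(bad)), collapse = ", "), call. = FALSE)

  takeRight <- function(contig, start, end) {  # last `flank` nt
    s <- max(start, end - flank + 1L)
    substr(contigSeqs[[contig]], s, end)
  }
  takeLeft <- function(contig, start, end) {   # first `flank` nt
    e <- min(end, start + flank - 1L)
    substr(contigSeqs[[contig]], start, e)
  }

  rows <- list()
  for (tx in unique(annotation$transcript)) {
    ex <- annotation[annotation$transcript == tx, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)]))
      stop("overlapping exons in transcript ", tx, call. = FALSE)
    ctg <- ex$contig[1L]
    nEx <- nrow(ex)
    if (nEx >= 3L) {
      for (i in seq_len(nEx - 2L)) {
        e1 <- ex[i, ]; e2 <- ex[i + 1L, ]; e3 <- ex[i + 2L, ]
        key <- paste("ES", ctg, e1$end, e2$start, e2$end, e3$start,
                     sep = ":")
        rows[[key]] <- data.frame(
          tripletId = key, kind = "ES",
          J1 = paste0(takeRight(ctg, e1$start, e1$end),
                      takeLeft(ctg, e2$start, e2$end)),
          J2 = paste0(takeRight(ctg, e2$start, e2$end),
                      takeLeft(ctg, e3$start, e3$end)),
          J3 = paste0(takeRight(ctg, e1$start, e1$end),
                      takeLeft(ctg, e3$start, e3$end)),
          stringsAsFactors = FALSE)
      }
    }
    if (nEx >= 2L) {
      for (i in seq_len(nEx - 1L)) {
        e1 <- ex[i, ]; e2 <- ex[i + 1L, ]
        iStart <- e1$end + 1L; iEnd <- e2$start - 1L
        if (iStart > iEnd) next  # adjacent exons: no intron
        key <- paste("IR", ctg, e1$end, e2$start, sep = ":")
        rows[[key]] <- data.frame(
          tripletId = key, kind = "IR",
          J1 = paste0(takeRight(ctg, e1$start, e1$end),
                      takeLeft(ctg, iStart, iEnd)),
          J2 = paste0(takeRight(ctg, iStart, iEnd),
                      takeLeft(ctg, e2$start, e2$end)),
          J3 = paste0(takeRight(ctg, e1$start, e1$end),
                      takeLeft(ctg, e2$start, e2$end)),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, unname(rows))
  if (is.null(out))
    out <- data.frame(tripletId = character(0), kind = character(0),
                      J1 = character(0), J2 = character(0),
                      J3 = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Effective mappability of junction sequences
#'
#' For each junction, counts the k-mers (default 50-mers) fully contained
#' in it that occur exactly once across the whole junction set — an exact
#' unique-match emulation of mapping junction k-mers back against all
#' junctions. An 84 nt junction of globally unique sequence scores the
#' maximum 84 - 50 + 1 = 35.
#'
#' @param junctionSeqs character vector of junction sequences.
#' @param k k-mer length (default 50).
#' @return integer vector of mappabilities, one per junction (0 for
#'   junctions shorter than \code{k}).
#' @export
effectiveMappability <- function(junctionSeqs, k = 50L) {
  kmersOf <- function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    starts <- seq_len(L - k + 1L)
    substring(s, starts, starts + k - 1L)
  }
  perJunction <- lapply(junctionSeqs, kmersOf)
  allKmers <- unlist(perJunction, use.names = FALSE)
  # an instance is uniquely mappable iff its k-mer occurs once overall
  dup <- duplicated(allKmers) | duplicated(allKmers, fromLast = TRUE)
  origin <- rep.int(seq_along(perJunction), lengths(perJunction))
  m <- integer(length(perJunction))
  if (length(origin)) {
    tallies <- tapply(!dup, origin, sum)
    m[as.integer(names(tallies))] <- as.integer(tallies)
  }
  m
}

#' Mappability-adjusted junction read counts
#'
#' Scales each raw junction count by \code{kMax / m}: the count a junction
#' of full mappability would have received. Junctions with zero
#' mappability give \code{NA}.
#'
#' @param counts numeric vector of raw read counts.
#' @param mappability integer vector of effective mappabilities.
#' @param kMax full mappability (35 for 84 nt junctions and 50-mers).
#' @return numeric vector of adjusted counts.
#' @export
adjustCounts <- function(counts, mappability, kMax = 35L) {
  if (any(counts < 0)) stop("negative read counts", call. = FALSE)
  ifelse(mappability > 0L, counts * kMax / mappability, NA_real_)
}

#' Exon-skipping and intron-retention rates
#'
#' \code{rateES} computes the exon-skipping rate of a triplet from its
#' mappability-adjusted junction counts:
#' \deqn{rES = N_{E1E3} / ((N_{E1E2} + N_{E2E3})/2 + N_{E1E3})}
#' \code{rateIR} computes the intron-retention rate:
#' \deqn{rIR = \bar N_I / (\bar N_I + N_{E1E2}),\quad
#'       \bar N_I = (N_{E1I} + N_{IE2})/2}
#' Counts are passed in triplet order (J1, J2, J3) as produced by
#' \code{\link{buildTriplets}}: for ES \code{(E1E2, E2E3, E1E3)}, for IR
#' \code{(E1I, IE2, E1E2)}. A zero denominator yields \code{NA}.
#'
#' @param counts numeric length-3 vector of raw junction read counts.
#' @param mappability integer length-3 vector; counts are adjusted by
#'   \code{kMax/m} before the rate is formed.
#' @param kMax full mappability.
#' @return the rate, a fraction in [0, 1], or \code{NA} if undefined.
#' @examples
#' rateES(c(10, 10, 10))                       # 0.5
#' rateES(c(35, 35, 10), c(35, 35, 20))        # 17.5/(35+17.5) = 1/3
#' rateIR(c(6, 2, 4))                          # mean(6,2)/(4+4) = 0.5
#' @export
rateES <- function(counts, mappability = c(35L, 35L, 35L), kMax = 35L) {
  a <- adjustCounts(counts, mappability, kMax)
  den <- (a[1L] + a[2L]) / 2 + a[3L]
  if (is.na(den) || den == 0) return(NA_real_)
  unname(a[3L] / den)
}

#' @rdname rateES
#' @export
rateIR <- function(counts, mappability = c(35L, 35L, 35L), kMax = 35L) {
  a <- adjustCounts(counts, mappability, kMax)
  intronMean <- (a[1L] + a[2L]) / 2
  den <- intronMean + a[3L]
  if (is.na(den) || den == 0) return(NA_real_)
  unname(intronMean / den)
}

#' Cross-tissue subsampled splicing-rate distributions
#'
#' Equalises sequencing depth and triplet sets before comparing splicing
#' rates across tissues. Per tissue and repetition: sample
#' \code{nTriplets} eligible triplets without replacement, draw exactly
#' \code{nReads} reads multinomially over the sampled triplets' junction
#' counts, adjust for mappability and average the defined per-triplet
#' rates. Eligible triplets have at least \code{minMajorReads} raw reads on
#' the two major junctions (J1 + J2) and all three mappabilities at least
#' \code{minMappability}.
#'
#' @param tripletCounts named list (one element per tissue) of data.frames
#'   with columns \code{tripletId}, \code{kind}, \code{N1}, \code{N2},
#'   \code{N3}, \code{m1}, \code{m2}, \code{m3}.
#' @param kind \code{"ES"} or \code{"IR"}.
#' @param nTriplets triplets sampled per repetition (default 1000).
#' @param nReads reads drawn per repetition (default 25000).
#' @param nReps repetitions per tissue (default 100).
#' @param minMajorReads eligibility threshold on major-junction reads
#'   (default 5).
#' @param minMappability eligibility threshold on junction mappability
#'   (default 20).
#' @param seed integer seed; the whole protocol is deterministic given it.
#' @return matrix of mean rates, \code{nReps} rows x one column per
#'   tissue.
#' @export
subsampleTissueRates <- function(tripletCounts, kind = c("ES", "IR"),
                                 nTriplets = 1000L, nReads = 25000L,
                                 nReps = 100L, minMajorReads = 5L,
                                 minMappability = 20L, seed = 1L) {
  kind <- match.arg(kind)
  restore <- .localRNG(seed)
  on.exit(restore())
  out <- sapply(names(tripletCounts), function(tissue) {
    tc <- tripletCounts[[tissue]]
    tc <- tc[tc$kind == kind, , drop = FALSE]
    eligible <- (tc$N1 + tc$N2) >= minMajorReads &
      pmin(tc$m1, tc$m2, tc$m3) >= minMappability
    tc <- tc[eligible, , drop = FALSE]
    if (nrow(tc) < nTriplets)
      stop("tissue ", tissue, ": only ", nrow(tc),
           " eligible triplets, need ", nTriplets, call. = FALSE)
    countsM <- as.matrix(tc[, c("N1", "N2", "N3")])
    adjFactor <- 35 / as.matrix(tc[, c("m1", "m2", "m3")])
    adjFactor[!is.finite(adjFactor)] <- NA_real_
    vapply(seq_len(nReps), function(rep) {
      pick <- sample.int(nrow(tc), nTriplets, replace = FALSE)
      reads <- matrix(stats::rmultinom(
        1L, nReads, prob = as.vector(t(countsM[pick, ]))), nrow = 3L)
      a <- t(reads) * adjFactor[pick, ]
      if (kind == "ES") {
        den <- (a[, 1L] + a[, 2L]) / 2 + a[, 3L]
        rates <- ifelse(den > 0, a[, 3L] / den, NA_real_)
      } else {
        intronMean <- (a[, 1L] + a[, 2L]) / 2
        den <- intronMean + a[, 3L]
        rates <- ifelse(den > 0, intronMean / den, NA_real_)
      }
      mean(rates, na.rm = TRUE)
    }, numeric(1))
  })
  matrix(out, nrow = nReps,
         dimnames = list(NULL, names(tripletCounts)))
}
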