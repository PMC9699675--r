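#' Cluster 3'-end tags into cleavage sites
#'
#' Two-pass clustering of long-read 3'-end tag positions. Pass 1 merges
#' tags closer than 20 bp (single linkage) and assigns the summed count to
#' the most supported member position (ties broken toward the 3'-most
#' position on the tag's strand). Pass 2 merges clusters whose
#' representatives are less than 40 nt apart, keeping the representative
#' with the higher count (same tie rule). Tag counts are conserved
#' throughout. Contigs and strands are clustered independently.
#'
#' @param tags data.frame with columns \code{contig}, \code{position}
#'   (0-based), \code{strand} (\code{"+"}/\code{"-"}), \code{count}.
#' @param mergeTags pass-1 distance: tags strictly closer than this merge
#'   (default 20).
#' @param mergeClusters pass-2 distance: representatives strictly closer
#'   than this merge (default 40).
#' @return data.frame of clusters: \code{contig}, \code{strand},
#'   \code{position} (representative), \code{count} (total),
#'   \code{members} (comma-separated member positions).
#' @examples
#' clusterTags(data.frame(contig = "c1", position = c(100, 110, 150),
#'                        strand = "+", count = c(5, 3, 3)))
#' @export
clusterTags <- function(tags, mergeTags = 20L, mergeClusters = 40L) {
  required <- c("contig", "position", "strand", "count")
  if (!all(required %in% names(tags)))
    stop("tags must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  groups <- split(tags, paste(tags$contig, tags$strand))
  res <- lapply(groups, function(g) {
    g <- g[order(g$position), , drop = FALSE]
    # pass 1: single-linkage chains of tags < mergeTags apart
    chain <- cumsum(c(1L, diff(g$position) >= mergeTags))
    cl <- do.call(rbind, lapply(split(g, chain), function(memb) {
      rep <- .representative(memb$position, memb$count, memb$strand[1L])
      data.frame(contig = memb$contig[1L], strand = memb$strand[1L],
                 position = rep, count = sum(memb$count),
                 members = paste(memb$position, collapse = ","),
                 repCount = max(memb$count),
                 stringsAsFactors = FALSE)
    }))
    # pass 2: merge clusters whose representatives are < mergeClusters apart
    cl <- cl[order(cl$position), , drop = FALSE]
    chain2 <- cumsum(c(1L, diff(cl$position) >= mergeClusters))
    do.call(rbind, lapply(split(cl, chain2), function(memb) {
      rep <- .representative(memb$position, memb$repCount,
                             memb$strand[1L])
      data.frame(contig = memb$contig[1L], strand = memb$strand[1L],
                 position = rep, count = sum(memb$count),
                 members = paste(memb$members, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, unname(res))
  out <- out[, c("contig", "strand", "position", "count", "members")]
  rownames(out) <- NULL
  out[order(out$contig, out$strand, out$position), , drop = FALSE]
}

# highest-count member; ties toward the 3'-most position on the strand
.representative <- function(positions, counts, strand) {
  best <- counts == max(counts)
  cand <- positions[best]
  if (strand == "-") min(cand) else max(cand)
}

#' Filter cleavage-site clusters by linkage to an upstream gene
#'
#' A cluster is kept when it can be tied to an annotated upstream stop
#' codon: either continuous short-read coverage of at least
#' \code{minDepth} at every base between the representative position and
#' the stop codon, or at least one member read overlapping the stop codon.
#' Clusters with no assignable upstream gene are dropped (with a message).
#'
#' @param clusters data.frame as returned by \code{\link{clusterTags}},
#'   plus a column \code{stopCodon} giving the assigned upstream stop-codon
#'   position (NA if unassignable).
#' @param coverage data.frame of per-base short-read depth: \code{contig},
#'   \code{position}, \code{depth} (absent positions count 0).
#' @param minDepth required continuous coverage (default 5).
#' @param readLength length of member reads used for the stop-codon
#'   overlap test (member position is the 3' end; default 1 tests the tag
#'   position itself).
#' @return the retained rows of \code{clusters}.
#' @export
filterClusters <- function(clusters, coverage, minDepth = 5L,
                           readLength = 1L) {
  if (!"stopCodon" %in% names(clusters))
    stop("clusters must carry a stopCodon column", call. = FALSE)
  covKey <- paste(coverage$contig, coverage$position)
  keep <- vapply(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    if (is.na(cl$stopCodon)) {
      message("dropping cluster at ", cl$contig, ":", cl$position,
              ": no assignable upstream gene")
      return(FALSE)
    }
    span <- seq(min(cl$position, cl$stopCodon),
                max(cl$position, cl$stopCodon))
    d <- coverage$depth[match(paste(cl$contig, span), covKey)]
    d[is.na(d)] <- 0
    if (all(d >= minDepth)) return(TRUE)
    members <- as.integer(strsplit(cl$members, ",")[[1]])
    # a member read covers [pos - readLength + 1, pos] on +, mirrored on -
    any(vapply(members, function(p) {
      if (cl$strand == "-") cl$stopCodon >= p &&
        cl$stopCodon <= p + readLength - 1L
      else cl$stopCodon <= p && cl$stopCodon >= p - readLength + 1L
    }, logical(1)))
  }, logical(1))
  clusters[keep, , drop = FALSE]
}

#' Canonical metazoan polyadenylation-signal hexamers
#'
#' The default motif table: the canonical AATAAA, its strongest variant
#' ATTAAA, and ten further single-substitution variants described across
#' metazoans. The table is a plain character vector ordered by typical
#' abundance and fully configurable in \code{\link{assignPas}}.
#'
#' @return character vector of 12 hexamers.
#' @export
pasMotifs <- function() {
  c("AATAAA", "ATTAAA", "TATAAA", "AGTAAA", "AAGAAA", "AATATA",
    "AATACA", "CATAAA", "GATAAA", "AATGAA", "TTTAAA", "ACTAAA")
}

#' Assign a polyadenylation signal to a cleavage site
#'
#' Scans the 50 nt of sequence upstream of the cleavage site for known PAS
#' hexamers. When several distinct motifs occur in the window, the one
#' more abundant across the whole dataset wins (ties broken by motif table
#' order). Windows shorter than 50 nt are searched in full.
#'
#' @param upstreamSeq character vector: the (up to) 50 nt upstream of each
#'   cleavage site, 5'->3'.
#' @param motifs character vector of candidate hexamers, in priority order
#'   (default \code{\link{pasMotifs}()}).
#' @param datasetFrequencies optional named numeric vector of dataset-wide
#'   motif frequencies used for the tie-break; when \code{NULL} they are
#'   computed from \code{upstreamSeq} itself (occurrence counts of each
#'   motif across all windows).
#' @return character vector of assigned motifs (\code{NA} where no motif
#'   occurs).
#' @examples
#' assignPas(c("GGGAATAAAGG", "GGGGGG"))
#' @export
assignPas <- function(upstreamSeq, motifs = pasMotifs(),
                      datasetFrequencies = NULL) {
  upstreamSeq <- toupper(upstreamSeq)
  windows <- substr(upstreamSeq,
                    pmax(1L, nchar(upstreamSeq) - 50L + 1L),
                    nchar(upstreamSeq))
  present <- sapply(motifs, function(m)
    grepl(m, windows, fixed = TRUE))
  present <- matrix(present, nrow = length(windows),
                    dimnames = list(NULL, motifs))
  if (is.null(datasetFrequencies))
    datasetFrequencies <- colSums(present)
  freq <- datasetFrequencies[motifs]
  freq[is.na(freq)] <- 0
  # stable priority: dataset frequency, then table order
  priority <- order(-freq, seq_along(motifs))
  ranked <- motifs[priority]
  apply(present[, ranked, drop = FALSE], 1L, function(hit) {
    i <- which(hit)
    if (length(i)) ranked[i[1L]] else NA_character_
  })
}
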