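# shared independent oracles and fixture builders

randomDna <- function(n, min = 20, max = 60) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), sample(min:max, 1),
                 replace = TRUE), collapse = ""), character(1))
}

randomRna <- function(n, min = 20, max = 23) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), sample(min:max, 1),
                 replace = TRUE), collapse = ""), character(1))
}

# naive O(L*8) sliding-window scan (0-based starts)
naiveScan <- function(utr, octamer) {
  L <- nchar(utr)
  if (L < 8) return(integer(0))
  hits <- integer(0)
  for (p in 0:(L - 8)) {
    if (substr(utr, p + 1, p + 8) == octamer) hits <- c(hits, p)
  }
  hits
}

dinucCounts <- function(s) {
  chars <- strsplit(s, "")[[1]]
  di <- paste0(chars[-length(chars)], chars[-1])
  table(factor(di, levels = as.vector(outer(c("A", "C", "G", "T"),
                                            c("A", "C", "G", "T"),
                                            paste0))))
}

# exhaustive feasible set: all 8-mers over ACGT with the same dinucleotide
# multiset as `s` (brute force over the full 4^8 space)
bruteForceDinucSet <- function(s) {
  all8 <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 8),
                                      stringsAsFactors = FALSE))
  ref <- dinucCounts(s)
  all8[vapply(all8, function(x) identical(as.vector(dinucCounts(x)),
                                          as.vector(ref)), logical(1))]
}

# walk an alignment column by column and test conservation of the window
# starting at 0-based reference position p (independent of the package's
# coordinate-map machinery)
bruteForceConserved <- function(alignedRef, alignedOrth, p, octamer) {
  ra <- strsplit(alignedRef, "")[[1]]
  oa <- strsplit(alignedOrth, "")[[1]]
  refPos <- -1L
  cols <- integer(0)
  for (j in seq_along(ra)) {
    if (ra[j] != "-") {
      refPos <- refPos + 1L
      if (refPos >= p && refPos < p + 8) cols <- c(cols, j)
    }
  }
  if (length(cols) < 8) stop("window out of range")
  # homologous window: must be 8 adjacent columns, no gap in either row,
  # ortholog spelling the octamer
  if (any(diff(cols) != 1L)) return(FALSE)
  if (any(oa[cols] == "-")) return(FALSE)
  paste(oa[cols], collapse = "") == octamer
}

# exact two-sided Mann-Whitney p-value by complete enumeration of group
# assignments (no ties assumed)
exactMannWhitneyP <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  uOf <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  uObs <- uOf(seq_len(na))
  allIdx <- utils::combn(length(pooled), na)
  us <- apply(allIdx, 2, uOf)
  pLow <- mean(us <= uObs)
  pHigh <- mean(us >= uObs)
  min(1, 2 * min(pLow, pHigh))
}

# brute-force 50-mer dictionary mappability
bruteForceMappability <- function(junctions, k = 50) {
  dict <- list()
  for (j in seq_along(junctions)) {
    L <- nchar(junctions[j])
    if (L < k) next
    for (s in 1:(L - k + 1)) {
      km <- substr(junctions[j], s, s + k - 1)
      dict[[km]] <- c(dict[[km]], j)
    }
  }
  vapply(seq_along(junctions), function(j) {
    L <- nchar(junctions[j])
    if (L < k) return(0L)
    cnt <- 0L
    for (s in 1:(L - k + 1)) {
      km <- substr(junctions[j], s, s + k - 1)
      if (length(dict[[km]]) == 1L) cnt <- cnt + 1L
    }
    cnt
  }, integer(1))
}

# reconstruct the printed let-7 example as a per-site list:
# cells (sites, genes): no-codet/mismatch (4,4), no-codet/match (5,4),
# codet/mismatch (29,27), codet/match (39,39)
let7SiteFixture <- function() {
  gene <- function(prefix, nSites, nGenes) {
    # distribute nSites over nGenes distinct genes (first gene absorbs
    # the surplus)
    ids <- paste0(prefix, seq_len(nGenes))
    c(ids, rep(ids[1], nSites - nGenes))
  }
  data.frame(
    gene = c(gene("ncmm", 4, 4), gene("ncex", 5, 4),
             gene("cdmm", 29, 27), gene("cdex", 39, 39)),
    codetected = rep(c(FALSE, FALSE, TRUE, TRUE), c(4, 5, 29, 39)),
    conserved = rep(c(FALSE, TRUE, FALSE, TRUE), c(4, 5, 29, 39)),
    stringsAsFactors = FALSE)
}
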