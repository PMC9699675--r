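#' Classify miRNA-mRNA codetection from CPM profiles
#'
#' A miRNA and an mRNA are "codetected" when at least one tissue expresses
#' both simultaneously at or above the thresholds: by default 100 CPM for
#' the miRNA and 10 CPM for the mRNA. Comparisons are inclusive
#' ("recovered at" the threshold counts).
#'
#' @param mirnaCpm,mrnaCpm numeric vectors of CPM values over the same
#'   ordered tissue set. If both carry names, the names must agree.
#' @param mirnaThreshold,mrnaThreshold detection thresholds in CPM.
#' @return \code{TRUE} if some tissue passes both thresholds.
#' @examples
#' classifyCodetection(c(150, 0), c(12, 500))  # TRUE (tissue 1)
#' classifyCodetection(c(150, 0), c(0, 500))   # FALSE (no shared tissue)
#' @export
classifyCodetection <- function(mirnaCpm, mrnaCpm,
                                mirnaThreshold = 100, mrnaThreshold = 10) {
  if (length(mirnaCpm) != length(mrnaCpm))
    stop("expression profiles cover different tissue sets", call. = FALSE)
  if (!is.null(names(mirnaCpm)) && !is.null(names(mrnaCpm)) &&
      !identical(names(mirnaCpm), names(mrnaCpm)))
    stop("tissue names differ between the two profiles", call. = FALSE)
  any(mirnaCpm >= mirnaThreshold & mrnaCpm >= mrnaThreshold)
}

#' Build the codetection-by-conservation table from a site list
#'
#' Each site carries a \code{conserved} and a \code{codetected} flag and
#' a host \code{gene}; every site increments exactly one of the four cells.
#' Distinct-gene counts per cell are tallied alongside.
#'
#' @param sites data.frame with columns \code{gene}, \code{conserved},
#'   \code{codetected} (logical, no NAs).
#' @param label identifier for the resulting table (e.g. the miRNA name).
#' @return a \linkS4class{ConservationTable}.
#' @examples
#' sites <- data.frame(gene = c("g1", "g1", "g2"),
#'                     conserved = c(TRUE, FALSE, TRUE),
#'                     codetected = c(TRUE, TRUE, FALSE))
#' buildConservationTable(sites)
#' @export
buildConservationTable <- function(sites, label = "sites") {
  required <- c("gene", "conserved", "codetected")
  if (!all(required %in% names(sites)))
    stop("sites must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  if (anyNA(sites$conserved) || anyNA(sites$codetected))
    stop("conserved/codetected flags must be set for every site",
         call. = FALSE)
  cell <- function(codet, cons) {
    sel <- sites$codetected == codet & sites$conserved == cons
    c(sites = sum(sel), genes = length(unique(sites$gene[sel])))
  }
  cells <- cbind(cell(FALSE, FALSE), cell(FALSE, TRUE),
                 cell(TRUE, FALSE), cell(TRUE, TRUE))
  ConservationTable(label, sites = cells["sites", ],
                    genes = cells["genes", ])
}

#' Conservation scores of the codetected and non-codetected arms
#'
#' Within each codetection arm, the score is the fraction of sites matched
#' exactly at the homologous ortholog position: matches / (matches +
#' mismatches). An empty arm yields \code{NA} (undefined), never 0.
#'
#' @param table a \linkS4class{ConservationTable}.
#' @param level \code{"sites"} (default) scores pooled sites;
#'   \code{"genes"} scores distinct host genes per cell.
#' @return named list with \code{codetected} and \code{noncodetected}
#'   scores.
#' @examples
#' tab <- ConservationTable("let-7", sites = c(4, 5, 29, 39))
#' conservationScores(tab)  # 39/68 and 5/9
#' @export
conservationScores <- function(table, level = c("sites", "genes")) {
  stopifnot(is(table, "ConservationTable"))
  level <- match.arg(level)
  n <- if (level == "sites") table@sites else table@genes
  arm <- function(mismatch, match) {
    tot <- n[[mismatch]] + n[[match]]
    if (tot == 0L) NA_real_ else n[[match]] / tot
  }
  list(codetected = arm("codetectMismatch", "codetectMatch"),
       noncodetected = arm("noCodetectMismatch", "noCodetectMatch"))
}

#' Convert a panel of conservation rates to Z scores
#'
#' Standardises each rate against the mean and standard deviation of all
#' defined rates in the panel. The panel is the plotting unit: site rates
#' and their shuffled-control rates standardised together put the control
#' distribution near zero.
#'
#' @param rates named numeric vector of conservation rates (NAs dropped
#'   with a warning).
#' @return named numeric vector of Z scores.
#' @examples
#' zscorePanel(c(a = 0.2, b = 0.4, c = 0.6))
#' @export
zscorePanel <- function(rates) {
  if (anyNA(rates)) {
    warning("dropping ", sum(is.na(rates)), " undefined rates",
            call. = FALSE)
    rates <- rates[!is.na(rates)]
  }
  if (length(rates) < 2L)
    stop("need at least 2 defined rates to standardise", call. = FALSE)
  s <- stats::sd(rates)
  if (s == 0)
    stop("all rates identical: Z scores undefined (sd = 0)", call. = FALSE)
  (rates - mean(rates)) / s
}

#' Pairwise Mann-Whitney comparisons with Bonferroni correction
#'
#' Runs a two-sided Mann-Whitney (Wilcoxon rank-sum) U test for every pair
#' of groups and multiplies raw p-values by the number of pairs performed
#' (capped at 1). Labels follow the usual convention: \code{n.s.} for
#' p > 0.05, \code{*} for p <= 0.05, \code{**} for p < 0.01, \code{***} for
#' p < 0.001, judged on the corrected p-value.
#'
#' @param groups named list of numeric vectors (each nonempty).
#' @return data.frame with one row per pair: \code{groupA}, \code{groupB},
#'   \code{U}, \code{pRaw}, \code{pBonferroni}, \code{label}.
#' @examples
#' compareGroups(list(a = 1:5, b = 6:10 + 0.5))
#' @export
compareGroups <- function(groups) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named", call. = FALSE)
  if (any(lengths(groups) == 0L))
    stop("empty group: ",
         paste(names(groups)[lengths(groups) == 0L], collapse = ", "),
         call. = FALSE)
  pairs <- utils::combn(names(groups), 2L)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(i) {
    a <- groups[[pairs[1L, i]]]
    b <- groups[[pairs[2L, i]]]
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided"))
    data.frame(groupA = pairs[1L, i], groupB = pairs[2L, i],
               U = unname(wt$statistic), pRaw = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pBonferroni <- pmin(out$pRaw * m, 1)
  out$label <- .significanceLabel(out$pBonferroni)
  out
}

.significanceLabel <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p <= 0.05, "*", "n.s.")))
}
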