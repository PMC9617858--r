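#' Classify a long read at a breakpoint as wild-type or rearranged
#'
#' A read is wild-type (WT) evidence when its mapping quality is at least
#' \code{minq} and one contiguous alignment spans the full
#' \code{[pos - margin, pos + margin]} window. It is rearranged (CGR)
#' evidence when, at sufficient mapping quality, the alignment passes only
#' one side of the breakpoint (ends beyond one margin boundary but not
#' both) and a supplementary alignment places the rest of the read
#' elsewhere in the genome. Reads ending inside the margin window without a
#' supplementary alignment, or below the quality threshold, are
#' uninformative (NoBpInfo).
#'
#' @param alnStart,alnEnd contiguous alignment span of the read's primary
#'   alignment overlapping the breakpoint (0-based half-open)
#' @param mapq mapping quality
#' @param hasSupplementary whether the read has a supplementary alignment
#'   elsewhere
#' @param pos breakpoint position (0-based)
#' @param margin half-window in bp
#' @param minq mapping-quality threshold
#' @return \code{"WT"}, \code{"CGR"} or \code{"NoBpInfo"}
#' @export
classifyReadAtBreakpoint <- function(alnStart, alnEnd, mapq,
                                     hasSupplementary, pos,
                                     margin = 90, minq = 20) {
  lo <- pos - margin
  hi <- pos + margin
  n <- max(length(alnStart), 1L)
  out <- character(n)
  for (k in seq_len(n)) {
    if (mapq[k] < minq) { out[k] <- "NoBpInfo"; next }
    spans <- alnStart[k] <= lo && alnEnd[k] >= hi
    if (spans) { out[k] <- "WT"; next }
    endsInside <- (alnEnd[k] > lo && alnEnd[k] < hi) ||
      (alnStart[k] > lo && alnStart[k] < hi)
    if (endsInside && !hasSupplementary[k]) { out[k] <- "NoBpInfo"; next }
    passesOneSide <- (alnStart[k] <= lo && alnEnd[k] > lo) ||
      (alnEnd[k] >= hi && alnStart[k] < hi)
    if (passesOneSide && hasSupplementary[k]) out[k] <- "CGR"
    else out[k] <- "NoBpInfo"
  }
  out
}

#' Vote on which haplotype carries the rearrangement in a phase set
#'
#' Reads carrying both a haplotype tag (H1/H2) and a breakpoint class
#' (WT/CGR) are votes: scenario A (WT on H1, CGR on H2) collects WT/H1 and
#' CGR/H2 reads, scenario B the mirror combinations. The majority scenario
#' labels the phase set; ties are unresolved. Votes for the losing scenario
#' are reported as conflicts.
#'
#' @param haplotype character vector of read haplotype tags
#'   (\code{"H1"}, \code{"H2"}, \code{"NoHapInfo"})
#' @param bpClass character vector of breakpoint classes
#'   (\code{"WT"}, \code{"CGR"}, \code{"NoBpInfo"})
#' @param phaseSet phase-set identifier (scalar, bookkeeping only)
#' @return list with \code{phaseSet}, \code{label} (\code{"CGR=H1"},
#'   \code{"CGR=H2"} or \code{"unresolved"}), the four vote counts and
#'   \code{conflicts}
#' @export
votePhaseSet <- function(haplotype, bpClass, phaseSet = NA) {
  wtH1 <- sum(haplotype == "H1" & bpClass == "WT")
  wtH2 <- sum(haplotype == "H2" & bpClass == "WT")
  cgrH1 <- sum(haplotype == "H1" & bpClass == "CGR")
  cgrH2 <- sum(haplotype == "H2" & bpClass == "CGR")
  a <- wtH1 + cgrH2   # CGR on H2
  b <- wtH2 + cgrH1   # CGR on H1
  label <- if (a == b) "unresolved" else if (a > b) "CGR=H2" else "CGR=H1"
  list(phaseSet = phaseSet, label = label,
       votes = c(WT_H1 = wtH1, WT_H2 = wtH2, CGR_H1 = cgrH1,
                 CGR_H2 = cgrH2),
       conflicts = min(a, b))
}

#' Expand phase-set labels to a genome-wide allele assignment
#'
#' Under the assumption that all rearrangements originate from a single
#' allele, every resolved phase set maps its haplotypes onto the global CGR
#' and WT alleles; unresolved sets are excluded from allele-specific
#' counting and logged.
#'
#' @param labels list of \code{\link{votePhaseSet}} results
#' @return data.frame: \code{phaseSet}, \code{cgrHaplotype}
#'   (\code{"H1"}/\code{"H2"}), with unresolved sets dropped
#' @export
expandLabels <- function(labels) {
  ps <- vapply(labels, function(x) as.character(x$phaseSet), character(1))
  if (anyDuplicated(ps[!is.na(ps)]))
    stop("contradictory double-labeling: phase set labeled more than once")
  lab <- vapply(labels, function(x) x$label, character(1))
  keep <- lab != "unresolved"
  if (any(!keep))
    message(sum(!keep), " unresolved phase set(s) excluded")
  data.frame(phaseSet = ps[keep],
             cgrHaplotype = sub("CGR=", "", lab[keep]))
}

#' Per-gene allele-specific read counts
#'
#' Aggregates phased RNA-seq read assignments into per-gene, per-allele,
#' per-replicate counts and drops genes with fewer than \code{minReads}
#' phased reads in total (too few informative heterozygous variants).
#'
#' @param phased data.frame with columns \code{gene}, \code{allele}
#'   (\code{"CGR"}/\code{"WT"}) and \code{replicate}
#' @param minReads minimum total phased reads per gene
#' @return data.frame: \code{gene}, \code{replicate}, \code{cgr},
#'   \code{wt}, \code{total}
#' @export
countAlleles <- function(phased, minReads = 16L) {
  tot <- table(phased$gene)
  keep <- names(tot)[tot >= minReads]
  phased <- phased[phased$gene %in% keep, , drop = FALSE]
  if (nrow(phased) == 0L)
    return(data.frame(gene = character(), replicate = character(),
                      cgr = numeric(), wt = numeric(), total = numeric()))
  agg <- stats::aggregate(list(n = rep(1L, nrow(phased))),
                          by = list(gene = phased$gene,
                                    replicate = phased$replicate,
                                    allele = phased$allele),
                          FUN = sum)
  wide <- stats::reshape(agg, idvar = c("gene", "replicate"),
                         timevar = "allele", direction = "wide")
  cgr <- wide[["n.CGR"]]; wt <- wide[["n.WT"]]
  cgr[is.na(cgr)] <- 0; wt[is.na(wt)] <- 0
  out <- data.frame(gene = wide$gene, replicate = wide$replicate,
                    cgr = cgr, wt = wt, total = cgr + wt)
  out[order(out$gene, out$replicate), , drop = FALSE]
}

#' Call allelic imbalance genes
#'
#' Preferred input is an external differential-expression table with
#' per-gene \code{log2FC} and \code{padj} (CGR vs WT contrast across
#' replicates). When only raw allelic counts are available, a self-contained
#' stand-in pools counts across replicates, tests each gene with an exact
#' binomial test against a balanced 50/50 expectation, and BH-adjusts the
#' p-values; this simpler model ignores replicate-level dispersion and is
#' flagged in the output. A gene is an allelic imbalance gene (AIG) when
#' \code{abs(log2FC) > lfc} and \code{padj < alpha}; genes without a
#' computable padj are excluded.
#'
#' @param x either a data.frame with \code{gene}, \code{log2FC},
#'   \code{padj}, or allelic counts from \code{\link{countAlleles}}
#' @param lfc,alpha AIG thresholds
#' @param excludeGenes optional genes to drop (e.g. sex-chromosome genes)
#' @return data.frame: \code{gene}, \code{log2FC}, \code{padj}, \code{aig},
#'   \code{method}
#' @export
callAig <- function(x, lfc = 1.0, alpha = 0.05, excludeGenes = NULL) {
  if (all(c("log2FC", "padj") %in% names(x))) {
    tab <- x[, c("gene", "log2FC", "padj")]
    tab$method <- "external"
  } else {
    pooled <- stats::aggregate(cbind(cgr, wt) ~ gene, data = x, FUN = sum)
    pooled$log2FC <- log2(pooled$cgr / pooled$wt)
    pooled$p <- vapply(seq_len(nrow(pooled)), function(k)
      stats::binom.test(round(pooled$cgr[k]),
                        round(pooled$cgr[k] + pooled$wt[k]))$p.value,
      numeric(1))
    pooled$padj <- stats::p.adjust(pooled$p, method = "BH")
    tab <- pooled[, c("gene", "log2FC", "padj")]
    tab$method <- "binomial"
  }
  if (!is.null(excludeGenes))
    tab <- tab[!(tab$gene %in% excludeGenes), , drop = FALSE]
  dropped <- is.na(tab$padj)
  tab <- tab[!dropped, , drop = FALSE]
  tab$aig <- abs(tab$log2FC) > lfc & tab$padj < alpha
  rownames(tab) <- NULL
  tab
}
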