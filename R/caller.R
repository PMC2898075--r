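## Nucleosome calling: score-peak detection with low-score filtering and
## greedy proximity suppression; gene-relative ordinal assignment.

#' Call nucleosome center positions from a score track
#'
#' Nucleosome centers are peaks of the Gaussian-smoothed score track that are
#' (i) not among the lowest-scoring fraction of raw peaks and (ii) not within
#' \code{min_spacing} bp of another peak with higher score. All strict local
#' maxima are detected (plateaus resolve to their leftmost bp), the lowest
#' \code{low_score_quantile} fraction per chromosome is dropped, and the
#' remainder is processed greedily in descending score order (ties: leftmost
#' first), discarding any peak closer than \code{min_spacing} to an accepted
#' one. Output is deterministic and independent of input peak ordering.
#'
#' @param score a score-kind \linkS4class{GenomeTrack}.
#' @param min_spacing minimal distance between retained calls, bp.
#' @param low_score_quantile fraction of raw peaks discarded as low-score,
#'   computed per chromosome.
#' @param centers optional center-kind track of the same sample; when given,
#'   \code{supporting_reads} counts fragment centers within +/- 73 bp of each
#'   call.
#' @return data.frame (chrom, center, score, supporting_reads, gene_id,
#'   ordinal) sorted by chromosome and center; gene columns are NA until
#'   \code{\link{assignOrdinals}}.
#' @export
callNucleosomes <- function(score, min_spacing = 100, low_score_quantile = 0.10,
                            centers = NULL) {
  stopifnot(trackKind(score) == "score")
  res <- list()
  for (chr in names(trackValues(score))) {
    v <- trackValues(score, chr)
    if (!all(is.finite(v))) stop("non-finite scores on ", chr)
    pk <- localMaxima(v)
    pk <- pk[v[pk] > 0]
    if (!length(pk)) next
    sc <- v[pk]
    ## (i) drop the lowest-scoring fraction of raw peaks
    ndrop <- floor(low_score_quantile * length(pk))
    if (ndrop > 0) {
      ord <- order(sc, pk)
      keep <- sort(ord[-seq_len(ndrop)])
      pk <- pk[keep]; sc <- sc[keep]
    }
    ## (ii) greedy suppression, descending score, ties leftmost
    ord <- order(-sc, pk)
    len <- length(v)
    occ <- logical(len)
    acc <- logical(length(pk))
    w <- as.integer(min_spacing) - 1L
    for (i in ord) {
      p <- pk[i]
      if (!any(occ[max(1L, p - w):min(len, p + w)])) {
        occ[p] <- TRUE
        acc[i] <- TRUE
      }
    }
    pk <- pk[acc]; sc <- sc[acc]
    o <- order(pk)
    res[[chr]] <- data.frame(chrom = chr, center = pk[o], score = sc[o],
                             stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(chrom = character(), center = integer(),
                      score = numeric(), supporting_reads = integer(),
                      gene_id = character(), ordinal = integer(),
                      stringsAsFactors = FALSE))
  calls <- do.call(rbind, res)
  rownames(calls) <- NULL
  calls$supporting_reads <- if (!is.null(centers))
    supportingReads(calls, centers) else NA_integer_
  calls$gene_id <- NA_character_
  calls$ordinal <- NA_integer_
  calls
}

## fragment centers within +/- 73 bp of each call
supportingReads <- function(calls, centers, halfwidth = 73L) {
  out <- integer(nrow(calls))
  for (chr in unique(calls$chrom)) {
    v <- trackValues(centers, chr)
    if (is.null(v)) next
    idx <- which(calls$chrom == chr)
    cs <- c(0, cumsum(v))
    hi <- pmin(calls$center[idx] + halfwidth, length(v))
    lo <- pmax(calls$center[idx] - halfwidth, 1L)
    out[idx] <- as.integer(cs[hi + 1L] - cs[lo])
  }
  out
}

#' Fraction of the genome covered by called nucleosomes
#'
#' Calibration diagnostic: the fraction of genomic bp covered by the union of
#' call +/- 73 bp intervals (i.e. assumed 147 bp nucleosome footprints).
#' Genome-wide maps typically cover roughly 80% of nucleosomal DNA.
#'
#' @param calls nucleosome call table.
#' @param seqlengths named integer chromosome lengths.
#' @param nucleosome_length footprint width, bp.
#' @return fraction in [0, 1].
#' @export
nucleosomalFraction <- function(calls, seqlengths, nucleosome_length = 147) {
  h <- (as.integer(nucleosome_length) - 1L) %/% 2L
  covered <- 0
  for (chr in names(seqlengths)) {
    ctr <- calls$center[calls$chrom == chr]
    if (!length(ctr)) next
    ir <- IRanges::IRanges(pmax(ctr - h, 1L),
                           pmin(ctr + (nucleosome_length - 1L - h),
                                seqlengths[[chr]]))
    covered <- covered + sum(IRanges::width(IRanges::reduce(ir)))
  }
  covered / sum(seqlengths)
}

#' Assign gene-relative ordinals to nucleosome calls
#'
#' In gene orientation, +1 is the first call at or downstream of the TSS,
#' incrementing 3'-ward up to the stop codon; -1 is the first call upstream
#' of the TSS, decrementing through the promoter window. Calls beyond both
#' remain intergenic (NA). Gene-body assignment takes precedence over
#' another gene's promoter window; contested promoter calls go to the
#' nearest TSS.
#'
#' @param calls call table from \code{\link{callNucleosomes}}.
#' @param genes gene model data.frame.
#' @param promoter_window upstream window considered part of the gene, bp.
#' @return the call table with \code{gene_id} and \code{ordinal} filled in.
#' @export
assignOrdinals <- function(calls, genes, promoter_window = 1000) {
  calls$gene_id <- NA_character_
  calls$ordinal <- NA_integer_
  tss_dist <- rep(Inf, nrow(calls))
  for (chr in unique(genes$chrom)) {
    cidx <- which(calls$chrom == chr)
    if (!length(cidx)) next
    pos <- calls$center[cidx]
    for (gi in which(genes$chrom == chr)) {
      g <- genes[gi, ]
      dir <- if (g$strand == "+") 1L else -1L
      rel <- dir * (pos - g$tss)           # oriented offset from TSS
      glen <- dir * (g$stop_codon - g$tss)
      body <- which(rel >= 0 & rel <= glen)
      if (length(body)) {
        body <- body[order(rel[body])]
        calls$gene_id[cidx[body]] <- g$gene_id
        calls$ordinal[cidx[body]] <- seq_along(body)
        tss_dist[cidx[body]] <- 0
      }
      prom <- which(rel < 0 & rel >= -promoter_window)
      if (length(prom)) {
        prom <- prom[order(-rel[prom])]    # nearest to TSS first
        d <- -rel[prom]
        better <- d < tss_dist[cidx[prom]]
        if (any(better)) {
          calls$gene_id[cidx[prom[better]]] <- g$gene_id
          calls$ordinal[cidx[prom[better]]] <-
            -seq_along(prom)[better]
          tss_dist[cidx[prom[better]]] <- d[better]
        }
      }
    }
  }
  calls
}
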