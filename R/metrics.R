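## Gene- and genome-level statistics: fuzziness, shift directionality and
## propagation, linker distances, TSS profiles, positional enrichment,
## covariate stratification, region occupancy ratios, and the decomposition
## of the observed shift-size distribution into error and activity.

## oriented coordinate helpers ------------------------------------------

geneDir <- function(genes) ifelse(genes$strand == "+", 1L, -1L)

#' Per-gene nucleosome fuzziness
#'
#' Fuzziness quantifies the delocalization of nucleosomes across the cell
#' population as the percentage of gene-body fragment centers that lie
#' within \code{window} bp of the nearest called nucleosome center: well
#' positioned nucleosomes give high percentages, fuzzy ones low.
#' Denominators use reads within the start..stop codon interval only.
#'
#' @param genes gene model data.frame.
#' @param calls nucleosome call table of the sample.
#' @param centers center-kind \linkS4class{GenomeTrack} of the sample.
#' @param window distance threshold, bp.
#' @param sample_id label recorded in the output.
#' @return data.frame (gene_id, sample_id, pct_within, n_nucleosomes,
#'   n_reads); genes without gene-body reads get NA pct and are flagged
#'   \code{undefined}.
#' @export
computeFuzziness <- function(genes, calls, centers, window = 20,
                             sample_id = "sample") {
  out <- data.frame(gene_id = genes$gene_id, sample_id = sample_id,
                    pct_within = NA_real_, n_nucleosomes = 0L,
                    n_reads = 0L, undefined = TRUE,
                    stringsAsFactors = FALSE)
  for (chr in unique(genes$chrom)) {
    v <- trackValues(centers, chr)
    cc <- sort(calls$center[calls$chrom == chr])
    for (gi in which(genes$chrom == chr)) {
      g <- genes[gi, ]
      lo <- max(1L, min(g$start_codon, g$stop_codon))
      hi <- min(length(v), max(g$start_codon, g$stop_codon))
      pos <- rep(lo:hi, v[lo:hi])
      n <- length(pos)
      out$n_reads[gi] <- n
      out$n_nucleosomes[gi] <- sum(cc >= lo & cc <= hi)
      if (n == 0L || !length(cc)) next
      i <- findInterval(pos, cc)
      dl <- abs(pos - cc[pmax(i, 1L)])
      dr <- abs(cc[pmin(i + 1L, length(cc))] - pos)
      out$pct_within[gi] <- 100 * mean(pmin(dl, dr) <= window)
      out$undefined[gi] <- FALSE
    }
  }
  out
}

#' Classify per-gene fuzziness changes across samples
#'
#' A sample is flagged as having increased fuzziness at a gene iff its
#' percentage of reads near called centers is lower by at least
#' \code{min_delta} percentage points than in every other sample, while the
#' number of called nucleosomes in the gene is identical across samples.
#'
#' Genes failing the preconditions (undefined records, or nucleosome counts
#' that differ between samples, e.g. through a loss/gain) are not
#' classifiable and are never flagged.
#'
#' @param records row-bound \code{\link{computeFuzziness}} tables of >= 2
#'   samples.
#' @param min_delta minimal percentage-point deficit.
#' @return data.frame (gene_id, classifiable, fuzzier_in) where
#'   \code{fuzzier_in} is the flagged sample id or NA.
#' @export
classifyFuzzinessChange <- function(records, min_delta = 5) {
  samples <- unique(records$sample_id)
  if (length(samples) < 2L) stop("need records from >= 2 samples")
  genes <- unique(records$gene_id)
  out <- data.frame(gene_id = genes, classifiable = FALSE,
                    fuzzier_in = NA_character_,
                    stringsAsFactors = FALSE)
  sp <- split(records, records$gene_id)
  for (i in seq_along(genes)) {
    r <- sp[[genes[i]]]
    if (nrow(r) != length(samples) || any(r$undefined)) next
    if (length(unique(r$n_nucleosomes)) != 1L) next
    out$classifiable[i] <- TRUE
    for (j in seq_len(nrow(r))) {
      others <- r$pct_within[-j]
      if (all(r$pct_within[j] <= others - min_delta)) {
        out$fuzzier_in[i] <- r$sample_id[j]
        break
      }
    }
  }
  out
}

#' Directionality of nucleosome shifts
#'
#' Fraction of shift calls displaced toward the gene 5' end (upstream), with
#' a two-sided exact binomial test against 0.5.
#'
#' @param changes change table (or any data.frame with \code{class} and
#'   gene-oriented \code{signed_shift}).
#' @param ordinals optional ordinal filter (e.g. mid-coding ordinals).
#' @param rel_range optional normalized gene-position filter c(lo, hi) in
#'   [0, 1]; requires \code{genes}.
#' @param genes gene models, needed for \code{rel_range}.
#' @param confirmed_only restrict to strand-confirmed changes when the
#'   column is available.
#' @return list(upstream_fraction, n, n_upstream, p_value).
#' @export
shiftDirectionality <- function(changes, ordinals = NULL, rel_range = NULL,
                                genes = NULL, confirmed_only = FALSE) {
  s <- changes[changes$class == "shift", , drop = FALSE]
  if (confirmed_only && "confirmed" %in% names(s))
    s <- s[which(s$confirmed), , drop = FALSE]
  if (!is.null(ordinals))
    s <- s[s$ordinal %in% ordinals, , drop = FALSE]
  if (!is.null(rel_range)) {
    if (is.null(genes)) stop("rel_range filtering requires genes")
    r <- relativePosition(s$center_A, s$gene_id, genes)
    s <- s[!is.na(r) & r >= rel_range[1L] & r <= rel_range[2L], , drop = FALSE]
  }
  if (!nrow(s)) stop("no shifts after filtering")
  up <- sum(s$signed_shift > 0)
  list(upstream_fraction = up / nrow(s), n = nrow(s), n_upstream = up,
       p_value = stats::binom.test(up, nrow(s), 0.5)$p.value)
}

## normalized position of a chromosome coordinate within its gene body
relativePosition <- function(center, gene_id, genes) {
  i <- match(gene_id, genes$gene_id)
  dir <- geneDir(genes)[i]
  (dir * (center - genes$start_codon[i])) /
    (dir * (genes$stop_codon[i] - genes$start_codon[i]))
}

#' Shift propagation to adjacent nucleosomes
#'
#' For each gene carrying at least one shift of magnitude >=
#' \code{min_shift}, takes the maximally shifted nucleosome and records the
#' gene-oriented shift of its immediate upstream (ordinal - 1) and
#' downstream (ordinal + 1) neighbors, zero when the neighbor is unshifted
#' or absent from the shift table. Means across genes expose asymmetric
#' propagation.
#'
#' @param changes change table.
#' @param min_shift magnitude threshold for the focal nucleosome, bp.
#' @return named numeric c(upstream, focal, downstream) of mean shifts, with
#'   attribute \code{n_genes}.
#' @export
neighborShiftPropagation <- function(changes, min_shift = 15) {
  s <- changes[changes$class == "shift" & !is.na(changes$signed_shift), ,
               drop = FALSE]
  s <- s[abs(s$signed_shift) >= 0, , drop = FALSE]  # keep all for neighbor lookup
  focal <- s[abs(s$signed_shift) >= min_shift, , drop = FALSE]
  genes <- unique(focal$gene_id)
  if (!length(genes)) stop("no genes with shifts above min_shift")
  trip <- matrix(0, nrow = length(genes), ncol = 3L,
                 dimnames = list(genes, c("upstream", "focal", "downstream")))
  for (i in seq_along(genes)) {
    gs <- s[s$gene_id == genes[i], , drop = FALSE]
    f <- gs[which.max(abs(gs$signed_shift)), ]
    at <- function(o) {
      v <- gs$signed_shift[gs$ordinal == o]
      if (length(v)) v[1L] else 0
    }
    trip[i, ] <- c(at(f$ordinal - 1L), f$signed_shift, at(f$ordinal + 1L))
  }
  out <- colMeans(trip)
  attr(out, "n_genes") <- length(genes)
  out
}

#' Distances between selected nucleosomes and their upstream neighbors
#'
#' Center-to-center distance between each selected (gene, ordinal)
#' nucleosome and its flanking upstream neighbor (ordinal - 1; the -1
#' nucleosome for +1 targets) within one sample's calls. Distances below the
#' 147 bp footprint imply vanishing or invaded linkers.
#'
#' @param calls call table of one sample (with ordinals assigned).
#' @param selection data.frame (gene_id, ordinal) of downstream pair members.
#' @param nucleosome_length footprint used for the short-linker fractions.
#' @return list(distances, median, frac_lt_147, frac_lt_137, n_skipped)
#'   where the fractions use \code{nucleosome_length} and
#'   \code{nucleosome_length - 10}.
#' @export
linkerDistribution <- function(calls, selection, nucleosome_length = 147) {
  key <- paste(calls$gene_id, calls$ordinal)
  up_ord <- ifelse(selection$ordinal == 1L, -1L, selection$ordinal - 1L)
  i <- match(paste(selection$gene_id, selection$ordinal), key)
  j <- match(paste(selection$gene_id, up_ord), key)
  ok <- !is.na(i) & !is.na(j)
  d <- abs(calls$center[i[ok]] - calls$center[j[ok]])
  list(distances = d,
       median = if (length(d)) median(d) else NA_real_,
       frac_lt_147 = if (length(d)) mean(d < nucleosome_length) else NA_real_,
       frac_lt_137 = if (length(d)) mean(d < nucleosome_length - 10) else NA_real_,
       n_skipped = sum(!ok))
}

#' TSS-aligned average read profile
#'
#' Pools gene-oriented offsets of all fragment centers relative to the TSS
#' across genes and reports the percentage of pooled reads per offset bin --
#' the classic average nucleosome-organization profile with its NFR and
#' phased array.
#'
#' @param centers center-kind \linkS4class{GenomeTrack}.
#' @param genes gene model data.frame.
#' @param range offset range c(upstream, downstream) around the TSS, bp.
#' @param bin bin width, bp.
#' @return data.frame (offset = bin start, pct); pct sums to 100.
#' @export
tssProfile <- function(centers, genes, range = c(-500, 2000), bin = 10) {
  offsets <- seq(range[1L], range[2L] - 1L)
  acc <- numeric(length(offsets))
  for (chr in unique(genes$chrom)) {
    v <- trackValues(centers, chr)
    for (gi in which(genes$chrom == chr)) {
      g <- genes[gi, ]
      dir <- if (g$strand == "+") 1L else -1L
      pos <- g$tss + dir * offsets
      inb <- pos >= 1L & pos <= length(v)
      acc[inb] <- acc[inb] + v[pos[inb]]
    }
  }
  grp <- (offsets - range[1L]) %/% bin
  cnt <- tapply(acc, grp, sum)
  data.frame(offset = range[1L] + as.integer(names(cnt)) * bin,
             pct = 100 * as.numeric(cnt) / sum(cnt))
}

#' Positional enrichment of nucleosome changes along gene bodies
#'
#' Maps every gene-body nucleosome call to its normalized position r =
#' (center - start codon) / (stop codon - start codon) in gene orientation,
#' bins r into \code{n_bins} equal bins and reports the percentage of
#' nucleosomes changed (for one change class) per bin. Promoter calls
#' (r outside [0, 1]) are excluded from this view.
#'
#' @param changes change table.
#' @param calls call table of the reference sample (assigns the universe of
#'   nucleosomes).
#' @param genes gene model data.frame.
#' @param n_bins number of normalized-position bins.
#' @param change_class class to count.
#' @return data.frame (bin_mid, n_total, n_changed, pct).
#' @export
positionalEnrichment <- function(changes, calls, genes, n_bins = 20,
                                 change_class = "shift") {
  body <- calls[!is.na(calls$gene_id) & calls$ordinal > 0, , drop = FALSE]
  r <- relativePosition(body$center, body$gene_id, genes)
  keep <- !is.na(r) & r >= 0 & r <= 1
  body <- body[keep, , drop = FALSE]; r <- r[keep]
  b <- pmin(floor(r * n_bins), n_bins - 1L)
  ch <- changes[changes$class == change_class, , drop = FALSE]
  changed <- paste(body$gene_id, body$ordinal) %in%
    paste(ch$gene_id, ch$ordinal)
  tot <- tabulate(b + 1L, n_bins)
  chg <- tabulate((b + 1L)[changed], n_bins)
  data.frame(bin_mid = (seq_len(n_bins) - 0.5) / n_bins,
             n_total = tot, n_changed = chg,
             pct = ifelse(tot > 0, 100 * chg / tot, 0))
}

#' Mean shift size stratified by a per-gene covariate
#'
#' Orders the genes carrying a given ordinal by a covariate (e.g. a histone
#' modification level), splits them into \code{n_strata} equal-size strata
#' and averages the gene-oriented shift at that ordinal per stratum;
#' unshifted genes contribute zero. By default downstream shifts enter with
#' negative sign (\code{mode = "signed"}); \code{mode = "upstream_only"}
#' zeroes them instead.
#'
#' @param changes change table.
#' @param covariate data.frame (gene_id, covariate).
#' @param gene_universe character vector of genes that carry the ordinal
#'   (e.g. genes with a pair at that ordinal); defaults to all covariate
#'   genes.
#' @param ordinal the nucleosome ordinal examined.
#' @param n_strata number of strata.
#' @param mode \code{"signed"} or \code{"upstream_only"}.
#' @return data.frame (stratum, mean_shift, n, mean_covariate); stratum 1 is
#'   the lowest covariate.
#' @export
stratifiedShiftMeans <- function(changes, covariate, gene_universe = NULL,
                                 ordinal = 5, n_strata = 10,
                                 mode = c("signed", "upstream_only")) {
  mode <- match.arg(mode)
  cov <- covariate
  if (!is.null(gene_universe))
    cov <- cov[cov$gene_id %in% gene_universe, , drop = FALSE]
  if (nrow(cov) < n_strata) stop("fewer genes than strata")
  s <- changes[changes$class == "shift" & changes$ordinal == ordinal, ,
               drop = FALSE]
  sh <- s$signed_shift[match(cov$gene_id, s$gene_id)]
  sh[is.na(sh)] <- 0
  if (mode == "upstream_only") sh[sh < 0] <- 0
  ## stable order: covariate, then gene_id for ties
  o <- order(cov$covariate, cov$gene_id)
  sh <- sh[o]; cv <- cov$covariate[o]
  stratum <- ceiling(seq_along(sh) * n_strata / length(sh))
  data.frame(stratum = seq_len(n_strata),
             mean_shift = as.numeric(tapply(sh, stratum, mean)),
             n = as.integer(table(stratum)),
             mean_covariate = as.numeric(tapply(cv, stratum, mean)))
}

#' Per-gene log2 occupancy ratio over promoter or 5' coding regions
#'
#' Counts fragment centers in a gene-oriented region -- the 250 bp upstream
#' of the TSS (\code{"promoter_250"}) or the first 500 bp of the coding
#' region (\code{"coding_500"}) -- in both samples and returns
#' log2((B + pseudocount) / (A * depth_factor + pseudocount)), where
#' depth_factor rescales sample A counts to sample B's sequencing depth.
#'
#' @param centers_A,centers_B center-kind tracks.
#' @param genes gene model data.frame.
#' @param region \code{"promoter_250"} or \code{"coding_500"}.
#' @param pseudocount added to both counts.
#' @return data.frame (gene_id, n_A, n_B, log2_ratio).
#' @export
regionOccupancyLogratio <- function(centers_A, centers_B, genes,
                                    region = c("promoter_250", "coding_500"),
                                    pseudocount = 1) {
  region <- match.arg(region)
  factor <- totalReads(centers_B) / totalReads(centers_A)
  nA <- nB <- integer(nrow(genes))
  for (chr in unique(genes$chrom)) {
    vA <- trackValues(centers_A, chr); vB <- trackValues(centers_B, chr)
    csA <- c(0, cumsum(vA)); csB <- c(0, cumsum(vB))
    for (gi in which(genes$chrom == chr)) {
      g <- genes[gi, ]
      dir <- if (g$strand == "+") 1L else -1L
      ends <- if (region == "promoter_250")
        c(g$tss - dir * 250L, g$tss - dir * 1L)
      else c(g$start_codon, g$start_codon + dir * 499L)
      lo <- max(1L, min(ends)); hi <- min(length(vA), max(ends))
      if (lo > hi) next
      nA[gi] <- csA[hi + 1L] - csA[lo]
      nB[gi] <- csB[hi + 1L] - csB[lo]
    }
  }
  data.frame(gene_id = genes$gene_id, n_A = nA, n_B = nB,
             log2_ratio = log2((nB + pseudocount) /
                               (nA * factor + pseudocount)),
             stringsAsFactors = FALSE)
}

#' Decompose an observed shift-size distribution into error and activity
#'
#' Under the assumptions that the remodeler only shifts nucleosomes upstream
#' and that position-estimation errors produce equally many apparent
#' upstream and downstream shifts, the downstream half of the observed
#' distribution estimates the error component: per magnitude bin b, error =
#' min(U_b, D_b) (mirrored on both sides) and activity = max(U_b - D_b, 0).
#' The estimated fraction of genes with a genuine upstream shift is
#' sum_b max(U_b - D_b, 0) / N, with N all genes examined (zero shifts
#' included). Bins where D_b > U_b are clamped at zero activity; the clamped
#' mass is reported.
#'
#' @param shifts numeric vector of per-gene gene-oriented signed shift
#'   estimates at one ordinal, including zeros and sub-threshold values
#'   (e.g. \code{pairTable(x)$signed_shift} restricted to the ordinal).
#' @param bin_width histogram bin width, bp.
#' @return object of class \code{ShiftDecomposition}: list with \code{bins}
#'   (data.frame: bin_lo, bin_hi, upstream, downstream, error, activity),
#'   \code{estimated_shifted_fraction}, \code{n}, \code{clamped}.
#' @export
decomposeShiftDistribution <- function(shifts, bin_width = 5) {
  shifts <- shifts[!is.na(shifts)]
  n <- length(shifts)
  if (n == 0L) stop("no shift estimates supplied")
  mag_up <- shifts[shifts > 0]
  mag_dn <- -shifts[shifts < 0]
  mx <- max(c(mag_up, mag_dn, bin_width))
  breaks <- seq(0, ceiling(mx / bin_width) * bin_width, by = bin_width)
  U <- tabulate(pmin(ceiling(mag_up / bin_width), length(breaks) - 1L),
                length(breaks) - 1L)
  D <- tabulate(pmin(ceiling(mag_dn / bin_width), length(breaks) - 1L),
                length(breaks) - 1L)
  err <- pmin(U, D)
  act <- pmax(U - D, 0L)
  structure(list(
    bins = data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
                      upstream = U, downstream = D, error = err,
                      activity = act),
    estimated_shifted_fraction = sum(act) / n,
    n = n,
    clamped = sum(pmax(D - U, 0L))), class = "ShiftDecomposition")
}

#' @export
print.ShiftDecomposition <- function(x, ...) {
  cat("ShiftDecomposition over", x$n, "genes:",
      sprintf("estimated shifted fraction %.3f", x$estimated_shifted_fraction),
      if (x$clamped) sprintf("(%d clamped)", x$clamped) else "", "\n")
  invisible(x)
}
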