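## Between-strain comparison: mutual-nearest nucleosome pairing, shift /
## occupancy / loss-gain detectors, strand-split confirmation, orchestrator.

#' Pair nucleosome calls between two samples
#'
#' Mutual-nearest-neighbor pairing within \code{max_pair_distance} bp. When
#' two calls from one strain contend for the same call in the other, the
#' nearer one wins and the more distant becomes unpaired -- a loss/gain
#' candidate. Symmetric in A/B up to labeling.
#'
#' @param calls_A,calls_B call tables (sorted by center within chromosome, as
#'   produced by \code{\link{callNucleosomes}}).
#' @param max_pair_distance maximal center-to-center pairing distance, bp.
#' @return list with \code{pairs} (data.frame: chrom, center_A, center_B,
#'   distance, score_A, score_B, supporting_reads_A, supporting_reads_B,
#'   gene_id, ordinal -- gene columns taken from sample A's assignment,
#'   falling back to B's), \code{unpaired_A} and \code{unpaired_B} (rows of
#'   the input call tables).
#' @export
pairNucleosomes <- function(calls_A, calls_B, max_pair_distance = 100) {
  pairs <- list(); upA <- list(); upB <- list()
  for (chr in union(calls_A$chrom, calls_B$chrom)) {
    ia <- which(calls_A$chrom == chr)
    ib <- which(calls_B$chrom == chr)
    a <- calls_A$center[ia]; b <- calls_B$center[ib]
    if (!length(a) || !length(b)) {
      if (length(ia)) upA[[chr]] <- calls_A[ia, ]
      if (length(ib)) upB[[chr]] <- calls_B[ib, ]
      next
    }
    nn <- function(x, y) {        # index in y of nearest element (ties: left)
      i <- findInterval(x, y)
      lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(y))
      ifelse(abs(x - y[lo]) <= abs(y[hi] - x), lo, hi)
    }
    nab <- nn(a, b); nba <- nn(b, a)
    mutual <- which(nba[nab] == seq_along(a) &
                    abs(a - b[nab]) <= max_pair_distance)
    if (length(mutual)) {
      pa <- ia[mutual]; pb <- ib[nab[mutual]]
      gid <- ifelse(is.na(calls_A$gene_id[pa]), calls_B$gene_id[pb],
                    calls_A$gene_id[pa])
      ord <- ifelse(is.na(calls_A$gene_id[pa]), calls_B$ordinal[pb],
                    calls_A$ordinal[pa])
      pairs[[chr]] <- data.frame(
        chrom = chr,
        center_A = calls_A$center[pa], center_B = calls_B$center[pb],
        distance = abs(calls_A$center[pa] - calls_B$center[pb]),
        score_A = calls_A$score[pa], score_B = calls_B$score[pb],
        supporting_reads_A = calls_A$supporting_reads[pa],
        supporting_reads_B = calls_B$supporting_reads[pb],
        gene_id = gid, ordinal = ord, stringsAsFactors = FALSE)
      ia <- setdiff(ia, pa); ib <- setdiff(ib, pb)
    }
    if (length(ia)) upA[[chr]] <- calls_A[ia, ]
    if (length(ib)) upB[[chr]] <- calls_B[ib, ]
  }
  empty <- data.frame(chrom = character(), center_A = integer(),
                      center_B = integer(), distance = integer(),
                      score_A = numeric(), score_B = numeric(),
                      supporting_reads_A = integer(),
                      supporting_reads_B = integer(),
                      gene_id = character(), ordinal = integer(),
                      stringsAsFactors = FALSE)
  list(pairs = if (length(pairs)) do.call(rbind, c(pairs, make.row.names = FALSE)) else empty,
       unpaired_A = if (length(upA)) do.call(rbind, c(upA, make.row.names = FALSE)) else calls_A[0, ],
       unpaired_B = if (length(upB)) do.call(rbind, c(upB, make.row.names = FALSE)) else calls_B[0, ])
}

## Welch/Student t-test p-value robust to the zero-variance degenerate case:
## both samples constant with different means -> p = 0 (flagged upstream);
## equal means -> p = 1.
positionTestP <- function(x, y, test = "welch") {
  if (var(x) == 0 && var(y) == 0)
    return(if (mean(x) == mean(y)) 1 else 0)
  tryCatch(stats::t.test(x, y, var.equal = (test == "student"))$p.value,
           error = function(e) if (mean(x) == mean(y)) 1 else 0)
}

## fragment-center positions within +/- window of pos, expanded from counts
windowPositions <- function(values, pos, window) {
  lo <- max(1L, pos - window); hi <- min(length(values), pos + window)
  v <- values[lo:hi]
  rep(lo:hi, v)
}

#' Detect nucleosome position shifts between paired calls
#'
#' For every pair, collects the fragment-center positions within
#' \code{read_window} bp of each strain's own call center and compares the
#' two position samples with a two-sided t-test (Welch by default). A shift
#' is called iff the call centers differ by at least \code{min_shift} bp and
#' p < \code{alpha}. The raw signed estimate and p-value are recorded for
#' every pair (needed by the shift-distribution decomposition). Signs are
#' gene-oriented: positive = the sample-B nucleosome lies closer to the gene
#' 5' end.
#'
#' @param pairs pair table from \code{\link{pairNucleosomes}}.
#' @param centers_A,centers_B center-kind tracks of the two samples.
#' @param genes gene model data.frame (for strand orientation).
#' @param min_shift minimal center difference for a shift call, bp.
#' @param alpha p-value threshold.
#' @param read_window half-window of fragment centers entering the test, bp.
#' @param min_reads minimal centers per strain in the window (pairs below are
#'   flagged \code{insufficient} and never called).
#' @param test \code{"welch"} (unequal variance) or \code{"student"}.
#' @return the pair table with columns \code{signed_shift}, \code{p_value},
#'   \code{n_A}, \code{n_B}, \code{insufficient}, \code{is_shift}.
#' @export
detectShifts <- function(pairs, centers_A, centers_B, genes,
                         min_shift = 15, alpha = 0.05, read_window = 30,
                         min_reads = 3, test = c("welch", "student")) {
  test <- match.arg(test)
  n <- nrow(pairs)
  strand <- genes$strand[match(pairs$gene_id, genes$gene_id)]
  ## gene-oriented sign: + strand upstream = smaller coordinate
  sgn <- ifelse(is.na(strand) | strand == "+", 1, -1)
  pairs$signed_shift <- sgn * (pairs$center_A - pairs$center_B)
  pairs$p_value <- NA_real_
  pairs$n_A <- NA_integer_; pairs$n_B <- NA_integer_
  pairs$insufficient <- FALSE
  if (n) for (chr in unique(pairs$chrom)) {
    vA <- trackValues(centers_A, chr); vB <- trackValues(centers_B, chr)
    for (i in which(pairs$chrom == chr)) {
      xa <- windowPositions(vA, pairs$center_A[i], read_window)
      xb <- windowPositions(vB, pairs$center_B[i], read_window)
      pairs$n_A[i] <- length(xa); pairs$n_B[i] <- length(xb)
      if (length(xa) < min_reads || length(xb) < min_reads) {
        pairs$insufficient[i] <- TRUE
        next
      }
      pairs$p_value[i] <- positionTestP(xa, xb, test)
    }
  }
  pairs$is_shift <- !pairs$insufficient & !is.na(pairs$p_value) &
    abs(pairs$signed_shift) >= min_shift & pairs$p_value < alpha
  pairs
}

## mean occupancy over pos +/- window
meanOcc <- function(occ, chr, pos, window = 30L) {
  v <- trackValues(occ, chr)
  lo <- max(1L, pos - window); hi <- min(length(v), pos + window)
  mean(v[lo:hi])
}

#' Detect occupancy changes at paired nucleosomes
#'
#' Occupancy is measured as the mean occupancy over call center +/- 30 bp in
#' each sample; the fold change is computed after correcting for the overall
#' depth difference via \code{global_factor} (ratio of total A to total B
#' fragment centers by default). A change is called iff the corrected fold is
#' >= \code{min_fold} or <= 1/\code{min_fold}.
#'
#' @param pairs pair table.
#' @param occ_A,occ_B occupancy-kind tracks.
#' @param global_factor depth-correction factor, total_A / total_B.
#' @param min_fold fold-change threshold.
#' @param window averaging half-window, bp.
#' @return the pair table with \code{occ_log2_fold} and \code{is_occ_change};
#'   a zero denominator yields +Inf fold and a flagged call.
#' @export
detectOccupancyChanges <- function(pairs, occ_A, occ_B,
                                   global_factor = totalReads(occ_A) / totalReads(occ_B),
                                   min_fold = 2, window = 30) {
  n <- nrow(pairs)
  fold <- rep(NA_real_, n)
  if (n) for (i in seq_len(n)) {
    mA <- meanOcc(occ_A, pairs$chrom[i], pairs$center_A[i], window)
    mB <- meanOcc(occ_B, pairs$chrom[i], pairs$center_B[i], window)
    fold[i] <- if (mB * global_factor == 0) Inf else mA / (mB * global_factor)
  }
  pairs$occ_log2_fold <- log2(fold)
  pairs$is_occ_change <- !is.na(fold) & (fold >= min_fold | fold <= 1 / min_fold)
  pairs
}

#' Classify unpaired nucleosome calls as losses or gains
#'
#' An unpaired call is a loss/gain iff the depth-corrected occupancy at its
#' position is at least \code{min_fold} higher in the strain retaining the
#' nucleosome and the call is supported by at least \code{min_reads}
#' fragment centers. Class is \code{"loss"} when the nucleosome is present
#' only in sample A (absent from the mutant under the usual wild-type-first
#' orientation) and \code{"gain"} when present only in sample B.
#'
#' @param unpaired unpaired call rows from \code{\link{pairNucleosomes}}.
#' @param occ_present occupancy track of the strain with the call.
#' @param occ_absent occupancy track of the other strain.
#' @param global_factor depth correction, total_present / total_absent.
#' @param present which sample retains the nucleosome, \code{"A"} or \code{"B"}.
#' @param min_fold occupancy fold threshold.
#' @param min_reads minimal supporting fragment centers.
#' @param window occupancy averaging half-window, bp.
#' @return data.frame of loss/gain calls (possibly empty) with class,
#'   occupancy log2 fold and supporting reads.
#' @export
detectLossGain <- function(unpaired, occ_present, occ_absent, global_factor,
                           present = c("A", "B"), min_fold = 2, min_reads = 8,
                           window = 30) {
  present <- match.arg(present)
  n <- nrow(unpaired)
  out <- vector("list", n)
  if (n) for (i in seq_len(n)) {
    mp <- meanOcc(occ_present, unpaired$chrom[i], unpaired$center[i], window)
    ma <- meanOcc(occ_absent, unpaired$chrom[i], unpaired$center[i], window)
    fold <- if (ma * global_factor == 0) Inf else mp / (ma * global_factor)
    if (fold >= min_fold && !is.na(unpaired$supporting_reads[i]) &&
        unpaired$supporting_reads[i] >= min_reads) {
      out[[i]] <- data.frame(
        gene_id = unpaired$gene_id[i], ordinal = unpaired$ordinal[i],
        class = if (present == "A") "loss" else "gain",
        chrom = unpaired$chrom[i],
        center_A = if (present == "A") unpaired$center[i] else NA_integer_,
        center_B = if (present == "B") unpaired$center[i] else NA_integer_,
        signed_shift = NA_real_, p_value = NA_real_,
        occ_log2_fold = log2(fold),
        supporting_reads = unpaired$supporting_reads[i],
        stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE)) else
    data.frame(gene_id = character(), ordinal = integer(), class = character(),
               chrom = character(), center_A = integer(), center_B = integer(),
               signed_shift = numeric(), p_value = numeric(),
               occ_log2_fold = numeric(), supporting_reads = integer(),
               stringsAsFactors = FALSE)
}

## Core single-pass comparison on given read sets / strand selection.
## Returns calls, pairs with detector columns, change table (unconfirmed).
compareCore <- function(reads_A, reads_B, genes, config, strands = "both",
                        fl_A = resolveFragmentLength(reads_A, config),
                        fl_B = resolveFragmentLength(reads_B, config)) {
  cA <- readsToCenters(reads_A, fl_A, strands = strands)
  cB <- readsToCenters(reads_B, fl_B, strands = strands)
  oA <- computeOccupancy(cA, config$nucleosome_length)
  oB <- computeOccupancy(cB, config$nucleosome_length)
  sA <- computeScores(cA, config$kernel_sd, config$kernel_halfwidth)
  sB <- computeScores(cB, config$kernel_sd, config$kernel_halfwidth)
  norm <- percentileNormalize(list(sA, sB))
  callsA <- assignOrdinals(
    callNucleosomes(norm[[1L]], config$min_spacing, config$low_score_quantile,
                    centers = cA),
    genes, config$promoter_window)
  callsB <- assignOrdinals(
    callNucleosomes(norm[[2L]], config$min_spacing, config$low_score_quantile,
                    centers = cB),
    genes, config$promoter_window)
  pr <- pairNucleosomes(callsA, callsB, config$max_pair_distance)
  ## a paired call supported by fewer than min_reads fragment centers is not
  ## evidence of a nucleosome: such pairs (typically a real nucleosome facing
  ## a background-read peak) are demoted to loss/gain candidates
  weakB <- which(pr$pairs$supporting_reads_B < config$min_reads &
                 pr$pairs$supporting_reads_A >= config$min_reads)
  weakA <- which(pr$pairs$supporting_reads_A < config$min_reads &
                 pr$pairs$supporting_reads_B >= config$min_reads)
  demote <- function(p, side) {
    data.frame(chrom = p$chrom, center = p[[paste0("center_", side)]],
               score = p[[paste0("score_", side)]],
               supporting_reads = p[[paste0("supporting_reads_", side)]],
               gene_id = p$gene_id, ordinal = p$ordinal,
               stringsAsFactors = FALSE)
  }
  if (length(weakB))
    pr$unpaired_A <- rbind(pr$unpaired_A, demote(pr$pairs[weakB, ], "A"))
  if (length(weakA))
    pr$unpaired_B <- rbind(pr$unpaired_B, demote(pr$pairs[weakA, ], "B"))
  drop <- c(weakA, weakB)
  if (length(drop)) pr$pairs <- pr$pairs[-drop, , drop = FALSE]
  gf <- totalReads(cA) / totalReads(cB)
  pairs <- detectShifts(pr$pairs, cA, cB, genes,
                        min_shift = config$min_shift, alpha = config$alpha,
                        read_window = config$read_window,
                        min_reads = config$min_test_reads,
                        test = config$shift_test)
  pairs <- detectOccupancyChanges(pairs, oA, oB, global_factor = gf,
                                  min_fold = config$min_fold,
                                  window = config$occ_window)
  lossA <- detectLossGain(pr$unpaired_A, oA, oB, gf, present = "A",
                          min_fold = config$min_fold,
                          min_reads = config$min_reads,
                          window = config$occ_window)
  gainB <- detectLossGain(pr$unpaired_B, oB, oA, 1 / gf, present = "B",
                          min_fold = config$min_fold,
                          min_reads = config$min_reads,
                          window = config$occ_window)
  genic <- !is.na(pairs$gene_id)
  shift_rows <- pairs[genic & pairs$is_shift, , drop = FALSE]
  occ_rows <- pairs[genic & pairs$is_occ_change, , drop = FALSE]
  mk <- function(p, cls) {
    if (!nrow(p)) return(NULL)
    data.frame(gene_id = p$gene_id, ordinal = p$ordinal, class = cls,
               chrom = p$chrom, center_A = p$center_A, center_B = p$center_B,
               signed_shift = if (cls == "shift") p$signed_shift else NA_real_,
               p_value = if (cls == "shift") p$p_value else NA_real_,
               occ_log2_fold = if (cls == "occupancy") p$occ_log2_fold else NA_real_,
               supporting_reads = pmin(p$supporting_reads_A,
                                       p$supporting_reads_B),
               stringsAsFactors = FALSE)
  }
  lg <- rbind(lossA[!is.na(lossA$gene_id), , drop = FALSE],
              gainB[!is.na(gainB$gene_id), , drop = FALSE])
  changes <- do.call(rbind, c(Filter(Negate(is.null),
    list(mk(shift_rows, "shift"), mk(occ_rows, "occupancy"), lg)),
    make.row.names = FALSE))
  if (is.null(changes))
    changes <- data.frame(gene_id = character(), ordinal = integer(),
                          class = character(), chrom = character(),
                          center_A = integer(), center_B = integer(),
                          signed_shift = numeric(), p_value = numeric(),
                          occ_log2_fold = numeric(),
                          supporting_reads = integer(),
                          stringsAsFactors = FALSE)
  list(callsA = callsA, callsB = callsB, pairs = pairs, changes = changes)
}

resolveFragmentLength <- function(reads, config) {
  fl <- config$fragment_length
  if (identical(fl, "auto"))
    estimateFragmentLength(reads)$fragment_length
  else as.integer(fl)
}

#' Confirm changes by independent single-strand reanalysis
#'
#' Repeats the whole analysis (track building, calling, pairing, detection)
#' once with forward-strand reads only and once with reverse-strand reads
#' only, and flags a combined-analysis change as confirmed on a strand iff a
#' change of the same class passes all thresholds there with its call
#' centers within \code{tol_shift} bp (shifts) or \code{tol_general} bp
#' (occupancy, loss/gain) of the combined-analysis centers. A change is
#' confirmed iff it is confirmed on both strands; a strand with no matching
#' call leaves it unconfirmed (not an error).
#'
#' @param changes combined-analysis change table.
#' @param reads_A,reads_B the two \linkS4class{ReadSet}s.
#' @param genes gene model data.frame.
#' @param config a \code{\link{pipelineConfig}}.
#' @return the change table with \code{confirmed_forward},
#'   \code{confirmed_reverse} and \code{confirmed} columns.
#' @export
strandSplitConfirm <- function(changes, reads_A, reads_B, genes, config,
                               fl_A = resolveFragmentLength(reads_A, config),
                               fl_B = resolveFragmentLength(reads_B, config)) {
  changes$confirmed_forward <- FALSE
  changes$confirmed_reverse <- FALSE
  if (!nrow(changes)) { changes$confirmed <- logical(0); return(changes) }
  for (strand in c("forward_only", "reverse_only")) {
    sub <- compareCore(reads_A, reads_B, genes, config, strands = strand,
                       fl_A = fl_A, fl_B = fl_B)$changes
    col <- if (strand == "forward_only") "confirmed_forward" else "confirmed_reverse"
    if (!nrow(sub)) next
    for (i in seq_len(nrow(changes))) {
      tol <- if (changes$class[i] == "shift") config$tol_shift else config$tol_general
      cand <- sub$class == changes$class[i] & sub$chrom == changes$chrom[i]
      if (!any(cand)) next
      okA <- is.na(changes$center_A[i]) |
        (!is.na(sub$center_A[cand]) &
           abs(sub$center_A[cand] - changes$center_A[i]) <= tol)
      okB <- is.na(changes$center_B[i]) |
        (!is.na(sub$center_B[cand]) &
           abs(sub$center_B[cand] - changes$center_B[i]) <= tol)
      ## direction of a shift must agree as well
      okS <- if (changes$class[i] == "shift")
        sign(sub$signed_shift[cand]) == sign(changes$signed_shift[i])
      else TRUE
      if (any(okA & okB & okS, na.rm = TRUE))
        changes[[col]][i] <- TRUE
    }
  }
  changes$confirmed <- changes$confirmed_forward & changes$confirmed_reverse
  changes
}

#' Compare nucleosome organization between two samples
#'
#' Full orchestrated comparison of two read sets: center/occupancy/score
#' tracks, quantile normalization across the two samples, nucleosome calling
#' and ordinal assignment, mutual-nearest pairing, shift / occupancy /
#' loss-gain classification restricted to genes and their promoter windows,
#' and (optionally) strand-split confirmation. Comparing two biological
#' repeats of the same strain yields the empirical null change counts.
#'
#' @param reads_A,reads_B \linkS4class{ReadSet}s (conventionally A = wild
#'   type / reference, B = mutant).
#' @param genes gene model data.frame.
#' @param config a \code{\link{pipelineConfig}}.
#' @param confirm run strand-split confirmation.
#' @return A \linkS4class{StrainComparison}.
#' @examples
#' gl <- generateGenomeLayout(20, seed = 1)
#' map <- buildNucleosomeMap(gl$genes)
#' a <- sampleReads(map, gl$seqlengths, depth = 30, seed = 1, sample_id = "wt")
#' b <- sampleReads(map, gl$seqlengths, depth = 30, seed = 2, sample_id = "mut")
#' cmp <- compareStrains(a, b, gl$genes, confirm = FALSE)
#' cmp
#' @export
compareStrains <- function(reads_A, reads_B, genes, config = pipelineConfig(),
                           confirm = TRUE) {
  validateConfig(config)
  fl_A <- resolveFragmentLength(reads_A, config)
  fl_B <- resolveFragmentLength(reads_B, config)
  core <- compareCore(reads_A, reads_B, genes, config, strands = "both",
                      fl_A = fl_A, fl_B = fl_B)
  changes <- core$changes
  if (confirm) {
    changes <- strandSplitConfirm(changes, reads_A, reads_B, genes, config,
                                  fl_A = fl_A, fl_B = fl_B)
  } else {
    changes$confirmed_forward <- rep(NA, nrow(changes))
    changes$confirmed_reverse <- rep(NA, nrow(changes))
    changes$confirmed <- rep(NA, nrow(changes))
  }
  cls <- factor(changes$class, levels = c("shift", "occupancy", "loss", "gain"))
  summ <- list(
    n_calls_A = nrow(core$callsA), n_calls_B = nrow(core$callsB),
    n_pairs = nrow(core$pairs),
    n_by_class = as.list(table(cls)),
    n_confirmed_by_class = if (confirm)
      as.list(tapply(changes$confirmed, cls, sum, default = 0L)) else NULL)
  new("StrainComparison", changes = changes, pairs = core$pairs,
      callsA = core$callsA, callsB = core$callsB, summary = summ,
      config = unclass(config))
}
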