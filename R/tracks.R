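## Track building: fragment-length estimation, read-center conversion,
## occupancy (boxcar) and nucleosome-score (Gaussian) tracks, quantile
## normalization across samples, replicate averaging.

## center offset of a read 5' end for fragment length L (see sampleReads
## for the even-L convention)
centerOffsets <- function(L) {
  L <- as.integer(L)
  if (L %% 2L == 1L) c(fwd = (L - 1L) %/% 2L, rev = -(L - 1L) %/% 2L)
  else               c(fwd = L %/% 2L,        rev = -(L %/% 2L - 1L))
}

## unit-mass discrete Gaussian kernel on -halfwidth..halfwidth
gaussKernel <- function(sd, halfwidth) {
  d <- seq(-halfwidth, halfwidth)
  k <- exp(-d^2 / (2 * sd^2))
  k / sum(k)
}

## strict local maxima (plateaus -> leftmost bp) via run-length encoding
localMaxima <- function(v) {
  r <- rle(as.numeric(v))
  n <- length(r$values)
  if (n < 3L) return(integer())
  starts <- cumsum(c(1L, r$lengths[-n]))
  mid <- 2:(n - 1L)
  peak <- r$values[mid] > r$values[mid - 1L] & r$values[mid] > r$values[mid + 1L]
  starts[mid][peak]
}

#' Estimate the sequenced fragment length from strand-shifted peak pairs
#'
#' Smooths the forward- and reverse-strand read 5'-end densities, finds local
#' maxima, pairs each forward peak with the nearest reverse peak at greater
#' coordinate, and returns the median of (reverse 5' - forward 5' + 1) over
#' pairs. This exploits the fixed offset between the two sequenced ends of
#' mono-nucleosome fragments.
#'
#' @param reads a \linkS4class{ReadSet} with reads on both strands.
#' @param smoothing_sd Gaussian sd (bp) used to smooth the per-strand
#'   densities before peak finding.
#' @param min_peak_reads minimum raw reads within +/- 3 sd of a smoothed peak
#'   for it to count.
#' @param search_window maximal forward-to-reverse peak distance considered.
#' @return list with \code{fragment_length} (bp), \code{n_pairs} and
#'   \code{iqr} of the pair distances. Fewer than 50 pairs triggers a
#'   low-confidence warning; zero pairs is an error asking for an explicit
#'   fragment length.
#' @export
estimateFragmentLength <- function(reads, smoothing_sd = 10,
                                   min_peak_reads = 10, search_window = 300) {
  k <- gaussKernel(smoothing_sd, 3L * ceiling(smoothing_sd))
  hw <- (length(k) - 1L) %/% 2L
  dists <- numeric()
  for (chr in names(chromLengths(reads))) {
    len <- chromLengths(reads)[[chr]]
    peaksOf <- function(pos) {
      if (length(pos) == 0L) return(integer())
      cnt <- tabulate(pos, nbins = len)
      sm <- stats::filter(c(numeric(hw), cnt, numeric(hw)), k, sides = 2)
      sm <- as.numeric(sm[(hw + 1L):(hw + len)])
      pk <- localMaxima(sm)
      if (!length(pk)) return(integer())
      cs <- cumsum(cnt)
      lo <- pmax(pk - 3L * smoothing_sd, 1L)
      hi <- pmin(pk + 3L * smoothing_sd, len)
      support <- cs[hi] - c(0, cs)[lo]
      pk[support >= min_peak_reads]
    }
    fp <- peaksOf(strandReads(reads, "+", chr))
    rp <- peaksOf(strandReads(reads, "-", chr))
    if (!length(fp) || !length(rp)) next
    ## nearest reverse peak strictly downstream of each forward peak
    idx <- findInterval(fp, rp) + 1L
    ok <- idx <= length(rp)
    d <- rp[idx[ok]] - fp[ok]
    dists <- c(dists, d[d > 0 & d <= search_window] + 1L)
  }
  if (!length(dists))
    stop("no forward/reverse peak pairs found; supply fragment_length explicitly")
  if (length(dists) < 50L)
    warning("fragment-length estimate based on only ", length(dists),
            " peak pairs (low confidence)")
  list(fragment_length = as.integer(round(median(dists))),
       n_pairs = length(dists),
       iqr = unname(diff(quantile(dists, c(0.25, 0.75)))))
}

#' Convert read 5' positions to a fragment-center count track
#'
#' Each forward read at p contributes a center at p + (L-1)/2 and each
#' reverse read at q a center at q - (L-1)/2 (left-of-middle bp for even L),
#' assuming a constant fragment length L. Centers falling off the chromosome
#' are clipped and counted.
#'
#' @param reads a \linkS4class{ReadSet}.
#' @param fragment_length assumed constant fragment length L in bp.
#' @param strands which reads to use: \code{"both"}, \code{"forward_only"} or
#'   \code{"reverse_only"}.
#' @return \linkS4class{GenomeTrack} of kind \code{"center"}; the values sum
#'   to the number of reads used minus the clip count.
#' @examples
#' rs <- ReadSet(fwd = list(chrI = 100L), rev = list(chrI = 250L),
#'               seqlengths = c(chrI = 1000L))
#' which(trackValues(readsToCenters(rs, 151), "chrI") > 0)  # both at 175
#' @export
readsToCenters <- function(reads, fragment_length,
                           strands = c("both", "forward_only", "reverse_only")) {
  strands <- match.arg(strands)
  if (fragment_length < 1) stop("fragment_length must be >= 1")
  off <- centerOffsets(fragment_length)
  vals <- list(); used <- 0; clipped <- 0
  for (chr in names(chromLengths(reads))) {
    len <- chromLengths(reads)[[chr]]
    ctr <- integer()
    if (strands != "reverse_only")
      ctr <- c(ctr, strandReads(reads, "+", chr) + off[["fwd"]])
    if (strands != "forward_only")
      ctr <- c(ctr, strandReads(reads, "-", chr) + off[["rev"]])
    used <- used + length(ctr)
    inb <- ctr >= 1L & ctr <= len
    clipped <- clipped + sum(!inb)
    vals[[chr]] <- as.numeric(tabulate(ctr[inb], nbins = len))
  }
  GenomeTrack(vals, "center", totalReads = used - clipped, clipped = clipped,
              metadata = list(fragment_length = as.integer(fragment_length),
                              strands = strands, sample_id = sampleId(reads)))
}

#' Nucleosome occupancy track from fragment centers
#'
#' Occupancy at bp x is the number of fragment centers within
#' x +/- (nucleosome_length - 1)/2, i.e. the number of reads whose implied
#' 147 bp mono-nucleosome fragment covers x. Exact discrete boxcar
#' convolution via cumulative sums.
#'
#' @param centers a center-kind \linkS4class{GenomeTrack}.
#' @param nucleosome_length assumed nucleosome footprint, bp; odd values are
#'   expected (even values warn and use an asymmetric split, one bp more on
#'   the left).
#' @return \linkS4class{GenomeTrack} of kind \code{"occupancy"}.
#' @export
computeOccupancy <- function(centers, nucleosome_length = 147) {
  stopifnot(trackKind(centers) == "center")
  nl <- as.integer(nucleosome_length)
  if (nl %% 2L == 0L) {
    warning("even nucleosome_length: using ", nl %/% 2L, " bp left / ",
            nl %/% 2L - 1L, " bp right of each position")
    hl <- nl %/% 2L; hr <- nl %/% 2L - 1L
  } else hl <- hr <- (nl - 1L) %/% 2L
  vals <- lapply(trackValues(centers), function(v) {
    len <- length(v)
    cs <- c(0, cumsum(v))
    hi <- pmin(seq_len(len) + hr, len)
    lo <- pmax(seq_len(len) - hl, 1L)
    cs[hi + 1L] - cs[lo]
  })
  GenomeTrack(vals, "occupancy", totalReads = totalReads(centers),
              metadata = c(centers@metadata,
                           list(nucleosome_length = nl)))
}

#' Gaussian-smoothed nucleosome-score track
#'
#' Convolves the fragment-center counts with a discrete Gaussian kernel
#' (default sd 25 bp) truncated at +/- \code{halfwidth} (default 50 bp) and
#' renormalized to unit mass, producing sharp peaks at nucleosome centers.
#' Away from chromosome ends the transformation conserves total center mass;
#' boundary-truncated mass is tracked in the \code{clipped} slot.
#'
#' @param centers a center-kind \linkS4class{GenomeTrack}.
#' @param sd kernel standard deviation, bp.
#' @param halfwidth kernel truncation half-width, bp (>= sd).
#' @return \linkS4class{GenomeTrack} of kind \code{"score"}.
#' @export
computeScores <- function(centers, sd = 25, halfwidth = 50) {
  stopifnot(trackKind(centers) == "center")
  if (sd <= 0) stop("sd must be positive")
  if (halfwidth < sd) stop("halfwidth must be >= sd")
  k <- gaussKernel(sd, as.integer(halfwidth))
  hw <- as.integer(halfwidth)
  clipped <- 0
  vals <- lapply(trackValues(centers), function(v) {
    len <- length(v)
    sm <- stats::filter(c(numeric(hw), v, numeric(hw)), k, sides = 2)
    sm <- as.numeric(sm[(hw + 1L):(hw + len)])
    clipped <<- clipped + (sum(v) - sum(sm))
    sm
  })
  GenomeTrack(vals, "score", totalReads = totalReads(centers),
              clipped = clipped,
              metadata = c(centers@metadata,
                           list(kernel_sd = sd, kernel_halfwidth = hw,
                                normalized = FALSE)))
}

#' Quantile-normalize nucleosome-score tracks across samples
#'
#' Classic quantile (percentile) normalization: genome-wide, the value of
#' rank r in each track is replaced by the across-track mean of the rank-r
#' values (ties share their rank-range mean), after which all tracks have
#' identical sorted value vectors. Delegates to
#' \code{\link[limma]{normalizeQuantiles}}.
#'
#' @param tracks list of >= 2 score-kind \linkS4class{GenomeTrack}s over the
#'   same genome.
#' @return list of normalized tracks, same order.
#' @export
percentileNormalize <- function(tracks) {
  if (length(tracks) < 2L) stop("need at least two tracks")
  lens <- lapply(tracks, chromLengths)
  for (i in seq_along(tracks)[-1L])
    if (!identical(lens[[1L]], lens[[i]]))
      stop("tracks cover different genomes")
  m <- vapply(tracks, function(t) unlist(trackValues(t), use.names = FALSE),
              numeric(sum(lens[[1L]])))
  m <- limma::normalizeQuantiles(m, ties = TRUE)
  bounds <- c(0L, cumsum(lens[[1L]]))
  lapply(seq_along(tracks), function(i) {
    v <- m[, i]
    vals <- lapply(seq_along(lens[[1L]]), function(j)
      v[(bounds[j] + 1L):bounds[j + 1L]])
    names(vals) <- names(lens[[1L]])
    t <- tracks[[i]]
    md <- t@metadata; md$normalized <- TRUE
    GenomeTrack(vals, "score", totalReads = totalReads(t),
                clipped = t@clipped, metadata = md)
  })
}

#' Average center tracks of biological repeats
#'
#' Simple per-bp mean of two or more center tracks, for merging biological
#' repeats before scoring.
#'
#' @param tracks list of center-kind \linkS4class{GenomeTrack}s over the same
#'   genome.
#' @return a center-kind \linkS4class{GenomeTrack}.
#' @export
averageCenterTracks <- function(tracks) {
  if (length(tracks) < 2L) stop("need at least two tracks")
  chroms <- names(trackValues(tracks[[1L]]))
  vals <- lapply(chroms, function(chr)
    Reduce(`+`, lapply(tracks, trackValues, chrom = chr)) / length(tracks))
  names(vals) <- chroms
  GenomeTrack(vals, "center",
              totalReads = mean(vapply(tracks, totalReads, numeric(1L))),
              metadata = c(tracks[[1L]]@metadata, list(n_repeats = length(tracks))))
}
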