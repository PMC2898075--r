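#' @import methods
#' @importFrom stats median quantile rnorm rpois rbinom rgamma runif sd var
#' @importFrom utils head tail
NULL

#' ReadSet: strand-specific mapped read 5' positions
#'
#' Container for the 5'-end coordinates of mapped single-end mono-nucleosome
#' reads, kept separately for the forward and reverse strand of each
#' chromosome. Positions are 1-based and sorted ascending. This is the raw
#' evidence for every downstream track, call and comparison.
#'
#' @slot sampleId single character identifier of the sample.
#' @slot readLength mapped read length in bp.
#' @slot seqlengths named integer vector of chromosome lengths.
#' @slot fwd named list (one element per chromosome) of sorted integer
#'   vectors: 5' positions of forward-strand reads.
#' @slot rev same as \code{fwd} for reverse-strand reads (the 5' end of a
#'   reverse read is its rightmost base).
#'
#' @exportClass ReadSet
setClass("ReadSet",
  representation(
    sampleId   = "character",
    readLength = "integer",
    seqlengths = "integer",
    fwd        = "list",
    rev        = "list"
  )
)

setValidity("ReadSet", function(object) {
  msg <- character()
  sl <- object@seqlengths
  if (is.null(names(sl)) || anyDuplicated(names(sl)))
    msg <- c(msg, "seqlengths must be uniquely named")
  for (slot in c("fwd", "rev")) {
    x <- slot(object, slot)
    if (!identical(sort(names(x)), sort(names(sl))))
      msg <- c(msg, sprintf("names of @%s must match names(seqlengths)", slot))
    for (chr in names(x)) {
      p <- x[[chr]]
      if (length(p)) {
        if (is.unsorted(p))
          msg <- c(msg, sprintf("@%s[[%s]] is not sorted", slot, chr))
        if (p[1L] < 1L || p[length(p)] > sl[[chr]])
          msg <- c(msg, sprintf("@%s[[%s]] has positions outside [1, %d]",
                                slot, chr, sl[[chr]]))
      }
    }
  }
  if (length(object@readLength) != 1L || object@readLength < 1L)
    msg <- c(msg, "readLength must be a single positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct a ReadSet
#'
#' @param fwd,rev named lists of integer vectors of read 5' positions per
#'   chromosome (forward / reverse strand). Unsorted input is sorted.
#' @param seqlengths named integer vector of chromosome lengths.
#' @param readLength read length in bp (default 36).
#' @param sampleId sample identifier.
#' @return A \linkS4class{ReadSet}.
#' @examples
#' rs <- ReadSet(fwd = list(chrI = c(10L, 50L)), rev = list(chrI = 120L),
#'               seqlengths = c(chrI = 1000L), sampleId = "wt")
#' nReads(rs)
#' @export
ReadSet <- function(fwd, rev, seqlengths, readLength = 36L, sampleId = "sample") {
  sl <- setNames(as.integer(seqlengths), names(seqlengths))
  norm <- function(x) {
    out <- setNames(vector("list", length(sl)), names(sl))
    for (chr in names(sl)) {
      p <- x[[chr]]
      out[[chr]] <- if (is.null(p)) integer() else sort(as.integer(p))
    }
    out
  }
  new("ReadSet", sampleId = as.character(sampleId),
      readLength = as.integer(readLength), seqlengths = sl,
      fwd = norm(fwd), rev = norm(rev))
}

#' GenomeTrack: per-base-pair genomic signal
#'
#' A per-bp numeric signal over a genome, used for fragment-center counts
#' (\code{kind = "center"}), nucleosome occupancy under the 147 bp fragment
#' assumption (\code{kind = "occupancy"}) and Gaussian-smoothed nucleosome
#' scores (\code{kind = "score"}).
#'
#' @slot values named list of numeric vectors, one per chromosome, with
#'   length equal to the chromosome length.
#' @slot kind one of \code{"center"}, \code{"occupancy"}, \code{"score"}.
#' @slot totalReads number of reads that contributed to the track.
#' @slot clipped mass lost at chromosome boundaries (off-end centers for
#'   center tracks; truncated kernel mass for score tracks).
#' @slot metadata free-form list (fragment length, strands used, kernel
#'   parameters, normalization flag, ...).
#'
#' @exportClass GenomeTrack
setClass("GenomeTrack",
  representation(
    values     = "list",
    kind       = "character",
    totalReads = "numeric",
    clipped    = "numeric",
    metadata   = "list"
  )
)

setValidity("GenomeTrack", function(object) {
  msg <- character()
  if (!object@kind %in% c("center", "occupancy", "score"))
    msg <- c(msg, "kind must be 'center', 'occupancy' or 'score'")
  if (is.null(names(object@values)))
    msg <- c(msg, "values must be a named list")
  if (length(msg)) msg else TRUE
})

GenomeTrack <- function(values, kind, totalReads = 0, clipped = 0,
                        metadata = list()) {
  new("GenomeTrack", values = values, kind = kind,
      totalReads = as.numeric(totalReads), clipped = as.numeric(clipped),
      metadata = metadata)
}

#' StrainComparison: classified nucleosome differences between two samples
#'
#' Result container of \code{\link{compareStrains}}: the per-nucleosome pair
#' table with raw shift estimates, the classified and (optionally)
#' strand-confirmed change table, the nucleosome calls of both samples, and
#' summary counts per change class.
#'
#' @slot changes data.frame of classified changes (one row per change; a
#'   nucleosome pair may yield both a shift and an occupancy row).
#' @slot pairs data.frame of all mutual-nearest nucleosome pairs with raw
#'   signed shift estimates and t-test p-values (including sub-threshold
#'   pairs; substrate for the shift-distribution decomposition).
#' @slot callsA,callsB nucleosome call tables of samples A and B.
#' @slot summary named list of counts per class and confirmation status.
#' @slot config the PipelineConfig used.
#'
#' @exportClass StrainComparison
setClass("StrainComparison",
  representation(
    changes = "data.frame",
    pairs   = "data.frame",
    callsA  = "data.frame",
    callsB  = "data.frame",
    summary = "list",
    config  = "list"
  )
)
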