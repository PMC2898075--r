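#' Accessors for nucleodiff data containers
#'
#' Small accessor generics shared by \linkS4class{ReadSet},
#' \linkS4class{GenomeTrack} and \linkS4class{StrainComparison}.
#'
#' @param x a nucleodiff object.
#' @param chrom optional chromosome name; if omitted, list-valued slots are
#'   returned whole.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname accessors
#' @export
setGeneric("nReads", function(x) standardGeneric("nReads"))

#' @rdname accessors
#' @export
setGeneric("strandReads", function(x, strand = c("+", "-"), chrom = NULL)
  standardGeneric("strandReads"))

#' @rdname accessors
#' @export
setGeneric("trackValues", function(x, chrom = NULL) standardGeneric("trackValues"))

#' @rdname accessors
#' @export
setGeneric("trackKind", function(x) standardGeneric("trackKind"))

#' @rdname accessors
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname accessors
#' @export
setGeneric("changeTable", function(x) standardGeneric("changeTable"))

#' @rdname accessors
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname accessors
#' @export
setGeneric("callTable", function(x, which = c("A", "B")) standardGeneric("callTable"))

## ---- ReadSet methods --------------------------------------------------

#' @rdname accessors
#' @export
setMethod("sampleId", "ReadSet", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("chromLengths", "ReadSet", function(x) x@seqlengths)

#' @rdname accessors
#' @export
setMethod("nReads", "ReadSet", function(x)
  sum(lengths(x@fwd)) + sum(lengths(x@rev)))

#' @rdname accessors
#' @param strand \code{"+"} or \code{"-"}.
#' @export
setMethod("strandReads", "ReadSet", function(x, strand = c("+", "-"), chrom = NULL) {
  strand <- match.arg(strand)
  lst <- if (strand == "+") x@fwd else x@rev
  if (is.null(chrom)) lst else lst[[chrom]]
})

setMethod("show", "ReadSet", function(object) {
  cat("ReadSet '", object@sampleId, "': ",
      format(nReads(object), big.mark = ","), " reads (",
      format(sum(lengths(object@fwd)), big.mark = ","), " fwd / ",
      format(sum(lengths(object@rev)), big.mark = ","), " rev), ",
      length(object@seqlengths), " chromosome(s), read length ",
      object@readLength, " bp\n", sep = "")
})

## ---- GenomeTrack methods ----------------------------------------------

#' @rdname accessors
#' @export
setMethod("chromLengths", "GenomeTrack", function(x)
  setNames(vapply(x@values, length, integer(1L)), names(x@values)))

#' @rdname accessors
#' @export
setMethod("trackValues", "GenomeTrack", function(x, chrom = NULL)
  if (is.null(chrom)) x@values else x@values[[chrom]])

#' @rdname accessors
#' @export
setMethod("trackKind", "GenomeTrack", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("totalReads", "GenomeTrack", function(x) x@totalReads)

setMethod("show", "GenomeTrack", function(object) {
  cat("GenomeTrack [", object@kind, "]: ",
      length(object@values), " chromosome(s), ",
      format(sum(chromLengths(object)), big.mark = ","), " bp, ",
      format(round(object@totalReads), big.mark = ","), " reads",
      if (isTRUE(object@metadata$normalized)) ", quantile-normalized" else "",
      "\n", sep = "")
})

## ---- StrainComparison methods ------------------------------------------

#' @rdname accessors
#' @export
setMethod("changeTable", "StrainComparison", function(x) x@changes)

#' @rdname accessors
#' @export
setMethod("pairTable", "StrainComparison", function(x) x@pairs)

#' @rdname accessors
#' @param which \code{"A"} or \code{"B"}.
#' @export
setMethod("callTable", "StrainComparison", function(x, which = c("A", "B")) {
  which <- match.arg(which)
  if (which == "A") x@callsA else x@callsB
})

setMethod("show", "StrainComparison", function(object) {
  s <- object@summary
  cat("StrainComparison: ", nrow(object@callsA), " vs ", nrow(object@callsB),
      " nucleosome calls\n", sep = "")
  cls <- table(factor(object@changes$class,
                      levels = c("shift", "occupancy", "loss", "gain")))
  conf <- if ("confirmed" %in% names(object@changes))
    tapply(object@changes$confirmed, factor(object@changes$class,
           levels = names(cls)), sum)
  for (k in names(cls)) {
    cat(sprintf("  %-9s %4d", k, cls[[k]]))
    if (!is.null(conf) && !is.na(conf[[k]]))
      cat(sprintf("  (%d confirmed)", conf[[k]]))
    cat("\n")
  }
  invisible(NULL)
})
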