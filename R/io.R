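## Readers/writers for the standard plain-text formats the pipeline speaks:
## BED6 read files, gene-model TSV (with a minimal GFF3 adapter), bedGraph
## tracks, and TSV tables with a metadata header block. Coordinates are
## 1-based inclusive inside the package and converted to 0-based half-open
## only at the BED/bedGraph boundary.

#' @importFrom data.table fread fwrite data.table setDF
NULL

#' Read mapped reads from a BED6 file
#'
#' Expects 6 columns (chrom, start, end, name, score, strand), 0-based
#' half-open, strand in \{+, -\}. The 5' end of a + read is start + 1
#' (1-based); of a - read, end. Malformed rows raise an error naming the
#' first offending line.
#'
#' @param path BED6 file.
#' @param seqlengths optional named chromosome lengths; inferred from the
#'   data (max end, rounded up) when missing.
#' @param sample_id sample identifier.
#' @return A \linkS4class{ReadSet}.
#' @export
readBedReads <- function(path, seqlengths = NULL, sample_id = NULL) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 6L)
    stop("BED6 required: ", path, " has ", ncol(dt), " columns")
  names(dt)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad))
    stop("invalid strand '", dt$strand[bad[1L]], "' at line ", bad[1L],
         " of ", path)
  bad <- which(!is.finite(dt$start) | !is.finite(dt$end) | dt$end <= dt$start)
  if (length(bad))
    stop("invalid interval at line ", bad[1L], " of ", path)
  rl <- as.integer(round(median(dt$end - dt$start)))
  p5 <- ifelse(dt$strand == "+", dt$start + 1L, dt$end)
  if (is.null(seqlengths)) {
    mx <- tapply(dt$end, dt$chrom, max)
    seqlengths <- setNames(as.integer(mx + 1000L), names(mx))
  }
  fwd <- split(p5[dt$strand == "+"], dt$chrom[dt$strand == "+"])
  rev <- split(p5[dt$strand == "-"], dt$chrom[dt$strand == "-"])
  if (is.null(sample_id))
    sample_id <- sub("\\.bed(\\.gz)?$", "", basename(path))
  ReadSet(fwd, rev, seqlengths, readLength = rl, sampleId = sample_id)
}

#' Write a ReadSet as BED6
#'
#' Inverse of \code{\link{readBedReads}}: a + read with 5' end p occupies
#' [p - 1, p - 1 + L) and a - read [p - L, p), 0-based half-open, with the
#' sample id as name and score 0.
#'
#' @param reads a \linkS4class{ReadSet}.
#' @param path output file.
#' @export
writeBedReads <- function(reads, path) {
  L <- reads@readLength
  rows <- list()
  for (chr in names(chromLengths(reads))) {
    f <- strandReads(reads, "+", chr)
    r <- strandReads(reads, "-", chr)
    if (length(f))
      rows[[paste0(chr, "+")]] <- data.table(
        chrom = chr, start = f - 1L, end = f - 1L + L,
        name = sampleId(reads), score = 0L, strand = "+")
    if (length(r))
      rows[[paste0(chr, "-")]] <- data.table(
        chrom = chr, start = r - L, end = r,
        name = sampleId(reads), score = 0L, strand = "-")
  }
  dt <- data.table::rbindlist(rows)
  dt <- dt[order(dt$chrom, dt$start), ]
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read gene models from TSV (or minimal GFF3)
#'
#' TSV dialect: header row with gene_id, chrom, strand, tss, start_codon,
#' stop_codon; 1-based inclusive coordinates. The GFF3 adapter takes
#' \code{type == "gene"} features, uses the ID attribute as gene_id and --
#' lacking UTR annotation -- sets the TSS equal to the start codon (the
#' strand-appropriate feature end) with a warning. Anchor ordering is
#' validated against the strand, naming the offending gene.
#'
#' @param path input file.
#' @param format \code{"tsv"} or \code{"gff3"}.
#' @return gene model data.frame.
#' @export
readGeneTable <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    genes <- setDF(fread(path, header = TRUE, sep = "\t"))
  } else {
    ln <- readLines(path)
    ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
    dt <- fread(text = ln, header = FALSE, sep = "\t",
                col.names = c("chrom", "source", "type", "start", "end",
                              "score", "strand", "phase", "attr"))
    dt <- dt[dt$type == "gene", ]
    id <- sub(".*ID=([^;]+).*", "\\1", dt$attr)
    warning("GFF3 input lacks UTR annotation: TSS set to the start codon")
    genes <- data.frame(
      gene_id = id, chrom = dt$chrom, strand = dt$strand,
      tss = ifelse(dt$strand == "+", dt$start, dt$end),
      start_codon = ifelse(dt$strand == "+", dt$start, dt$end),
      stop_codon = ifelse(dt$strand == "+", dt$end, dt$start),
      stringsAsFactors = FALSE)
  }
  validateGeneModels(genes)
}

#' @rdname readGeneTable
#' @param genes gene model data.frame.
#' @export
writeGeneTable <- function(genes, path) {
  fwrite(genes[, c("gene_id", "chrom", "strand", "tss", "start_codon",
                   "stop_codon")], path, sep = "\t")
  invisible(path)
}

#' Write / read a GenomeTrack as bedGraph
#'
#' Run-length-encoded 4-column bedGraph (chrom, start, end, value; 0-based
#' half-open). Zero-valued runs are omitted on write and implied on read.
#'
#' @param track a \linkS4class{GenomeTrack}.
#' @param path file path.
#' @export
writeTrackBedGraph <- function(track, path) {
  rows <- lapply(names(trackValues(track)), function(chr) {
    v <- trackValues(track, chr)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    keep <- r$values != 0
    data.table(chrom = chr, start = (ends - r$lengths)[keep],
               end = ends[keep], value = r$values[keep])
  })
  fwrite(data.table::rbindlist(rows), path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname writeTrackBedGraph
#' @param seqlengths named chromosome lengths of the track to reconstruct.
#' @param kind track kind to stamp on the result.
#' @export
readTrackBedGraph <- function(path, seqlengths, kind = "score") {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "start", "end", "value"))
  vals <- lapply(names(seqlengths), function(chr) {
    v <- numeric(seqlengths[[chr]])
    d <- dt[dt$chrom == chr, ]
    if (nrow(d)) for (i in seq_len(nrow(d)))
      v[(d$start[i] + 1L):d$end[i]] <- d$value[i]
    v
  })
  names(vals) <- names(seqlengths)
  GenomeTrack(vals, kind, totalReads = sum(unlist(vals)))
}

#' Write a table with a metadata header block
#'
#' TSV preceded by \code{# key: value} comment lines recording thresholds
#' and sample roles, so every emitted metric documents how it was computed.
#'
#' @param df data.frame to write.
#' @param path output file.
#' @param metadata named list written as header comments.
#' @export
writeTableWithMeta <- function(df, path, metadata = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(metadata))
    writeLines(sprintf("# %s: %s", k, paste(metadata[[k]], collapse = ",")),
               con)
  close(con); on.exit()
  fwrite(df, path, sep = "\t", append = length(metadata) > 0,
         col.names = TRUE)
  invisible(path)
}

#' @rdname writeTableWithMeta
#' @return for the reader: the data.frame, with header comments in
#'   \code{attr(, "metadata")}.
#' @export
readTableWithMeta <- function(path) {
  hdr <- character()
  con <- file(path, "r")
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  close(con)
  df <- setDF(fread(path, header = TRUE, sep = "\t", skip = length(hdr)))
  meta <- list()
  for (ln in hdr) {
    kv <- sub("^#\\s*", "", ln)
    k <- sub(":.*", "", kv)
    meta[[k]] <- trimws(sub("^[^:]*:", "", kv))
  }
  attr(df, "metadata") <- meta
  df
}
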