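## Shared fixture builders. Everything is generated in code at test time.

## a ReadSet with reads piled at given 5' positions
pileReads <- function(fwd_pos, rev_pos, len = 1000L, n_each = 1L,
                      sample_id = "toy") {
  ReadSet(fwd = list(chrT = rep(as.integer(fwd_pos), each = n_each)),
          rev = list(chrT = rep(as.integer(rev_pos), each = n_each)),
          seqlengths = c(chrT = as.integer(len)), sampleId = sample_id)
}

## a center track with given counts at given positions
centerTrack <- function(pos, counts = 1, len = 1000L, chrom = "chrT") {
  v <- numeric(len)
  counts <- rep_len(counts, length(pos))
  for (i in seq_along(pos)) v[pos[i]] <- v[pos[i]] + counts[i]
  GenomeTrack(setNames(list(v), chrom), "center", totalReads = sum(v))
}

## a score track straight from per-bp values
scoreTrack <- function(v, chrom = "chrT") {
  GenomeTrack(setNames(list(as.numeric(v)), chrom), "score",
              totalReads = sum(v))
}

## a minimal call table
callRows <- function(center, score = 1, supporting_reads = 10L,
                     gene_id = NA_character_, ordinal = NA_integer_,
                     chrom = "chrT") {
  data.frame(chrom = rep_len(chrom, length(center)),
             center = as.integer(center),
             score = rep_len(score, length(center)),
             supporting_reads = rep_len(as.integer(supporting_reads),
                                        length(center)),
             gene_id = rep_len(gene_id, length(center)),
             ordinal = rep_len(as.integer(ordinal), length(center)),
             stringsAsFactors = FALSE)
}

## one + strand and one - strand gene on separate chromosomes
twinGenes <- function() {
  data.frame(
    gene_id = c("gp", "gm"), chrom = c("chrP", "chrM"),
    strand = c("+", "-"), tss = c(1000L, 9000L),
    start_codon = c(1050L, 8950L), stop_codon = c(2550L, 7450L),
    stringsAsFactors = FALSE)
}
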