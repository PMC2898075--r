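## End-to-end pipeline: simulate two strains, compare, compute metrics,
## write every artifact with a provenance block. Backs the command-line
## wrapper in inst/scripts/nucleodiff.

#' Simulate a two-strain MNase-seq study with known ground truth
#'
#' Builds a synthetic genome, a wild-type nucleosome map, a perturbed mutant
#' map, and samples reads for both strains; the workhorse behind validation
#' and the command-line \code{simulate} step.
#'
#' @param n_genes number of genes.
#' @param spec a \code{\link{perturbationSpec}} applied to the mutant map;
#'   \code{NULL} for an unperturbed pair (biological-repeat null).
#' @param depth mean reads per unit-weight nucleosome.
#' @param seed integer seed; wild-type and mutant read draws use
#'   \code{seed} and \code{seed + 1}.
#' @param ... further arguments to \code{\link{sampleReads}} (e.g.
#'   \code{jitter_sd}, \code{background_rate}, \code{both_ends}).
#' @return list: genes, seqlengths, map_wt, map_mut, truth, reads_wt,
#'   reads_mut.
#' @export
simulateStudy <- function(n_genes = 500, spec = NULL, depth = 30, seed = 1,
                          ...) {
  gl <- generateGenomeLayout(n_genes, seed = seed)
  map <- buildNucleosomeMap(gl$genes)
  if (is.null(spec)) {
    pert <- list(map = map,
                 truth = data.frame(gene_id = character(), ordinal = integer(),
                                    type = character(), value = numeric(),
                                    stringsAsFactors = FALSE))
  } else {
    pert <- applyPerturbation(map, spec, seed = seed)
  }
  reads_wt <- sampleReads(map, gl$seqlengths, depth = depth, seed = seed,
                          sample_id = "wt", ...)
  reads_mut <- sampleReads(pert$map, gl$seqlengths, depth = depth,
                           seed = seed + 1L, sample_id = "mut", ...)
  list(genes = gl$genes, seqlengths = gl$seqlengths, map_wt = map,
       map_mut = pert$map, truth = pert$truth,
       reads_wt = reads_wt, reads_mut = reads_mut)
}

#' Run the full comparison pipeline and write all outputs
#'
#' Reads two BED6 read files and a gene table (or takes the in-memory
#' objects), runs \code{\link{compareStrains}} and the downstream metrics,
#' and writes calls, the change table, metric tables and a provenance block
#' (config, seed, package version, input checksums) to \code{outdir}.
#' Deterministic given identical inputs and config.
#'
#' @param reads_A,reads_B \linkS4class{ReadSet}s or BED6 paths.
#' @param genes gene model data.frame or TSV path.
#' @param config a \code{\link{pipelineConfig}}.
#' @param outdir output directory (created).
#' @param confirm run strand-split confirmation.
#' @return the \linkS4class{StrainComparison}, invisibly.
#' @export
runPipeline <- function(reads_A, reads_B, genes, config = pipelineConfig(),
                        outdir = "nucleodiff_out", confirm = TRUE) {
  if (is.character(reads_A)) reads_A <- readBedReads(reads_A)
  if (is.character(reads_B)) reads_B <- readBedReads(reads_B)
  if (is.character(genes)) genes <- readGeneTable(genes)
  if (!identical(chromLengths(reads_A), chromLengths(reads_B))) {
    ## chromosome lengths inferred per file can disagree; use their union
    chroms <- union(names(chromLengths(reads_A)), names(chromLengths(reads_B)))
    sl <- setNames(pmax(chromLengths(reads_A)[chroms],
                        chromLengths(reads_B)[chroms], na.rm = TRUE), chroms)
    reads_A <- ReadSet(reads_A@fwd, reads_A@rev, sl, reads_A@readLength,
                       sampleId(reads_A))
    reads_B <- ReadSet(reads_B@fwd, reads_B@rev, sl, reads_B@readLength,
                       sampleId(reads_B))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cmp <- compareStrains(reads_A, reads_B, genes, config, confirm = confirm)

  meta <- list(sample_A = sampleId(reads_A), sample_B = sampleId(reads_B),
               min_shift = config$min_shift, alpha = config$alpha,
               min_fold = config$min_fold, min_reads = config$min_reads)
  writeTableWithMeta(callTable(cmp, "A"), file.path(outdir, "calls_A.tsv"), meta)
  writeTableWithMeta(callTable(cmp, "B"), file.path(outdir, "calls_B.tsv"), meta)
  writeTableWithMeta(changeTable(cmp), file.path(outdir, "changes.tsv"), meta)
  writeTableWithMeta(pairTable(cmp), file.path(outdir, "pairs.tsv"), meta)

  flA <- resolveFragmentLength(reads_A, config)
  flB <- resolveFragmentLength(reads_B, config)
  cA <- readsToCenters(reads_A, flA); cB <- readsToCenters(reads_B, flB)
  fuzz <- rbind(
    computeFuzziness(genes, callTable(cmp, "A"), cA,
                     window = config$fuzziness_window,
                     sample_id = sampleId(reads_A)),
    computeFuzziness(genes, callTable(cmp, "B"), cB,
                     window = config$fuzziness_window,
                     sample_id = sampleId(reads_B)))
  writeTableWithMeta(fuzz, file.path(outdir, "fuzziness.tsv"), meta)
  writeTableWithMeta(tssProfile(cA, genes), file.path(outdir, "tss_profile_A.tsv"), meta)
  writeTableWithMeta(tssProfile(cB, genes), file.path(outdir, "tss_profile_B.tsv"), meta)

  writePipelineConfig(config, file.path(outdir, "config.yaml"))
  prov <- c(sprintf("package: nucleodiff %s",
                    as.character(utils::packageVersion("nucleodiff"))),
            sprintf("date: %s", format(Sys.time(), "%Y-%m-%d")),
            sprintf("sample_A: %s (%d reads)", sampleId(reads_A), nReads(reads_A)),
            sprintf("sample_B: %s (%d reads)", sampleId(reads_B), nReads(reads_B)),
            sprintf("fragment_length_A: %d", flA),
            sprintf("fragment_length_B: %d", flB),
            sprintf("config_md5: %s",
                    unname(tools::md5sum(file.path(outdir, "config.yaml")))),
            sprintf("n_calls: %d / %d", nrow(callTable(cmp, "A")),
                    nrow(callTable(cmp, "B"))),
            sprintf("n_changes: %d", nrow(changeTable(cmp))))
  writeLines(prov, file.path(outdir, "provenance.txt"))
  invisible(cmp)
}
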