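## Synthetic chromatin: gene layouts, phased nucleosome maps, perturbations
## and MNase-seq-like read sampling with known ground truth.

#' Generate a synthetic genome layout of non-overlapping genes
#'
#' Tiles \code{n_genes} gene models along one or more chromosomes with
#' alternating strand, random (gamma-distributed) gene-body and intergenic
#' lengths, and a short 5' UTR separating the TSS from the start codon.
#' Purely structural plumbing for the simulator; deterministic given
#' \code{seed}.
#'
#' @param n_genes number of genes (>= 1).
#' @param mean_gene_length mean start-to-stop codon distance in bp.
#' @param mean_intergenic mean gap between adjacent gene spans in bp.
#' @param seed integer RNG seed.
#' @param genes_per_chrom genes tiled per chromosome before starting a new one.
#' @return list with \code{genes} (data.frame: gene_id, chrom, strand, tss,
#'   start_codon, stop_codon; 1-based) and \code{seqlengths} (named integer).
#' @examples
#' gl <- generateGenomeLayout(5, seed = 1)
#' gl$genes
#' @export
generateGenomeLayout <- function(n_genes, mean_gene_length = 1500,
                                 mean_intergenic = 700, seed = 1,
                                 genes_per_chrom = 250) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (mean_gene_length <= 0 || mean_intergenic <= 0)
    stop("mean_gene_length and mean_intergenic must be positive")
  set.seed(as.integer(seed))
  ## gamma lengths: cv ~ 0.5 for gene bodies, floor keeps room for >= 1
  ## nucleosome; intergenic floor keeps room for facing promoters
  body <- pmax(300L, as.integer(round(
    rgamma(n_genes, shape = 4, rate = 4 / mean_gene_length))))
  gap  <- pmax(200L, as.integer(round(
    rgamma(n_genes + 1L, shape = 2, rate = 2 / mean_intergenic))))
  utr  <- as.integer(sample(30:70, n_genes, replace = TRUE))
  strand <- rep_len(c("+", "-"), n_genes)

  chrom_of <- paste0("chr", (seq_len(n_genes) - 1L) %/% genes_per_chrom + 1L)
  genes <- vector("list", n_genes)
  seqlen <- integer()
  cursor <- 1L
  for (i in seq_len(n_genes)) {
    chr <- chrom_of[i]
    if (i > 1L && chrom_of[i - 1L] != chr) {  # close previous chromosome
      seqlen[chrom_of[i - 1L]] <- cursor + as.integer(mean_intergenic)
      cursor <- 1L
    }
    cursor <- cursor + gap[i]
    if (strand[i] == "+") {
      tss <- cursor; sc <- tss + utr[i]; ec <- sc + body[i]
      cursor <- ec + 1L
    } else {
      ec <- cursor; sc <- ec + body[i]; tss <- sc + utr[i]
      cursor <- tss + 1L
    }
    genes[[i]] <- data.frame(
      gene_id = sprintf("g%04d", i), chrom = chr, strand = strand[i],
      tss = tss, start_codon = sc, stop_codon = ec,
      stringsAsFactors = FALSE)
  }
  seqlen[chrom_of[n_genes]] <- cursor + gap[n_genes + 1L] +
    as.integer(mean_intergenic)
  genes <- do.call(rbind, genes)
  validateGeneModels(genes)
  list(genes = genes, seqlengths = seqlen)
}

## shared invariant checks for gene model tables
validateGeneModels <- function(genes) {
  req <- c("gene_id", "chrom", "strand", "tss", "start_codon", "stop_codon")
  miss <- setdiff(req, names(genes))
  if (length(miss)) stop("gene table lacks columns: ", paste(miss, collapse = ", "))
  plus <- genes$strand == "+"
  bad <- (plus  & !(genes$tss <= genes$start_codon &
                    genes$start_codon < genes$stop_codon)) |
         (!plus & !(genes$tss >= genes$start_codon &
                    genes$start_codon > genes$stop_codon))
  if (any(bad))
    stop("gene model anchor ordering violates strand for: ",
         paste(head(genes$gene_id[bad], 5L), collapse = ", "))
  invisible(genes)
}

#' Build a phased nucleosome map over gene models
#'
#' Emulates the canonical yeast promoter architecture: a nucleosome-free
#' region (NFR) upstream of the TSS followed by a phased array with
#' geometrically decaying occupancy. The +1 center sits a fixed offset
#' downstream of the TSS, subsequent centers every \code{spacing} bp up to
#' the stop codon (a gene shorter than one spacing still gets its +1);
#' upstream ordinals (-1, -2, ...) sit beyond the NFR. Cross-gene center
#' collisions closer than 120 bp (possible between facing promoters) are
#' resolved deterministically by dropping the lower-weight center, so the
#' returned map is the exact ground truth for read sampling.
#'
#' @param genes gene model data.frame (see \code{\link{generateGenomeLayout}}).
#' @param spacing center-to-center array spacing in bp (default 165, the
#'   wild-type median inter-nucleosome distance); a warning is issued below
#'   147 bp.
#' @param nfr_width edge-to-edge nucleosome-free gap between the -1 and +1
#'   nucleosomes, in bp.
#' @param decay fractional occupancy loss per ordinal step away from +1.
#' @param n_upstream number of upstream (promoter) nucleosomes per gene.
#' @param plus_one_offset distance from the TSS to the +1 center, bp.
#' @return data.frame (gene_id, chrom, strand, ordinal, center, weight,
#'   jitter_sd) with attributes \code{spacing} and \code{nfr_width}.
#' @examples
#' gl <- generateGenomeLayout(2, seed = 1)
#' map <- buildNucleosomeMap(gl$genes)
#' subset(map, gene_id == "g0001")
#' @export
buildNucleosomeMap <- function(genes, spacing = 165, nfr_width = 140,
                               decay = 0.05, n_upstream = 2,
                               plus_one_offset = 73) {
  if (spacing < 147)
    warning("spacing below 147 bp: nucleosomes will overlap")
  validateGeneModels(genes)
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    dir <- if (g$strand == "+") 1L else -1L
    p1 <- g$tss + dir * as.integer(plus_one_offset)
    ## downstream array: keep +1 unconditionally, extend while <= stop codon
    k <- 1L; centers <- p1; ords <- 1L
    repeat {
      nxt <- p1 + dir * as.integer(spacing) * k
      if (dir * (nxt - g$stop_codon) > 0) break
      k <- k + 1L; centers <- c(centers, nxt); ords <- c(ords, k)
    }
    ## upstream: -1 beyond the NFR, then spaced array
    if (n_upstream > 0) {
      m1 <- p1 - dir * (as.integer(nfr_width) + 147L)
      up <- m1 - dir * as.integer(spacing) * (seq_len(n_upstream) - 1L)
      centers <- c(up, centers); ords <- c(-seq_len(n_upstream), ords)
    }
    rows[[i]] <- data.frame(
      gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
      ordinal = ords, center = as.integer(centers),
      weight = (1 - decay)^(abs(ords) - 1L), jitter_sd = 0,
      stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, rows)
  map <- map[map$center >= 74L, , drop = FALSE]
  ## resolve cross-gene collisions (< 120 bp): drop the lighter center
  keep <- rep(TRUE, nrow(map))
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    idx <- idx[order(map$center[idx])]
    repeat {
      live <- idx[keep[idx]]
      d <- diff(map$center[live])
      j <- which(d < 120L &
                 map$gene_id[live[-length(live)]] != map$gene_id[live[-1L]])
      if (!length(j)) break
      a <- live[j[1L]]; b <- live[j[1L] + 1L]
      drop <- if (map$weight[a] < map$weight[b]) a
              else if (map$weight[b] < map$weight[a]) b
              else if (map$ordinal[a] < 0) a else b
      keep[drop] <- FALSE
    }
  }
  map <- map[keep, , drop = FALSE]
  rownames(map) <- NULL
  attr(map, "spacing") <- spacing
  attr(map, "nfr_width") <- nfr_width
  map
}

#' Describe a set of perturbations to inject into a nucleosome map
#'
#' Encodes the phenotypes of a chromatin-remodeler deletion: directional
#' position shifts at chosen gene/ordinal targets, evictions, occupancy
#' scaling, and per-gene positional jitter (fuzziness).
#'
#' @param shift_targets data.frame (gene_id, ordinal) of nucleosomes to shift.
#' @param shift_size shift magnitude in bp; positive displacement is applied
#'   toward the gene 5' end (upstream) with probability
#'   \code{shift_direction_bias}, else toward the 3' end.
#' @param shift_direction_bias fraction of targets shifted upstream, in [0,1].
#' @param eviction_targets data.frame (gene_id, ordinal) of nucleosomes to
#'   remove.
#' @param occupancy_scale data.frame (gene_id, ordinal, fold) of weight
#'   scalings.
#' @param jitter_sd data.frame (gene_id, sd) of per-gene positional jitter to
#'   apply at read sampling.
#' @return object of class \code{PerturbationSpec} (a validated list).
#' @examples
#' perturbationSpec(shift_targets = data.frame(gene_id = "g0001", ordinal = 5),
#'                  shift_size = 20, shift_direction_bias = 1)
#' @export
perturbationSpec <- function(shift_targets = NULL, shift_size = 20,
                             shift_direction_bias = 1,
                             eviction_targets = NULL,
                             occupancy_scale = NULL,
                             jitter_sd = NULL) {
  if (shift_direction_bias < 0 || shift_direction_bias > 1)
    stop("shift_direction_bias must be in [0, 1]")
  if (shift_size < 0) stop("shift_size must be non-negative")
  structure(list(shift_targets = shift_targets, shift_size = shift_size,
                 shift_direction_bias = shift_direction_bias,
                 eviction_targets = eviction_targets,
                 occupancy_scale = occupancy_scale, jitter_sd = jitter_sd),
            class = "PerturbationSpec")
}

#' Apply a perturbation spec to a nucleosome map
#'
#' Moves, removes and re-weights targeted nucleosomes and records every
#' applied change in a ground-truth table. Shift signs in the truth table are
#' gene-oriented: positive means the perturbed center lies closer to the gene
#' 5' end, regardless of chromosome strand. Unknown targets are skipped with
#' a warning and listed in the \code{skipped} element.
#'
#' @param map nucleosome map from \code{\link{buildNucleosomeMap}}.
#' @param spec a \code{\link{perturbationSpec}}.
#' @param seed integer seed (direction draws).
#' @return list with \code{map} (perturbed; structurally identical to the
#'   input when \code{spec} is empty), \code{truth} (data.frame: gene_id,
#'   ordinal, type, value) and \code{skipped}.
#' @export
applyPerturbation <- function(map, spec, seed = 1) {
  stopifnot(inherits(spec, "PerturbationSpec"))
  set.seed(as.integer(seed))
  out <- map
  truth <- list()
  skipped <- character()
  key <- paste(map$gene_id, map$ordinal)
  locate <- function(targets, what) {
    idx <- match(paste(targets$gene_id, targets$ordinal), key)
    bad <- is.na(idx)
    if (any(bad)) {
      warning(sum(bad), " unknown ", what, " target(s) skipped")
      skipped <<- c(skipped, paste(what, targets$gene_id[bad],
                                   targets$ordinal[bad]))
    }
    idx[!bad]
  }
  st <- spec$shift_targets
  if (!is.null(st) && nrow(st)) {
    idx <- locate(st, "shift")
    if (length(idx)) {
      upstream <- rbinom(length(idx), 1L, spec$shift_direction_bias) == 1L
      dir5 <- ifelse(out$strand[idx] == "+", -1L, 1L)  # toward smaller coord on +
      delta <- ifelse(upstream, dir5, -dir5) * as.integer(spec$shift_size)
      out$center[idx] <- out$center[idx] + delta
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = out$gene_id[idx], ordinal = out$ordinal[idx],
        type = "shift",
        value = ifelse(upstream, 1, -1) * spec$shift_size,
        stringsAsFactors = FALSE)
    }
  }
  ev <- spec$eviction_targets
  evict_idx <- integer()
  if (!is.null(ev) && nrow(ev)) {
    evict_idx <- locate(ev, "eviction")
    if (length(evict_idx))
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = out$gene_id[evict_idx], ordinal = out$ordinal[evict_idx],
        type = "eviction", value = NA_real_, stringsAsFactors = FALSE)
  }
  os <- spec$occupancy_scale
  if (!is.null(os) && nrow(os)) {
    idx <- locate(os, "occupancy")
    if (length(idx)) {
      ok <- !is.na(match(paste(os$gene_id, os$ordinal), key))
      out$weight[idx] <- out$weight[idx] * os$fold[ok]
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = out$gene_id[idx], ordinal = out$ordinal[idx],
        type = "occupancy", value = os$fold[ok], stringsAsFactors = FALSE)
    }
  }
  js <- spec$jitter_sd
  if (!is.null(js) && nrow(js)) {
    hit <- out$gene_id %in% js$gene_id
    out$jitter_sd[hit] <- js$sd[match(out$gene_id[hit], js$gene_id)]
    truth[[length(truth) + 1L]] <- data.frame(
      gene_id = js$gene_id, ordinal = NA_integer_, type = "jitter",
      value = js$sd, stringsAsFactors = FALSE)
  }
  if (length(evict_idx)) out <- out[-evict_idx, , drop = FALSE]
  rownames(out) <- NULL
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(), ordinal = integer(),
               type = character(), value = numeric(), stringsAsFactors = FALSE)
  list(map = out, truth = truth, skipped = skipped)
}

#' Sample strand-specific MNase-seq-like reads from a nucleosome map
#'
#' For each nucleosome, draws Poisson(\code{depth} x weight) mono-nucleosome
#' fragments with centers normally jittered around the true center, and emits
#' exactly one single-end read per fragment on the forward or reverse strand
#' with equal probability (or both ends when \code{both_ends = TRUE}, for
#' symmetric strand-split testing). For odd fragment length L the forward 5'
#' end is center - (L-1)/2 and the reverse 5' end center + (L-1)/2; for even
#' L, center - L/2 and center + L/2 - 1. Uniform background reads are added
#' at \code{background_rate} per kb. Reads whose 5' end falls off the
#' chromosome are discarded.
#'
#' @param map nucleosome map (possibly perturbed).
#' @param seqlengths named integer chromosome lengths.
#' @param depth mean fragments per unit-weight nucleosome.
#' @param fragment_length mono-nucleosome fragment length in bp.
#' @param read_length sequenced read length in bp.
#' @param jitter_sd global positional jitter sd (bp), combined in quadrature
#'   with the map's per-gene \code{jitter_sd}.
#' @param background_rate uniform background reads per kb of genome.
#' @param both_ends emit reads from both fragment ends.
#' @param seed integer seed.
#' @param sample_id sample identifier for the resulting \linkS4class{ReadSet}.
#' @return A \linkS4class{ReadSet}.
#' @examples
#' gl <- generateGenomeLayout(2, seed = 1)
#' map <- buildNucleosomeMap(gl$genes)
#' sampleReads(map, gl$seqlengths, depth = 10, seed = 1)
#' @export
sampleReads <- function(map, seqlengths, depth = 30, fragment_length = 151,
                        read_length = 36, jitter_sd = 0, background_rate = 5,
                        both_ends = FALSE, seed = 1, sample_id = "sample") {
  if (depth <= 0) stop("depth must be positive")
  if (fragment_length < read_length)
    stop("fragment_length must be >= read_length")
  set.seed(as.integer(seed))
  L <- as.integer(fragment_length)
  off_f <- if (L %% 2L == 1L) -(L - 1L) %/% 2L else -L %/% 2L
  off_r <- if (L %% 2L == 1L)  (L - 1L) %/% 2L else  L %/% 2L - 1L

  nfrag <- rpois(nrow(map), depth * map$weight)
  sds <- sqrt(jitter_sd^2 + map$jitter_sd^2)
  centers <- rep(map$center, nfrag)
  csd <- rep(sds, nfrag)
  if (any(csd > 0))
    centers <- centers + as.integer(round(rnorm(length(centers), 0, csd)))
  cchrom <- rep(map$chrom, nfrag)

  if (both_ends) {
    fpos <- centers + off_f; fchr <- cchrom
    rpos <- centers + off_r; rchr <- cchrom
  } else {
    fw <- rbinom(length(centers), 1L, 0.5) == 1L
    fpos <- centers[fw] + off_f;  fchr <- cchrom[fw]
    rpos <- centers[!fw] + off_r; rchr <- cchrom[!fw]
  }
  fwd <- list(); rev <- list()
  for (chr in names(seqlengths)) {
    len <- seqlengths[[chr]]
    f <- fpos[fchr == chr]; r <- rpos[rchr == chr]
    if (background_rate > 0) {
      nb <- rpois(1L, background_rate * len / 1000)
      if (nb > 0) {
        bpos <- sample.int(len, nb, replace = TRUE)
        bf <- rbinom(nb, 1L, 0.5) == 1L
        f <- c(f, bpos[bf]); r <- c(r, bpos[!bf])
      }
    }
    fwd[[chr]] <- f[f >= 1L & f <= len]
    rev[[chr]] <- r[r >= 1L & r <= len]
  }
  ReadSet(fwd, rev, seqlengths, readLength = as.integer(read_length),
          sampleId = sample_id)
}

#' Generate a per-gene covariate correlated with injected shifts
#'
#' Emulates a gene-level covariate (e.g. a histone-modification score) with a
#' controlled correlation to the indicator of a gene carrying an injected
#' shift: covariate = rho * standardized indicator +
#' sqrt(1 - rho^2) * standard normal noise.
#'
#' @param genes gene model data.frame.
#' @param truth ground-truth table from \code{\link{applyPerturbation}}.
#' @param correlation_strength rho in [0, 1].
#' @param seed integer seed.
#' @return data.frame (gene_id, covariate).
#' @export
generateCovariate <- function(genes, truth, correlation_strength = 0.6,
                              seed = 1) {
  if (correlation_strength < 0 || correlation_strength > 1)
    stop("correlation_strength must be in [0, 1]")
  set.seed(as.integer(seed))
  shifted <- genes$gene_id %in% truth$gene_id[truth$type == "shift"]
  z <- as.numeric(shifted)
  if (sd(z) > 0) z <- (z - mean(z)) / sd(z)
  rho <- correlation_strength
  data.frame(gene_id = genes$gene_id,
             covariate = rho * z + sqrt(1 - rho^2) * rnorm(nrow(genes)),
             stringsAsFactors = FALSE)
}
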