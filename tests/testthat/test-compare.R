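test_that("pairing is mutual-nearest with loss/gain spillover", {
  a <- callRows(1000L); b <- callRows(1010L)
  pr <- pairNucleosomes(a, b)
  expect_equal(nrow(pr$pairs), 1L)
  expect_equal(pr$pairs$distance, 10L)
  expect_equal(nrow(pr$unpaired_A) + nrow(pr$unpaired_B), 0L)

  ## contention: the nearer of two A calls wins the single B call
  a2 <- callRows(c(1000L, 1090L)); b2 <- callRows(1040L)
  pr2 <- pairNucleosomes(a2, b2)
  expect_equal(pr2$pairs$center_A, 1000L)
  expect_equal(pr2$unpaired_A$center, 1090L)
  expect_equal(nrow(pr2$unpaired_B), 0L)

  ## identity: perfect pairing; beyond the radius: no pairing
  pr3 <- pairNucleosomes(a2, a2)
  expect_equal(nrow(pr3$pairs), 2L)
  expect_equal(pr3$pairs$distance, c(0L, 0L))
  pr4 <- pairNucleosomes(callRows(1000L), callRows(1150L))
  expect_equal(nrow(pr4$pairs), 0L)
  expect_equal(pr4$unpaired_A$center, 1000L)
  expect_equal(pr4$unpaired_B$center, 1150L)
})

test_that("shift detection applies the 15 bp / p<0.05 rule with gene signs", {
  genes <- twinGenes()
  ## + strand gene: A at 1300, B at 1284 -> upstream shift +16
  mkt <- function(pos, n, chrom = "chrP", len = 10000L) {
    set.seed(sum(pos) + n)
    p <- rep(pos, each = n) + sample(-5:5, n * length(pos), replace = TRUE)
    centerTrack(p, len = len, chrom = chrom)
  }
  cA <- mkt(1300L, 30L); cB <- mkt(1284L, 30L)
  pairs <- data.frame(chrom = "chrP", center_A = 1300L, center_B = 1284L,
                      distance = 16L, score_A = 1, score_B = 1,
                      supporting_reads_A = 30L, supporting_reads_B = 30L,
                      gene_id = "gp", ordinal = 2L, stringsAsFactors = FALSE)
  det <- detectShifts(pairs, cA, cB, genes)
  expect_true(det$is_shift)
  expect_equal(det$signed_shift, 16)
  expect_lt(det$p_value, 0.05)

  ## same geometry on the - strand gene flips the sign
  cAm <- mkt(8300L, 30L, chrom = "chrM")
  cBm <- mkt(8316L, 30L, chrom = "chrM")
  pm <- pairs; pm$chrom <- "chrM"; pm$center_A <- 8300L; pm$center_B <- 8316L
  pm$gene_id <- "gm"
  detm <- detectShifts(pm, cAm, cBm, genes)
  expect_equal(detm$signed_shift, 16)
  expect_true(detm$is_shift)

  ## below 15 bp: never a shift call, whatever the p-value
  p10 <- pairs; p10$center_B <- 1290L
  c10 <- mkt(1290L, 30L)
  d10 <- detectShifts(p10, cA, c10, genes)
  expect_false(d10$is_shift)
  ## insufficient reads: flagged, not called
  thin <- detectShifts(pairs, centerTrack(1300L, len = 10000L, chrom = "chrP"),
                       centerTrack(1284L, len = 10000L, chrom = "chrP"), genes)
  expect_true(thin$insufficient)
  expect_false(thin$is_shift)
})

test_that("the t-test matches a direct Welch computation on toy reads", {
  x <- c(100, 102, 103, 105, 110, 111)
  y <- c(120, 121, 125, 130)
  cA <- centerTrack(as.integer(x), len = 300L)
  cB <- centerTrack(as.integer(y), len = 300L)
  pairs <- data.frame(chrom = "chrT", center_A = 105L, center_B = 124L,
                      distance = 19L, score_A = 1, score_B = 1,
                      supporting_reads_A = 6L, supporting_reads_B = 4L,
                      gene_id = NA_character_, ordinal = NA_integer_,
                      stringsAsFactors = FALSE)
  det <- detectShifts(pairs, cA, cB,
                      genes = data.frame(gene_id = character(),
                                         strand = character()))
  ## independent brute-force Welch t
  se <- sqrt(var(x) / length(x) + var(y) / length(y))
  tstat <- (mean(x) - mean(y)) / se
  df <- se^4 / ((var(x) / length(x))^2 / (length(x) - 1) +
                (var(y) / length(y))^2 / (length(y) - 1))
  expect_equal(det$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-12)

  ## degenerate zero-variance case: different means -> p 0, equal -> 1
  z1 <- centerTrack(150L, counts = 5, len = 300L)
  z2 <- centerTrack(160L, counts = 5, len = 300L)
  pz <- pairs; pz$center_A <- 150L; pz$center_B <- 160L
  dz <- detectShifts(pz, z1, z2, genes = data.frame(gene_id = character(),
                                                    strand = character()))
  expect_equal(dz$p_value, 0)
})

test_that("occupancy changes require a two-fold depth-corrected difference", {
  ## flat occupancy 10 vs 4, factor 1 -> fold 2.5
  oA <- GenomeTrack(list(chrT = rep(10, 1000)), "occupancy", totalReads = 100)
  oB <- GenomeTrack(list(chrT = rep(4, 1000)), "occupancy", totalReads = 100)
  pairs <- data.frame(chrom = "chrT", center_A = 500L, center_B = 500L,
                      distance = 0L, score_A = 1, score_B = 1,
                      supporting_reads_A = 10L, supporting_reads_B = 4L,
                      gene_id = "g", ordinal = 1L, stringsAsFactors = FALSE)
  det <- detectOccupancyChanges(pairs, oA, oB, global_factor = 1)
  expect_true(det$is_occ_change)
  expect_equal(det$occ_log2_fold, log2(2.5))

  ## equal occupancy: no call; 1.5-fold: no call
  d2 <- detectOccupancyChanges(pairs, oA, oA, global_factor = 1)
  expect_false(d2$is_occ_change)
  oC <- GenomeTrack(list(chrT = rep(6.67, 1000)), "occupancy", totalReads = 100)
  expect_false(detectOccupancyChanges(pairs, oA, oC,
                                      global_factor = 1)$is_occ_change)
  ## depth correction: 2x global depth difference is not a change
  d3 <- detectOccupancyChanges(pairs, oA, oB, global_factor = 2.5)
  expect_false(d3$is_occ_change)
  ## zero denominator: +Inf fold, still called
  oZ <- GenomeTrack(list(chrT = rep(0, 1000)), "occupancy", totalReads = 100)
  dz <- detectOccupancyChanges(pairs, oA, oZ, global_factor = 1)
  expect_true(dz$is_occ_change)
  expect_equal(dz$occ_log2_fold, Inf)
})

test_that("loss/gain needs two-fold occupancy and eight supporting reads", {
  oHi <- GenomeTrack(list(chrT = rep(9, 1000)), "occupancy", totalReads = 100)
  oLo <- GenomeTrack(list(chrT = rep(3, 1000)), "occupancy", totalReads = 100)
  up <- callRows(500L, supporting_reads = 12L, gene_id = "g", ordinal = 3L)
  hit <- detectLossGain(up, oHi, oLo, global_factor = 1, present = "A")
  expect_equal(hit$class, "loss")
  expect_equal(hit$occ_log2_fold, log2(3))
  gain <- detectLossGain(up, oHi, oLo, global_factor = 1, present = "B")
  expect_equal(gain$class, "gain")

  ## seven supporting reads: no call even at fold 3
  seven <- callRows(500L, supporting_reads = 7L, gene_id = "g", ordinal = 3L)
  expect_equal(nrow(detectLossGain(seven, oHi, oLo, global_factor = 1,
                                   present = "A")), 0L)
  ## sufficient reads but < 2-fold: no call
  oMid <- GenomeTrack(list(chrT = rep(6, 1000)), "occupancy", totalReads = 100)
  expect_equal(nrow(detectLossGain(up, oHi, oMid, global_factor = 1,
                                   present = "A")), 0L)
})

test_that("self-comparison yields no confirmed changes and A/B symmetry holds", {
  gl <- generateGenomeLayout(40, seed = 31)
  map <- buildNucleosomeMap(gl$genes)
  g5 <- unique(map$gene_id[map$ordinal == 5L])
  spec <- perturbationSpec(
    shift_targets = data.frame(gene_id = g5, ordinal = 5L),
    shift_size = 20, shift_direction_bias = 1)
  pm <- applyPerturbation(map, spec, seed = 31)$map
  rA <- sampleReads(map, gl$seqlengths, depth = 30, seed = 32, sample_id = "wt")
  rB <- sampleReads(pm, gl$seqlengths, depth = 30, seed = 33, sample_id = "mut")

  ## identical input on both sides: zero changes of any class
  self <- compareStrains(rA, rA, gl$genes, confirm = FALSE)
  expect_equal(nrow(changeTable(self)), 0L)

  ## symmetry: swapping samples negates shift signs
  ab <- compareStrains(rA, rB, gl$genes, confirm = FALSE)
  ba <- compareStrains(rB, rA, gl$genes, confirm = FALSE)
  shab <- changeTable(ab); shab <- shab[shab$class == "shift", ]
  shba <- changeTable(ba); shba <- shba[shba$class == "shift", ]
  expect_equal(nrow(shab), nrow(shba))
  m <- merge(shab[, c("gene_id", "ordinal", "signed_shift")],
             shba[, c("gene_id", "ordinal", "signed_shift")],
             by = c("gene_id", "ordinal"))
  expect_equal(m$signed_shift.x, -m$signed_shift.y)

  ## injected shifts are recovered and confirmed by strand splitting
  cmp <- compareStrains(rA, rB, gl$genes, confirm = TRUE)
  sh <- changeTable(cmp)
  sh <- sh[sh$class == "shift" & sh$ordinal == 5L, ]
  expect_gte(nrow(sh), 0.8 * length(g5))
  expect_equal(mean(sh$signed_shift), 20, tolerance = 0.25)
  expect_gte(mean(sh$confirmed), 0.8)

  ## monotonicity: raising the shift floor cannot increase the call count
  strict <- compareStrains(rA, rB, gl$genes,
                           config = pipelineConfig(min_shift = 25),
                           confirm = FALSE)
  expect_lte(sum(changeTable(strict)$class == "shift"),
             sum(changeTable(ab)$class == "shift"))
})

test_that("strand-split confirmation rejects strand-discordant shifts", {
  gl <- generateGenomeLayout(30, seed = 41)
  map <- buildNucleosomeMap(gl$genes)
  g4 <- unique(map$gene_id[map$ordinal == 4L])
  spec <- perturbationSpec(
    shift_targets = data.frame(gene_id = g4, ordinal = 4L),
    shift_size = 20, shift_direction_bias = 1)
  pm <- applyPerturbation(map, spec, seed = 41)$map
  ## both-end emission gives symmetric strand coverage
  rA <- sampleReads(map, gl$seqlengths, depth = 20, both_ends = TRUE,
                    seed = 42, sample_id = "wt")
  rB <- sampleReads(pm, gl$seqlengths, depth = 20, both_ends = TRUE,
                    seed = 43, sample_id = "mut")
  cmp <- compareStrains(rA, rB, gl$genes, confirm = TRUE)
  sh <- changeTable(cmp)
  sh <- sh[sh$class == "shift" & sh$ordinal == 4L, ]
  expect_gte(nrow(sh), 1L)
  expect_gte(mean(sh$confirmed), 0.8)

  ## chimera: forward strand carries the shift, reverse strand does not --
  ## such strand-discordant shifts must not be confirmed
  rB0 <- sampleReads(map, gl$seqlengths, depth = 20, both_ends = TRUE,
                     seed = 43, sample_id = "mut0")
  chim <- ReadSet(rB@fwd, rB0@rev, chromLengths(rB), readLength = 36L,
                  sampleId = "chimera")
  cmpc <- compareStrains(rA, chim, gl$genes, confirm = TRUE)
  shc <- changeTable(cmpc)
  shc <- shc[shc$class == "shift" & shc$ordinal == 4L, ]
  if (nrow(shc)) expect_lte(mean(shc$confirmed), 0.2)
})
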