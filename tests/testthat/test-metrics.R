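test_that("fuzziness counts reads near called centers over gene bodies", {
  genes <- data.frame(gene_id = "g1", chrom = "chrT", strand = "+",
                      tss = 60L, start_codon = 100L, stop_codon = 600L,
                      stringsAsFactors = FALSE)
  calls <- callRows(c(182L, 350L, 515L))
  ## all reads exactly at call centers -> 100%
  exact <- centerTrack(c(182L, 350L, 515L), counts = 10, len = 1000L)
  f <- computeFuzziness(genes, calls, exact)
  expect_equal(f$pct_within, 100)
  expect_equal(f$n_nucleosomes, 3L)

  ## uniform reads over a 165 bp tile with one central call: 41/165
  tile <- data.frame(gene_id = "t", chrom = "chrT", strand = "+",
                     tss = 100L, start_codon = 100L, stop_codon = 264L,
                     stringsAsFactors = FALSE)
  unif <- centerTrack(100:264, counts = 1, len = 1000L)
  ft <- computeFuzziness(tile, callRows(182L), unif)
  expect_equal(ft$pct_within, 100 * 41 / 165)

  ## no reads: undefined and flagged
  none <- computeFuzziness(genes, calls, centerTrack(900L, len = 1000L))
  expect_true(none$undefined)
  expect_true(is.na(none$pct_within))

  ## jittered reads are fuzzier than exact ones
  set.seed(51)
  jit <- centerTrack(as.integer(rep(c(182L, 350L, 515L), each = 30) +
                                round(rnorm(90, 0, 30))), len = 1000L)
  fj <- computeFuzziness(genes, calls, jit)
  expect_lt(fj$pct_within, f$pct_within)

  ## translation invariance: shifting reads and calls together is a no-op
  sh <- 37L
  f2 <- computeFuzziness(
    within(genes, { tss <- tss + sh; start_codon <- start_codon + sh
                    stop_codon <- stop_codon + sh }),
    callRows(c(182L, 350L, 515L) + sh),
    centerTrack(c(182L, 350L, 515L) + sh, counts = 10, len = 1000L))
  expect_equal(f2$pct_within, f$pct_within)
})

test_that("fuzziness classification follows the 5-point all-others rule", {
  rec <- function(pcts, counts = 5L) {
    data.frame(gene_id = "g", sample_id = paste0("s", seq_along(pcts)),
               pct_within = pcts, n_nucleosomes = rep_len(counts, length(pcts)),
               n_reads = 100L, undefined = FALSE, stringsAsFactors = FALSE)
  }
  ## 25 vs 45..49: the low sample is flagged
  cl <- classifyFuzzinessChange(rec(c(25, 45, 47, 49)))
  expect_equal(cl$fuzzier_in, "s1")
  expect_true(cl$classifiable)
  ## deltas below 5 points: nothing flagged
  expect_true(is.na(classifyFuzzinessChange(rec(c(44, 45, 47)))$fuzzier_in))
  ## unequal nucleosome counts: not classifiable
  r <- rec(c(25, 45, 47, 49)); r$n_nucleosomes <- c(5L, 5L, 6L, 5L)
  cl2 <- classifyFuzzinessChange(r)
  expect_false(cl2$classifiable)
  expect_true(is.na(cl2$fuzzier_in))
})

test_that("directionality uses the exact binomial against 0.5", {
  ch <- function(sh, ord = 5L) {
    data.frame(gene_id = sprintf("g%d", seq_along(sh)),
               ordinal = rep_len(ord, length(sh)),
               class = rep_len("shift", length(sh)),
               signed_shift = sh, stringsAsFactors = FALSE)
  }
  all_up <- shiftDirectionality(ch(rep(20, 10)))
  expect_equal(all_up$upstream_fraction, 1)
  expect_equal(all_up$p_value, 2 * 0.5^10)
  even <- shiftDirectionality(ch(c(20, 20, 20, 20, 20, -20, -20, -20, -20, -20)))
  expect_equal(even$upstream_fraction, 0.5)
  expect_equal(even$p_value, 1)
  ## closed-form check for n <= 20 against binom.test
  mixed <- shiftDirectionality(ch(c(rep(16, 14), rep(-16, 6))))
  expect_equal(mixed$p_value, binom.test(14, 20, 0.5)$p.value)
  ## ordinal filter
  two <- rbind(ch(rep(20, 4), ord = 5L), ch(rep(-20, 3), ord = 2L))
  expect_equal(shiftDirectionality(two, ordinals = 5L)$upstream_fraction, 1)
  expect_error(shiftDirectionality(ch(numeric())), "no shifts")
})

test_that("propagation reports the focal nucleosome and its neighbors", {
  ch <- data.frame(gene_id = "atp23", ordinal = c(4L, 5L), class = "shift",
                   signed_shift = c(34, 22), stringsAsFactors = FALSE)
  tr <- neighborShiftPropagation(ch)
  expect_equal(as.numeric(tr), c(0, 34, 22))   # +3 unshifted, +4 focal, +5 next
  ## single shifted nucleosome: both neighbors contribute zero
  single <- data.frame(gene_id = "g", ordinal = 3L, class = "shift",
                       signed_shift = 18, stringsAsFactors = FALSE)
  expect_equal(as.numeric(neighborShiftPropagation(single)), c(0, 18, 0))
  ## averaging across genes
  both <- rbind(ch, single)
  expect_equal(as.numeric(neighborShiftPropagation(both)), c(0, 26, 11))
})

test_that("linker distances and short-linker fractions are exact", {
  calls <- rbind(
    callRows(c(1000L, 1165L), gene_id = "a", ordinal = c(4L, 5L)),
    callRows(c(3000L, 3150L), gene_id = "b", ordinal = c(4L, 5L)),
    callRows(c(5000L, 5130L), gene_id = "c", ordinal = c(4L, 5L)))
  sel <- data.frame(gene_id = c("a", "b", "c", "zz"), ordinal = 5L)
  ld <- linkerDistribution(calls, sel)
  expect_equal(sort(ld$distances), c(130L, 150L, 165L))
  expect_equal(ld$median, 150)
  expect_equal(ld$frac_lt_147, 1 / 3)
  expect_equal(ld$frac_lt_137, 1 / 3)
  expect_equal(ld$n_skipped, 1L)
  ## all linkers >= 147: both fractions zero
  wide <- linkerDistribution(calls[calls$gene_id != "c", ],
                             sel[sel$gene_id %in% c("a", "b"), ])
  expect_equal(wide$frac_lt_147, 0)     # 150 and 165 both >= 147
  long <- linkerDistribution(callRows(c(100L, 265L), gene_id = "a",
                                      ordinal = c(4L, 5L)),
                             data.frame(gene_id = "a", ordinal = 5L))
  expect_equal(long$frac_lt_147, 0)
  expect_equal(long$frac_lt_137, 0)
})

test_that("TSS profiles are normalized and strand-symmetric", {
  genes <- twinGenes()
  genes$chrom <- c("chrP", "chrM")
  ## reads at mirrored oriented offsets
  offs <- c(-200L, 100L, 150L, 400L)
  cp <- centerTrack(1000L + offs, counts = 2, len = 10000L, chrom = "chrP")
  cm <- centerTrack(9000L - offs, counts = 2, len = 10000L, chrom = "chrM")
  both <- GenomeTrack(c(trackValues(cp), trackValues(cm)), "center",
                      totalReads = 16)
  pr <- tssProfile(both, genes, range = c(-500, 500), bin = 10)
  expect_equal(sum(pr$pct), 100)
  ## brute-force per-gene oracle: both genes contribute identical offsets,
  ## so each offset bin holds exactly twice the single-gene mass
  single <- tssProfile(cp, genes[1L, ], range = c(-500, 500), bin = 10)
  expect_equal(pr$pct, single$pct)
  hit <- pr$offset[pr$pct > 0]
  expect_setequal(hit, c(-200, 100, 150, 400))
})

test_that("positional enrichment localizes changes within gene bodies", {
  genes <- data.frame(gene_id = "g1", chrom = "chrT", strand = "+",
                      tss = 100L, start_codon = 140L, stop_codon = 2140L,
                      stringsAsFactors = FALSE)
  calls <- callRows(seq(240L, 2040L, by = 200L), gene_id = "g1",
                    ordinal = 1:10)
  ## no changes: all bins zero
  none <- positionalEnrichment(
    data.frame(gene_id = character(), ordinal = integer(),
               class = character(), stringsAsFactors = FALSE),
    calls, genes, n_bins = 10)
  expect_true(all(none$pct == 0))
  expect_equal(sum(none$n_total), 10L)
  ## mid-gene changes enrich central bins and conserve counts
  ch <- data.frame(gene_id = "g1", ordinal = 5:6, class = "shift",
                   stringsAsFactors = FALSE)
  mid <- positionalEnrichment(ch, calls, genes, n_bins = 10)
  expect_equal(sum(mid$n_changed), 2L)
  expect_equal(which(mid$n_changed > 0), 5:6)
})

test_that("stratified shift means recover covariate gradients", {
  set.seed(61)
  n <- 200L
  gid <- sprintf("g%03d", seq_len(n))
  shifted <- seq_len(n) %% 2L == 0L
  ch <- data.frame(gene_id = gid[shifted], ordinal = 5L, class = "shift",
                   signed_shift = 20, stringsAsFactors = FALSE)
  ## perfectly separating covariate: top strata at the injected size
  cov1 <- data.frame(gene_id = gid, covariate = as.numeric(shifted),
                     stringsAsFactors = FALSE)
  s1 <- stratifiedShiftMeans(ch, cov1, ordinal = 5L)
  expect_equal(s1$mean_shift[1:5], rep(0, 5))
  expect_equal(s1$mean_shift[6:10], rep(20, 5))
  ## independent covariate: no gradient (slope CI covers 0)
  cov0 <- data.frame(gene_id = gid, covariate = rnorm(n),
                     stringsAsFactors = FALSE)
  s0 <- stratifiedShiftMeans(ch, cov0, ordinal = 5L)
  fit <- summary(lm(mean_shift ~ stratum, data = s0))$coefficients
  expect_gt(fit["stratum", "Pr(>|t|)"], 0.05)
  expect_error(stratifiedShiftMeans(ch, cov1[1:5, ], ordinal = 5L),
               "fewer genes")
})

test_that("region occupancy log-ratios are zero on identity and exact", {
  genes <- twinGenes()
  cp <- centerTrack(c(900L, 1100L, 1200L), counts = c(5, 3, 2), len = 10000L,
                    chrom = "chrP")
  cm <- centerTrack(c(9100L, 8900L, 8800L), counts = c(5, 3, 2), len = 10000L,
                    chrom = "chrM")
  A <- GenomeTrack(c(trackValues(cp), trackValues(cm)), "center",
                   totalReads = 20)
  idp <- regionOccupancyLogratio(A, A, genes, "promoter_250")
  expect_equal(idp$log2_ratio, c(0, 0))
  ## brute-force region counts: promoter = 250 bp upstream of the TSS
  expect_equal(idp$n_A, c(5L, 5L))   # 900 in [750,999]; 9100 in [9001,9250]
  idc <- regionOccupancyLogratio(A, A, genes, "coding_500")
  expect_equal(idc$n_A, c(5L, 5L))   # 1100+1200 in [1050,1549]; mirrored
  ## injected 2x coding occupancy shows up as ~1 log2 unit
  B <- GenomeTrack(list(chrP = trackValues(cp, "chrP") * 2,
                        chrM = trackValues(cm, "chrM") * 2), "center",
                   totalReads = 40)
  dbl <- regionOccupancyLogratio(A, B, genes, "coding_500", pseudocount = 0)
  expect_equal(dbl$log2_ratio, c(0, 0))  # global factor absorbs uniform 2x
})

test_that("shift decomposition separates error from activity", {
  ## forced single-bin example: 500 up, 200 down, 300 zero -> fraction 0.30
  sh <- c(rep(3, 500), rep(-3, 200), rep(0, 300))
  d <- decomposeShiftDistribution(sh, bin_width = 5)
  expect_equal(d$estimated_shifted_fraction, 0.30)
  expect_equal(d$n, 1000L)
  ## symmetric histogram: fraction 0, all mass is error
  sym <- c(rep(c(4, -4), 50), rep(c(12, -12), 20))
  ds <- decomposeShiftDistribution(sym)
  expect_equal(ds$estimated_shifted_fraction, 0)
  expect_equal(ds$bins$error, pmin(ds$bins$upstream, ds$bins$downstream))
  ## error + activity reproduce the upstream histogram when U >= D
  set.seed(71)
  shifts <- c(rnorm(400, 20, 6), rnorm(600, 0, 4))
  dd <- decomposeShiftDistribution(shifts)
  expect_equal(dd$bins$error + dd$bins$activity, dd$bins$upstream)
  expect_equal(sum(dd$bins$activity) / dd$n, dd$estimated_shifted_fraction)
  expect_error(decomposeShiftDistribution(numeric()), "no shift")
})

test_that("metrics are invariant to chromosome strand given orientation", {
  ## identical gene architecture on + and - strands, mirrored reads
  genes <- twinGenes()
  map <- buildNucleosomeMap(genes)
  sl <- c(chrP = 10000L, chrM = 10000L)
  rs <- sampleReads(map, sl, depth = 40, jitter_sd = 0, background_rate = 0,
                    seed = 81)
  ctr <- readsToCenters(rs, 151)
  calls <- assignOrdinals(callNucleosomes(computeScores(ctr), centers = ctr),
                          genes)
  fz <- computeFuzziness(genes, calls, ctr)
  expect_equal(fz$n_nucleosomes[1L], fz$n_nucleosomes[2L])
  expect_lt(abs(fz$pct_within[1L] - fz$pct_within[2L]), 8)
  ## ordinals mirror
  op <- calls$ordinal[calls$gene_id == "gp"]
  om <- calls$ordinal[calls$gene_id == "gm"]
  expect_setequal(op, om)
})
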