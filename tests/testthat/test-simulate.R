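# Synthetic-data generator: determinism, expected intensities, truth
# scoring, fixture bundles.

small_cfg <- function(seed = 1L, background_depth = 0, ...) {
  asm <- toy_assembly(chrS = 100000L)
  genes <- GRanges("chrS", IRanges(30001L, 40000L), strand = "+",
                   seqinfo = asm)
  mcols(genes)$name <- "gA"
  ft <- data.frame(chrom = "chrS",
                   start = c(10000L, 60000L),
                   end = c(11500L, 61500L),
                   kind = c("rloop", "bubble"),
                   displaced_strand = c("+", "+"),
                   asymmetry = c(4, 1),
                   depth = c(40, 40))
  sim_config(asm, genes, ft, background_depth = background_depth,
             seed = seed, ...)
}

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- small_cfg(seed = 42L)
  a <- simulate_condition(cfg, "control")
  b <- simulate_condition(cfg, "control")
  expect_identical(granges(a$frags$plus), granges(b$frags$plus))
  expect_identical(granges(a$frags$minus), granges(b$frags$minus))
  c_ <- simulate_condition(small_cfg(seed = 43L), "control")
  expect_false(identical(granges(a$frags$plus), granges(c_$frags$plus)))
})

test_that("expected intensities encode the signal model", {
  cfg <- small_cfg()
  tr <- expected_intensities(cfg, "control")
  # asymmetry 4, depth 40 -> displaced 40, paired 10 (background 0)
  expect_equal(tr[tr$kind == "rloop", ]$exp_plus, 40)
  expect_equal(tr[tr$kind == "rloop", ]$exp_minus, 10)
  expect_equal(tr[tr$kind == "bubble", ]$exp_plus, 40)
  expect_equal(tr[tr$kind == "bubble", ]$exp_minus, 40)

  # full digestion erases R-loop asymmetry, bubbles untouched
  cfg1 <- small_cfg(rnase_h_efficiency = c(`hi` = 1))
  t1 <- expected_intensities(cfg1, "rnase_h", dose = "hi")
  expect_equal(t1[t1$kind == "rloop", ]$exp_plus,
               t1[t1$kind == "rloop", ]$exp_minus)
  expect_equal(t1[t1$kind == "rloop", ]$exp_plus, 25)

  # dose-monotone asymmetry when efficiencies are non-decreasing
  asym <- sapply(names(cfg$rnase_h_efficiency), function(d) {
    t_ <- expected_intensities(cfg, "rnase_h", dose = d)
    r <- t_[t_$kind == "rloop", ]
    r$exp_plus - r$exp_minus
  })
  expect_true(all(diff(asym) <= 0))

  expect_error(expected_intensities(cfg, "rnase_h", dose = "999"),
               "invalid RNase H dose")
})

test_that("efficiency-0 RNase H is bit-identical to control", {
  cfg <- small_cfg(seed = 5L)
  ctl <- simulate_condition(cfg, "control")
  rh0 <- simulate_condition(cfg, "rnase_h", dose = "0")
  expect_identical(granges(ctl$frags$plus), granges(rh0$frags$plus))
  expect_identical(granges(ctl$frags$minus), granges(rh0$frags$minus))
})

test_that("empirical coverage matches the truth set across seeds", {
  # 50 independent seeds on a tiny world; per-feature mean bin coverage
  # should match the stated intensity within 3 standard errors
  depths <- matrix(NA_real_, nrow = 50L, ncol = 2L)
  for (i in 1:50) {
    cfg <- small_cfg(seed = 1000L + i)
    sim <- simulate_condition(cfg, "control")
    bins <- truth_granges(sim$truth, cfg$assembly)
    d <- bin_density(sim$frags, bins)
    depths[i, ] <- d$plus_density
  }
  est <- colMeans(depths)
  se <- apply(depths, 2, sd) / sqrt(nrow(depths))
  expect_lt(abs(est[1] - 40), 3 * se[1])  # R-loop displaced strand
  expect_lt(abs(est[2] - 40), 3 * se[2])  # bubble plus strand

  # bubbles are balanced in expectation: mean log2 ratio ~ 0
  ratios <- sapply(1:50, function(i) {
    cfg <- small_cfg(seed = 2000L + i)
    sim <- simulate_condition(cfg, "control")
    bins <- truth_granges(sim$truth, cfg$assembly)[2]
    d <- bin_density(sim$frags, bins)
    log2((d$plus_density + 1) / (d$minus_density + 1))
  })
  expect_lt(abs(mean(ratios)), 0.05)
})

test_that("transcription inhibitors zero out non-retained features", {
  asm <- toy_assembly(chrS = 50000L)
  ft <- data.frame(chrom = "chrS", start = c(10000L, 30000L),
                   end = c(11500L, 31500L), kind = "rloop",
                   displaced_strand = "+", asymmetry = 4, depth = 40,
                   drb_retained = c(TRUE, FALSE),
                   trp_retained = c(FALSE, FALSE))
  cfg <- sim_config(asm, GRanges(seqinfo = asm), ft, background_depth = 0)
  td <- expected_intensities(cfg, "drb")
  expect_equal(td$exp_plus, c(40, 0))
  tt <- expected_intensities(cfg, "trp")
  expect_equal(tt$exp_plus, c(0, 0))
  sim <- simulate_condition(cfg, "trp")
  expect_equal(sim$frags$library_size, 0L)
})

test_that("score_calls measures recovery against the truth", {
  cfg <- small_cfg()
  truth <- expected_intensities(cfg, "control")
  asm <- cfg$assembly
  exact <- truth_granges(truth[truth$kind == "rloop", ], asm)
  strand(exact) <- "+"
  s <- score_calls(exact, truth, asm)
  expect_equal(s[c("sensitivity", "precision", "strand_accuracy")],
               list(sensitivity = 1, precision = 1, strand_accuracy = 1))
  expect_equal(s$bubble_false_rate, 0)

  s0 <- score_calls(GRanges(seqinfo = asm), truth, asm)
  expect_true(s0$no_calls)
  expect_equal(s0$sensitivity, 0)
  expect_equal(s0$precision, 0)

  bubble_only <- truth_granges(truth[truth$kind == "bubble", ], asm)
  sb <- score_calls(bubble_only, truth, asm)
  expect_equal(sb$precision, 0)
  expect_equal(sb$bubble_false_rate, 1)

  wrong <- exact
  strand(wrong) <- "-"
  expect_equal(score_calls(wrong, truth, asm)$strand_accuracy, 0)
  expect_error(score_calls(exact, truth[0], asm), "empty truth")
})

test_that("fixture bundles are byte-identical and internally consistent", {
  cfg <- small_cfg(seed = 77L, background_depth = 1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- emit_fixture_bundle(cfg, d1, conditions = c("control", "drb"))
  emit_fixture_bundle(cfg, d2, conditions = c("control", "drb"))
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  # bundle round-trips through the readers and peaks cover planted loci
  asm <- read_chrom_sizes(p1$chrom_sizes)
  expect_identical(seqlengths(asm), seqlengths(cfg$assembly))
  peaks <- read_bed(p1$peaks, asm)
  wins <- make_windows(asm, 500L, 250L)
  cand <- filter_candidates(wins, peaks, 250L)
  truth <- data.table::fread(p1$truth, sep = "\t")
  tr_gr <- truth_granges(truth[truth$condition == "control"], asm)
  expect_true(all(overlapsAny(tr_gr, cand)))
  frags <- reads_to_fragments(read_bed(p1$fragments_control, asm),
                              mode = "paired_fragments")
  expect_gt(frags$library_size, 0L)
})
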