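# Shared fixture builders and independent oracles. All fixtures are built
# in code; coordinates passed to helpers are BED-style (0-based half-open).

library(GenomicRanges)

toy_assembly <- function(...) {
  v <- c(...)
  if (length(v) == 0L) v <- c(chrT = 10000L)
  do.call(rloopr::assembly, as.list(v))
}

# GRanges from a matrix-like list of c(start0, end0) pairs
gr0 <- function(asm, chrom, ranges0, strand = "*") {
  if (length(ranges0) == 0L) return(GRanges(seqinfo = asm))
  m <- do.call(rbind, ranges0)
  GRanges(chrom, IRanges(m[, 1] + 1L, m[, 2]), strand = strand,
          seqinfo = asm)
}

frags0 <- function(asm, chrom, plus = list(), minus = list(),
                   label = "toy") {
  stranded_fragments(gr0(asm, chrom, plus), gr0(asm, chrom, minus),
                     label = label)
}

peaks_everywhere <- function(asm) {
  GRanges(seqlevels(asm), IRanges(1L, seqlengths(asm)), seqinfo = asm)
}

# peak mask a simulation bundle would emit: planted loci + gene spans,
# padded 500 bp and unioned
sim_peaks <- function(cfg, pad = 500L) {
  ft <- cfg$features
  loci <- c(granges(cfg$genes),
            GRanges(ft$chrom, IRanges(ft$start + 1L, ft$end),
                    seqinfo = cfg$assembly))
  reduce(trim(suppressWarnings(loci + pad)), ignore.strand = TRUE)
}

truth_granges <- function(truth, asm) {
  GRanges(truth$chrom, IRanges(truth$start + 1L, truth$end),
          seqinfo = asm)
}

# --- independent oracles -------------------------------------------------

# two-sided exact binomial p at p0 = 0.5 by direct enumeration of the
# probability mass ("sum of probabilities no larger than the observed one")
brute_binom_p <- function(k, n) {
  if (n == 0) return(1)
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-12)])
}

# hand-rolled BH step-up: q_(i) = min_{j >= i} m p_(j) / j, input order kept
bh_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}
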