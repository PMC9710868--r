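# Core R-loop caller: per-bin strand-imbalance testing, thresholding, and
# direction-aware merging of significant bins into R-loop calls.

#' Caller configuration
#'
#' Defaults encode the published rule set: 500-bp bins with 250-bp step over
#' KAS-seq peaks (>= 250 bp overlap, blacklist excluded), averaged read
#' density strictly greater than 20, |log2(plus/minus)| >= 1 with a
#' pseudocount of 1 on both densities, BH-adjusted q <= 0.05, book-ended
#' merging of significant bins.
#'
#' @param bin_width Bin width in bp.
#' @param bin_step Step between bin starts in bp.
#' @param min_peak_overlap Minimum total bin/peak-union overlap in bp.
#' @param min_density Density threshold; a bin must exceed it strictly.
#' @param min_abs_log2_ratio Minimum |log2 strand ratio| (inclusive).
#' @param max_q Maximum BH-adjusted q (inclusive).
#' @param pseudocount Added to both strand densities inside the log2 ratio.
#' @param merge_gap Maximum gap bridged when merging significant bins.
#' @param density_mode How "averaged read density" combines the two strands
#'   for the `min_density` filter: `"mean"` (default), `"sum"`, or `"max"`.
#' @return A `CallerConfig` list.
#' @export
caller_config <- function(bin_width = 500L, bin_step = 250L,
                          min_peak_overlap = 250L, min_density = 20,
                          min_abs_log2_ratio = 1, max_q = 0.05,
                          pseudocount = 1, merge_gap = 0L,
                          density_mode = c("mean", "sum", "max")) {
  density_mode <- match.arg(density_mode)
  if (bin_width < 1L || bin_step < 1L || bin_step > bin_width)
    stop("need 1 <= bin_step <= bin_width")
  if (min_peak_overlap < 1L) stop("min_peak_overlap must be >= 1")
  if (min_density < 0) stop("min_density must be >= 0")
  if (min_abs_log2_ratio < 0) stop("min_abs_log2_ratio must be >= 0")
  if (max_q < 0 || max_q > 1) stop("max_q must be in [0, 1]")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (merge_gap < 0L) stop("merge_gap must be >= 0")
  structure(list(bin_width = as.integer(bin_width),
                 bin_step = as.integer(bin_step),
                 min_peak_overlap = as.integer(min_peak_overlap),
                 min_density = min_density,
                 min_abs_log2_ratio = min_abs_log2_ratio,
                 max_q = max_q, pseudocount = pseudocount,
                 merge_gap = as.integer(merge_gap),
                 density_mode = density_mode),
            class = "CallerConfig")
}

#' Two-sided exact binomial test of strand balance
#'
#' Tests `plus_count` successes out of `plus_count + minus_count` trials at
#' success probability 0.5. Because the null is symmetric the two-sided
#' p-value is `min(1, 2 * P(X <= min(counts)))`, identical to the exact
#' "sum of probabilities no larger than the observed one" rule. Zero trials
#' give p = 1 (no data, no evidence). Vectorised and symmetric in its
#' arguments.
#'
#' @param plus_count,minus_count Non-negative integer vectors.
#' @return Vector of two-sided exact p-values.
#' @export
strand_imbalance_test <- function(plus_count, minus_count) {
  if (length(plus_count) != length(minus_count))
    stop("count vectors must have equal length")
  if (length(plus_count) == 0L) return(numeric(0))
  if (any(plus_count < 0 | minus_count < 0)) stop("negative counts")
  if (any(plus_count != floor(plus_count) | minus_count != floor(minus_count)))
    stop("counts must be integers")
  n <- plus_count + minus_count
  k <- pmin(plus_count, minus_count)
  pmin(1, 2 * stats::pbinom(k, n, 0.5))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up q-values: `q_(i) = min_{j >= i} (m * p_(j) / j)`, clipped to 1,
#' returned in input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return q-values in the same order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-bin strand-imbalance statistics
#'
#' Extends [bin_density()] with the log2 strand ratio (pseudocount on both
#' densities), the exact binomial p-value, and BH q-values adjusted across
#' exactly the supplied bins (the q universe is the candidate-bin set).
#'
#' @param frags A StrandedFragmentSet.
#' @param bins GRanges of candidate bins.
#' @param cfg A [caller_config()].
#' @return data.table of BinStats: bin_density columns plus `log2_ratio`,
#'   `p_value`, `q_value` (and `partial` when the bins carry that flag).
#' @export
compute_bin_stats <- function(frags, bins, cfg = caller_config()) {
  dt <- bin_density(frags, bins)
  # difference of logs, not log of the quotient: bit-exactly antisymmetric
  # under a strand swap, which the symmetry contract requires
  dt[, log2_ratio := log2(plus_density + cfg$pseudocount) -
       log2(minus_density + cfg$pseudocount)]
  dt[, p_value := strand_imbalance_test(plus_count, minus_count)]
  dt[, q_value := bh_adjust(p_value)]
  if (!is.null(mcols(bins)$partial)) dt[, partial := mcols(bins)$partial]
  dt[]
}

bin_signal <- function(stats, cfg) {
  switch(cfg$density_mode,
         mean = (stats$plus_density + stats$minus_density) / 2,
         sum = stats$plus_density + stats$minus_density,
         max = pmax(stats$plus_density, stats$minus_density))
}

#' Select significant (R-loop) bins
#'
#' Keeps bins with averaged density strictly above `min_density`,
#' `|log2_ratio| >= min_abs_log2_ratio`, and `q_value <= max_q` -- the
#' comparison directions follow the printed rules exactly (density strictly
#' greater; ratio and q inclusive).
#'
#' @param stats BinStats from [compute_bin_stats()].
#' @param cfg A [caller_config()].
#' @return The significant subset of `stats`.
#' @export
call_rloop_bins <- function(stats, cfg = caller_config()) {
  sig <- bin_signal(stats, cfg)
  stats[sig > cfg$min_density &
          abs(stats$log2_ratio) >= cfg$min_abs_log2_ratio &
          stats$q_value <= cfg$max_q]
}

#' Merge significant bins into R-loop calls
#'
#' Overlapping or book-ended significant bins with the same imbalance
#' direction merge into one call; bins dominant on opposite strands never
#' merge (the displaced strand is a physical property of one R-loop). Call
#' density is the mean over constituent bins of
#' `|plus_density - minus_density|`; the displaced strand comes from the
#' sign of the log2 ratio.
#'
#' @param sig Significant BinStats (from [call_rloop_bins()]).
#' @param cfg A [caller_config()] (supplies `merge_gap`).
#' @param assembly Seqinfo for the output GRanges.
#' @return GRanges of calls: strand = displaced strand, metadata `name`,
#'   `density`, `n_bins`, `min_q`.
#' @export
merge_rloop_bins <- function(sig, cfg = caller_config(), assembly) {
  empty <- GRanges(seqinfo = assembly)
  mcols(empty) <- S4Vectors::DataFrame(name = character(0),
                                       density = numeric(0),
                                       n_bins = integer(0),
                                       min_q = numeric(0))
  if (nrow(sig) == 0L) return(empty)
  dirs <- ifelse(sig$log2_ratio >= 0, "+", "-")
  pieces <- lapply(c("+", "-"), function(d) {
    sub <- sig[dirs == d]
    if (nrow(sub) == 0L) return(empty)
    gr <- GRanges(sub$chrom, IRanges(sub$start + 1L, sub$end),
                  seqinfo = assembly)
    red <- reduce(gr, min.gapwidth = cfg$merge_gap + 1L, with.revmap = TRUE)
    rv <- mcols(red)$revmap
    dens <- vapply(rv, function(ix)
      mean(abs(sub$plus_density[ix] - sub$minus_density[ix])), numeric(1))
    minq <- vapply(rv, function(ix) min(sub$q_value[ix]), numeric(1))
    mcols(red) <- NULL
    strand(red) <- d
    mcols(red)$density <- dens
    mcols(red)$n_bins <- lengths(rv)
    mcols(red)$min_q <- minq
    red
  })
  calls <- sort(do.call(c, pieces), ignore.strand = TRUE)
  mcols(calls) <- cbind(S4Vectors::DataFrame(
    name = sprintf("rloop_%05d", seq_along(calls))), mcols(calls))
  calls
}

#' End-to-end R-loop calling
#'
#' Composes the full rule set: genome windows -> blacklist exclusion ->
#' candidate filter over the peak union -> per-bin densities and counts ->
#' exact binomial strand test -> BH over candidate bins only -> threshold
#' filter -> direction-aware merge.
#'
#' @param frags A StrandedFragmentSet (pool replicates first if needed).
#' @param peaks GRanges of KAS-seq peaks (the candidate mask).
#' @param blacklist Optional GRanges of excluded regions.
#' @param assembly Seqinfo of the genome.
#' @param cfg A [caller_config()].
#' @return An `rloop_result`: list with `calls` (GRanges, see
#'   [merge_rloop_bins()]), `bin_stats` (candidate-bin BinStats table),
#'   `sig_bins`, `config`, `n_candidate_bins`, `label`.
#' @export
call_rloops <- function(frags, peaks, blacklist = NULL, assembly,
                        cfg = caller_config()) {
  stopifnot(inherits(frags, "StrandedFragmentSet"),
            inherits(cfg, "CallerConfig"))
  wins <- make_windows(assembly, cfg$bin_width, cfg$bin_step)
  if (!is.null(blacklist) && length(blacklist) > 0L)
    wins <- subtract_blacklist(wins, blacklist)
  cand <- filter_candidates(wins, peaks, cfg$min_peak_overlap)
  stats <- compute_bin_stats(frags, cand, cfg)
  sig <- call_rloop_bins(stats, cfg)
  calls <- merge_rloop_bins(sig, cfg, assembly)
  structure(list(calls = calls, bin_stats = stats, sig_bins = sig,
                 config = cfg, n_candidate_bins = nrow(stats),
                 label = frags$label),
            class = "rloop_result")
}

#' @export
print.rloop_result <- function(x, ...) {
  cat("rloop_result '", x$label, "': ", length(x$calls), " calls from ",
      x$n_candidate_bins, " candidate bins (", nrow(x$sig_bins),
      " significant)\n", sep = "")
  invisible(x)
}

#' Genome-wide census of strand-imbalanced bins
#'
#' Tiles the genome with non-overlapping bins (2 kb by default), tests every
#' bin for strand imbalance, and counts bins passing
#' `|log2_ratio| >= min_abs_log2_ratio` and `q <= max_q`. No density or peak
#' filter: this is the raw genome-wide imbalance census used for volcano
#' summaries.
#'
#' @param frags A StrandedFragmentSet.
#' @param assembly Seqinfo.
#' @param bin_width Bin width in bp (default 2000, non-overlapping).
#' @param min_abs_log2_ratio,max_q,pseudocount Thresholds as in
#'   [caller_config()].
#' @return List with `n_imbalanced` and the full per-bin `table` (BinStats
#'   plus logical `imbalanced`).
#' @export
imbalanced_bin_census <- function(frags, assembly, bin_width = 2000L,
                                  min_abs_log2_ratio = 1, max_q = 0.05,
                                  pseudocount = 1) {
  cfg <- caller_config(bin_width = bin_width, bin_step = bin_width,
                       min_abs_log2_ratio = min_abs_log2_ratio,
                       max_q = max_q, pseudocount = pseudocount)
  wins <- make_windows(assembly, bin_width, bin_width)
  stats <- compute_bin_stats(frags, wins, cfg)
  stats[, imbalanced := abs(log2_ratio) >= min_abs_log2_ratio &
          q_value <= max_q]
  list(n_imbalanced = sum(stats$imbalanced), table = stats[])
}

#' Write R-loop calls as BED6+
#'
#' Columns: chrom, start, end, name, `round(density * 10)` as integer score,
#' displaced strand, then density, n_bins, min_q.
#'
#' @param calls GRanges of calls from [merge_rloop_bins()].
#' @param path Output path.
#' @export
write_calls <- function(calls, path) {
  gr <- calls
  mcols(gr)$score <- as.integer(round(mcols(gr)$density * 10))
  write_bed(gr, path, extra = c("density", "n_bins", "min_q"))
}

#' Read R-loop calls written by [write_calls()]
#'
#' @param path BED6+ path.
#' @param assembly Seqinfo.
#' @return GRanges with name, density, n_bins, min_q.
#' @export
read_calls <- function(path, assembly) {
  if (!file.exists(path)) stop("calls file not found: ", path)
  dt <- if (file.size(path) == 0) data.table::data.table()
    else data.table::fread(path, header = FALSE, sep = "\t",
                           colClasses = list(character = 1))
  if (nrow(dt) == 0L) {
    gr <- GRanges(seqinfo = assembly)
    mcols(gr) <- S4Vectors::DataFrame(name = character(0),
                                      density = numeric(0),
                                      n_bins = integer(0),
                                      min_q = numeric(0))
    return(gr)
  }
  if (ncol(dt) < 6L) stop("calls file needs >= 6 columns: ", path)
  gr <- GRanges(as.character(dt[[1]]), IRanges(dt[[2]] + 1L, dt[[3]]),
                strand = as.character(dt[[6]]), seqinfo = assembly)
  mcols(gr)$name <- as.character(dt[[4]])
  mcols(gr)$density <- if (ncol(dt) >= 7L) as.numeric(dt[[7]])
    else as.numeric(dt[[5]]) / 10
  mcols(gr)$n_bins <- if (ncol(dt) >= 8L) as.integer(dt[[8]]) else NA_integer_
  mcols(gr)$min_q <- if (ncol(dt) >= 9L) as.numeric(dt[[9]]) else NA_real_
  sort(gr, ignore.strand = TRUE)
}
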