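# Genomic annotation, metagene profiles, overlap fractions, binned
# correlation, and call summaries.

#' Category scheme for genomic annotation
#'
#' Windows are conventions (the underlying assay defines no canonical
#' sizes): promoter = TSS -upstream/+downstream, TES window likewise around
#' the transcription end site, both strand-aware. Precedence is total:
#' promoter > TES > gene body > intergenic.
#'
#' @param promoter_upstream,promoter_downstream Promoter window around the
#'   TSS in bp (defaults 1000/1000).
#' @param tes_upstream,tes_downstream TES window in bp (defaults 1000/1000).
#' @return A `CategoryScheme` list.
#' @export
category_scheme <- function(promoter_upstream = 1000L,
                            promoter_downstream = 1000L,
                            tes_upstream = 1000L, tes_downstream = 1000L) {
  v <- c(promoter_upstream, promoter_downstream, tes_upstream,
         tes_downstream)
  if (any(v < 0)) stop("windows must be >= 0")
  structure(list(promoter_upstream = as.integer(promoter_upstream),
                 promoter_downstream = as.integer(promoter_downstream),
                 tes_upstream = as.integer(tes_upstream),
                 tes_downstream = as.integer(tes_downstream)),
            class = "CategoryScheme")
}

#' Genomic categories in precedence order
#' @export
rloop_categories <- function() c("promoter", "tes", "gene_body", "intergenic")

#' Read a gene model
#'
#' Accepts BED6 (chrom, start, end, name, score, strand) or a minimal
#' 5-column TSV (chrom, start, end, strand, name); coordinates 0-based
#' half-open in both. The TSS is the strand-aware 5' end, the TES the 3'
#' end.
#'
#' @param path File path.
#' @param assembly Seqinfo.
#' @return GRanges with a `name` metadata column and definite strand.
#' @export
read_genes <- function(path, assembly) {
  if (!file.exists(path)) stop("gene file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) == 5L && all(dt[[4]] %in% c("+", "-"))) {
    gr <- GRanges(as.character(dt[[1]]), IRanges(dt[[2]] + 1L, dt[[3]]),
                  strand = as.character(dt[[4]]), seqinfo = assembly)
    mcols(gr)$name <- as.character(dt[[5]])
    return(sort(gr, ignore.strand = TRUE))
  }
  gr <- read_bed(path, assembly)
  if (any(strand(gr) == "*")) stop("gene model requires a strand per gene")
  if (is.null(mcols(gr)$name))
    mcols(gr)$name <- sprintf("gene_%05d", seq_along(gr))
  gr
}

#' Strand-aware TSS / TES points
#'
#' @param genes Stranded GRanges.
#' @return 1-bp GRanges at the 5' (TSS) or 3' (TES) end of each gene.
#' @export
gene_tss <- function(genes) resize(genes, width = 1L, fix = "start")

#' @rdname gene_tss
#' @export
gene_tes <- function(genes) resize(genes, width = 1L, fix = "end")

#' Assign regions to genomic categories
#'
#' Each region is classified by its midpoint under the precedence
#' promoter > TES > gene body > intergenic; assignment is total and
#' deterministic, so each region counts exactly once in distribution
#' summaries.
#'
#' @param regions GRanges to classify.
#' @param genes Stranded gene GRanges.
#' @param scheme A [category_scheme()].
#' @return Factor with levels [rloop_categories()].
#' @export
assign_category <- function(regions, genes, scheme = category_scheme()) {
  if (length(genes) == 0L) stop("gene model is empty")
  lv <- rloop_categories()
  if (length(regions) == 0L)
    return(factor(character(0), levels = lv))
  mid <- GRanges(seqnames(regions),
                 IRanges(start(regions) + (width(regions) - 1L) %/% 2L,
                         width = 1L),
                 seqinfo = seqinfo(regions))
  prom <- trim(suppressWarnings(promoters(
    genes, upstream = scheme$promoter_upstream,
    downstream = scheme$promoter_downstream)))
  tesw <- trim(suppressWarnings(promoters(
    gene_tes(genes), upstream = scheme$tes_upstream,
    downstream = scheme$tes_downstream)))
  cat <- rep("intergenic", length(regions))
  cat[overlapsAny(mid, genes, ignore.strand = TRUE)] <- "gene_body"
  cat[overlapsAny(mid, tesw, ignore.strand = TRUE)] <- "tes"
  cat[overlapsAny(mid, prom, ignore.strand = TRUE)] <- "promoter"
  factor(cat, levels = lv)
}

#' Fraction of one interval set overlapping another
#'
#' `|{a in A : a overlaps >= 1 bp with some b in B}| / |A|` -- asymmetric by
#' design.
#'
#' @param a,b GRanges on the same assembly.
#' @return A fraction in \[0, 1\].
#' @export
overlap_fraction <- function(a, b) {
  if (length(a) == 0L) stop("overlap_fraction undefined for empty A")
  mean(overlapsAny(a, b, ignore.strand = TRUE))
}

# evenly partition the closed 1-based range [a, b] into n bins (widths may
# differ by 1 bp); requires b - a + 1 >= n
split_range <- function(a, b, n) {
  edges <- floor(seq(a, b + 1, length.out = n + 1))
  IRanges(edges[-(n + 1)], edges[-1] - 1L)
}

#' Metagene profile over scaled gene bodies
#'
#' Genes are oriented TSS to TES; fixed-width flanks are binned into
#' `flank_bins` positions each and the body length-normalised into
#' `body_bins` positions; the profile is the per-position mean across genes.
#' `mode = "relative"` computes the relative R-loop density -- nontemplate
#' minus template strand coverage per gene (for a plus-strand gene the
#' template is the minus strand, so the signal is plus minus minus
#' coverage); `mode = "plain"` averages a single signal track. Genes shorter
#' than `body_bins` bp or whose flanks leave the chromosome are skipped.
#'
#' @param x A StrandedFragmentSet (required for `"relative"`; for `"plain"`
#'   total coverage is used) or an RleList coverage (`"plain"` only).
#' @param genes Stranded gene GRanges.
#' @param flank Flank width in bp on each side (default 3000).
#' @param body_bins Number of body positions (default 100).
#' @param flank_bins Number of positions per flank (default 100).
#' @param mode `"relative"` or `"plain"`.
#' @return Numeric profile of length `2 * flank_bins + body_bins` with a
#'   `segment` attribute (upstream/body/downstream) and `n_genes` attribute.
#' @export
metagene_profile <- function(x, genes, flank = 3000L, body_bins = 100L,
                             flank_bins = 100L,
                             mode = c("relative", "plain")) {
  mode <- match.arg(mode)
  if (flank < flank_bins) stop("flank must be >= flank_bins")
  if (mode == "relative") {
    if (!inherits(x, "StrandedFragmentSet"))
      stop("relative mode requires a StrandedFragmentSet")
    sig <- coverage(x$plus) - coverage(x$minus)
  } else {
    sig <- if (inherits(x, "StrandedFragmentSet"))
      coverage(x$plus) + coverage(x$minus)
    else x
  }
  sl <- vapply(sig, length, numeric(1))
  ok <- width(genes) >= body_bins &
    start(genes) - flank >= 1 &
    end(genes) + flank <= sl[as.character(seqnames(genes))]
  genes <- genes[ok]
  if (length(genes) == 0L) stop("no gene long enough for the profile")
  nb <- 2L * flank_bins + body_bins
  mat <- matrix(NA_real_, nrow = length(genes), ncol = nb)
  for (i in seq_along(genes)) {
    g <- genes[i]
    ch <- as.character(seqnames(g))
    rng <- c(split_range(start(g) - flank, start(g) - 1L, flank_bins),
             split_range(start(g), end(g), body_bins),
             split_range(end(g) + 1L, end(g) + flank, flank_bins))
    v <- viewMeans(Views(sig[[ch]], rng))
    if (as.character(strand(g)) == "-") {
      v <- rev(v)
      if (mode == "relative") v <- -v
    }
    mat[i, ] <- v
  }
  prof <- colMeans(mat)
  attr(prof, "segment") <- rep(c("upstream", "body", "downstream"),
                               c(flank_bins, body_bins, flank_bins))
  attr(prof, "n_genes") <- length(genes)
  prof
}

as_coverage <- function(x, assembly = NULL) {
  if (inherits(x, "StrandedFragmentSet"))
    return(coverage(x$plus) + coverage(x$minus))
  if (is(x, "GRanges")) {
    if (is.null(mcols(x)$score))
      return(coverage(x))
    return(coverage(x, weight = "score"))
  }
  if (is(x, "RleList")) {
    # RleList arithmetic with a leading scalar drops names; repair from
    # the assembly when the shape is unambiguous
    if (is.null(names(x)) && !is.null(assembly) &&
        length(x) == length(seqlevels(assembly)))
      names(x) <- seqlevels(assembly)
    return(x)
  }
  stop("cannot interpret signal of class ", class(x)[1])
}

#' Pearson correlation of two signals over genome bins
#'
#' Both signals are averaged within equal-size genome bins (5 kb default);
#' bins overlapping the blacklist are removed and, when `restrict_to` is
#' given, only bins overlapping it are kept (e.g. peaks or R-loop calls).
#' The p-value uses the t transform with n - 2 degrees of freedom.
#'
#' @param a,b Signals: StrandedFragmentSet, coverage RleList, or GRanges
#'   with a `score` column (BedGraph-style).
#' @param assembly Seqinfo.
#' @param bin_size Bin width in bp (default 5000, non-overlapping).
#' @param restrict_to Optional GRanges mask of bins to keep.
#' @param blacklist Optional GRanges of bins to drop.
#' @return A `CorrelationResult` list: `r`, `p`, `n`.
#' @export
binned_pearson <- function(a, b, assembly, bin_size = 5000L,
                           restrict_to = NULL, blacklist = NULL) {
  bins <- make_windows(assembly, bin_size, bin_size)
  if (!is.null(blacklist) && length(blacklist))
    bins <- subtract_blacklist(bins, blacklist)
  if (!is.null(restrict_to))
    bins <- bins[overlapsAny(bins, restrict_to, ignore.strand = TRUE)]
  if (length(bins) < 3L) stop("fewer than 3 bins retained")
  ca <- as_coverage(a, assembly); cb <- as_coverage(b, assembly)
  g <- granges(bins)
  g <- GenomicRanges::binnedAverage(g, ca, "va")
  g <- GenomicRanges::binnedAverage(g, cb, "vb")
  va <- mcols(g)$va; vb <- mcols(g)$vb
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("constant signal in retained bins; correlation undefined")
  n <- length(va)
  r <- stats::cor(va, vb)
  p <- if (abs(r) >= 1 - 1e-15) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  structure(list(r = r, p = p, n = n), class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (p = %.3g, n = %d bins)\n", x$r, x$p, x$n))
  invisible(x)
}

#' Summaries of a call set
#'
#' Length histogram in fixed 250-bp bins, and (when a gene model is given)
#' per-category counts and mean densities.
#'
#' @param calls GRanges of calls with a `density` metadata column.
#' @param genes Optional stranded gene GRanges.
#' @param scheme A [category_scheme()].
#' @param length_bin Histogram bin width in bp (default 250).
#' @return List with `length_histogram` (data.table length_from, length_to,
#'   count) and, if genes given, `by_category` (data.table category, n,
#'   mean_density).
#' @export
call_summaries <- function(calls, genes = NULL, scheme = category_scheme(),
                           length_bin = 250L) {
  if (length(calls) == 0L) stop("no calls to summarise")
  idx <- width(calls) %/% length_bin
  tab <- table(factor(idx, levels = 0:max(idx)))
  hist <- data.table::data.table(
    length_from = as.integer(names(tab)) * length_bin,
    length_to = (as.integer(names(tab)) + 1L) * length_bin,
    count = as.integer(tab))
  out <- list(length_histogram = hist)
  if (!is.null(genes)) {
    cat <- assign_category(calls, genes, scheme)
    dens <- mcols(calls)$density
    out$by_category <- data.table::data.table(
      category = rloop_categories(),
      n = as.integer(table(cat)),
      mean_density = vapply(rloop_categories(), function(k) {
        if (any(cat == k)) mean(dens[cat == k]) else NA_real_
      }, numeric(1)))
  }
  out
}
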