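# Cross-condition comparison of R-loop calls: RNase H-style dose-response
# summaries and three-type classification under transcription inhibitors.

#' Bundle one condition's calls and fragments
#'
#' @param label Condition name (e.g. "control", "DRB_120min", "RNaseH_50U").
#' @param calls An `rloop_result` or a calls GRanges.
#' @param frags The condition's StrandedFragmentSet.
#' @return A `ConditionResult` list with a reads-per-million `scale`
#'   (`1e6 / library_size`).
#' @export
condition_result <- function(label, calls, frags) {
  if (inherits(calls, "rloop_result")) calls <- calls$calls
  stopifnot(is(calls, "GRanges"), inherits(frags, "StrandedFragmentSet"))
  if (frags$library_size == 0L) stop("empty library in condition ", label)
  structure(list(label = label, calls = calls, frags = frags,
                 scale = 1e6 / frags$library_size),
            class = "ConditionResult")
}

# per-region R-loop density: |mean plus coverage - mean minus coverage|
region_strand_diff <- function(frags, regions) {
  if (length(regions) == 0L) return(numeric(0))
  g <- granges(regions)
  g <- GenomicRanges::binnedAverage(g, coverage(frags$plus), "dp")
  g <- GenomicRanges::binnedAverage(g, coverage(frags$minus), "dm")
  abs(mcols(g)$dp - mcols(g)$dm)
}

#' Classify control R-loops by inhibitor susceptibility
#'
#' Types follow the elongation/initiation-inhibitor taxonomy: type I is
#' retained under the elongation inhibitor (DRB) but abolished by the
#' initiation inhibitor (triptolide); type II is lost under both; type III
#' is impervious to both. The residual combination (lost under DRB, present
#' under triptolide) falls outside the taxonomy and is labelled
#' "unclassified". "Retained" is, by default, >= 1 bp overlap with any call
#' in the treated condition; `mode = "density_ratio"` instead requires the
#' treated reads-per-million-scaled region density to reach
#' `retain_ratio` of the control's.
#'
#' @param control,drb,trp [condition_result()] objects called with the same
#'   configuration and assembly.
#' @param mode `"overlap"` (default) or `"density_ratio"`.
#' @param retain_ratio Retention threshold for `"density_ratio"` mode
#'   (default 0.5).
#' @return The control calls GRanges with a `type` factor metadata column
#'   (levels I, II, III, unclassified).
#' @export
classify_types <- function(control, drb, trp,
                           mode = c("overlap", "density_ratio"),
                           retain_ratio = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(control, "ConditionResult"),
            inherits(drb, "ConditionResult"),
            inherits(trp, "ConditionResult"))
  sl <- seqlengths(control$calls)
  if (!identical(sl, seqlengths(drb$calls)) ||
      !identical(sl, seqlengths(trp$calls)))
    stop("conditions were called on different assemblies")
  calls <- control$calls
  retained <- function(treated) {
    if (mode == "overlap") {
      if (length(treated$calls) == 0L) return(rep(FALSE, length(calls)))
      overlapsAny(calls, treated$calls, ignore.strand = TRUE)
    } else {
      d0 <- region_strand_diff(control$frags, calls) * control$scale
      dt <- region_strand_diff(treated$frags, calls) * treated$scale
      dt >= retain_ratio * d0
    }
  }
  rD <- retained(drb)
  rT <- retained(trp)
  type <- rep("unclassified", length(calls))
  type[rD & !rT] <- "I"
  type[!rD & !rT] <- "II"
  type[rD & rT] <- "III"
  mcols(calls)$type <- factor(type,
                              levels = c("I", "II", "III", "unclassified"))
  calls
}

#' Dose-response summary across an ordered condition series
#'
#' For each condition and genomic category: the number of that condition's
#' own calls (by midpoint category) and the reads-per-million-scaled mean
#' R-loop density measured over a fixed reference region set -- the first
#' (lowest-dose) condition's calls -- so densities stay comparable when
#' calls vanish at high dose. A per-category monotonicity flag reports
#' whether the density sequence is non-increasing along the given order
#' (equality allowed).
#'
#' @param conditions List of [condition_result()] in stated dose order
#'   (>= 2).
#' @param genes Stranded gene GRanges.
#' @param scheme A [category_scheme()].
#' @return List: `table` (data.table condition, category, n_calls,
#'   mean_density_scaled), `monotone_density` and `monotone_calls` (named
#'   logical per category).
#' @export
dose_response <- function(conditions, genes, scheme = category_scheme()) {
  stopifnot(length(conditions) >= 2L,
            all(vapply(conditions, inherits, TRUE, "ConditionResult")))
  ref <- conditions[[1]]$calls
  if (length(ref) == 0L) stop("reference (first) condition has no calls")
  refcat <- assign_category(ref, genes, scheme)
  lv <- rloop_categories()
  rows <- lapply(conditions, function(cc) {
    owncat <- assign_category(cc$calls, genes, scheme)
    dens <- region_strand_diff(cc$frags, ref) * cc$scale
    data.table::data.table(
      condition = cc$label,
      category = lv,
      n_calls = as.integer(table(owncat)[lv]),
      mean_density_scaled = vapply(lv, function(k) {
        if (any(refcat == k)) mean(dens[refcat == k]) else NA_real_
      }, numeric(1)))
  })
  tab <- data.table::rbindlist(rows)
  mono <- function(col) {
    vapply(lv, function(k) {
      x <- tab[category == k][[col]]
      x <- x[!is.na(x)]
      length(x) <= 1L || all(diff(x) <= 0)
    }, logical(1))
  }
  list(table = tab, monotone_density = mono("mean_density_scaled"),
       monotone_calls = mono("n_calls"))
}

#' Genomic-location percentages along a time course
#'
#' Per condition, the percentage of its calls in each genomic category;
#' percentages sum to 100 for every condition with at least one call.
#'
#' @param conditions List of [condition_result()] in time order.
#' @param genes Stranded gene GRanges.
#' @param scheme A [category_scheme()].
#' @return data.table: condition, category, n_calls, percent.
#' @export
timecourse_summary <- function(conditions, genes,
                               scheme = category_scheme()) {
  stopifnot(length(conditions) >= 1L,
            all(vapply(conditions, inherits, TRUE, "ConditionResult")))
  lv <- rloop_categories()
  rows <- lapply(conditions, function(cc) {
    n <- length(cc$calls)
    cat <- assign_category(cc$calls, genes, scheme)
    cnt <- as.integer(table(cat)[lv])
    if (n == 0L) warning("condition ", cc$label, " has no calls")
    data.table::data.table(condition = cc$label, category = lv,
                           n_calls = cnt,
                           percent = if (n > 0L) 100 * cnt / n else NA_real_)
  })
  data.table::rbindlist(rows)
}
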