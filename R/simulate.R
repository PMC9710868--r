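# Synthetic spKAS-seq-style data: toy genomes with planted R-loops and
# transcription bubbles, perturbation effects, and machine-readable truth.
#
# Signal model: an R-loop exposes its displaced strand, so that strand gets
# per-bp fragment intensity `depth` while the hybrid-sequestered strand gets
# `depth / asymmetry`; a transcription bubble exposes both strands equally at
# `depth`. Fragment counts per locus are Poisson, placement is uniform, so
# the expected coverage across the locus interior equals the stated
# intensity. RNase H digestion of the RNA strand is modelled as symmetric
# convergence of the two strand intensities toward their mean by the dose's
# efficiency; transcription inhibitors zero out non-retained features.

run_with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' @param assembly A Seqinfo.
#' @param genes Stranded gene GRanges (may be empty; used for annotation
#'   and for the emitted fixture's gene model).
#' @param features data.frame of planted features with columns `chrom`,
#'   `start` (0-based), `end`, `kind` ("rloop" or "bubble"),
#'   `displaced_strand` ("+"/"-"), `asymmetry` (>= 1; must be 1 for
#'   bubbles), `depth` (per-bp fragment intensity of the exposed strand),
#'   and optional logicals `drb_retained`, `trp_retained` (default TRUE).
#' @param background_depth Per-bp background intensity on each strand.
#' @param fragment_length Fixed fragment length in bp (default 150).
#' @param rnase_h_efficiency Named map dose -> fraction of R-loop asymmetry
#'   removed, all in \[0, 1\].
#' @param blacklist Optional GRanges written into fixture bundles.
#' @param seed Integer master seed; each condition derives its own
#'   substream.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(assembly, genes = GRanges(seqinfo = assembly),
                       features, background_depth = 2,
                       fragment_length = 150L,
                       rnase_h_efficiency = c(`0` = 0, `50` = 0.3,
                                              `100` = 0.5, `150` = 0.7),
                       blacklist = NULL, seed = 1L) {
  ft <- data.table::as.data.table(features)
  need <- c("chrom", "start", "end", "kind", "displaced_strand",
            "asymmetry", "depth")
  miss <- setdiff(need, names(ft))
  if (length(miss)) stop("features lack column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(ft$drb_retained)) ft$drb_retained <- TRUE
  if (is.null(ft$trp_retained)) ft$trp_retained <- TRUE
  if (is.null(ft$feature_id))
    ft$feature_id <- sprintf("%s_%04d", ft$kind, seq_len(nrow(ft)))
  if (!all(ft$kind %in% c("rloop", "bubble")))
    stop("feature kind must be 'rloop' or 'bubble'")
  if (!all(ft$displaced_strand %in% c("+", "-")))
    stop("displaced_strand must be '+' or '-'")
  if (any(ft$asymmetry < 1)) stop("asymmetry must be >= 1")
  if (any(ft$kind == "bubble" & ft$asymmetry != 1))
    stop("bubbles must have asymmetry 1")
  if (any(ft$depth <= 0)) stop("feature depth must be > 0")
  sl <- seqlengths(assembly)
  if (!all(ft$chrom %in% names(sl)))
    stop("feature on unknown chromosome")
  if (any(ft$start < 0 | ft$end > sl[ft$chrom] | ft$start >= ft$end))
    stop("feature locus outside assembly bounds")
  if (any(rnase_h_efficiency < 0 | rnase_h_efficiency > 1))
    stop("RNase H efficiencies must lie in [0, 1]")
  if (is.null(names(rnase_h_efficiency)))
    stop("rnase_h_efficiency must be a named (dose -> efficiency) vector")
  if (background_depth < 0) stop("background_depth must be >= 0")
  if (fragment_length < 1) stop("fragment_length must be >= 1")
  structure(list(assembly = assembly, genes = genes, features = ft,
                 background_depth = background_depth,
                 fragment_length = as.integer(fragment_length),
                 rnase_h_efficiency = rnase_h_efficiency,
                 blacklist = blacklist, seed = as.integer(seed)),
            class = "SimConfig")
}

condition_label <- function(condition, dose = NULL) {
  if (condition == "rnase_h") paste0("rnase_h_", dose) else condition
}

#' Expected per-strand intensities of planted features under a condition
#'
#' The truth set: per feature, the expected plus/minus per-bp coverage
#' (background included) under the requested condition.
#'
#' @param cfg A [sim_config()].
#' @param condition One of "control", "rnase_h", "drb", "trp".
#' @param dose RNase H dose key (required for "rnase_h").
#' @return data.table: feature_id, chrom, start, end, kind,
#'   displaced_strand, condition, exp_plus, exp_minus.
#' @export
expected_intensities <- function(cfg,
                                 condition = c("control", "rnase_h",
                                               "drb", "trp"),
                                 dose = NULL) {
  condition <- match.arg(condition)
  ft <- data.table::copy(cfg$features)
  fp <- ifelse(ft$kind == "bubble", ft$depth,
               ifelse(ft$displaced_strand == "+", ft$depth,
                      ft$depth / ft$asymmetry))
  fm <- ifelse(ft$kind == "bubble", ft$depth,
               ifelse(ft$displaced_strand == "-", ft$depth,
                      ft$depth / ft$asymmetry))
  if (condition == "rnase_h") {
    dose <- as.character(dose)
    if (length(dose) != 1L || !dose %in% names(cfg$rnase_h_efficiency))
      stop("invalid RNase H dose: ", if (length(dose)) dose else "<missing>")
    e <- cfg$rnase_h_efficiency[[dose]]
    m <- (fp + fm) / 2
    isr <- ft$kind == "rloop"
    fp[isr] <- fp[isr] * (1 - e) + e * m[isr]
    fm[isr] <- fm[isr] * (1 - e) + e * m[isr]
  } else if (condition == "drb") {
    fp[!ft$drb_retained] <- 0
    fm[!ft$drb_retained] <- 0
  } else if (condition == "trp") {
    fp[!ft$trp_retained] <- 0
    fm[!ft$trp_retained] <- 0
  }
  data.table::data.table(
    feature_id = ft$feature_id, chrom = ft$chrom, start = ft$start,
    end = ft$end, kind = ft$kind, displaced_strand = ft$displaced_strand,
    condition = condition_label(condition, dose),
    exp_plus = cfg$background_depth + fp,
    exp_minus = cfg$background_depth + fm)
}

# draw Poisson fragment starts giving expected per-bp coverage `intensity`
# across [lo0, hi0) (0-based); starts may precede lo0 by up to
# fraglen - 1 bp so interior coverage is uniform. Returns 0-based starts.
draw_starts <- function(lo0, hi0, intensity, fraglen) {
  span <- hi0 - lo0
  nslots <- span + fraglen - 1
  n <- stats::rpois(1L, intensity * nslots / fraglen)
  if (n == 0L) return(integer(0))
  lo0 - fraglen + 1L + as.integer(floor(stats::runif(n) * nslots))
}

#' Simulate one condition's fragment set
#'
#' Background fragments are laid on each strand of each chromosome at
#' per-bp Poisson intensity `background_depth`; planted features add
#' strand-specific intensity per [expected_intensities()]. Fragments have
#' fixed length, uniform placement, and are clipped to chromosome bounds.
#' Deterministic given the config seed: each condition (and dose) derives
#' an independent substream, so `rnase_h` at efficiency 0 is bit-identical
#' to nothing but itself yet distributionally identical to control.
#'
#' @inheritParams expected_intensities
#' @return List: `frags` (StrandedFragmentSet labelled by condition),
#'   `truth` (the [expected_intensities()] table), `label`.
#' @export
simulate_condition <- function(cfg,
                               condition = c("control", "rnase_h",
                                             "drb", "trp"),
                               dose = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  condition <- match.arg(condition)
  truth <- expected_intensities(cfg, condition, dose)
  offset <- switch(condition,
                   control = 0L,
                   # a zero-efficiency dose is generatively identical to
                   # control, so it shares control's substream and the
                   # identity limit holds bit-exactly
                   rnase_h = if (cfg$rnase_h_efficiency[[as.character(dose)]] == 0)
                     0L
                   else 10000L + match(as.character(dose),
                                       names(cfg$rnase_h_efficiency)),
                   drb = 20000L, trp = 30000L)
  seed_used <- (abs(cfg$seed) * 131L + offset) %% 2147483647L
  fraglen <- cfg$fragment_length
  sl <- seqlengths(cfg$assembly)
  frags <- run_with_seed(seed_used, {
    out <- list(`+` = list(), `-` = list())
    for (ch in names(sl)) {
      L <- sl[[ch]]
      for (s in c("+", "-")) {
        st <- draw_starts(0L, L, cfg$background_depth, fraglen)
        out[[s]][[length(out[[s]]) + 1L]] <-
          data.table::data.table(chrom = rep(ch, length(st)), start = st)
      }
    }
    ft <- truth
    for (i in seq_len(nrow(ft))) {
      for (s in c("+", "-")) {
        intensity <- (if (s == "+") ft$exp_plus[i] else ft$exp_minus[i]) -
          cfg$background_depth
        if (intensity <= 0) next
        st <- draw_starts(ft$start[i], ft$end[i], intensity, fraglen)
        out[[s]][[length(out[[s]]) + 1L]] <-
          data.table::data.table(chrom = rep(ft$chrom[i], length(st)),
                                 start = st)
      }
    }
    to_gr <- function(lst) {
      dt <- data.table::rbindlist(lst)
      if (nrow(dt) == 0L) return(GRanges(seqinfo = cfg$assembly))
      trim(suppressWarnings(
        GRanges(dt$chrom, IRanges(dt$start + 1L, dt$start + fraglen),
                seqinfo = cfg$assembly)))
    }
    stranded_fragments(to_gr(out[["+"]]), to_gr(out[["-"]]),
                       label = condition_label(condition, dose))
  })
  list(frags = frags, truth = truth,
       label = condition_label(condition, dose))
}

parse_condition <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  list(condition = parts[1],
       dose = if (length(parts) > 1L) parts[2] else NULL)
}

#' Write a complete plain-text fixture bundle
#'
#' Emits everything the pipeline consumes: `chrom.sizes`, `genes.bed`,
#' `blacklist.bed`, `peaks.bed` (union of planted loci and gene spans
#' padded by 500 bp), one `fragments_<label>.bed` per condition,
#' `truth.tsv`, and `manifest.tsv`. Regenerating with the same seed is
#' byte-identical.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param conditions Character vector of condition specs: "control",
#'   "rnase_h:<dose>", "drb", "trp".
#' @return Invisibly, a named list of written paths.
#' @export
emit_fixture_bundle <- function(cfg, dir, conditions = "control") {
  stopifnot(inherits(cfg, "SimConfig"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(chrom_sizes = file.path(dir, "chrom.sizes"),
                genes = file.path(dir, "genes.bed"),
                blacklist = file.path(dir, "blacklist.bed"),
                peaks = file.path(dir, "peaks.bed"),
                truth = file.path(dir, "truth.tsv"),
                manifest = file.path(dir, "manifest.tsv"))
  write_chrom_sizes(cfg$assembly, paths$chrom_sizes)
  write_bed(cfg$genes, paths$genes)
  bl <- if (is.null(cfg$blacklist)) GRanges(seqinfo = cfg$assembly)
    else cfg$blacklist
  write_bed(bl, paths$blacklist)
  ft <- cfg$features
  loci <- c(granges(cfg$genes),
            GRanges(ft$chrom, IRanges(ft$start + 1L, ft$end),
                    seqinfo = cfg$assembly))
  peaks <- reduce(trim(suppressWarnings(loci + 500L)),
                  ignore.strand = TRUE)
  write_bed(peaks, paths$peaks)
  truths <- list()
  manifest <- list()
  for (spec in conditions) {
    pc <- parse_condition(spec)
    sim <- simulate_condition(cfg, pc$condition, pc$dose)
    fp <- file.path(dir, paste0("fragments_", sim$label, ".bed"))
    write_bed(c(sim$frags$plus, sim$frags$minus), fp)
    truths[[spec]] <- sim$truth
    manifest[[spec]] <- data.table::data.table(
      label = sim$label, condition = pc$condition,
      dose = if (is.null(pc$dose)) NA_character_ else pc$dose,
      frags_path = basename(fp),
      library_size = sim$frags$library_size)
    paths[[paste0("fragments_", sim$label)]] <- fp
  }
  data.table::fwrite(data.table::rbindlist(truths), paths$truth,
                     sep = "\t")
  data.table::fwrite(data.table::rbindlist(manifest), paths$manifest,
                     sep = "\t")
  invisible(paths)
}

#' Score calls against a planted truth set
#'
#' Sensitivity = planted R-loops recovered (>= 1 bp overlap) / planted
#' R-loops; precision = calls overlapping a planted R-loop / calls;
#' strand_accuracy = among calls overlapping a planted R-loop, the fraction
#' whose displaced strand matches the feature's; bubble_false_rate =
#' fraction of planted bubbles overlapped by any call. With no calls,
#' sensitivity and precision are reported as 0 with `no_calls = TRUE`.
#'
#' @param calls GRanges of calls (strand = displaced strand).
#' @param truth Truth table from [simulate_condition()] (one condition).
#' @param assembly Seqinfo.
#' @return List: sensitivity, precision, strand_accuracy,
#'   bubble_false_rate, no_calls.
#' @export
score_calls <- function(calls, truth, assembly) {
  truth <- data.table::as.data.table(truth)
  if (nrow(truth) == 0L) stop("empty truth set")
  tr <- truth[kind == "rloop"]
  tb <- truth[kind == "bubble"]
  if (nrow(tr) == 0L) stop("truth contains no planted R-loops")
  gr_tr <- GRanges(tr$chrom, IRanges(tr$start + 1L, tr$end),
                   seqinfo = assembly)
  gr_tb <- if (nrow(tb)) GRanges(tb$chrom, IRanges(tb$start + 1L, tb$end),
                                 seqinfo = assembly)
    else GRanges(seqinfo = assembly)
  if (length(calls) == 0L)
    return(list(sensitivity = 0, precision = 0,
                strand_accuracy = NA_real_,
                bubble_false_rate = 0, no_calls = TRUE))
  first <- findOverlaps(calls, gr_tr, ignore.strand = TRUE,
                        select = "first")
  hit <- !is.na(first)
  list(
    sensitivity = mean(overlapsAny(gr_tr, calls, ignore.strand = TRUE)),
    precision = mean(hit),
    strand_accuracy = if (any(hit))
      mean(as.character(strand(calls))[hit] ==
             tr$displaced_strand[first[hit]])
      else NA_real_,
    bubble_false_rate = if (length(gr_tb))
      mean(overlapsAny(gr_tb, calls, ignore.strand = TRUE))
      else NA_real_,
    no_calls = FALSE)
}

#' Build a regular synthetic world
#'
#' Deterministic layout: genes evenly spaced with alternating strands;
#' features (R-loops first, then bubbles) assigned one per gene, cycling
#' through promoter-, gene-body-, and intergenic-centred placement, with
#' alternating displaced strands. Defaults state the standard test world:
#' R-loops of 4-fold asymmetry at 40 reads-per-base over a 2 reads-per-base
#' background, 150-bp fragments.
#'
#' @param n_chrom,chrom_length Assembly shape.
#' @param n_genes,gene_length Gene layout; requires
#'   `n_rloops + n_bubbles <= n_genes`.
#' @param n_rloops,n_bubbles Planted feature counts.
#' @param feature_length Planted feature length in bp.
#' @param depth Exposed-strand intensity (reads-per-base).
#' @param asymmetry R-loop strand asymmetry ratio.
#' @param background_depth Per-strand background intensity.
#' @param fragment_length Fragment length in bp.
#' @param rnase_h_efficiency Dose -> efficiency map.
#' @param rloop_types Optional character vector of designed inhibitor types
#'   ("I", "II", "III"), recycled over the R-loops, setting the DRB /
#'   triptolide retention flags (I: DRB-retained only; II: neither;
#'   III: both). Default: all type III.
#' @param seed Master seed.
#' @return A [sim_config()].
#' @export
random_sim_config <- function(n_chrom = 2L, chrom_length = 6e6,
                              n_genes = 120L, gene_length = 20000L,
                              n_rloops = 60L, n_bubbles = 60L,
                              feature_length = 1500L, depth = 40,
                              asymmetry = 4, background_depth = 2,
                              fragment_length = 150L,
                              rnase_h_efficiency = c(`0` = 0, `50` = 0.3,
                                                     `100` = 0.5,
                                                     `150` = 0.7),
                              rloop_types = "III", seed = 1L) {
  nf <- n_rloops + n_bubbles
  if (nf > n_genes)
    stop("need n_rloops + n_bubbles <= n_genes (one feature per gene)")
  gpc <- ceiling(n_genes / n_chrom)
  spacing <- floor(chrom_length / gpc)
  margin <- 4000L
  if (spacing < gene_length + 3L * margin)
    stop("chromosomes too short for this many genes")
  chroms <- paste0("chr", seq_len(n_chrom))
  asm <- do.call(assembly,
                 as.list(stats::setNames(rep(chrom_length, n_chrom),
                                         chroms)))
  gi <- seq_len(n_genes) - 1L
  gchrom <- chroms[gi %/% gpc + 1L]
  gstart0 <- (gi %% gpc) * spacing + margin
  gend0 <- gstart0 + gene_length
  gstrand <- ifelse(gi %% 2L == 0L, "+", "-")
  genes <- GRanges(gchrom, IRanges(gstart0 + 1L, gend0),
                   strand = gstrand, seqinfo = asm)
  mcols(genes)$name <- sprintf("gene_%04d", seq_len(n_genes))

  fi <- seq_len(nf)
  half <- feature_length %/% 2L
  tss0 <- ifelse(gstrand == "+", gstart0, gend0)
  center <- integer(nf)
  for (j in fi) {
    g <- j  # feature j sits on gene j
    center[j] <- switch((j %% 3L) + 1L,
      gend0[g] + (spacing - gene_length - margin) %/% 2L,  # intergenic
      tss0[g],                                             # promoter
      (gstart0[g] + gend0[g]) %/% 2L)                      # gene body
  }
  kinds <- rep(c("rloop", "bubble"), c(n_rloops, n_bubbles))
  types <- rep_len(rloop_types, n_rloops)
  ft <- data.table::data.table(
    chrom = gchrom[fi],
    start = center - half,
    end = center - half + feature_length,
    kind = kinds,
    displaced_strand = ifelse(fi %% 2L == 0L, "+", "-"),
    asymmetry = ifelse(kinds == "rloop", asymmetry, 1),
    depth = depth,
    drb_retained = c(types %in% c("I", "III"), rep(TRUE, n_bubbles)),
    trp_retained = c(types == "III", rep(TRUE, n_bubbles)))
  ft$designed_type <- c(types, rep(NA_character_, n_bubbles))
  sim_config(asm, genes, ft, background_depth = background_depth,
             fragment_length = fragment_length,
             rnase_h_efficiency = rnase_h_efficiency, seed = seed)
}
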