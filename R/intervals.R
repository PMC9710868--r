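# Interval algebra and plain-text genomic I/O.
#
# Coordinates are BED-native (0-based, half-open) in every file this package
# reads or writes; in memory intervals live in GRanges (1-based, closed) with
# a Seqinfo carrying the assembly. read_bed()/write_bed() do the conversion,
# nothing else ever shifts coordinates.

#' Build a genome assembly from chromosome lengths
#'
#' @param ... named chromosome lengths in bp, e.g. `assembly(chr1 = 1e6)`.
#' @return A [GenomeInfoDb::Seqinfo] object.
#' @examples
#' assembly(chrT = 1200)
#' @export
assembly <- function(...) {
  v <- c(...)
  if (length(v) == 0L || is.null(names(v)) || any(!nzchar(names(v))))
    stop("assembly() needs named chromosome lengths")
  if (anyDuplicated(names(v)))
    stop("duplicate chromosome name: ", names(v)[anyDuplicated(names(v))])
  if (any(!is.finite(v) | v < 1 | v != floor(v)))
    stop("chromosome lengths must be positive integers")
  GenomeInfoDb::Seqinfo(seqnames = names(v), seqlengths = as.integer(v))
}

#' Read a two-column chromosome-sizes table
#'
#' @param path TSV with columns chromosome name and length in bp.
#' @return A [GenomeInfoDb::Seqinfo].
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom sizes file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 2L) stop("chrom sizes file needs two columns: ", path)
  nm <- as.character(dt[[1]])
  len <- suppressWarnings(as.numeric(dt[[2]]))
  bad <- which(is.na(len) | len < 1 | len != floor(len))
  if (length(bad))
    stop("invalid chromosome length at line ", bad[1], " of ", path)
  if (anyDuplicated(nm))
    stop("duplicate chromosome name in ", path, ": ", nm[anyDuplicated(nm)])
  GenomeInfoDb::Seqinfo(seqnames = nm, seqlengths = as.integer(len))
}

#' Write a chromosome-sizes table
#'
#' @param assembly A Seqinfo.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(assembly, path) {
  dt <- data.table::data.table(chrom = seqlevels(assembly),
                               length = unname(seqlengths(assembly)))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 file into a GRanges
#'
#' Records are validated against the assembly: a malformed line or an
#' interval with `start >= end` is an error naming the offending line;
#' records ending past the chromosome are rejected and their count reported
#' (attribute `n_rejected` and a message). Unknown chromosomes are an error
#' unless `permissive = TRUE`, in which case they are dropped and counted.
#' Strand "." maps to "*" (unstranded). Output is sorted by
#' (chrom, start, end).
#'
#' @param path BED file path.
#' @param assembly A Seqinfo the records must fit.
#' @param permissive Drop (rather than error on) unknown chromosomes.
#' @return Sorted GRanges with optional `name` and `score` metadata columns
#'   and attribute `n_rejected`.
#' @export
read_bed <- function(path, assembly, permissive = FALSE) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0) {
    gr <- GRanges(seqinfo = assembly)
    attr(gr, "n_rejected") <- 0L
    return(gr)
  }
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      colClasses = list(character = 1)),
    error = function(e) stop("failed to parse BED ", path, ": ",
                             conditionMessage(e)))
  if (nrow(dt) == 0L) {
    gr <- GRanges(seqinfo = assembly)
    attr(gr, "n_rejected") <- 0L
    return(gr)
  }
  if (ncol(dt) < 3L) stop("BED file needs >= 3 columns: ", path)
  chrom <- as.character(dt[[1]])
  start0 <- suppressWarnings(as.numeric(dt[[2]]))
  end0 <- suppressWarnings(as.numeric(dt[[3]]))
  bad <- which(is.na(start0) | is.na(end0) | start0 != floor(start0) |
                 end0 != floor(end0))
  if (length(bad))
    stop("malformed BED line ", bad[1], " in ", path)
  neg <- which(start0 < 0)
  if (length(neg)) stop("negative start at line ", neg[1], " in ", path)
  ge <- which(start0 >= end0)
  if (length(ge)) stop("start >= end at line ", ge[1], " in ", path)

  keep <- rep(TRUE, nrow(dt))
  unknown <- !(chrom %in% seqlevels(assembly))
  if (any(unknown)) {
    if (!permissive)
      stop("unknown chromosome '", chrom[unknown][1], "' at line ",
           which(unknown)[1], " in ", path)
    keep[unknown] <- FALSE
  }
  n_rejected <- sum(unknown & !keep)
  sl <- seqlengths(assembly)[chrom]
  oob <- keep & !is.na(sl) & end0 > sl
  if (any(oob)) {
    message(sum(oob), " out-of-bounds record(s) rejected from ", path)
    keep[oob] <- FALSE
  }
  n_rejected <- sum(!keep)
  if (!any(keep)) {
    gr <- GRanges(seqinfo = assembly)
    attr(gr, "n_rejected") <- n_rejected
    return(gr)
  }

  st <- if (ncol(dt) >= 6L) {
    s <- as.character(dt[[6]])
    s[is.na(s) | s == "." | s == ""] <- "*"
    badst <- which(keep & !(s %in% c("+", "-", "*")))
    if (length(badst))
      stop("invalid strand '", s[badst[1]], "' at line ", badst[1],
           " in ", path)
    s
  } else "*"

  gr <- GRanges(chrom[keep],
                IRanges(start0[keep] + 1, end0[keep]),
                strand = if (length(st) == 1L) st else st[keep],
                seqinfo = assembly)
  if (ncol(dt) >= 4L) {
    nmcol <- as.character(dt[[4]])[keep]
    if (!all(is.na(nmcol))) mcols(gr)$name <- nmcol
  }
  if (ncol(dt) >= 5L) {
    sc <- suppressWarnings(as.numeric(dt[[5]]))[keep]
    if (!all(is.na(sc))) mcols(gr)$score <- sc
  }
  gr <- sort(gr, ignore.strand = TRUE)
  attr(gr, "n_rejected") <- n_rejected
  gr
}

#' Write a GRanges to BED
#'
#' Emits BED3 when no strand/name/score is present, BED6 otherwise, plus any
#' extra metadata columns named in `extra`. Output is sorted.
#'
#' @param gr GRanges to write.
#' @param path Output path.
#' @param extra Character vector of metadata-column names appended after
#'   column 6.
#' @export
write_bed <- function(gr, path, extra = NULL) {
  gr <- sort(gr, ignore.strand = TRUE)
  dt <- data.table::data.table(chrom = as.character(seqnames(gr)),
                               start = start(gr) - 1L, end = end(gr))
  has_meta <- any(strand(gr) != "*") || !is.null(mcols(gr)$name) ||
    !is.null(mcols(gr)$score) || length(extra) > 0L
  if (has_meta) {
    nm <- mcols(gr)$name
    dt$name <- if (is.null(nm)) "." else ifelse(is.na(nm), ".", nm)
    sc <- mcols(gr)$score
    dt$score <- if (is.null(sc)) 0 else ifelse(is.na(sc), 0, sc)
    s <- as.character(strand(gr))
    dt$strand <- ifelse(s == "*", ".", s)
    for (col in extra) dt[[col]] <- mcols(gr)[[col]]
  }
  if (nrow(dt) == 0L) {
    file.create(path)
  } else {
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  }
  invisible(path)
}

#' Write a BedGraph track
#'
#' Four columns (chrom, 0-based start, end, value), value formatted with six
#' decimals, sorted by position.
#'
#' @param gr GRanges with the value in `value_col`.
#' @param path Output path.
#' @param value_col Metadata column holding the track value.
#' @export
write_bedgraph <- function(gr, path, value_col = "score") {
  gr <- sort(gr, ignore.strand = TRUE)
  v <- mcols(gr)[[value_col]]
  if (is.null(v)) stop("no metadata column '", value_col, "'")
  dt <- data.table::data.table(chrom = as.character(seqnames(gr)),
                               start = start(gr) - 1L, end = end(gr),
                               value = sprintf("%.6f", v))
  if (nrow(dt) == 0L) file.create(path)
  else data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a four-column BedGraph track
#'
#' @param path BedGraph path (chrom, 0-based start, end, value).
#' @param assembly A Seqinfo.
#' @return Sorted GRanges with a numeric `score` column.
#' @export
read_bedgraph <- function(path, assembly) {
  if (!file.exists(path)) stop("BedGraph file not found: ", path)
  dt <- if (file.size(path) == 0) data.table::data.table()
    else data.table::fread(path, header = FALSE, sep = "\t",
                           colClasses = list(character = 1))
  if (nrow(dt) == 0L) {
    gr <- GRanges(seqinfo = assembly)
    mcols(gr)$score <- numeric(0)
    return(gr)
  }
  if (ncol(dt) < 4L) stop("BedGraph needs 4 columns: ", path)
  v <- suppressWarnings(as.numeric(dt[[4]]))
  bad <- which(is.na(v))
  if (length(bad)) stop("malformed BedGraph value at line ", bad[1],
                        " in ", path)
  gr <- GRanges(as.character(dt[[1]]), IRanges(dt[[2]] + 1L, dt[[3]]),
                seqinfo = assembly)
  mcols(gr)$score <- v
  sort(gr, ignore.strand = TRUE)
}

#' Tile an assembly with (optionally sliding) windows
#'
#' Per chromosome, windows start at 0, `step`, 2*`step`, ...; each window is
#' `[s, min(s + width, L))`. A terminal partial window is emitted whenever
#' its length is at least 1 bp and flagged in the `partial` metadata column;
#' partial windows face the same downstream thresholds as full ones.
#'
#' @param assembly A Seqinfo.
#' @param width Window width in bp (default 500).
#' @param step Step between window starts, `1 <= step <= width`
#'   (default `width`, i.e. non-overlapping).
#' @return Sorted GRanges of windows with logical metadata column `partial`.
#' @export
make_windows <- function(assembly, width = 500L, step = width) {
  if (width < 1L) stop("width must be >= 1")
  if (step < 1L || step > width) stop("step must satisfy 1 <= step <= width")
  sl <- seqlengths(assembly)
  parts <- lapply(seq_along(sl), function(i) {
    L <- sl[[i]]
    s0 <- seq.int(0L, L - 1L, by = step)
    GRanges(names(sl)[i], IRanges(s0 + 1, pmin(s0 + width, L)),
            seqinfo = assembly)
  })
  w <- suppressWarnings(do.call(c, parts))
  mcols(w)$partial <- width(w) < width
  w
}

#' Remove bins overlapping a blacklist
#'
#' A bin with >= 1 bp overlap with any blacklist interval is removed whole
#' (excluded, not trimmed).
#'
#' @param bins,blacklist GRanges on the same assembly.
#' @return The surviving bins.
#' @export
subtract_blacklist <- function(bins, blacklist) {
  if (length(blacklist) == 0L) return(bins)
  bins[!overlapsAny(bins, blacklist, ignore.strand = TRUE)]
}

#' Keep bins with sufficient total overlap with peaks
#'
#' Overlap is measured against the union of the peaks (peaks are reduced
#' first), so abutting peaks are not double-counted.
#'
#' @param bins GRanges of candidate bins.
#' @param peaks GRanges of peak regions.
#' @param min_overlap Minimum total overlap in bp (default 250).
#' @return The bins whose total overlap with the peak union is
#'   `>= min_overlap`.
#' @export
filter_candidates <- function(bins, peaks, min_overlap = 250L) {
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  if (length(peaks) == 0L || length(bins) == 0L) return(bins[0])
  pk <- reduce(granges(peaks), ignore.strand = TRUE)
  hits <- findOverlaps(granges(bins), pk, ignore.strand = TRUE)
  if (length(hits) == 0L) return(bins[0])
  ov <- width(pintersect(granges(bins)[queryHits(hits)],
                         pk[subjectHits(hits)]))
  tot <- rep(0, length(bins))
  agg <- rowsum(ov, queryHits(hits))
  tot[as.integer(rownames(agg))] <- agg[, 1]
  bins[tot >= min_overlap]
}

#' Merge overlapping or nearby intervals
#'
#' Intervals separated by a gap of at most `max_gap` bp merge; `max_gap = 0`
#' merges overlapping and book-ended intervals. Strand is ignored.
#'
#' @param x GRanges.
#' @param max_gap Maximum gap bridged (default 0).
#' @return Disjoint, sorted GRanges whose union equals the union of `x`.
#' @export
merge_intervals <- function(x, max_gap = 0L) {
  if (max_gap < 0L) stop("max_gap must be >= 0")
  reduce(granges(x), min.gapwidth = max_gap + 1L, ignore.strand = TRUE)
}
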