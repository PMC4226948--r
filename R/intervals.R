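## Peak sets and the multi-factor segmentation primitive.
##
## Internally every interval is a GRanges (1-based, closed, the Bioconductor
## convention); BED files are 0-based half-open and converted at I/O. Peak
## summits are stored in mcols()$summit as 1-based positions.

#' Read a BED file of ChIP-seq peaks
#'
#' Accepts BED3, BED6, and BED6 plus one extra integer column holding the
#' summit offset relative to the interval start (the MACS "peaks.xls"
#' convention). Peaks without a summit column get the interval midpoint
#' (floor) as their summit.
#'
#' @param path Path to a BED file.
#' @param genome A `Seqinfo` from [genome_spec()]; coordinates are validated
#'   against it.
#' @param factor Optional factor (protein) label stored in
#'   `metadata(x)$factor`.
#' @return A sorted `GRanges` with mcols `name`, `score`, `summit` (1-based).
#' @export
read_bed <- function(path, genome, factor = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) stop("no intervals in BED file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("parse error at line ", which(nf < 3L)[1L],
         ": fewer than 3 BED fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start0) | is.na(end0)
  if (any(bad)) {
    stop("parse error at line ", which(bad)[1L],
         ": non-numeric start/end")
  }
  bad <- start0 >= end0 | start0 < 0
  if (any(bad)) {
    stop("invalid interval at line ", which(bad)[1L],
         ": start must satisfy 0 <= start < end")
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), NA_character_)
  name[nf < 4L] <- NA_character_
  score <- rep(NA_real_, length(lines))
  has5 <- nf >= 5L
  score[has5] <- suppressWarnings(
    as.numeric(vapply(fields[has5], `[[`, "", 5L)))
  summit0 <- floor((start0 + end0) / 2)
  has7 <- nf >= 7L
  if (any(has7)) {
    off <- suppressWarnings(as.numeric(vapply(fields[has7], `[[`, "", 7L)))
    if (any(is.na(off))) {
      stop("parse error at line ", which(has7)[which(is.na(off))[1L]],
           ": non-numeric summit offset")
    }
    summit0[has7] <- start0[has7] + off
  }
  if (any(summit0 < start0 | summit0 >= end0)) {
    i <- which(summit0 < start0 | summit0 >= end0)[1L]
    stop("invalid summit at line ", i, ": summit outside [start, end)")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    name = name, score = score, summit = as.integer(summit0 + 1))
  validate_intervals(gr, genome, what = "peak")
  gr <- set_genome(gr, genome)
  gr <- GenomicRanges::sort(gr)
  if (!is.null(factor)) S4Vectors::metadata(gr)$factor <- factor
  gr
}

#' Write intervals to BED
#'
#' Emits BED6 when `name`/`score` metadata are present (missing values become
#' `.` and `0`), else BED3. Coordinates are converted back to the 0-based
#' half-open BED convention.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param score_col Name of the mcols column to place in the BED score field
#'   (default `"score"`).
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, score_col = "score") {
  m <- GenomicRanges::mcols(gr)
  cols <- list(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = format(GenomicRanges::start(gr) - 1L, scientific = FALSE, trim = TRUE),
    end = format(GenomicRanges::end(gr), scientific = FALSE, trim = TRUE))
  has_meta <- (!is.null(m$name) || (score_col %in% names(m)))
  if (has_meta) {
    nm <- if (!is.null(m$name)) as.character(m$name) else rep(NA_character_, length(gr))
    sc <- if (score_col %in% names(m)) m[[score_col]] else rep(NA_real_, length(gr))
    cols$name <- ifelse(is.na(nm), ".", nm)
    cols$score <- ifelse(is.na(sc), "0",
                         format(sc, scientific = FALSE, trim = TRUE))
    cols$strand <- rep(".", length(gr))
  }
  writeLines(do.call(paste, c(unname(cols), sep = "\t")), path)
  invisible(path)
}

#' Fixed-width windows around peak summits
#'
#' Replaces each peak by the window `[summit - halfwidth, summit + halfwidth)`
#' (0-based half-open semantics, i.e. `2 * halfwidth` bp), the standard
#' refinement of MACS peaks to 400 bp summit windows at the default. Windows
#' are clipped (not dropped) at chromosome ends.
#'
#' @param peaks `GRanges` with a `summit` mcol, as from [read_bed()].
#' @param halfwidth Half window size in bp (> 0; default 200, giving 400 bp
#'   windows).
#' @return A sorted `GRanges` of summit windows (the `summit` mcol is kept).
#' @export
summit_windows <- function(peaks, halfwidth = 200) {
  if (length(halfwidth) != 1L || is.na(halfwidth) || halfwidth <= 0) {
    stop("halfwidth must be a single positive number")
  }
  summit <- GenomicRanges::mcols(peaks)$summit
  if (is.null(summit) || anyNA(summit)) {
    stop("every peak needs a summit (read_bed supplies midpoints)")
  }
  s0 <- summit - 1L           # 0-based summit
  start1 <- pmax(s0 - halfwidth + 1, 1)
  lens <- GenomeInfoDb::seqlengths(peaks)[
    as.character(GenomicRanges::seqnames(peaks))]
  end1 <- s0 + halfwidth
  if (!all(is.na(lens))) end1 <- pmin(end1, lens)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                IRanges::IRanges(start1, end1),
                                seqinfo = GenomeInfoDb::seqinfo(peaks))
  GenomicRanges::mcols(out) <- GenomicRanges::mcols(peaks)
  GenomicRanges::sort(out)
}

#' Segment the union of several peak sets by factor membership
#'
#' The multi-factor occupancy segmentation: the union of all intervals is cut
#' into maximal segments of constant factor membership (the MultiIntersectBed
#' operation). Overlapping windows of the same factor count once — membership
#' is per factor, not per peak.
#'
#' @param peaksets Named list of `GRanges`, one per factor; names are the
#'   factor labels.
#' @return A sorted `GRanges` of occupancy segments with mcols:
#'   `membership` (logical matrix, one column per factor) and `k` (number of
#'   factors present, >= 1). Adjacent segments always differ in membership.
#' @export
multi_intersect <- function(peaksets) {
  if (!is.list(peaksets) || length(peaksets) == 0L) {
    stop("peaksets must be a non-empty named list of GRanges")
  }
  if (is.null(names(peaksets)) || any(!nzchar(names(peaksets)))) {
    stop("every peak set needs a factor name")
  }
  factors <- names(peaksets)
  stripped <- lapply(peaksets, function(g) {
    GenomicRanges::mcols(g) <- NULL
    g
  })
  pooled <- suppressWarnings(unlist(methods::as(stripped, "GRangesList"),
                                    use.names = FALSE))
  if (length(pooled) == 0L) stop("all peak sets are empty")
  segs <- GenomicRanges::disjoin(pooled)
  reduced <- lapply(stripped, GenomicRanges::reduce)
  memb <- vapply(reduced, function(r) IRanges::overlapsAny(segs, r),
                 logical(length(segs)))
  memb <- matrix(memb, nrow = length(segs),
                 dimnames = list(NULL, factors))
  segs <- GenomicRanges::sort(segs)
  ## disjoin() splits at every peak endpoint; re-fuse adjacent segments whose
  ## membership vector did not actually change
  n <- length(segs)
  if (n > 1L) {
    same_chrom <- as.character(GenomicRanges::seqnames(segs))[-1L] ==
      as.character(GenomicRanges::seqnames(segs))[-n]
    adjacent <- GenomicRanges::start(segs)[-1L] ==
      GenomicRanges::end(segs)[-n] + 1L
    same_memb <- rowSums(memb[-1L, , drop = FALSE] !=
                           memb[-n, , drop = FALSE]) == 0L
    new_run <- c(TRUE, !(same_chrom & adjacent & same_memb))
    run <- cumsum(new_run)
    if (max(run) < n) {
      starts <- tapply(GenomicRanges::start(segs), run, min)
      ends <- tapply(GenomicRanges::end(segs), run, max)
      first <- which(new_run)
      segs <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(segs)[first],
        IRanges::IRanges(as.integer(starts), as.integer(ends)),
        seqinfo = GenomeInfoDb::seqinfo(segs))
      memb <- memb[first, , drop = FALSE]
    }
  }
  GenomicRanges::mcols(segs)$membership <- memb
  GenomicRanges::mcols(segs)$k <- as.integer(rowSums(memb))
  stopifnot(all(GenomicRanges::mcols(segs)$k >= 1L))
  segs
}
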