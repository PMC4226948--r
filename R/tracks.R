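## Binned coverage tracks, rank-order (quantile) normalization across
## samples, and anchored tag-density profiles in RPM.

#' Construct a binned coverage track
#'
#' @param sample Sample label.
#' @param width Bin width in bp (>= 1).
#' @param values Named list of numeric vectors, one per chromosome; vector
#'   `i` holds the signal of bin `[(i-1)*width, i*width)`.
#' @param total Total read count of the library, used for RPM scaling
#'   (default: sum of values).
#' @return Object of class `binned_track`.
#' @export
binned_track <- function(sample, width, values, total = NULL) {
  if (width < 1 || width != floor(width)) stop("width must be an integer >= 1")
  if (!is.list(values) || is.null(names(values))) {
    stop("values must be a named list (one numeric vector per chromosome)")
  }
  values <- lapply(values, as.numeric)
  if (any(vapply(values, function(v) any(!is.finite(v)), logical(1)))) {
    stop("track values must be finite")
  }
  if (is.null(total)) total <- sum(vapply(values, sum, numeric(1)))
  structure(list(sample = sample, width = as.integer(width),
                 values = values, total = total),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat("binned_track:", x$sample, "-", x$width, "bp bins,",
      sum(lengths(x$values)), "bins, total", format(x$total), "\n")
  invisible(x)
}

#' Bin reads or bedGraph signal into a coverage track
#'
#' Read mode: `x` is a data.frame with columns `chrom` and `pos` (0-based 5'
#' start; or set `point = "midpoint"` and supply `start`/`end`). Each read is
#' assigned to exactly one bin, so the bin sum equals the read count.
#' bedGraph mode: `x` is a `GRanges` with a `score` mcol (as imported by
#' [read_bedgraph()]); each interval's value is apportioned to bins by
#' overlap length, conserving total signal.
#'
#' @param x Reads data.frame or bedGraph `GRanges`.
#' @param genome A `Seqinfo`.
#' @param width Bin width in bp (default 100).
#' @param sample Sample label.
#' @param point Read assignment point: `"start"` (5' position, default) or
#'   `"midpoint"`.
#' @param total Library total for RPM; defaults to the number of reads (read
#'   mode) or the summed signal (bedGraph mode).
#' @return A `binned_track`.
#' @export
bin_coverage <- function(x, genome, width = 100, sample = "sample",
                         point = c("start", "midpoint"), total = NULL) {
  point <- match.arg(point)
  chroms <- GenomeInfoDb::seqnames(genome)
  lens <- GenomeInfoDb::seqlengths(genome)
  nbins <- ceiling(lens / width)
  values <- lapply(stats::setNames(nbins, chroms), numeric)
  if (is.data.frame(x)) {
    pos <- if (point == "midpoint" && all(c("start", "end") %in% names(x))) {
      floor((x$start + x$end) / 2)
    } else if ("pos" %in% names(x)) {
      x$pos
    } else {
      x$start
    }
    if (any(!x$chrom %in% chroms)) stop("read on unknown chromosome")
    if (any(pos < 0 | pos >= lens[x$chrom])) {
      stop("read position outside its chromosome")
    }
    bin <- floor(pos / width) + 1L
    for (ch in unique(x$chrom)) {
      sel <- x$chrom == ch
      values[[ch]] <- as.numeric(
        tabulate(bin[sel], nbins = nbins[[ch]]))
    }
    if (is.null(total)) total <- nrow(x)
  } else if (inherits(x, "GRanges")) {
    score <- GenomicRanges::mcols(x)$score
    if (is.null(score)) stop("bedGraph GRanges needs a score mcol")
    chr <- as.character(GenomicRanges::seqnames(x))
    if (any(!chr %in% chroms)) stop("interval on unknown chromosome")
    s0 <- GenomicRanges::start(x) - 1L
    e0 <- GenomicRanges::end(x)
    if (any(s0 < 0 | e0 > lens[chr])) stop("interval outside its chromosome")
    for (idx in seq_along(x)) {
      ch <- chr[idx]
      first <- floor(s0[idx] / width) + 1L
      last <- floor((e0[idx] - 1L) / width) + 1L
      for (b in first:last) {
        lo <- max(s0[idx], (b - 1L) * width)
        hi <- min(e0[idx], b * width)
        values[[ch]][b] <- values[[ch]][b] + score[idx] * (hi - lo)
      }
    }
    ## bin value = summed per-base signal (score x covered bases), so the
    ## genome-wide total is conserved exactly
    if (is.null(total)) total <- sum(vapply(values, sum, numeric(1)))
  } else {
    stop("x must be a reads data.frame or a bedGraph GRanges")
  }
  binned_track(sample, width, values, total)
}

#' Import a bedGraph file
#'
#' @param path bedGraph path.
#' @return `GRanges` with a `score` mcol.
#' @export
read_bedgraph <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' Export a binned track as bedGraph
#'
#' @param track A `binned_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  grl <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    nz <- which(v != 0)
    if (length(nz) == 0L) return(NULL)
    GenomicRanges::GRanges(ch,
                           IRanges::IRanges((nz - 1L) * track$width + 1L,
                                            nz * track$width),
                           score = v[nz])
  })
  grl <- grl[!vapply(grl, is.null, logical(1))]
  gr <- suppressWarnings(unlist(methods::as(grl, "GRangesList")))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

## flatten a track's bins genome-wide in fixed chromosome order
flatten_track <- function(track, chrom_order) {
  unlist(track$values[chrom_order], use.names = FALSE)
}

#' Rank-order normalization across samples
#'
#' All samples' genome-wide bins are rank-ordered from high to low and, at
#' each rank level, re-assigned the cross-sample mean of the values at that
#' level (quantile normalization). Tied values within a sample receive the
#' mean of the level values their ranks span. Afterwards every sample has an
#' identical sorted value multiset while its internal ordering is preserved.
#'
#' @param tracks List of >= 2 `binned_track`s on the same genome and bin
#'   width.
#' @param nonzero_only If `TRUE`, only bins nonzero in at least one sample
#'   are normalized (others stay 0). Default `FALSE`: all bins genome-wide.
#' @return List of normalized `binned_track`s (totals preserved).
#' @export
rank_order_normalize <- function(tracks, nonzero_only = FALSE) {
  if (length(tracks) < 2L) stop("need at least 2 tracks")
  chroms <- names(tracks[[1L]]$values)
  width <- tracks[[1L]]$width
  sizes <- lengths(tracks[[1L]]$values)
  for (t in tracks[-1L]) {
    if (t$width != width || !identical(names(t$values), chroms) ||
        !identical(lengths(t$values), sizes)) {
      stop("tracks must share genome and bin width")
    }
  }
  mat <- vapply(tracks, flatten_track, numeric(sum(sizes)),
                chrom_order = chroms)
  active <- if (nonzero_only) rowSums(mat != 0) > 0 else
    rep(TRUE, nrow(mat))
  sub <- mat[active, , drop = FALSE]
  level_means <- rowMeans(apply(sub, 2L, sort))
  norm <- apply(sub, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    (level_means[floor(r)] + level_means[ceiling(r)]) / 2
  })
  mat[active, ] <- norm
  lapply(seq_along(tracks), function(j) {
    values <- split(mat[, j], rep(chroms, sizes))[chroms]
    binned_track(tracks[[j]]$sample, width, values,
                 total = tracks[[j]]$total)
  })
}

#' Anchored tag-density profile in RPM
#'
#' Extracts, for each anchor center, the track bins covering
#' `[center - flank, center + flank)` and scales them to reads per million
#' (value x 1e6 / library total). Anchors whose window runs off a chromosome
#' end are padded with `NA`, which column means exclude.
#'
#' @param track A `binned_track`.
#' @param anchors `GRanges` (centers = `summit` mcol, else midpoints) or a
#'   data.frame with `chrom` and `center` (1-based bp).
#' @param flank Flank size in bp; must be a multiple of the track bin width.
#' @return Matrix (anchors x 2*flank/width) of RPM values with relative bin
#'   start offsets as column names, plus attribute `"colmeans"`.
#' @export
anchored_profile <- function(track, anchors, flank) {
  width <- track$width
  if (flank <= 0 || flank %% width != 0) {
    stop("flank must be a positive multiple of the bin width")
  }
  if (inherits(anchors, "GRanges")) {
    center <- GenomicRanges::mcols(anchors)$summit
    if (is.null(center)) {
      center <- floor((GenomicRanges::start(anchors) - 1L +
                         GenomicRanges::end(anchors)) / 2) + 1L
    }
    chrom <- as.character(GenomicRanges::seqnames(anchors))
  } else {
    chrom <- anchors$chrom
    center <- anchors$center
  }
  if (length(center) == 0L) stop("no anchors supplied")
  ncol_out <- 2L * flank / width
  offsets <- seq(-flank, flank - width, by = width)
  out <- matrix(NA_real_, nrow = length(center), ncol = ncol_out,
                dimnames = list(NULL, offsets))
  for (i in seq_along(center)) {
    v <- track$values[[chrom[i]]]
    if (is.null(v)) stop("anchor on chromosome without track values: ",
                         chrom[i])
    c0 <- center[i] - 1L
    bins <- floor((c0 + offsets) / width) + 1L
    ok <- bins >= 1L & bins <= length(v)
    out[i, ok] <- v[bins[ok]] * 1e6 / track$total
  }
  if (all(is.na(out))) stop("no valid anchors within the track")
  attr(out, "colmeans") <- colMeans(out, na.rm = TRUE)
  out
}

#' Write a profile matrix (and its column means) as TSV
#'
#' @param profile Matrix from [anchored_profile()].
#' @param path Output path for the matrix.
#' @param colmeans_path Optional path for the column-mean metaprofile.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, colmeans_path = NULL) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(colmeans_path)) {
    cm <- attr(profile, "colmeans")
    utils::write.table(data.frame(offset = names(cm), mean_rpm = cm),
                       colmeans_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
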