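## Restriction-fragment Hi-C containers and the local-contrast border
## strength statistic.
##
## A FragmentMap holds, per chromosome, the ordered cut-site coordinates
## (0-based bp); fragment i (1-based index) spans [cuts[i], cuts[i+1]).
## A ContactMatrix holds symmetric fragment-level counts as a sparse matrix.

#' Build a fragment map from cut-site coordinates
#'
#' @param cuts Named list, one numeric vector of strictly increasing cut-site
#'   coordinates (0-based bp) per chromosome. A chromosome with C cut sites
#'   has C - 1 fragments.
#' @return An object of class `fragment_map`.
#' @export
fragment_map <- function(cuts) {
  if (!is.list(cuts) || is.null(names(cuts))) {
    stop("cuts must be a named list of coordinate vectors")
  }
  for (chrom in names(cuts)) {
    v <- cuts[[chrom]]
    if (length(v) < 2L || is.unsorted(v, strictly = TRUE)) {
      stop("cut sites on ", chrom, " must be >= 2 strictly increasing values")
    }
  }
  structure(list(cuts = lapply(cuts, as.numeric)), class = "fragment_map")
}

#' @export
print.fragment_map <- function(x, ...) {
  cat("fragment_map:", length(x$cuts), "chromosome(s),",
      sum(vapply(x$cuts, length, 1L) - 1L), "fragments\n")
  invisible(x)
}

## number of fragments per chromosome
n_fragments <- function(fragmap) {
  vapply(fragmap$cuts, length, integer(1)) - 1L
}

#' Read a fragment map from a BED file of restriction fragments
#'
#' Fragments must tile each chromosome contiguously (each fragment's start
#' equals the previous fragment's end).
#'
#' @param path BED3 path of restriction fragments.
#' @return A `fragment_map`.
#' @export
read_fragments_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "numeric", "numeric"))
  names(tab) <- c("chrom", "start", "end")
  cuts <- lapply(split(tab, tab$chrom), function(d) {
    d <- d[order(d$start), ]
    if (any(d$start[-1L] != d$end[-nrow(d)])) {
      stop("fragments on ", d$chrom[1L], " do not tile contiguously")
    }
    c(d$start, d$end[nrow(d)])
  })
  fragment_map(cuts)
}

#' Build a symmetric fragment-level contact matrix
#'
#' @param chrom Chromosome name.
#' @param i,j Fragment indices (1-based) of each contact pair.
#' @param count Contact counts (>= 0).
#' @param n_frag Number of fragments on the chromosome.
#' @return An object of class `contact_matrix` wrapping a sparse symmetric
#'   matrix.
#' @export
contact_matrix <- function(chrom, i, j, count, n_frag) {
  if (any(i < 1L | i > n_frag | j < 1L | j > n_frag)) {
    stop("fragment index out of range on ", chrom)
  }
  if (any(count < 0)) stop("contact counts must be >= 0")
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  m <- Matrix::sparseMatrix(i = lo, j = hi, x = count,
                            dims = c(n_frag, n_frag))
  m <- m + Matrix::t(m)
  ## the doubled diagonal from symmetrization is irrelevant: the statistic
  ## excludes diagonal terms, but keep counts faithful anyway
  Matrix::diag(m) <- Matrix::diag(m) / 2
  structure(list(chrom = chrom, matrix = m, n_frag = as.integer(n_frag)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", x$chrom, "-", x$n_frag, "fragments,",
      sum(x$matrix) - sum(Matrix::diag(x$matrix)) / 1, "off-diagonal count mass\n")
  invisible(x)
}

#' Read sparse contact triplets
#'
#' TSV with columns chrom, fragment_i, fragment_j, count (1-based fragment
#' indices, upper or lower triangle; symmetric completion is implied).
#'
#' @param path Triplet TSV path.
#' @param fragmap A `fragment_map` providing fragment counts per chromosome.
#' @return Named list of `contact_matrix`, one per chromosome present.
#' @export
read_contacts_tsv <- function(path, fragmap) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "numeric"))
  names(tab) <- c("chrom", "i", "j", "count")
  nf <- n_fragments(fragmap)
  out <- lapply(split(tab, tab$chrom), function(d) {
    chrom <- d$chrom[1L]
    if (!chrom %in% names(nf)) stop("no fragments for chromosome ", chrom)
    contact_matrix(chrom, d$i, d$j, d$count, nf[[chrom]])
  })
  out
}

#' Write a contact matrix as sparse triplets (upper triangle)
#'
#' @param cm A `contact_matrix` or list of them.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_contacts_tsv <- function(cm, path) {
  if (inherits(cm, "contact_matrix")) cm <- list(cm)
  rows <- lapply(cm, function(x) {
    tri <- methods::as(Matrix::triu(x$matrix), "TsparseMatrix")
    keep <- tri@x != 0
    data.frame(chrom = x$chrom, i = tri@i[keep] + 1L, j = tri@j[keep] + 1L,
               count = tri@x[keep])
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$chrom, tab$i, tab$j), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Local-contrast border strength at restriction cut sites
#'
#' At each interior cut site S with at least `window_w` fragments on both
#' sides, region A is the `window_w` fragments left of S and region B the
#' `window_w` fragments right. The raw contrast is the ratio of the mean
#' per-pair intra-region count (pairs within A plus pairs within B, diagonal
#' excluded) to the mean per-pair inter-region count (pairs spanning S), with
#' a pseudocount on the inter sum guarding empty windows:
#' \deqn{L_{raw} = \frac{intra / (w(w-1))}{(inter + pc) / w^2}.}
#' Scores are centered by dividing by the genome-wide median, so the median
#' border strength is exactly 1; strong TAD borders score well above 1.
#'
#' @param contacts A `contact_matrix` or named list of them (per chromosome).
#' @param fragmap A `fragment_map` covering the same chromosomes.
#' @param window_w Window size in fragments on each side (>= 2; default 10).
#' @param pseudocount Added to the inter-region sum (default 1).
#' @return A `data.frame` with columns `chrom`, `cut_index` (the cut site's
#'   1-based index in the fragment map), `cut_bp` (0-based coordinate),
#'   `L_raw`, and `L` (median-centered border strength).
#' @export
local_contrast <- function(contacts, fragmap, window_w = 10,
                           pseudocount = 1) {
  if (inherits(contacts, "contact_matrix")) {
    contacts <- stats::setNames(list(contacts), contacts$chrom)
  }
  if (window_w < 2 || window_w != floor(window_w)) {
    stop("window_w must be an integer >= 2")
  }
  w <- as.integer(window_w)
  n_intra <- w * (w - 1)          # unordered pairs within A plus within B
  n_inter <- w * w
  total <- sum(vapply(contacts, function(x) sum(x$matrix), numeric(1)))
  if (total == 0) stop("degenerate input: contact matrix is all zero")
  per_chrom <- lapply(contacts, function(x) {
    f <- x$n_frag
    if (f < 2L * w) {
      message("skipping ", x$chrom, ": fewer than ", 2L * w,
              " fragments for window_w = ", w)
      return(NULL)
    }
    m <- x$matrix
    dg <- Matrix::diag(m)
    cuts <- fragmap$cuts[[x$chrom]]
    if (is.null(cuts) || length(cuts) != f + 1L) {
      stop("fragment map does not match contact matrix on ", x$chrom)
    }
    sites <- (w + 1L):(f - w + 1L)   # cut index s separates fragments s-1 | s
    lraw <- vapply(sites, function(s) {
      A <- (s - w):(s - 1L)
      B <- s:(s + w - 1L)
      blockA <- m[A, A, drop = FALSE]
      blockB <- m[B, B, drop = FALSE]
      intra <- (sum(blockA) - sum(dg[A]) + sum(blockB) - sum(dg[B])) / 2
      inter <- sum(m[A, B, drop = FALSE])
      (intra / n_intra) / ((inter + pseudocount) / n_inter)
    }, numeric(1))
    data.frame(chrom = x$chrom, cut_index = sites, cut_bp = cuts[sites],
               L_raw = lraw, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_chrom[!vapply(per_chrom, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) {
    stop("no scorable cut sites: all chromosomes shorter than the window")
  }
  rownames(out) <- NULL
  out$L <- out$L_raw / stats::median(out$L_raw)
  out
}

#' Write border scores as TSV
#'
#' @param scores `data.frame` from [local_contrast()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_border_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read TAD calls from BED
#'
#' @param path BED3+ path of topological domains.
#' @return A sorted `GRanges` of domains (no overlap allowed).
#' @export
read_tads_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE)
  gr <- GenomicRanges::GRanges(tab[[1L]],
                               IRanges::IRanges(tab[[2L]] + 1, tab[[3L]]))
  gr <- GenomicRanges::sort(gr)
  if (length(gr) > 1L &&
      length(GenomicRanges::findOverlaps(gr, drop.self = TRUE)) > 0L) {
    stop("TADs must not overlap")
  }
  gr
}

#' Border positions implied by a TAD set
#'
#' Each boundary between consecutive domains on a chromosome contributes one
#' border at the end coordinate (0-based, i.e. the first base of the next
#' domain when domains are contiguous).
#'
#' @param tads `GRanges` of sorted, non-overlapping domains.
#' @return `data.frame` with columns `chrom`, `pos` (0-based bp).
#' @export
tad_borders <- function(tads) {
  tads <- GenomicRanges::sort(tads)
  per <- lapply(split(tads, droplevels(GenomicRanges::seqnames(tads))),
                function(d) {
    if (length(d) < 2L) return(NULL)
    data.frame(chrom = as.character(GenomicRanges::seqnames(d))[-length(d)],
               pos = GenomicRanges::end(d)[-length(d)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per[!vapply(per, is.null, logical(1))])
  if (is.null(out)) {
    return(data.frame(chrom = character(0), pos = numeric(0)))
  }
  rownames(out) <- NULL
  out
}

#' Classify TAD borders by the APBSs that delineate them
#'
#' Each border is labeled by the highest occupancy class among APBSs falling
#' in its window: in `"one_cut_site"` mode the window is the union of the two
#' restriction fragments adjacent to the border (i.e. the APBS lies between
#' the previous and the next cut site); in bp mode it is the border position
#' plus/minus `window` bp. Borders with no APBS in the window are labeled
#' `"none"`.
#'
#' @param tads `GRanges` of domains (borders are derived), or a `data.frame`
#'   of borders from [tad_borders()].
#' @param apbs `GRanges` of APBSs with `k` and `class` mcols.
#' @param fragmap A `fragment_map` (required for `"one_cut_site"` mode).
#' @param window `"one_cut_site"` or a window half-size in bp.
#' @return List with `borders` (data.frame: chrom, pos, class) and
#'   `percentages` (named numeric over high/medium/low/none, summing to 100
#'   up to rounding).
#' @export
delineate_borders <- function(tads, apbs, fragmap = NULL,
                              window = "one_cut_site") {
  borders <- if (is.data.frame(tads)) tads else tad_borders(tads)
  if (nrow(borders) == 0L) stop("no TAD borders to classify")
  if (identical(window, "one_cut_site")) {
    if (is.null(fragmap)) stop("one_cut_site mode needs a fragment map")
    lohi <- t(mapply(function(chrom, pos) {
      cuts <- fragmap$cuts[[chrom]]
      if (is.null(cuts)) stop("no fragment map for chromosome ", chrom)
      j <- findInterval(pos, cuts)   # fragment containing/starting at pos
      lo <- cuts[max(j - 1L, 1L)]
      hi <- cuts[min(j + 1L, length(cuts))]
      c(lo, hi)
    }, borders$chrom, borders$pos))
    win <- GenomicRanges::GRanges(borders$chrom,
                                  IRanges::IRanges(lohi[, 1L] + 1,
                                                   lohi[, 2L]))
  } else {
    if (!is.numeric(window) || window <= 0) {
      stop("window must be \"one_cut_site\" or a positive bp half-size")
    }
    win <- GenomicRanges::GRanges(
      borders$chrom,
      IRanges::IRanges(pmax(borders$pos - window + 1, 1),
                       borders$pos + window))
  }
  hits <- GenomicRanges::findOverlaps(win, apbs, ignore.strand = TRUE)
  cls <- rep("none", nrow(borders))
  if (length(hits) > 0L) {
    lev <- as.integer(GenomicRanges::mcols(apbs)$class[
      S4Vectors::subjectHits(hits)])   # ordered factor: low < medium < high
    best <- tapply(lev, S4Vectors::queryHits(hits), max)
    cls[as.integer(names(best))] <-
      c("low", "medium", "high")[as.integer(best)]
  }
  borders$class <- factor(cls, levels = c("high", "medium", "low", "none"))
  pct <- 100 * table(borders$class) / nrow(borders)
  list(borders = borders,
       percentages = stats::setNames(as.numeric(pct), names(pct)))
}

#' Mean border strength by APBS occupancy
#'
#' Each APBS is assigned the border score of the nearest scored cut site on
#' its chromosome within `max_dist` bp of its center; APBSs with no cut site
#' in range are dropped (and counted). Centered contrasts are then summarised
#' per occupancy k and per occupancy class.
#'
#' @param apbs `GRanges` with `k`, `class` and `center` mcols.
#' @param scores Border scores from [local_contrast()].
#' @param max_dist Maximum center-to-cut-site distance in bp.
#' @return List with `by_k` and `by_class` data.frames (n, mean and sd of L)
#'   and `n_dropped`.
#' @export
strength_by_occupancy <- function(apbs, scores, max_dist = 10000) {
  center <- GenomicRanges::mcols(apbs)$center
  if (is.null(center)) {
    center <- floor((GenomicRanges::start(apbs) - 1L +
                       GenomicRanges::end(apbs)) / 2) + 1L
  }
  chrom <- as.character(GenomicRanges::seqnames(apbs))
  L <- rep(NA_real_, length(apbs))
  for (ch in unique(chrom)) {
    sc <- scores[scores$chrom == ch, ]
    if (nrow(sc) == 0L) next
    idx <- which(chrom == ch)
    c0 <- center[idx] - 1L
    nearest <- findInterval(c0, sc$cut_bp)
    lo <- pmax(nearest, 1L)
    hi <- pmin(nearest + 1L, nrow(sc))
    d_lo <- abs(c0 - sc$cut_bp[lo])
    d_hi <- abs(sc$cut_bp[hi] - c0)
    pick <- ifelse(d_lo <= d_hi, lo, hi)
    d <- pmin(d_lo, d_hi)
    ok <- d <= max_dist
    L[idx[ok]] <- sc$L[pick[ok]]
  }
  keep <- !is.na(L)
  summarise <- function(by) {
    agg <- stats::aggregate(L[keep], list(by = by[keep]), function(v) {
      c(n = length(v), mean = mean(v), sd = stats::sd(v))
    })
    data.frame(group = agg$by, n = as.integer(agg$x[, "n"]),
               mean_L = agg$x[, "mean"], sd_L = agg$x[, "sd"])
  }
  list(by_k = summarise(GenomicRanges::mcols(apbs)$k),
       by_class = summarise(GenomicRanges::mcols(apbs)$class),
       n_dropped = sum(!keep))
}

#' TAD size versus local APBS density
#'
#' Per domain: size in bp, the maximum APBS occupancy k within
#' `density_radius` of either border, and the APBS density (number of APBS
#' centers within `density_radius` of either border). Sizes are summarised
#' by density tercile and the size-density association is reported as a
#' Spearman rank correlation.
#'
#' @param tads `GRanges` of domains (>= 2).
#' @param apbs `GRanges` of APBSs.
#' @param density_radius Radius around each border in bp (default 10000).
#' @return List with `per_tad` data.frame, `median_by_stratum` (named vector
#'   over density terciles) and `spearman` (size vs density).
#' @export
tad_size_by_apbs <- function(tads, apbs, density_radius = 10000) {
  if (length(tads) < 2L) stop("need at least 2 TADs")
  center <- GenomicRanges::mcols(apbs)$center
  if (is.null(center)) {
    center <- floor((GenomicRanges::start(apbs) - 1L +
                       GenomicRanges::end(apbs)) / 2) + 1L
  }
  pts <- GenomicRanges::GRanges(GenomicRanges::seqnames(apbs),
                                IRanges::IRanges(center, center))
  edges <- c(GenomicRanges::start(tads) - 1L, GenomicRanges::end(tads))
  edge_gr <- GenomicRanges::GRanges(
    rep(as.character(GenomicRanges::seqnames(tads)), 2L),
    IRanges::IRanges(pmax(edges - density_radius + 1, 1),
                     edges + density_radius))
  hits <- GenomicRanges::findOverlaps(edge_gr, pts, ignore.strand = TRUE)
  tad_of_edge <- rep(seq_along(tads), 2L)
  dens <- rep(0L, length(tads))
  maxk <- rep(0L, length(tads))
  if (length(hits) > 0L) {
    tad_id <- tad_of_edge[S4Vectors::queryHits(hits)]
    apbs_id <- S4Vectors::subjectHits(hits)
    ## count each APBS once per TAD even if near both borders
    uq <- !duplicated(paste(tad_id, apbs_id))
    cnt <- table(tad_id[uq])
    dens[as.integer(names(cnt))] <- as.integer(cnt)
    k <- GenomicRanges::mcols(apbs)$k
    if (!is.null(k)) {
      mk <- tapply(k[apbs_id], tad_id, max)
      maxk[as.integer(names(mk))] <- as.integer(mk)
    }
  }
  per_tad <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(tads)),
    start = GenomicRanges::start(tads) - 1L,
    end = GenomicRanges::end(tads),
    size = GenomicRanges::width(tads),
    apbs_density = dens, max_border_k = maxk)
  if (length(unique(dens)) == 1L) {
    strat <- factor(rep("all", length(tads)))
    rho <- 0
  } else {
    br <- unique(stats::quantile(dens, c(0, 1 / 3, 2 / 3, 1)))
    strat <- cut(dens, breaks = br, include.lowest = TRUE)
    rho <- if (stats::sd(per_tad$size) == 0) 0 else
      stats::cor(per_tad$size, per_tad$apbs_density, method = "spearman")
  }
  per_tad$stratum <- strat
  med <- tapply(per_tad$size, strat, stats::median)
  list(per_tad = per_tad,
       median_by_stratum = stats::setNames(as.numeric(med), names(med)),
       spearman = rho)
}
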