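## APBS construction, occupancy classification and occupancy summaries.

#' Factor-list presets
#'
#' Named presets for the architectural protein panels used in Drosophila
#' Kc167 cells: `"drosophila11"` is the full 11-factor APBS panel
#' (insulator proteins plus cohesin subunit Rad21, condensin II subunit
#' CAP-H2 and dTFIIIC220); `"combinatorial9"` is the 9-factor panel
#' (including Zw5) used to define combinatorially bound loci independently
#' of TFIIIC and the SMC complexes.
#'
#' @param preset One of `"drosophila11"`, `"combinatorial9"`.
#' @return Character vector of factor labels.
#' @export
apbs_factors <- function(preset = c("drosophila11", "combinatorial9")) {
  preset <- match.arg(preset)
  switch(preset,
    drosophila11 = c("dCTCF", "BEAF-32", "Su(Hw)", "CP190", "Mod(mdg4)",
                     "DREF", "Chromator", "L(3)mbt", "dTFIIIC220", "Rad21",
                     "CAP-H2"),
    combinatorial9 = c("dCTCF", "BEAF-32", "Su(Hw)", "CP190", "Mod(mdg4)",
                       "Zw5", "DREF", "Chromator", "L(3)mbt"))
}

#' Classify occupancy counts
#'
#' Maps the number of distinct bound factors k to the occupancy class used
#' throughout: low (1-3 proteins), medium (4-6), high (7 or more).
#'
#' @param k Integer vector of occupancy counts (>= 1).
#' @return Factor with levels `low < medium < high`.
#' @export
classify_occupancy <- function(k) {
  if (any(is.na(k)) || any(k < 1) || any(k != floor(k))) {
    stop("k must be integers >= 1")
  }
  cut(k, breaks = c(0, 3, 6, Inf), labels = c("low", "medium", "high"),
      ordered_result = TRUE)
}

#' Collapse occupancy segments into APBSs
#'
#' Maximal runs of directly adjacent (boundary-sharing) segments are merged
#' into one architectural protein binding site. The representative segment is
#' the one with the highest occupancy in the run (first on ties); the APBS
#' span is the union of the run, while factor set, occupancy k and center are
#' taken from the representative (e.g. an adjacent k = 4, 5, 4 run becomes a
#' single APBS with k = 5 centered on the middle segment). Any gap of
#' >= 1 bp separates APBSs.
#'
#' @param segments `GRanges` from [multi_intersect()].
#' @return A `GRanges` of APBSs with mcols: `k`, `class`, `factors`
#'   (comma-joined factor labels), `membership` (logical matrix), `center`
#'   (1-based bp midpoint of the representative segment), `rep_start`,
#'   `rep_end` (its 1-based span).
#' @export
collapse_segments <- function(segments) {
  memb <- GenomicRanges::mcols(segments)$membership
  k <- GenomicRanges::mcols(segments)$k
  if (is.null(memb) || is.null(k)) {
    stop("segments must carry membership and k (see multi_intersect)")
  }
  if (is.unsorted(GenomicRanges::order(segments))) {
    stop("segments must be sorted")
  }
  n <- length(segments)
  if (n == 0L) return(segments)
  if (n > 1L) {
    ov <- GenomicRanges::findOverlaps(segments, drop.self = TRUE)
    if (length(ov) > 0L) stop("segments must not overlap")
  }
  new_run <- c(TRUE,
               as.character(GenomicRanges::seqnames(segments))[-1L] !=
                 as.character(GenomicRanges::seqnames(segments))[-n] |
               GenomicRanges::start(segments)[-1L] !=
                 GenomicRanges::end(segments)[-n] + 1L)
  run <- cumsum(new_run)
  rep_idx <- vapply(split(seq_len(n), run),
                    function(ix) ix[which.max(k[ix])], integer(1))
  starts <- as.integer(tapply(GenomicRanges::start(segments), run, min))
  ends <- as.integer(tapply(GenomicRanges::end(segments), run, max))
  chrom <- as.character(GenomicRanges::seqnames(segments))[rep_idx]
  apbs <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(starts, ends),
    seqinfo = GenomeInfoDb::seqinfo(segments))
  rep_memb <- memb[rep_idx, , drop = FALSE]
  GenomicRanges::mcols(apbs)$k <- k[rep_idx]
  GenomicRanges::mcols(apbs)$class <- classify_occupancy(k[rep_idx])
  GenomicRanges::mcols(apbs)$factors <- apply(rep_memb, 1L, function(row) {
    paste(colnames(rep_memb)[row], collapse = ",")
  })
  GenomicRanges::mcols(apbs)$membership <- rep_memb
  GenomicRanges::mcols(apbs)$center <- as.integer(
    floor((GenomicRanges::start(segments)[rep_idx] - 1L +
             GenomicRanges::end(segments)[rep_idx]) / 2) + 1L)
  GenomicRanges::mcols(apbs)$rep_start <-
    GenomicRanges::start(segments)[rep_idx]
  GenomicRanges::mcols(apbs)$rep_end <- GenomicRanges::end(segments)[rep_idx]
  apbs
}

#' Anchor-centric occupancy (mESC/human style)
#'
#' For each anchor site (e.g. a CTCF peak), occupancy is 1 (the anchor
#' factor) plus the number of distinct partner groups with at least one peak
#' whose nearest edge lies within `radius` bp of the anchor center. Factors
#' belonging to the same group (subunits of one complex, e.g. TFIIIC-220/
#' -110/-90 or condensin CAP-H2/CAP-D3) count once: proximity to any subunit
#' suffices.
#'
#' @param anchors `GRanges` with centers (a `summit` mcol, else midpoints).
#' @param factor_sets Named list of `GRanges`, one per partner factor.
#' @param radius Center-to-nearest-edge distance in bp (default 500).
#' @param subunit_groups Optional named character vector mapping factor name
#'   to group label; unlisted factors form their own group.
#' @return Integer vector of per-anchor occupancies, with a `"groups"`
#'   attribute holding the per-anchor logical group-proximity matrix.
#' @export
anchor_occupancy <- function(anchors, factor_sets, radius = 500,
                             subunit_groups = NULL) {
  if (length(radius) != 1L || is.na(radius) || radius < 0) {
    stop("radius must be a single non-negative number")
  }
  centers <- GenomicRanges::mcols(anchors)$summit
  if (is.null(centers)) {
    centers <- floor((GenomicRanges::start(anchors) - 1L +
                        GenomicRanges::end(anchors)) / 2) + 1L
  }
  group_of <- names(factor_sets)
  names(group_of) <- names(factor_sets)
  if (!is.null(subunit_groups)) {
    group_of[names(subunit_groups)] <- subunit_groups
  }
  groups <- unique(unname(group_of))
  padded <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(anchors),
    IRanges::IRanges(pmax(centers - radius, 1L), centers + radius))
  hit <- vapply(groups, function(g) {
    members <- names(group_of)[group_of == g]
    pool <- suppressWarnings(unlist(
      methods::as(lapply(factor_sets[members], function(x) {
        GenomicRanges::mcols(x) <- NULL
        x
      }), "GRangesList"), use.names = FALSE))
    IRanges::overlapsAny(padded, pool, ignore.strand = TRUE)
  }, logical(length(anchors)))
  hit <- matrix(hit, nrow = length(anchors), dimnames = list(NULL, groups))
  occ <- 1L + as.integer(rowSums(hit))
  attr(occ, "groups") <- hit
  occ
}

#' Fraction of loci overlapping a peak set
#'
#' @param loci `GRanges` of query loci (e.g. combinatorially bound APBSs).
#' @param peaks `GRanges` of a factor's peaks.
#' @return List with `count` (loci with >= 1 bp overlap), `fraction` and
#'   `percent` (rounded to nearest integer).
#' @export
overlap_fraction <- function(loci, peaks) {
  if (length(loci) == 0L) stop("loci must be non-empty")
  count <- sum(IRanges::overlapsAny(loci, peaks, ignore.strand = TRUE))
  list(count = count,
       fraction = count / length(loci),
       percent = round(100 * count / length(loci)))
}

#' Co-binding overlap-frequency table
#'
#' For one or several locus sets, the fraction of loci in each set overlapped
#' by each factor's peaks. A factor scored against loci defined by its own
#' peaks gives 1.
#'
#' @param loci A `GRanges`, or a named list of `GRanges` (one row per set).
#' @param factor_sets Named list of `GRanges`, one per factor (columns).
#' @return Numeric matrix of overlap frequencies in \[0, 1\].
#' @export
cobinding_matrix <- function(loci, factor_sets) {
  if (!is.list(loci)) loci <- list(loci = loci)
  out <- t(vapply(loci, function(l) {
    if (length(l) == 0L) stop("locus sets must be non-empty")
    vapply(factor_sets,
           function(f) mean(IRanges::overlapsAny(l, f, ignore.strand = TRUE)),
           numeric(1))
  }, numeric(length(factor_sets))))
  dimnames(out) <- list(names(loci), names(factor_sets))
  out
}

#' Occupancy summaries over labeled regions
#'
#' Per region, occupancy is the maximum k over APBSs overlapping the region
#' (0 if none overlaps); groups (e.g. robust / context-dependent /
#' non-blocking enhancer-blocking calls) are summarised by n and mean
#' occupancy.
#'
#' @param regions `GRanges` with a `group` mcol labeling each region.
#' @param apbs `GRanges` of APBSs with a `k` mcol.
#' @return A `data.frame` with columns `group`, `n`, `mean_occupancy`
#'   (1 decimal), plus attribute `"per_region"` (a data.frame of per-region
#'   occupancies).
#' @export
region_occupancy_summary <- function(regions, apbs) {
  group <- GenomicRanges::mcols(regions)$group
  if (is.null(group) || anyNA(group)) {
    stop("every region needs a group label")
  }
  hits <- GenomicRanges::findOverlaps(regions, apbs, ignore.strand = TRUE)
  occ <- rep(0L, length(regions))
  if (length(hits) > 0L) {
    mx <- tapply(GenomicRanges::mcols(apbs)$k[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits), max)
    occ[as.integer(names(mx))] <- as.integer(mx)
  }
  per_region <- data.frame(group = as.character(group), occupancy = occ,
                           stringsAsFactors = FALSE)
  agg <- stats::aggregate(occupancy ~ group, per_region, function(v) {
    c(n = length(v), mean = mean(v))
  })
  out <- data.frame(group = agg$group,
                    n = as.integer(agg$occupancy[, "n"]),
                    mean_occupancy = round(agg$occupancy[, "mean"], 1),
                    stringsAsFactors = FALSE)
  attr(out, "per_region") <- per_region
  out
}

#' Write an APBS catalog as BED6 plus a locus-by-factor matrix
#'
#' @param apbs `GRanges` from [collapse_segments()].
#' @param bed_path Output BED path (name = factor set, score = k).
#' @param matrix_path Optional TSV path for the locus x factor boolean
#'   membership matrix.
#' @return `bed_path`, invisibly.
#' @export
write_apbs <- function(apbs, bed_path, matrix_path = NULL) {
  g <- apbs
  GenomicRanges::mcols(g) <- S4Vectors::DataFrame(
    name = GenomicRanges::mcols(apbs)$factors,
    score = GenomicRanges::mcols(apbs)$k)
  write_bed(g, bed_path)
  if (!is.null(matrix_path)) {
    memb <- GenomicRanges::mcols(apbs)$membership
    tab <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(apbs)),
      start = GenomicRanges::start(apbs) - 1L,
      end = GenomicRanges::end(apbs),
      occupancy = GenomicRanges::mcols(apbs)$k,
      class = as.character(GenomicRanges::mcols(apbs)$class),
      memb * 1L, check.names = FALSE)
    utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(bed_path)
}
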