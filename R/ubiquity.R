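## Multi-experiment site catalogs, ubiquity scoring/merging, ubiquity
## binning and TAD-border localization by ubiquity.

#' Build a composite site catalog across experiments
#'
#' Sites from all experiments are pooled per chromosome and clustered by
#' center distance: single-linkage at threshold `match_dist` (in 1D this
#' breaks clusters wherever the gap between consecutive centers exceeds the
#' threshold). Each cluster becomes one composite site whose center is the
#' mean of its member centers; its ubiquity u is the number of distinct
#' experiments contributing. Composites supported by only one experiment
#' fail to replicate and are discarded.
#'
#' @param site_lists Named list of `GRanges` (>= 2), one per experiment;
#'   centers come from a `summit` mcol when present, else midpoints.
#' @param match_dist Maximum center-to-center distance for clustering
#'   (default 200 bp).
#' @return A sorted `GRanges` of composite sites with mcols `u` (ubiquity),
#'   `experiments` (comma-joined contributing labels) and `center`.
#' @export
build_catalog <- function(site_lists, match_dist = 200) {
  if (!is.list(site_lists) || length(site_lists) < 2L) {
    stop("need at least 2 experiments")
  }
  if (is.null(names(site_lists))) stop("experiments must be named")
  pooled <- do.call(rbind, lapply(names(site_lists), function(lab) {
    g <- site_lists[[lab]]
    ctr <- GenomicRanges::mcols(g)$summit
    if (is.null(ctr)) {
      ctr <- floor((GenomicRanges::start(g) - 1L +
                      GenomicRanges::end(g)) / 2) + 1L
    }
    data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
               start = GenomicRanges::start(g), end = GenomicRanges::end(g),
               center = as.numeric(ctr), experiment = lab,
               stringsAsFactors = FALSE)
  }))
  comp <- lapply(split(pooled, pooled$chrom), function(d) {
    d <- d[order(d$center), ]
    cl <- cumsum(c(TRUE, diff(d$center) > match_dist))
    uq <- !duplicated(paste0(cl, "\r", d$experiment))
    exps <- vapply(split(d$experiment[uq], cl[uq]),
                   function(e) paste(sort(e), collapse = ","), "")
    data.frame(chrom = d$chrom[1L],
               start = as.integer(tapply(d$start, cl, min)),
               end = as.integer(tapply(d$end, cl, max)),
               center = floor(tapply(d$center, cl, mean)),
               u = as.integer(tabulate(cl[uq])),
               experiments = exps,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, comp)
  tab <- tab[tab$u >= 2L, , drop = FALSE]
  out <- GenomicRanges::GRanges(tab$chrom,
                                IRanges::IRanges(tab$start, tab$end),
                                u = as.integer(tab$u),
                                experiments = tab$experiments,
                                center = as.integer(tab$center))
  GenomicRanges::sort(out)
}

#' Absorb weak sites into nearby much more ubiquitous sites
#'
#' A site whose center lies strictly less than `max_dist` bp from a site
#' supported by strictly more than twice as many experiments is merged into
#' the more ubiquitous site (which keeps its coordinates and its u).
#' Candidates are processed in descending u (ties broken by leftmost
#' coordinate) and the rule is iterated to a fixed point.
#'
#' @param sites Catalog `GRanges` from [build_catalog()].
#' @param max_dist Center-to-center merge distance (default 1000 bp,
#'   exclusive).
#' @return The merged catalog (sorted `GRanges`).
#' @export
ubiquity_merge <- function(sites, max_dist = 1000) {
  tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(sites)),
                    start = GenomicRanges::start(sites),
                    end = GenomicRanges::end(sites),
                    center = as.numeric(GenomicRanges::mcols(sites)$center),
                    u = GenomicRanges::mcols(sites)$u,
                    experiments = GenomicRanges::mcols(sites)$experiments,
                    stringsAsFactors = FALSE)
  ## candidate absorptions (i absorbs j) found once via sorted neighbor
  ## search; u never changes, so a single descending-u cascade over live
  ## sites reaches the fixed point (absorbed sites can no longer absorb)
  n <- nrow(tab)
  absorbable <- vector("list", n)
  for (ch in unique(tab$chrom)) {
    idx <- which(tab$chrom == ch)
    idx <- idx[order(tab$center[idx])]
    ctr <- tab$center[idx]
    lo <- findInterval(ctr - max_dist, ctr) + 1L
    hi <- findInterval(ctr + max_dist - 0.5, ctr)
    for (a in seq_along(idx)) {
      if (hi[a] < lo[a]) next
      nb <- idx[lo[a]:hi[a]]
      nb <- nb[nb != idx[a] & tab$u[idx[a]] > 2L * tab$u[nb]]
      if (length(nb) > 0L) absorbable[[idx[a]]] <- nb
    }
  }
  live <- rep(TRUE, n)
  for (i in order(-tab$u, tab$chrom, tab$center)) {
    if (!live[i] || is.null(absorbable[[i]])) next
    live[absorbable[[i]]] <- FALSE
  }
  tab <- tab[live, , drop = FALSE]
  out <- GenomicRanges::GRanges(tab$chrom,
                                IRanges::IRanges(tab$start, tab$end),
                                u = as.integer(tab$u),
                                experiments = tab$experiments,
                                center = as.integer(tab$center))
  GenomicRanges::sort(out)
}

#' Bin catalog sites by ubiquity
#'
#' Sites are ordered by ascending ubiquity (cell-type-specific first,
#' constitutive last) and partitioned into `n_bins` bins of approximately
#' equal size whose boundaries never split a u level across bins. With fewer
#' distinct u levels than requested bins, fewer bins are returned with a
#' warning.
#'
#' @param sites Catalog `GRanges` with a `u` mcol.
#' @param n_bins Number of bins (default 8).
#' @return List of bins, each a list with `u_range` (c(min, max)), `n`, and
#'   `sites` (`GRanges` subset), ordered specific to constitutive.
#' @export
bin_by_ubiquity <- function(sites, n_bins = 8) {
  u <- GenomicRanges::mcols(sites)$u
  if (length(sites) < n_bins) stop("fewer sites than bins")
  levels_u <- sort(unique(u))
  counts <- as.integer(table(factor(u, levels = levels_u)))
  if (length(levels_u) < n_bins) {
    warning("only ", length(levels_u), " distinct ubiquity levels; ",
            "returning that many bins")
    n_bins <- length(levels_u)
  }
  ## greedy partition of whole u levels into n_bins roughly equal-count bins
  bin_of_level <- integer(length(levels_u))
  remaining_sites <- sum(counts)
  lev <- 1L
  for (b in seq_len(n_bins)) {
    remaining_bins <- n_bins - b + 1L
    target <- remaining_sites / remaining_bins
    taken <- 0L
    repeat {
      bin_of_level[lev] <- b
      taken <- taken + counts[lev]
      remaining_sites <- remaining_sites - counts[lev]
      lev <- lev + 1L
      levels_left <- length(levels_u) - lev + 1L
      if (lev > length(levels_u)) break
      if (levels_left < remaining_bins) break   # keep one level per bin
      ## stop when adding the next level overshoots the target more than
      ## stopping now undershoots it
      if (taken >= target ||
          abs(taken + counts[lev] - target) > abs(taken - target)) break
    }
    if (lev > length(levels_u)) break
  }
  n_bins_actual <- max(bin_of_level)
  lapply(seq_len(n_bins_actual), function(b) {
    lv <- levels_u[bin_of_level == b]
    sel <- u %in% lv
    list(u_range = range(lv), n = sum(sel), sites = sites[sel])
  })
}

#' TAD-border localization by ubiquity bin
#'
#' For each ubiquity bin, the observed fraction of sites whose center lies
#' within `window` bp (inclusive) of a TAD border is compared with the
#' fraction expected when the bin's sites are shuffled span-bounded (between
#' the first and the last catalog site on each chromosome), with ubiquity,
#' size and chromosome conserved. Reports per-bin observed, expected,
#' obs/exp ratio, and a one-sided empirical P value.
#'
#' @param bins List of bins from [bin_by_ubiquity()].
#' @param borders `data.frame` from [tad_borders()] (columns chrom, pos) or a
#'   `GRanges` of TADs.
#' @param window Border window in bp (default 20000, inclusive).
#' @param shuffles Number of shuffles for the expectation (default 100).
#' @param seed Integer seed.
#' @param span_sites Optional `GRanges` defining the per-chromosome placement
#'   spans (default: union of all bins' sites).
#' @return `data.frame` with one row per bin: `bin`, `u_min`, `u_max`, `n`,
#'   `observed`, `expected`, `obs_over_exp`, `p_value`, `p_less_than`.
#' @export
border_localization <- function(bins, borders, window = 20000,
                                shuffles = 100, seed = NULL,
                                span_sites = NULL) {
  if (inherits(borders, "GRanges")) borders <- tad_borders(borders)
  if (!is.null(seed)) set.seed(seed)
  border_pos <- split(borders$pos, borders$chrom)
  if (is.null(span_sites)) {
    span_sites <- suppressWarnings(unlist(methods::as(
      lapply(bins, `[[`, "sites"), "GRangesList"), use.names = FALSE))
  }
  sp_chrom <- as.character(GenomicRanges::seqnames(span_sites))
  spans <- lapply(split(seq_along(span_sites), sp_chrom), function(ix) {
    c(min(GenomicRanges::start(span_sites)[ix]) - 1,
      max(GenomicRanges::end(span_sites)[ix]))
  })
  at_border <- function(chrom, center0) {
    out <- logical(length(center0))
    for (ch in unique(chrom)) {
      bp <- border_pos[[ch]]
      if (is.null(bp)) next
      idx <- chrom == ch
      out[idx] <- colSums(abs(outer(bp, center0[idx], "-")) <= window) > 0
    }
    out
  }
  rows <- lapply(seq_along(bins), function(b) {
    s <- bins[[b]]$sites
    chrom <- as.character(GenomicRanges::seqnames(s))
    len <- GenomicRanges::width(s)
    center0 <- as.numeric(GenomicRanges::mcols(s)$center) - 1
    obs <- mean(at_border(chrom, center0))
    null <- vapply(seq_len(shuffles), function(r) {
      new0 <- numeric(length(s))
      for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        sp <- spans[[ch]]
        new0[idx] <- shuffle_starts(len[idx], sp[1L], sp[2L])
      }
      mean(at_border(chrom, new0 + floor(len / 2)))
    }, numeric(1))
    expd <- mean(null)
    r_ge <- sum(null >= obs)
    data.frame(bin = b, u_min = bins[[b]]$u_range[1L],
               u_max = bins[[b]]$u_range[2L], n = bins[[b]]$n,
               observed = obs, expected = expd,
               obs_over_exp = if (expd > 0) obs / expd else NA_real_,
               p_value = if (r_ge == 0L) 1 / shuffles else r_ge / shuffles,
               p_less_than = r_ge == 0L)
  })
  do.call(rbind, rows)
}

#' Write a ubiquity catalog as BED6 plus experiment membership TSV
#'
#' @param sites Catalog `GRanges`.
#' @param bed_path Output BED path (score = u).
#' @param membership_path Optional TSV of contributing experiment labels.
#' @return `bed_path`, invisibly.
#' @export
write_catalog <- function(sites, bed_path, membership_path = NULL) {
  g <- sites
  GenomicRanges::mcols(g) <- S4Vectors::DataFrame(
    name = paste0("u", GenomicRanges::mcols(sites)$u),
    score = GenomicRanges::mcols(sites)$u)
  write_bed(g, bed_path)
  if (!is.null(membership_path)) {
    utils::write.table(
      data.frame(chrom = as.character(GenomicRanges::seqnames(sites)),
                 start = GenomicRanges::start(sites) - 1L,
                 end = GenomicRanges::end(sites),
                 u = GenomicRanges::mcols(sites)$u,
                 experiments = GenomicRanges::mcols(sites)$experiments),
      membership_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(bed_path)
}
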