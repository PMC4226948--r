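## Chromosome-aware shuffling nulls, Monte Carlo permutation P values and
## observed/expected enrichment.

#' Shuffle interval start positions (vectorized core)
#'
#' Draws uniform start positions for intervals of the given lengths within
#' `[lo, hi)` (0-based), so each interval fits entirely inside the range.
#' This is the placement primitive behind [shuffle_sites()]; it is exported
#' so that statistics evaluated inside tight permutation loops can avoid
#' GRanges construction overhead.
#'
#' @param lengths Interval lengths in bp.
#' @param lo,hi Placement range (0-based half-open).
#' @return Numeric vector of new 0-based starts.
#' @export
shuffle_starts <- function(lengths, lo, hi) {
  room <- hi - lo - lengths
  if (any(room < 0)) {
    stop("an interval is longer than its placement range")
  }
  lo + floor(stats::runif(length(lengths)) * (room + 1))
}

#' Chromosome-aware random shuffling of sites
#'
#' Produces, per chromosome, the same number of sites with identical lengths
#' (and all metadata columns, e.g. ubiquity, carried along), placed uniformly
#' at random. In `"chrom_bounded"` mode sites land anywhere within the
#' chromosome; in `"span_bounded"` mode they land between the first start and
#' the last end of the original sites on that chromosome (the convention used
#' when shuffling a site catalog while conserving its extent). Sites never
#' cross chromosome ends; independent placements may overlap one another.
#'
#' Randomness comes from R's global RNG: set a seed (or pass `seed`) for
#' reproducibility.
#'
#' @param sites `GRanges` to shuffle.
#' @param genome A `Seqinfo` (required for `"chrom_bounded"` mode).
#' @param mode `"chrom_bounded"` or `"span_bounded"`.
#' @param seed Optional integer seed.
#' @return A `GRanges` of shuffled sites (sorted), metadata preserved.
#' @export
shuffle_sites <- function(sites, genome = NULL,
                          mode = c("chrom_bounded", "span_bounded"),
                          seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  chrom <- as.character(GenomicRanges::seqnames(sites))
  len <- GenomicRanges::width(sites)
  start0 <- GenomicRanges::start(sites) - 1
  end0 <- as.numeric(GenomicRanges::end(sites))
  new0 <- numeric(length(sites))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (mode == "chrom_bounded") {
      if (is.null(genome)) stop("chrom_bounded mode needs a genome")
      L <- GenomeInfoDb::seqlengths(genome)[[ch]]
      new0[idx] <- shuffle_starts(len[idx], 0, L)
    } else {
      new0[idx] <- shuffle_starts(len[idx], min(start0[idx]),
                                  max(end0[idx]))
    }
  }
  out <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(new0 + 1, width = len),
                                seqinfo = GenomeInfoDb::seqinfo(sites))
  GenomicRanges::mcols(out) <- GenomicRanges::mcols(sites)
  if (!is.null(GenomicRanges::mcols(out)$summit)) {
    GenomicRanges::mcols(out)$summit <- as.integer(
      floor((GenomicRanges::start(out) - 1L + GenomicRanges::end(out)) / 2)
      + 1L)
  }
  GenomicRanges::sort(out)
}

## assemble the standard result object shared by the permutation tests
make_enrichment_result <- function(observed, null, n, seed,
                                   keep_null = FALSE) {
  r <- sum(null >= observed)
  expected <- mean(null)
  res <- list(
    observed = observed,
    expected = expected,
    null_sd = stats::sd(null),
    log2_ratio = if (expected > 0 && observed > 0) {
      log2(observed / expected)
    } else NA_real_,
    log2_undefined = expected <= 0 || observed <= 0,
    p_value = if (r == 0L) 1 / n else r / n,
    p_less_than = r == 0L,
    n_exceed = r,
    n_perm = n,
    seed = seed)
  if (keep_null) res$null <- null
  structure(res, class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Monte Carlo permutation test (", x$n_perm, " permutations)\n",
      "  observed = ", format(x$observed),
      ", expected = ", format(x$expected), "\n",
      "  log2(obs/exp) = ",
      if (x$log2_undefined) "undefined" else format(round(x$log2_ratio, 3)),
      "\n  ", format_pvalue(x), "\n", sep = "")
  invisible(x)
}

#' Format an empirical P value in the "P < 1/n" convention
#'
#' Zero exceedances are reported as a bound, never as P = 0: with
#' n = 100000 permutations and no null draw reaching the observed value the
#' report reads `"P < 0.00001"`.
#'
#' @param x An `enrichment_result`.
#' @return Character scalar.
#' @export
format_pvalue <- function(x) {
  p <- format(x$p_value, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  if (x$p_less_than) paste0("P < ", p) else paste0("P = ", p)
}

#' Monte Carlo permutation test
#'
#' Draws `n` values of the test statistic under the null by calling
#' `statistic()` repeatedly (the callable performs its own shuffling, e.g.
#' via [shuffle_sites()] or [shuffle_starts()]), and reports the one-sided
#' empirical P value: the chance of a null draw greater than or equal to the
#' observed value. Zero exceedances are reported as `P < 1/n`.
#'
#' @param observed Observed value of the statistic.
#' @param statistic Zero-argument function returning one null draw.
#' @param n Number of permutations (default 1e5).
#' @param seed Integer seed (the global RNG is seeded once before the loop);
#'   identical seeds give identical results.
#' @param keep_null If `TRUE`, the null sample is stored in the result.
#' @return An `enrichment_result`.
#' @export
perm_test <- function(observed, statistic, n = 100000, seed = NULL,
                      keep_null = FALSE) {
  if (n < 1 || n != floor(n)) stop("n must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n), function(i) statistic(), numeric(1))
  make_enrichment_result(observed, null, n, seed, keep_null)
}

#' Label-permutation test
#'
#' Site positions stay fixed while their class labels are permuted uniformly;
#' the statistic is re-evaluated on each permuted labeling. One-sided
#' (greater or equal) by default; the two-sided option doubles the smaller
#' tail (capped at 1).
#'
#' @param labels Vector of class labels (>= 2 distinct classes).
#' @param statistic Function of a label vector returning a scalar.
#' @param n Number of permutations.
#' @param seed Integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param keep_null If `TRUE`, keep the null sample.
#' @return An `enrichment_result` (with the observed statistic evaluated on
#'   the original labels).
#' @export
label_perm_test <- function(labels, statistic, n = 10000, seed = NULL,
                            alternative = c("greater", "two.sided"),
                            keep_null = FALSE) {
  alternative <- match.arg(alternative)
  if (length(unique(labels)) < 2L) {
    stop("need at least 2 label classes to permute")
  }
  observed <- statistic(labels)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n), function(i) statistic(sample(labels)),
                 numeric(1))
  res <- make_enrichment_result(observed, null, n, seed, keep_null)
  if (alternative == "two.sided") {
    r_lo <- sum(null <= observed)
    p <- 2 * min(max(res$n_exceed, 1L), max(r_lo, 1L)) / n
    res$p_less_than <- min(res$n_exceed, r_lo) == 0L
    res$p_value <- min(p, 1)
  }
  res
}

#' Observed over expected enrichment
#'
#' @param observed Observed statistic.
#' @param null_sample Numeric vector of null draws (its mean is the expected
#'   value).
#' @return List with `log2` (log2(observed / mean(null)); `NA` and flagged
#'   `undefined` when the expected value or the observed value is 0),
#'   `expected`, and `direction` (`"enrichment"`, `"depletion"` or `"none"`).
#' @export
obs_over_exp <- function(observed, null_sample) {
  expected <- mean(null_sample)
  if (expected <= 0 || observed <= 0) {
    return(list(log2 = NA_real_, expected = expected, undefined = TRUE,
                direction = NA_character_))
  }
  l2 <- log2(observed / expected)
  list(log2 = l2, expected = expected, undefined = FALSE,
       direction = if (l2 > 0) "enrichment" else if (l2 < 0) "depletion"
                   else "none")
}

#' Write enrichment results as TSV
#'
#' @param results Named list of `enrichment_result`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(results, path) {
  tab <- do.call(rbind, lapply(names(results), function(nm) {
    x <- results[[nm]]
    data.frame(statistic = nm, observed = x$observed, expected = x$expected,
               log2_obs_exp = x$log2_ratio, p_value = x$p_value,
               p_less_than = x$p_less_than, n_perm = x$n_perm,
               seed = if (is.null(x$seed)) NA_integer_ else x$seed)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
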