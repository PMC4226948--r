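## Shared fixtures and independent brute-force oracles used across tests.

## quick GRanges constructor from 0-based half-open coordinates
gr0 <- function(chrom, start0, end0, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0), ...)
}

test_genome <- function(lens = c(chrA = 10000)) {
  genome_spec(names(lens), lens)
}

## per-base membership oracle: logical matrix [base, factor] for one
## chromosome of length L (bases indexed 1..L = 1-based positions)
per_base_membership <- function(peaksets, chrom, L) {
  vapply(peaksets, function(g) {
    covered <- logical(L)
    g <- g[as.character(GenomicRanges::seqnames(g)) == chrom]
    for (i in seq_along(g)) {
      covered[GenomicRanges::start(g)[i]:GenomicRanges::end(g)[i]] <- TRUE
    }
    covered
  }, logical(L))
}

## expand an occupancy segmentation back to per-base membership
segments_to_base_membership <- function(segs, chrom, L, factors) {
  memb <- matrix(FALSE, nrow = L, ncol = length(factors),
                 dimnames = list(NULL, factors))
  segs <- segs[as.character(GenomicRanges::seqnames(segs)) == chrom]
  m <- GenomicRanges::mcols(segs)$membership
  for (i in seq_along(segs)) {
    memb[GenomicRanges::start(segs)[i]:GenomicRanges::end(segs)[i], ] <-
      matrix(m[i, ], nrow = GenomicRanges::end(segs)[i] -
               GenomicRanges::start(segs)[i] + 1L,
             ncol = length(factors), byrow = TRUE)
  }
  memb
}

## random peak landscape on a single small chromosome
random_peaksets <- function(n_factors, max_peaks, L) {
  factors <- paste0("F", seq_len(n_factors))
  sets <- lapply(factors, function(f) {
    n <- sample.int(max_peaks, 1L)
    s0 <- sort(sample.int(L - 100L, n, replace = TRUE)) - 1L
    w <- sample(20:200, n, replace = TRUE)
    gr0("chrA", s0, pmin(s0 + w, L))
  })
  names(sets) <- factors
  sets
}

## dense brute-force local contrast at one cut site (pair enumeration)
brute_contrast <- function(mat, s, w, pseudocount = 1) {
  A <- (s - w):(s - 1L)
  B <- s:(s + w - 1L)
  intra <- 0
  for (set in list(A, B)) {
    for (a in seq_along(set)) {
      for (b in seq_along(set)) {
        if (a < b) intra <- intra + mat[set[a], set[b]]
      }
    }
  }
  inter <- 0
  for (a in A) for (b in B) inter <- inter + mat[a, b]
  (intra / (w * (w - 1))) / ((inter + pseudocount) / w^2)
}

## naive repeated-scan fixed-point oracle for ubiquity merging
naive_ubiquity_merge <- function(tab, max_dist = 1000) {
  repeat {
    ord <- order(-tab$u, tab$chrom, tab$center)
    absorbed <- rep(FALSE, nrow(tab))
    changed <- FALSE
    for (i in ord) {
      if (absorbed[i]) next
      near <- which(!absorbed & seq_len(nrow(tab)) != i &
                      tab$chrom == tab$chrom[i] &
                      abs(tab$center - tab$center[i]) < max_dist &
                      tab$u[i] > 2L * tab$u)
      if (length(near) > 0L) {
        absorbed[near] <- TRUE
        changed <- TRUE
      }
    }
    tab <- tab[!absorbed, , drop = FALSE]
    if (!changed) break
  }
  tab
}

## build a ubiquity catalog GRanges directly (for merge tests)
make_catalog <- function(chrom, center, u) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(center - 100, center + 100),
                         u = as.integer(u),
                         experiments = vapply(u, function(x) {
                           paste(paste0("e", seq_len(x)), collapse = ",")
                         }, ""),
                         center = as.integer(center))
}
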