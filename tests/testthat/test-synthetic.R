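classify_peaksets <- function(peaksets, halfwidth = 200) {
  windows <- lapply(peaksets, summit_windows, halfwidth = halfwidth)
  collapse_segments(multi_intersect(windows))
}

## match each truth locus to the nearest APBS center on its chromosome
match_apbs_k <- function(truth, apbs, max_dist = 500) {
  ctr <- GenomicRanges::mcols(apbs)$center
  chrom <- as.character(GenomicRanges::seqnames(apbs))
  vapply(seq_len(nrow(truth)), function(r) {
    sel <- which(chrom == truth$chrom[r])
    if (length(sel) == 0L) return(NA_integer_)
    d <- abs(ctr[sel] - truth$pos[r])
    if (min(d) > max_dist) return(NA_integer_)
    GenomicRanges::mcols(apbs)$k[sel[which.min(d)]]
  }, integer(1))
}

test_that("synth_config validates its parameters", {
  expect_error(synth_config(), "seed is mandatory")
  expect_error(synth_config(1, alpha = 0), "alpha")
  expect_error(synth_config(1, leakage = 0), "leakage")
  expect_error(synth_config(1, leakage = 1.5), "leakage")
  expect_error(synth_config(1, border_prob = c(-0.1, 0.9)), "border_prob")
  expect_error(synth_config(1, k_weights = c(1, 2)), "one per possible")
  expect_error(synth_config(1, drop_prob = 1), "drop_prob")
  cfg <- synth_config(7)
  expect_s3_class(cfg, "synth_config")
  expect_length(cfg$factors, 11)
  expect_length(cfg$leakage, cfg$n_borders)
})

test_that("generators are pure functions of the config seed", {
  a <- gen_factor_peaks(synth_config(3, n_loci = 50))
  b <- gen_factor_peaks(synth_config(3, n_loci = 50))
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$peaksets, GenomicRanges::start),
                   lapply(b$peaksets, GenomicRanges::start))
  c <- gen_factor_peaks(synth_config(4, n_loci = 50))
  expect_false(identical(a$truth$pos, c$truth$pos))
})

test_that("planted peak landscapes agree with their truth table", {
  cfg <- synth_config(2, n_loci = 60)
  sim <- gen_factor_peaks(cfg)
  tr <- sim$truth
  expect_equal(nrow(tr), 60)
  expect_true(all(tr$k >= 1 & tr$k <= length(cfg$factors)))
  flist <- strsplit(tr$factors, ",", fixed = TRUE)
  expect_equal(lengths(flist), tr$k)
  expect_true(all(unlist(flist) %in% cfg$factors))
  ## each factor listed at a locus has a summit nearby in its peakset
  for (r in sample(nrow(tr), 20)) {
    for (f in flist[[r]]) {
      pk <- sim$peaksets[[f]]
      sel <- as.character(GenomicRanges::seqnames(pk)) == tr$chrom[r]
      expect_true(min(abs(pk$summit[sel] - tr$pos[r])) < 500)
    }
  }
})

test_that("occupancy classification recovers planted k on a seeded replicate", {
  cfg <- synth_config(11)
  sim <- gen_factor_peaks(cfg)
  apbs <- classify_peaksets(sim$peaksets)
  k_hat <- match_apbs_k(sim$truth, apbs)
  recovered <- mean(!is.na(k_hat) & k_hat == sim$truth$k)
  expect_gte(recovered, 0.99)
})

test_that("contact maps respect their fragment map and domain truth", {
  cfg <- synth_config(5)
  sim <- gen_contact_map(cfg)
  nf <- unname(n_fragments(sim$fragmap))
  expect_equal(sim$contacts$chrH$n_frag, nf)
  ## domains tile the fragment space contiguously
  cuts <- sim$fragmap$cuts$chrH
  expect_equal(GenomicRanges::start(sim$tads)[1] - 1L, 0)
  expect_equal(GenomicRanges::end(sim$tads)[length(sim$tads)],
               cuts[length(cuts)])
  expect_equal(tad_borders(sim$tads)$pos, sim$truth$pos)
  expect_equal(nrow(sim$truth), cfg$n_borders)
  ## border cut positions sit on actual cut sites
  expect_true(all(sim$truth$pos %in% cuts))
})

test_that("border strength recovers planted border leakage", {
  cfg <- synth_config(42)
  sim <- gen_contact_map(cfg)
  sc <- local_contrast(sim$contacts, sim$fragmap, window_w = 10)
  expect_equal(median(sc$L), 1)
  at_border <- sc[match(sim$truth$cut_index, sc$cut_index), ]
  keep <- !is.na(at_border$L)
  rho <- stats::cor(-sim$truth$lambda[keep], at_border$L[keep],
                    method = "spearman")
  expect_gte(rho, 0.9)
  ## border cut sites score above the genome-wide median on average
  expect_gt(mean(at_border$L[keep]), 1)
})

test_that("noise-free tracks share rank structure across distortions", {
  cfg <- synth_config(6, n_loci = 40, track_noise_sd = 0)
  sim <- gen_tracks(cfg)
  flat <- vapply(sim$tracks, function(t) unlist(t$values, use.names = FALSE),
                 numeric(sum(lengths(sim$latent))))
  base_rank <- rank(flat[, 1])
  for (j in 2:ncol(flat)) {
    expect_equal(rank(flat[, j]), base_rank)
  }
  ## normalization then removes the monotone distortions entirely
  norm <- rank_order_normalize(sim$tracks)
  expect_equal(norm[[1]]$values, norm[[cfg$n_samples]]$values)
  ## bumps rise above the baseline at planted loci
  expect_gt(max(sim$latent[[1]]), 1)
})

test_that("cell-line catalogs reproduce planted ubiquity and placement", {
  cfg <- synth_config(9)
  sim <- gen_cell_line_catalogs(cfg)
  expect_length(sim$catalogs, cfg$n_experiments)
  tr <- sim$truth
  ## at-border flags agree with distances to the planted borders
  d_border <- vapply(seq_len(nrow(tr)), function(r) {
    bp <- sim$borders$pos[sim$borders$chrom == tr$chrom[r]]
    min(abs(bp - tr$center[r]))
  }, numeric(1))
  expect_true(all(d_border[tr$at_border] <= cfg$border_window))
  expect_true(all(d_border[!tr$at_border] > cfg$border_window - 1000))
  ## rebuilding the catalog recovers each site's u exactly (no dropout)
  cat0 <- build_catalog(sim$catalogs, match_dist = 200)
  ctr <- cat0$center
  chrom <- as.character(GenomicRanges::seqnames(cat0))
  planted <- tr[tr$u >= 2, ]
  u_hat <- vapply(seq_len(nrow(planted)), function(r) {
    sel <- which(chrom == planted$chrom[r] &
                   abs(ctr - planted$center[r]) < 500)
    if (length(sel) == 0L) return(NA_integer_)
    cat0$u[sel[1L]]
  }, integer(1))
  expect_gte(mean(!is.na(u_hat) & u_hat == planted$u), 0.99)
  ## ubiquity placement probability rises with u in truth
  lo <- mean(tr$at_border[tr$u <= 10])
  hi <- mean(tr$at_border[tr$u >= 53])
  expect_gt(hi, lo + 0.5)
})

test_that("site capacity limits are enforced", {
  expect_error(gen_cell_line_catalogs(synth_config(1, n_sites = 50000)),
               "too many sites")
  expect_error(gen_factor_peaks(synth_config(1, n_loci = 100000)),
               "density too high")
})

test_that("truth tables round-trip as TSV", {
  sim <- gen_factor_peaks(synth_config(8, n_loci = 20))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_truth_tsv(sim$truth, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_equal(back$pos, sim$truth$pos)
  expect_equal(back$factors, sim$truth$factors)
})
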