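test_that("build_catalog clusters by center distance and counts experiments", {
  e1 <- gr0("chrA", c(1000, 5000), c(1400, 5400),
            summit = c(1201L, 5201L))
  e2 <- gr0("chrA", c(1100, 9000), c(1500, 9400),
            summit = c(1301L, 9201L))
  cat0 <- build_catalog(list(a = e1, b = e2), match_dist = 200)
  ## only the 1200/1300 pair replicates; u = 1 composites are discarded
  expect_length(cat0, 1)
  expect_equal(cat0$u, 2L)
  expect_equal(cat0$center, 1251L)   # floor(mean(1201, 1301)), 1-based
  expect_equal(cat0$experiments, "a,b")

  ## two peaks of the same experiment in one cluster count once
  e3 <- gr0("chrA", c(1000, 1050), c(1400, 1450),
            summit = c(1201L, 1251L))
  cat1 <- build_catalog(list(a = e3, b = e2), match_dist = 200)
  expect_equal(cat1$u[1], 2L)

  expect_error(build_catalog(list(a = e1)), "at least 2")
  expect_error(build_catalog(list(e1, e2)), "named")
})

test_that("catalog clustering is single-linkage through chained centers", {
  ## centers 1000, 1150, 1300: adjacent gaps 150 <= 200 chain into one
  ## composite although the extremes are 300 apart
  e1 <- gr0("chrA", 900, 1100, summit = 1001L)
  e2 <- gr0("chrA", 1050, 1250, summit = 1151L)
  e3 <- gr0("chrA", 1200, 1400, summit = 1301L)
  cat0 <- build_catalog(list(a = e1, b = e2, c = e3), match_dist = 200)
  expect_length(cat0, 1)
  expect_equal(cat0$u, 3L)
})

test_that("ubiquity merging enforces strict distance and strict 2x rules", {
  ## u = 10 absorbs u = 4 at 900 bp (900 < 1000 and 10 > 8)
  m <- ubiquity_merge(make_catalog("chrA", c(10000, 10900), c(4, 10)))
  expect_equal(m$u, 10L)
  ## 1200 bp apart: too far
  m2 <- ubiquity_merge(make_catalog("chrA", c(10000, 11200), c(4, 10)))
  expect_equal(sort(m2$u), c(4L, 10L))
  ## exactly twice as ubiquitous is not enough (strict >)
  m3 <- ubiquity_merge(make_catalog("chrA", c(10000, 10900), c(4, 8)))
  expect_equal(sort(m3$u), c(4L, 8L))
  ## exactly max_dist apart is not merged (strict <)
  m4 <- ubiquity_merge(make_catalog("chrA", c(10000, 11000), c(4, 10)))
  expect_equal(sort(m4$u), c(4L, 10L))
})

test_that("merging cascades in descending ubiquity order", {
  ## u20 at 10000 absorbs u9 at 10900; the absorbed u9 can no longer
  ## absorb u4 at 11800, and u20 is too far from u4 -> u4 survives
  m <- ubiquity_merge(make_catalog("chrA", c(10000, 10900, 11800),
                                   c(20, 9, 4)))
  expect_equal(sort(m$u), c(4L, 20L))
  expect_equal(m$center[m$u == 20L], 10000L)
})

test_that("merging matches the naive repeated-scan oracle", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    tab <- data.frame(chrom = sample(c("chrA", "chrB"), n, replace = TRUE),
                      center = sample(1000:50000, n),
                      u = sample(2:62, n, replace = TRUE))
    tab <- tab[!duplicated(paste(tab$chrom, tab$center)), ]
    got <- ubiquity_merge(make_catalog(tab$chrom, tab$center, tab$u))
    got_tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(got)),
                          center = got$center, u = got$u)
    got_tab <- got_tab[order(got_tab$chrom, got_tab$center), ]
    want <- naive_ubiquity_merge(tab)
    want <- want[order(want$chrom, want$center), ]
    expect_equal(got_tab$chrom, want$chrom)
    expect_equal(got_tab$center, as.integer(want$center))
    expect_equal(got_tab$u, as.integer(want$u))
  }
})

test_that("ubiquity bins keep u levels whole and sizes balanced", {
  set.seed(5)
  u <- sample(2:62, 3000, replace = TRUE)
  sites <- make_catalog("chrA", seq(1000, by = 500,
                                    length.out = length(u)), u)
  bins <- bin_by_ubiquity(sites, n_bins = 8)
  expect_length(bins, 8)
  expect_equal(sum(vapply(bins, `[[`, 0L, "n")), length(u))
  ranges <- t(vapply(bins, `[[`, numeric(2), "u_range"))
  ## ascending, non-overlapping u ranges: no level is split across bins
  expect_true(all(ranges[-1, 1] > ranges[-nrow(ranges), 2]))
  ## roughly equal sizes (within a factor of the largest level count)
  ns <- vapply(bins, `[[`, 0L, "n")
  expect_lt(max(ns) / min(ns), 2.5)
  ## every site's u falls inside its bin's range
  for (b in bins) {
    expect_true(all(b$sites$u >= b$u_range[1] & b$sites$u <= b$u_range[2]))
  }
})

test_that("binning degrades gracefully with few u levels", {
  sites <- make_catalog("chrA", seq(1000, by = 500, length.out = 40),
                        rep(c(2, 5, 9), length.out = 40))
  expect_warning(bins <- bin_by_ubiquity(sites, n_bins = 8), "3 distinct")
  expect_length(bins, 3)
  expect_error(bin_by_ubiquity(sites[1:3], n_bins = 8), "fewer sites")
})

test_that("border localization contrasts observed and shuffled fractions", {
  borders <- data.frame(chrom = "chrA", pos = 50000)
  near <- make_catalog("chrA", seq(35000, 65000, length.out = 30),
                       rep(40, 30))
  far <- make_catalog("chrA", seq(80000, 99000, length.out = 30),
                      rep(3, 30))
  span <- make_catalog("chrA", c(1000, 99500), c(2, 2))
  bins <- list(list(u_range = c(3, 3), n = 30, sites = far),
               list(u_range = c(40, 40), n = 30, sites = near))
  loc <- border_localization(bins, borders, window = 20000, shuffles = 50,
                             seed = 2, span_sites = span)
  expect_equal(loc$observed, c(0, 1))
  ## the all-at-border bin is enriched beyond any shuffle
  expect_gt(loc$obs_over_exp[2], 1)
  expect_true(loc$p_less_than[2])
  expect_equal(loc$p_value[2], 1 / 50)
  ## the far bin is never at a border
  expect_equal(loc$obs_over_exp[1], 0)
  ## TAD GRanges are accepted in place of a border table
  tads <- gr0("chrA", c(0, 50000), c(50000, 100000))
  loc2 <- border_localization(bins, tads, window = 20000, shuffles = 50,
                              seed = 2, span_sites = span)
  expect_equal(loc2$observed, loc$observed)
})

test_that("a seeded synthetic replicate recovers the planted ubiquity trend", {
  cfg <- synth_config(seed = 1001)
  cc <- gen_cell_line_catalogs(cfg)
  cat0 <- build_catalog(cc$catalogs, match_dist = 200)
  ## planted sites are well separated, so clustering recovers ~n_sites
  expect_gt(length(cat0), 0.95 * cfg$n_sites)
  merged <- ubiquity_merge(cat0, max_dist = 1000)
  bins <- bin_by_ubiquity(merged, n_bins = 8)
  loc <- border_localization(bins, cc$borders, window = 20000,
                             shuffles = 100, seed = 1)
  expect_false(is.unsorted(loc$obs_over_exp, strictly = TRUE))
  expect_gt(loc$obs_over_exp[8] / loc$obs_over_exp[1], 2)
})

test_that("catalogs export as BED plus membership", {
  sites <- make_catalog("chrA", c(5000, 9000), c(3, 12))
  bed <- withr::local_tempfile(fileext = ".bed")
  mem <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(sites, bed, mem)
  lines <- readLines(bed)
  expect_length(lines, 2)
  expect_match(lines[2], "\tu12\t12\t")
  tab <- utils::read.table(mem, header = TRUE, sep = "\t")
  expect_equal(tab$u, c(3, 12))
})
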