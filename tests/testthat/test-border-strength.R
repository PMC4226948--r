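random_contacts <- function(chrom, n_frag, density = 0.5, lambda = 4) {
  pairs <- which(upper.tri(matrix(0, n_frag, n_frag), diag = TRUE),
                 arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < density
  pairs <- pairs[keep, , drop = FALSE]
  contact_matrix(chrom, pairs[, 1], pairs[, 2],
                 stats::rpois(nrow(pairs), lambda), n_frag)
}

test_that("fragment maps validate cut sites and count fragments", {
  fm <- fragment_map(list(chr1 = c(0, 100, 250, 400), chr2 = c(0, 50)))
  expect_s3_class(fm, "fragment_map")
  expect_equal(unname(n_fragments(fm)), c(3L, 1L))
  expect_error(fragment_map(list(chr1 = 5)), "strictly increasing")
  expect_error(fragment_map(list(chr1 = c(0, 100, 100))),
               "strictly increasing")
  expect_error(fragment_map(list(c(0, 100))), "named")
  expect_output(print(fm), "4 fragments")
})

test_that("fragment BED reading enforces contiguous tiling", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t100\t250", "chr2\t0\t80"), f)
  fm <- read_fragments_bed(f)
  expect_equal(fm$cuts$chr1, c(0, 100, 250))
  expect_equal(fm$cuts$chr2, c(0, 80))
  writeLines(c("chr1\t0\t100", "chr1\t120\t250"), f)
  expect_error(read_fragments_bed(f), "tile")
})

test_that("contact matrices symmetrize and round-trip through TSV", {
  cm <- contact_matrix("chr1", c(1, 2, 3), c(2, 3, 3), c(5, 7, 2), 4)
  expect_equal(cm$matrix[1, 2], cm$matrix[2, 1])
  expect_equal(cm$matrix[2, 3], 7)
  expect_equal(cm$matrix[3, 3], 2)  # diagonal kept single, not doubled
  expect_error(contact_matrix("chr1", 1, 5, 1, 4), "out of range")
  expect_error(contact_matrix("chr1", 1, 2, -1, 4), ">= 0")

  fm <- fragment_map(list(chr1 = c(0, 10, 20, 30, 40)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_contacts_tsv(cm, f)
  back <- read_contacts_tsv(f, fm)
  expect_equal(as.matrix(back$chr1$matrix), as.matrix(cm$matrix))
})

test_that("local contrast matches a hand-computed two-window case", {
  ## F = 4, w = 2, single interior site s = 3 (A = {1,2}, B = {3,4}):
  ## intra = 4 + 6 = 10 over w(w-1) = 2 pairs; inter = 4 over w^2 = 4 pairs
  ## L_raw = (10/2) / ((4+1)/4) = 4
  cm <- contact_matrix("chr1", c(1, 3, 1, 1, 2, 2), c(2, 4, 3, 4, 3, 4),
                       c(4, 6, 1, 1, 1, 1), 4)
  fm <- fragment_map(list(chr1 = c(0, 10, 20, 30, 40)))
  sc <- local_contrast(cm, fm, window_w = 2, pseudocount = 1)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$cut_index, 3)
  expect_equal(sc$cut_bp, 20)
  expect_equal(sc$L_raw, 4)
  expect_equal(sc$L, 1)   # single site: median centering gives exactly 1
})

test_that("local contrast equals the brute-force pair enumeration", {
  set.seed(5)
  for (w in c(2, 5, 10)) {
    n_frag <- 2 * w + 12
    cm <- random_contacts("chr1", n_frag)
    fm <- fragment_map(list(chr1 = seq(0, n_frag * 100, by = 100)))
    sc <- local_contrast(cm, fm, window_w = w, pseudocount = 1)
    expect_equal(sc$cut_index, (w + 1):(n_frag - w + 1))
    dense <- as.matrix(cm$matrix)
    brute <- vapply(sc$cut_index, function(s) brute_contrast(dense, s, w, 1),
                    numeric(1))
    expect_equal(sc$L_raw, brute)
    expect_equal(median(sc$L), 1)
  }
})

test_that("local contrast handles minimal, short and degenerate inputs", {
  ## exactly 2w fragments: a single scorable cut site survives
  cm <- random_contacts("chr1", 10)
  fm <- fragment_map(list(chr1 = seq(0, 1000, by = 100)))
  sc <- local_contrast(cm, fm, window_w = 5)
  expect_equal(nrow(sc), 1)

  ## too-short chromosomes are skipped with a message, all-short errors
  fm2 <- fragment_map(list(chr1 = seq(0, 1000, by = 100),
                           chr2 = c(0, 100, 200)))
  cm2 <- list(chr1 = cm, chr2 = random_contacts("chr2", 2))
  expect_message(sc2 <- local_contrast(cm2, fm2, window_w = 5), "skipping")
  expect_equal(unique(sc2$chrom), "chr1")
  expect_error(suppressMessages(
    local_contrast(cm2["chr2"], fm2, window_w = 5)), "no scorable")

  zero <- contact_matrix("chr1", 1, 2, 0, 10)
  expect_error(local_contrast(zero, fm, window_w = 5), "degenerate")
  expect_error(local_contrast(cm, fm, window_w = 1), ">= 2")
})

test_that("per-side window width is honored across the allowed range", {
  set.seed(9)
  n_frag <- 52
  cm <- random_contacts("chr1", n_frag)
  fm <- fragment_map(list(chr1 = seq(0, n_frag * 50, by = 50)))
  for (w in c(5, 12, 20)) {
    sc <- local_contrast(cm, fm, window_w = w)
    expect_equal(nrow(sc), n_frag - 2 * w + 1)
    expect_equal(median(sc$L), 1)
  }
})

test_that("tad_borders returns interior boundaries only", {
  tads <- gr0(c("chr1", "chr1", "chr1", "chr2"),
              c(0, 1000, 2500, 0), c(1000, 2500, 4000, 900))
  b <- tad_borders(tads)
  expect_equal(b$chrom, c("chr1", "chr1"))
  expect_equal(b$pos, c(1000, 2500))
  ## a single domain on a chromosome has no interior border
  empty <- tad_borders(gr0("chr3", 0, 500))
  expect_equal(nrow(empty), 0)
})

test_that("delineate_borders classifies by highest class in the window", {
  fm <- fragment_map(list(chr1 = seq(0, 4000, by = 200)))
  tads <- gr0(c("chr1", "chr1", "chr1"), c(0, 1000, 3000), c(1000, 3000, 4000))
  ## borders at 1000 and 3000; one_cut_site window = [800, 1200) / [2800, 3200)
  apbs <- gr0("chr1", c(850, 1150, 2000), c(900, 1190, 2050),
              k = c(2L, 7L, 9L))
  apbs$class <- classify_occupancy(apbs$k)
  res <- delineate_borders(tads, apbs, fm)
  expect_equal(as.character(res$borders$class), c("high", "none"))
  expect_equal(sum(res$percentages), 100)
  expect_equal(unname(res$percentages["high"]), 50)
  expect_equal(unname(res$percentages["none"]), 50)

  ## bp mode: widen the window until the k = 9 APBS reaches border 2
  res2 <- delineate_borders(tads, apbs, window = 1000)
  expect_equal(as.character(res2$borders$class), c("high", "high"))
  expect_error(delineate_borders(tads, apbs, window = -5), "positive")
  expect_error(delineate_borders(tads, apbs, window = "one_cut_site"),
               "fragment map")
})

test_that("strength_by_occupancy assigns nearest scored cut sites", {
  scores <- data.frame(chrom = "chr1", cut_index = 2:4,
                       cut_bp = c(1000, 2000, 3000),
                       L_raw = c(2, 4, 8), L = c(0.5, 1, 2))
  apbs <- gr0("chr1", c(1090, 2940, 500000), c(1110, 2960, 500100),
              k = c(3L, 8L, 5L))
  apbs$class <- classify_occupancy(apbs$k)
  apbs$center <- c(1101L, 2951L, 500051L)
  res <- strength_by_occupancy(apbs, scores, max_dist = 10000)
  expect_equal(res$n_dropped, 1)
  expect_equal(res$by_k$group, c(3L, 8L))
  expect_equal(res$by_k$mean_L, c(0.5, 2))  # nearest cuts: 1000 and 3000
  expect_equal(as.character(res$by_class$group), c("low", "high"))
})

test_that("tad_size_by_apbs stratifies sizes by border APBS density", {
  ## small TADs flanked by many APBSs, large TADs by none
  tads <- gr0("chr1", c(0, 1000, 2000, 3000, 13000, 23000),
              c(1000, 2000, 3000, 13000, 23000, 33000))
  dense_centers <- as.integer(c(995, 1005, 1995, 2005, 2995))
  apbs <- gr0("chr1", dense_centers - 11L, dense_centers + 10L,
              k = rep(8L, 5), center = dense_centers)
  res <- tad_size_by_apbs(tads, apbs, density_radius = 500)
  expect_equal(res$per_tad$size,
               c(1000, 1000, 1000, 10000, 10000, 10000))
  expect_true(all(res$per_tad$apbs_density[1:3] > 0))
  expect_equal(res$per_tad$apbs_density[5:6], c(0L, 0L))
  expect_lt(res$spearman, 0)
  expect_equal(res$per_tad$max_border_k[1], 8L)

  ## uniform density: single stratum, rho defined as 0
  res0 <- tad_size_by_apbs(tads, apbs[0], density_radius = 500)
  expect_equal(res0$spearman, 0)
  expect_error(tad_size_by_apbs(tads[1], apbs), "at least 2")
})
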