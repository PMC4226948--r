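## Seeded synthetic-data generators with planted ground truth.
##
## Each generator is a pure function of its configuration: it seeds R's RNG
## from cfg$seed (plus a fixed per-generator offset so the four generators
## draw independent streams) and returns both the simulated inputs and a
## truth table sufficient to score recovery without re-reading the config.

#' Configuration for the synthetic-data generators
#'
#' Defaults emulate a desk-scale version of the data the pipeline consumes:
#' a two-chromosome genome carrying clustered co-binding of up to 11
#' architectural proteins, a restriction-fragment Hi-C map with 20 TAD
#' borders of tunable leakage, multi-sample coverage tracks sharing rank
#' structure, and a multi-experiment CTCF-style site compendium (62
#' experiments, as in large ENCODE-scale catalogs) with a planted
#' specific-to-constitutive ubiquity axis.
#'
#' @param seed Mandatory integer seed.
#' @param genome Named vector of chromosome lengths (bp).
#' @param factors Factor labels for peak simulation.
#' @param n_loci Number of planted co-binding loci.
#' @param k_weights Occupancy distribution over k = 1..length(factors);
#'   default geometric decay (most loci low occupancy).
#' @param jitter_sd Gaussian summit jitter sd in bp (default 50).
#' @param peak_halfwidth Range of simulated raw peak half-widths in bp.
#' @param background_rate Background peaks per bp per factor (default 5e-7).
#' @param min_gap Minimum distance between planted loci in bp.
#' @param n_borders Number of TAD borders in the contact map (default 20).
#' @param domain_frags Mean fragments per domain (default 20).
#' @param fragment_len Range of restriction fragment lengths in bp.
#' @param leakage Per-border leakage lambda in (0, 1]; recycled to
#'   `n_borders`. Lower lambda = stronger border.
#' @param amplitude Contact amplitude A at distance 0 (default 100).
#' @param alpha Distance-decay exponent (> 0, default 1).
#' @param noise Count noise: `"poisson"` (default) or `"nbinom"`.
#' @param nb_size Negative-binomial size when `noise = "nbinom"`.
#' @param n_samples Number of coverage tracks (default 5).
#' @param bin_width Track bin width in bp (default 100).
#' @param track_noise_sd Per-sample additive noise sd (default 0.1).
#' @param distortion_gamma Per-sample monotone distortion exponents; default
#'   `seq(0.7, 1.3, length.out = n_samples)`.
#' @param signal_amplitude Peak height of the latent track signal.
#' @param n_experiments Number of cell-line experiments (default 62).
#' @param n_sites Number of planted catalog sites (default 3000).
#' @param border_prob Border-placement probability at ubiquity 1 and at
#'   ubiquity `n_experiments` (linear in between); default c(0.1, 0.9).
#' @param site_jitter_sd Per-experiment center jitter sd in bp (default 30).
#' @param drop_prob Probability that a supporting experiment drops a site
#'   (replicate noise; default 0).
#' @param catalog_n_borders Number of synthetic TAD borders for the catalog
#'   genome (default 100).
#' @param border_window Border window used when planting at-border sites
#'   (default 20000 bp).
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed,
                         genome = c(chrS1 = 1e7, chrS2 = 1e7),
                         factors = apbs_factors("drosophila11"),
                         n_loci = 400,
                         k_weights = NULL,
                         jitter_sd = 50,
                         peak_halfwidth = c(150, 350),
                         background_rate = 5e-7,
                         min_gap = 5000,
                         n_borders = 20,
                         domain_frags = 20,
                         fragment_len = c(1000, 3000),
                         leakage = rep_len(seq(0.1, 0.9, by = 0.1), 20),
                         amplitude = 100,
                         alpha = 1,
                         noise = c("poisson", "nbinom"),
                         nb_size = 10,
                         n_samples = 5,
                         bin_width = 100,
                         track_noise_sd = 0.1,
                         distortion_gamma = NULL,
                         signal_amplitude = 10,
                         n_experiments = 62,
                         n_sites = 3000,
                         border_prob = c(0.1, 0.9),
                         site_jitter_sd = 30,
                         drop_prob = 0,
                         catalog_n_borders = 100,
                         border_window = 20000) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("seed is mandatory")
  }
  noise <- match.arg(noise)
  if (is.null(k_weights)) {
    k_weights <- 0.7 ^ (seq_along(factors) - 1)
  }
  if (length(k_weights) != length(factors) || any(k_weights < 0)) {
    stop("k_weights must be non-negative, one per possible occupancy")
  }
  if (is.null(distortion_gamma)) {
    distortion_gamma <- seq(0.7, 1.3, length.out = n_samples)
  }
  if (alpha <= 0) stop("alpha must be > 0")
  leakage <- rep_len(leakage, n_borders)
  if (any(leakage <= 0 | leakage > 1)) stop("leakage must lie in (0, 1]")
  if (any(border_prob < 0 | border_prob > 1)) {
    stop("border_prob must lie in [0, 1]")
  }
  if (drop_prob < 0 || drop_prob >= 1) stop("drop_prob must lie in [0, 1)")
  structure(as.list(environment()), class = "synth_config")
}

## truncated Gaussian jitter keeping positions inside [1, len]
trunc_jitter <- function(pos, sd, len) {
  if (sd == 0) return(pos)
  pmin(pmax(pos + round(stats::rnorm(length(pos), 0, sd)), 1), len)
}

## sample n well-separated positions on a chromosome (grid + uniform offset)
spaced_positions <- function(n, len, min_gap) {
  slots <- floor((len - min_gap) / min_gap)
  if (n > slots) {
    stop("locus density too high: ", n, " loci need more than ", len,
         " bp at min_gap ", min_gap)
  }
  grid <- sort(sample.int(slots, n)) * min_gap
  grid + floor(stats::runif(n, 0, min_gap / 4))
}

#' Simulate clustered multi-factor peak landscapes
#'
#' Plants `n_loci` co-binding loci; each locus draws an occupancy k from the
#' configured distribution and places one jittered summit per chosen factor.
#' Independent background peaks are added per factor at `background_rate`.
#'
#' @param cfg A `synth_config`.
#' @return List with `peaksets` (named list of `GRanges` with summits, one
#'   per factor), `genome` (`Seqinfo`), and `truth` (data.frame: locus,
#'   chrom, pos, k, factors).
#' @export
gen_factor_peaks <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  genome <- genome_spec(names(cfg$genome), cfg$genome)
  n_chrom <- length(cfg$genome)
  per_chrom <- diff(round(seq(0, cfg$n_loci,
                              length.out = n_chrom + 1L)))
  truth <- NULL
  rows <- list()
  for (ci in seq_len(n_chrom)) {
    ch <- names(cfg$genome)[ci]
    len <- cfg$genome[[ci]]
    pos <- spaced_positions(per_chrom[ci], len, cfg$min_gap)
    k <- sample(seq_along(cfg$factors), per_chrom[ci], replace = TRUE,
                prob = cfg$k_weights)
    fsets <- lapply(k, function(kk) sample(cfg$factors, kk))
    rows[[ci]] <- data.frame(
      chrom = ch, pos = pos, k = k,
      factors = vapply(fsets, paste, "", collapse = ","),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  truth$locus <- seq_len(nrow(truth))
  peak_rows <- lapply(cfg$factors, function(f) {
    sel <- grepl(f, truth$factors, fixed = TRUE) &
      vapply(strsplit(truth$factors, ",", fixed = TRUE),
             function(v) f %in% v, logical(1))
    d <- truth[sel, , drop = FALSE]
    if (nrow(d) > 0L) {
      lens <- cfg$genome[d$chrom]
      summit <- trunc_jitter(d$pos, cfg$jitter_sd, lens)
    } else {
      summit <- integer(0)
    }
    chrom <- d$chrom
    ## background peaks, uniform per chromosome
    for (ci in seq_along(cfg$genome)) {
      nb <- stats::rpois(1L, cfg$background_rate * cfg$genome[[ci]])
      if (nb > 0L) {
        chrom <- c(chrom, rep(names(cfg$genome)[ci], nb))
        summit <- c(summit,
                    floor(stats::runif(nb, cfg$min_gap,
                                       cfg$genome[[ci]] - cfg$min_gap)))
      }
    }
    if (length(summit) == 0L) {
      return(GenomicRanges::GRanges(seqinfo = genome))
    }
    hw <- floor(stats::runif(length(summit), cfg$peak_halfwidth[1L],
                             cfg$peak_halfwidth[2L]))
    lens <- cfg$genome[chrom]
    gr <- GenomicRanges::GRanges(
      chrom,
      IRanges::IRanges(pmax(summit - hw + 1, 1), pmin(summit + hw, lens)),
      summit = as.integer(summit))
    gr <- set_genome(gr, genome)
    GenomicRanges::sort(gr)
  })
  names(peak_rows) <- cfg$factors
  list(peaksets = peak_rows, genome = genome,
       truth = truth[, c("locus", "chrom", "pos", "k", "factors")])
}

#' Simulate a distance-decay Hi-C contact map with leaky TAD borders
#'
#' Builds one synthetic chromosome of restriction fragments grouped into
#' domains; the expected count between fragments i < j is
#' `A * (d + 1)^(-alpha) * prod(lambda_b)` over the borders crossed, with
#' Poisson (or negative-binomial) noise. Lambda close to 0 means an
#' almost impermeable (strong) border; lambda = 1 means no border at all.
#'
#' @param cfg A `synth_config`.
#' @return List with `contacts` (named list with one `contact_matrix`),
#'   `fragmap`, `tads` (`GRanges`), and `truth` (data.frame: border,
#'   cut_index, pos, lambda).
#' @export
gen_contact_map <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 1L)
  n_dom <- cfg$n_borders + 1L
  dom_sizes <- pmax(stats::rpois(n_dom, cfg$domain_frags), 5L)
  f_total <- sum(dom_sizes)
  frag_len <- floor(stats::runif(f_total, cfg$fragment_len[1L],
                                 cfg$fragment_len[2L]))
  cuts <- c(0, cumsum(frag_len))
  fragmap <- fragment_map(list(chrH = cuts))
  dom_of <- rep(seq_len(n_dom), dom_sizes)
  lambda <- rep_len(cfg$leakage, cfg$n_borders)
  ## cumulative log-attenuation of the borders left of each fragment
  slog <- c(0, cumsum(log(lambda)))[dom_of]
  ij <- which(upper.tri(matrix(0, f_total, f_total)), arr.ind = TRUE)
  d <- ij[, 2L] - ij[, 1L]
  mu <- cfg$amplitude * (d + 1) ^ (-cfg$alpha) *
    exp(slog[ij[, 2L]] - slog[ij[, 1L]])
  counts <- if (cfg$noise == "poisson") {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), size = cfg$nb_size, mu = mu)
  }
  nz <- counts > 0
  cm <- contact_matrix("chrH", ij[nz, 1L], ij[nz, 2L], counts[nz], f_total)
  dom_end_frag <- cumsum(dom_sizes)
  dom_start_frag <- c(1L, dom_end_frag[-n_dom] + 1L)
  tads <- GenomicRanges::GRanges(
    "chrH", IRanges::IRanges(cuts[dom_start_frag] + 1,
                             cuts[dom_end_frag + 1L]))
  border_cut <- dom_end_frag[-n_dom] + 1L  # cut index separating domains
  truth <- data.frame(border = seq_len(cfg$n_borders),
                      cut_index = border_cut,
                      pos = cuts[border_cut],
                      lambda = lambda)
  list(contacts = list(chrH = cm), fragmap = fragmap, tads = tads,
       truth = truth)
}

#' Simulate multi-sample coverage tracks with shared rank structure
#'
#' A latent signal (baseline plus Gaussian bumps at planted loci, bump height
#' scaling with locus occupancy) is observed by each sample through its own
#' monotone distortion (power `gamma`) plus non-negative additive noise, so
#' samples differ in scale but share rank structure.
#'
#' @param cfg A `synth_config`.
#' @param truth Optional locus truth table from [gen_factor_peaks()]; if
#'   `NULL`, loci are generated afresh from the config.
#' @return List with `tracks` (list of `binned_track`) and `latent` (named
#'   list of per-chromosome latent bin values).
#' @export
gen_tracks <- function(cfg, truth = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 2L)
  if (is.null(truth)) {
    truth <- gen_factor_peaks(cfg)$truth
    set.seed(cfg$seed + 2L)
  }
  w <- cfg$bin_width
  latent <- lapply(cfg$genome, function(len) rep(1, ceiling(len / w)))
  bump_halfwidth <- 5L   # bins on each side of a locus
  kern <- stats::dnorm(seq(-bump_halfwidth, bump_halfwidth), sd = 2)
  kern <- kern / max(kern)
  kmax <- max(truth$k)
  for (r in seq_len(nrow(truth))) {
    ch <- truth$chrom[r]
    b <- floor(truth$pos[r] / w) + 1L
    ix <- (b - bump_halfwidth):(b + bump_halfwidth)
    ok <- ix >= 1L & ix <= length(latent[[ch]])
    latent[[ch]][ix[ok]] <- latent[[ch]][ix[ok]] +
      cfg$signal_amplitude * truth$k[r] / kmax * kern[ok]
  }
  tracks <- lapply(seq_len(cfg$n_samples), function(j) {
    gam <- cfg$distortion_gamma[j]
    values <- lapply(latent, function(v) {
      obs <- v ^ gam
      if (cfg$track_noise_sd > 0) {
        obs <- pmax(obs + stats::rnorm(length(v), 0, cfg$track_noise_sd), 0)
      }
      obs
    })
    binned_track(paste0("sample", j), w, values)
  })
  list(tracks = tracks, latent = latent)
}

#' Simulate per-cell-line site catalogs with a planted ubiquity axis
#'
#' Plants `n_sites` sites, each with a ubiquity u drawn uniformly from
#' 1..n_experiments. A site sits within `border_window` of a synthetic TAD
#' border with probability linear in u (from `border_prob[1]` at u = 1 to
#' `border_prob[2]` at u = n_experiments); otherwise it is placed uniformly.
#' Each site then appears, with small center jitter, in u randomly chosen
#' experiments (minus replicate dropouts at `drop_prob`).
#'
#' @param cfg A `synth_config`.
#' @param borders Optional `data.frame` (chrom, pos); default: generated
#'   uniformly on the config genome.
#' @return List with `catalogs` (named list of `GRanges`, one per
#'   experiment), `borders`, `genome` (`Seqinfo`), and `truth` (data.frame:
#'   site, chrom, center, u, at_border).
#' @export
gen_cell_line_catalogs <- function(cfg, borders = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 3L)
  genome <- genome_spec(names(cfg$genome), cfg$genome)
  win <- cfg$border_window
  if (is.null(borders)) {
    per_chrom <- diff(round(seq(0, cfg$catalog_n_borders,
                                length.out = length(cfg$genome) + 1L)))
    borders <- do.call(rbind, lapply(seq_along(cfg$genome), function(ci) {
      data.frame(chrom = names(cfg$genome)[ci],
                 pos = spaced_positions(per_chrom[ci], cfg$genome[[ci]],
                                        3 * win),
                 stringsAsFactors = FALSE)
    }))
  }
  ## global grid of well-separated candidate slots, labeled border/non-border
  slot_gap <- 2000
  slots <- do.call(rbind, lapply(seq_along(cfg$genome), function(ci) {
    ch <- names(cfg$genome)[ci]
    pos <- seq(slot_gap, cfg$genome[[ci]] - slot_gap, by = slot_gap)
    bp <- borders$pos[borders$chrom == ch]
    near <- if (length(bp) == 0L) rep(FALSE, length(pos)) else
      colSums(abs(outer(bp, pos, "-")) <= win - 1000) > 0
    data.frame(chrom = ch, pos = pos, at_border = near,
               stringsAsFactors = FALSE)
  }))
  u <- sample.int(cfg$n_experiments, cfg$n_sites, replace = TRUE)
  p <- cfg$border_prob[1L] + (cfg$border_prob[2L] - cfg$border_prob[1L]) *
    (u - 1) / (cfg$n_experiments - 1)
  at_border <- stats::runif(cfg$n_sites) < p
  idx_b <- which(slots$at_border)
  idx_n <- which(!slots$at_border)
  if (sum(at_border) > length(idx_b) || sum(!at_border) > length(idx_n)) {
    stop("too many sites for the available well-separated slots; ",
         "reduce n_sites or enlarge the genome")
  }
  slot_of <- integer(cfg$n_sites)
  slot_of[at_border] <- sample(idx_b, sum(at_border))
  slot_of[!at_border] <- sample(idx_n, sum(!at_border))
  truth <- data.frame(site = seq_len(cfg$n_sites),
                      chrom = slots$chrom[slot_of],
                      center = slots$pos[slot_of],
                      u = u, at_border = at_border,
                      stringsAsFactors = FALSE)
  labs <- sprintf("exp%02d", seq_len(cfg$n_experiments))
  member <- lapply(seq_len(cfg$n_sites), function(i) {
    in_exp <- sample.int(cfg$n_experiments, u[i])
    if (cfg$drop_prob > 0) {
      in_exp <- in_exp[stats::runif(length(in_exp)) >= cfg$drop_prob]
    }
    in_exp
  })
  site_of_pair <- rep(seq_len(cfg$n_sites), times = lengths(member))
  exp_of_pair <- unlist(member, use.names = FALSE)
  ## one batched GRanges for all (site, experiment) pairs, then split by
  ## experiment: far cheaper than 62 separate constructions
  ctr <- trunc_jitter(truth$center[site_of_pair], cfg$site_jitter_sd,
                      cfg$genome[truth$chrom[site_of_pair]])
  all_gr <- GenomicRanges::GRanges(
    truth$chrom[site_of_pair],
    IRanges::IRanges(pmax(ctr - 150, 1), ctr + 150),
    summit = as.integer(ctr))
  all_gr <- set_genome(all_gr, genome)
  catalogs <- as.list(GenomicRanges::split(
    all_gr, factor(labs[exp_of_pair], levels = labs)))
  catalogs <- lapply(catalogs, GenomicRanges::sort)
  list(catalogs = catalogs, borders = borders, genome = genome,
       truth = truth)
}

#' Write a truth table as TSV
#'
#' @param truth A truth `data.frame` from any generator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
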