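#' Define a genome from chromosome names and lengths
#'
#' A genome is represented as a [GenomeInfoDb::Seqinfo] object: an ordered set
#' of uniquely named chromosomes with integer lengths. Every interval handled
#' by the package is validated against one of these.
#'
#' @param seqnames Character vector of unique chromosome names.
#' @param seqlengths Integer vector of chromosome lengths in bp (> 0).
#' @return A `Seqinfo` object.
#' @examples
#' gn <- genome_spec(c("chr2L", "chr2R"), c(23011544, 21146708))
#' @export
genome_spec <- function(seqnames, seqlengths) {
  if (anyDuplicated(seqnames)) {
    stop("chromosome names must be unique")
  }
  seqlengths <- as.integer(seqlengths)
  if (length(seqlengths) != length(seqnames) || any(is.na(seqlengths)) ||
      any(seqlengths <= 0L)) {
    stop("each chromosome needs a positive integer length")
  }
  GenomeInfoDb::Seqinfo(seqnames = as.character(seqnames),
                        seqlengths = seqlengths)
}

#' Read a two-column chrom.sizes file
#'
#' @param path Path to a TSV with columns chromosome name and length.
#' @return A `Seqinfo` object.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "integer"))
  if (nrow(tab) == 0L) stop("empty chrom.sizes file: ", path)
  genome_spec(tab$chrom, tab$length)
}

#' Write a chrom.sizes file
#'
#' @param genome A `Seqinfo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(
    data.frame(chrom = GenomeInfoDb::seqnames(genome),
               length = GenomeInfoDb::seqlengths(genome)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Validate a GRanges against a genome: known chromosomes, within bounds.
## Used by every reader and generator; errors name the offending interval.
validate_intervals <- function(gr, genome, what = "interval") {
  chroms <- as.character(GenomeInfoDb::seqnames(genome))
  bad <- !(as.character(GenomicRanges::seqnames(gr)) %in% chroms)
  if (any(bad)) {
    stop(what, " on unknown chromosome: ",
         paste(unique(as.character(GenomicRanges::seqnames(gr))[bad]),
               collapse = ", "))
  }
  lens <- GenomeInfoDb::seqlengths(genome)[
    as.character(GenomicRanges::seqnames(gr))]
  off <- GenomicRanges::start(gr) < 1L | GenomicRanges::end(gr) > lens
  if (any(off)) {
    i <- which(off)[1L]
    stop(what, " ", as.character(GenomicRanges::seqnames(gr))[i], ":",
         GenomicRanges::start(gr)[i] - 1L, "-", GenomicRanges::end(gr)[i],
         " lies outside its chromosome")
  }
  invisible(gr)
}

## Attach Seqinfo (names and lengths) of `genome` to gr without triggering
## out-of-bound warnings twice; assumes validate_intervals already ran.
set_genome <- function(gr, genome) {
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(genome)
  suppressWarnings(GenomeInfoDb::seqinfo(gr) <- genome)
  gr
}
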