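#' Genome-wide background coverage level
#'
#' The background is the mean binned coverage over all chromosomes that carry
#' any signal; chromosomes with all-zero coverage (e.g. decoys) are excluded
#' from the average so they cannot deflate it.
#'
#' @param coverage a `coverage_track` from [build_coverage()].
#' @return a strictly positive scalar.
#' @export
genome_background <- function(coverage) {
  stopifnot(inherits(coverage, "coverage_track"))
  nonzero <- Filter(function(v) any(v > 0), coverage$coverage)
  if (length(nonzero) == 0L) stop("coverage is zero everywhere; cannot define a background level")
  mean(unlist(nonzero, use.names = FALSE))
}

#' Select training regions by coverage fold change over background
#'
#' Scans the binned coverage for maximal runs of bins whose fold change over
#' the genome background lies within `[lower_fc, upper_fc]`. Each run (seed)
#' is extended by `extension` bp in both directions so that flanking
#' background is part of the training material, clipped to the chromosome,
#' and overlapping extended regions are merged. If more than `max_regions`
#' result, the strongest seeds (by maximum seed coverage, ties broken by
#' genomic order) are kept. Regions intersecting `masked` intervals are
#' dropped.
#'
#' @param coverage a `coverage_track`.
#' @param lower_fc,upper_fc fold-change band (defaults 10 and 20).
#' @param extension bp added on each side of a seed (default 5000).
#' @param max_regions cap on the number of regions (default 1000).
#' @param masked optional `GRanges` of intervals training must avoid.
#' @return a `GRanges` of training regions (attribute `provenance = "auto"`).
#' @export
select_training_regions <- function(coverage, lower_fc = 10, upper_fc = 20,
                                    extension = 5000, max_regions = 1000,
                                    masked = NULL) {
  stopifnot(inherits(coverage, "coverage_track"))
  if (lower_fc >= upper_fc) stop("lower_fc must be below upper_fc")
  bg <- genome_background(coverage)
  bs <- coverage$bin_size
  seeds <- list()
  for (chrom in names(coverage$coverage)) {
    v <- coverage$coverage[[chrom]]
    inband <- v / bg >= lower_fc & v / bg <= upper_fc
    if (!any(inband)) next
    r <- rle(inband)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    len <- coverage$layout[[chrom]]
    seeds[[chrom]] <- GenomicRanges::GRanges(
      chrom,
      IRanges::IRanges(start = (starts[runs] - 1L) * bs + 1L,
                       end = pmin(ends[runs] * bs, len)),
      seed_max_cov = vapply(runs, function(j) {
        max(v[starts[j]:ends[j]])
      }, numeric(1))
    )
  }
  if (length(seeds) == 0L) {
    stop("no training regions found in the fold-change band [", lower_fc,
         ", ", upper_fc, "]; supply a training BED or adjust -u/-l")
  }
  seeds <- sort(do.call(c, unname(seeds)))
  ext <- GenomicRanges::GRanges(
    seqnames(seeds),
    IRanges::IRanges(
      start = pmax(1L, BiocGenerics::start(seeds) - as.integer(extension)),
      end = pmin(unname(coverage$layout[as.character(seqnames(seeds))]),
                 BiocGenerics::end(seeds) + as.integer(extension))
    )
  )
  merged <- GenomicRanges::reduce(ext, with.revmap = TRUE)
  merged_max <- vapply(mcols(merged)$revmap, function(idx) {
    max(mcols(seeds)$seed_max_cov[idx])
  }, numeric(1))
  mcols(merged)$revmap <- NULL
  mcols(merged)$seed_max_cov <- merged_max
  if (!is.null(masked) && length(masked) > 0L) {
    merged <- merged[!IRanges::overlapsAny(merged, masked)]
  }
  if (length(merged) == 0L) {
    stop("all candidate training regions intersect masked intervals")
  }
  if (length(merged) > max_regions) {
    ord <- order(-mcols(merged)$seed_max_cov,
                 as.integer(match(seqnames(merged), names(coverage$layout))),
                 BiocGenerics::start(merged))
    merged <- sort(merged[ord[seq_len(max_regions)]])
  }
  attr(merged, "provenance") <- "auto"
  merged
}

#' Load user-provided training regions from a BED file
#'
#' Regions are validated against the genome layout and clipped to chromosome
#' bounds (with a warning); no extension is applied.
#'
#' @param bed_path path to a BED file of training regions.
#' @param layout named vector of chromosome lengths.
#' @return a `GRanges` (attribute `provenance = "user"`).
#' @export
load_user_training_regions <- function(bed_path, layout) {
  .check_layout(layout)
  gr <- read_bed(bed_path)
  if (length(gr) == 0L) stop("training BED is empty: ", bed_path)
  chr <- as.character(seqnames(gr))
  if (!all(chr %in% names(layout))) {
    stop("training region chromosome(s) not in genome layout: ",
         paste(unique(setdiff(chr, names(layout))), collapse = ", "))
  }
  gr2 <- suppressWarnings(
    GenomicRanges::GRanges(chr, ranges(gr),
                           seqinfo = .layout_seqinfo(layout)))
  trimmed <- GenomicRanges::trim(gr2)
  if (any(BiocGenerics::width(trimmed) != BiocGenerics::width(gr2))) {
    warning("training regions extending beyond chromosome ends were clipped")
  }
  trimmed <- sort(trimmed)
  attr(trimmed, "provenance") <- "user"
  trimmed
}
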