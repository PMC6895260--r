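# Binned genome-wide signal layers. A signal_tracks object holds, per
# chromosome, an n_bins x 4 matrix (columns nfr/mono/di/tri); a
# coverage_track holds one numeric vector of binned mean fragment depth.

LAYERS <- c("nfr", "mono", "di", "tri")

.n_bins <- function(chrom_len, bin_size) as.integer(ceiling(chrom_len / bin_size))

.bin_ranges <- function(chrom_len, bin_size) {
  nb <- .n_bins(chrom_len, bin_size)
  starts <- seq.int(1L, by = bin_size, length.out = nb)
  IRanges::IRanges(start = starts,
                   end = pmin(starts + bin_size - 1L, as.integer(chrom_len)))
}

.bin_sums <- function(cov_rle, chrom_len, bin_size) {
  v <- IRanges::Views(cov_rle, .bin_ranges(chrom_len, bin_size))
  IRanges::viewSums(v)
}

.clip_to_layout <- function(fragments, layout) {
  .check_layout(layout)
  chr <- as.character(seqnames(fragments))
  if (!all(chr %in% names(layout))) {
    stop("fragment chromosome(s) absent from genome layout: ",
         paste(unique(setdiff(chr, names(layout))), collapse = ", "))
  }
  gr <- suppressWarnings(
    GenomicRanges::GRanges(chr, ranges(fragments),
                           seqinfo = .layout_seqinfo(layout)))
  trimmed <- GenomicRanges::trim(gr)
  if (any(BiocGenerics::width(trimmed) != BiocGenerics::width(gr))) {
    warning("fragments extending beyond chromosome ends were clipped")
  }
  trimmed
}

#' Build the four binned signal layers from fragments and a fitted mixture
#'
#' Every genomic position covered by a fragment contributes, to each of the
#' four layers, the posterior probability that the fragment belongs to the
#' corresponding length component; positions are then aggregated into bins of
#' `bin_size` bp (a fragment overlapping part of a bin contributes
#' fractionally, overlap_bp / bin_size). The result is the raw
#' (untransformed) 4-layer signal matrix per chromosome.
#'
#' @param fragments a `GRanges` of fragments (widths = insertion lengths).
#' @param mixture a fitted [frag_mixture()].
#' @param layout named vector of chromosome lengths (bp).
#' @param bin_size bin width in bp (default 10).
#' @param hard_assign_nfr see [responsibilities()].
#' @return a `signal_tracks` object.
#' @export
build_tracks <- function(fragments, mixture, layout, bin_size = 10,
                         hard_assign_nfr = FALSE) {
  frags <- .clip_to_layout(fragments, layout)
  resp <- responsibilities(BiocGenerics::width(fragments), mixture,
                           include_nfr = TRUE,
                           hard_assign_nfr = hard_assign_nfr)
  signal <- lapply(names(layout), function(chrom) {
    len <- layout[[chrom]]
    nb <- .n_bins(len, bin_size)
    m <- matrix(0, nrow = nb, ncol = 4L, dimnames = list(NULL, LAYERS))
    on_chr <- as.character(seqnames(frags)) == chrom
    if (any(on_chr)) {
      r <- ranges(frags)[on_chr]
      for (k in 1:4) {
        cov <- IRanges::coverage(r, weight = resp[on_chr, k], width = len)
        # float cancellation in the weighted pileup can leave ~ -1e-17
        m[, k] <- pmax(.bin_sums(cov, len, bin_size), 0) / bin_size
      }
    }
    m
  })
  names(signal) <- names(layout)
  structure(list(bin_size = bin_size, transformed = FALSE,
                 signal = signal, layout = layout),
            class = "signal_tracks")
}

#' @export
print.signal_tracks <- function(x, ...) {
  cat(sprintf("signal_tracks: %d chromosome(s), bin %d bp, %s\n",
              length(x$signal), x$bin_size,
              if (x$transformed) "sqrt-transformed" else "raw"))
  invisible(x)
}

#' Square-root transform the signal layers
#'
#' Applies an elementwise square root to move the nonnegative, zero-rich
#' count-like signal into continuous space for the Gaussian emission model.
#' Transforming twice is an error.
#'
#' @param tracks a raw `signal_tracks` object.
#' @return the transformed `signal_tracks`.
#' @export
sqrt_transform <- function(tracks) {
  stopifnot(inherits(tracks, "signal_tracks"))
  if (tracks$transformed) stop("tracks are already sqrt-transformed")
  tracks$signal <- lapply(tracks$signal, sqrt)
  tracks$transformed <- TRUE
  tracks
}

#' Binned total fragment coverage
#'
#' Per-bin mean fragment depth: summed overlapping base pairs of all
#' fragments in each bin, divided by the bin size.
#'
#' @inheritParams build_tracks
#' @return a `coverage_track` object.
#' @export
build_coverage <- function(fragments, layout, bin_size = 10) {
  frags <- .clip_to_layout(fragments, layout)
  coverage <- lapply(names(layout), function(chrom) {
    len <- layout[[chrom]]
    on_chr <- as.character(seqnames(frags)) == chrom
    if (!any(on_chr)) return(numeric(.n_bins(len, bin_size)))
    cov <- IRanges::coverage(ranges(frags)[on_chr], width = len)
    pmax(as.numeric(.bin_sums(cov, len, bin_size)), 0) / bin_size
  })
  names(coverage) <- names(layout)
  structure(list(bin_size = bin_size, coverage = coverage, layout = layout),
            class = "coverage_track")
}

#' Write a binned track as bedGraph
#'
#' Consecutive equal-valued bins are merged into single records; zero-valued
#' runs are omitted (and restored as zeros by [read_bedgraph()]). Coordinates
#' are written 0-based half-open.
#'
#' @param track a `coverage_track` (or a single layer via [track_layer()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph", con)
  bs <- track$bin_size
  for (chrom in names(track$coverage)) {
    v <- track$coverage[[chrom]]
    if (length(v) == 0L) next
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    len <- track$layout[[chrom]]
    df <- data.frame(
      chrom = chrom,
      start = starts_bin[keep] * bs,
      end = pmin(ends_bin[keep] * bs, len),
      value = r$values[keep]
    )
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a bedGraph written by [write_bedgraph()] back into a coverage_track
#'
#' @param path bedGraph path.
#' @param layout named vector of chromosome lengths.
#' @param bin_size bin width the file was written at.
#' @return a `coverage_track`; bins not covered by any record are zero.
#' @export
read_bedgraph <- function(path, layout, bin_size = 10) {
  .check_layout(layout)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#|browser)", lines) & nzchar(lines)]
  coverage <- lapply(layout, function(len) numeric(.n_bins(len, bin_size)))
  names(coverage) <- names(layout)
  if (length(lines) > 0L) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- as.numeric(vapply(fields, `[[`, "", 2L))
    end <- as.numeric(vapply(fields, `[[`, "", 3L))
    value <- as.numeric(vapply(fields, `[[`, "", 4L))
    if (anyNA(start) || anyNA(end) || anyNA(value)) {
      stop("malformed bedGraph record in ", path)
    }
    for (i in seq_along(chrom)) {
      if (!chrom[i] %in% names(coverage)) {
        stop("bedGraph chromosome not in layout: ", chrom[i])
      }
      b0 <- floor(start[i] / bin_size) + 1L
      b1 <- ceiling(end[i] / bin_size)
      coverage[[chrom[i]]][b0:b1] <- value[i]
    }
  }
  structure(list(bin_size = bin_size, coverage = coverage, layout = layout),
            class = "coverage_track")
}

#' Extract one signal layer as a coverage_track
#'
#' @param tracks a `signal_tracks` object.
#' @param layer one of `"nfr"`, `"mono"`, `"di"`, `"tri"`.
#' @return a `coverage_track` holding that layer.
#' @export
track_layer <- function(tracks, layer = LAYERS) {
  layer <- match.arg(layer)
  structure(list(bin_size = tracks$bin_size,
                 coverage = lapply(tracks$signal, function(m) m[, layer]),
                 layout = tracks$layout),
            class = "coverage_track")
}

# Rows of the per-chromosome signal matrices for the bins overlapping each
# region; returns one observation matrix per region (in region order).
segment_observations <- function(tracks, regions) {
  stopifnot(inherits(tracks, "signal_tracks"))
  bs <- tracks$bin_size
  lapply(seq_along(regions), function(i) {
    chrom <- as.character(seqnames(regions)[i])
    m <- tracks$signal[[chrom]]
    if (is.null(m)) stop("region chromosome not in tracks: ", chrom)
    b0 <- max(1L, (BiocGenerics::start(regions)[i] - 1L) %/% bs + 1L)
    b1 <- min(nrow(m), (BiocGenerics::end(regions)[i] - 1L) %/% bs + 1L)
    m[b0:b1, , drop = FALSE]
  })
}
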