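#' Assemble accessible-region peaks from a state annotation
#'
#' Every center-state run longer than `min_center_length` bp is merged with
#' the nucleosome-state runs immediately upstream and downstream of it;
#' center runs separated only by nucleosome runs coalesce into a single
#' peak. Runs adjacent to masked intervals never extend across them (the
#' annotation itself guarantees this). A retained center run lacking a
#' nucleosome neighbor on one side still forms a peak from the blocks that
#' exist; such peaks are flagged in their name.
#'
#' @param annotation `GRanges` from [decode_genome()] (metadata column
#'   `role`).
#' @param min_center_length minimum center-run length in bp, exclusive
#'   (default 200).
#' @return a sorted `GRanges` of peaks with metadata columns `name` and
#'   `blocks` (a `GRangesList`; each block carries its `role`).
#' @export
assemble_peaks <- function(annotation, min_center_length = 200) {
  stopifnot(!is.null(mcols(annotation)$role))
  peaks <- list()
  for (chrom in unique(as.character(seqnames(annotation)))) {
    runs <- annotation[as.character(seqnames(annotation)) == chrom]
    runs <- runs[order(BiocGenerics::start(runs))]
    role <- mcols(runs)$role
    in_block <- role %in% c("nucleosome", "center")
    grp <- rle(in_block)
    g_end <- cumsum(grp$lengths)
    g_start <- g_end - grp$lengths + 1L
    for (gi in which(grp$values)) {
      idx <- g_start[gi]:g_end[gi]
      retained <- idx[role[idx] == "center" &
                        BiocGenerics::width(runs)[idx] > min_center_length]
      if (length(retained) == 0L) next
      lo <- min(retained); hi <- max(retained)
      has_left <- lo - 1L >= g_start[gi] && role[lo - 1L] == "nucleosome"
      has_right <- hi + 1L <= g_end[gi] && role[hi + 1L] == "nucleosome"
      if (has_left) lo <- lo - 1L
      if (has_right) hi <- hi + 1L
      block_idx <- lo:hi
      blocks <- GenomicRanges::granges(runs[block_idx])
      mcols(blocks)$role <- role[block_idx]
      flag <- if (has_left && has_right) "" else "_noflank"
      peaks[[length(peaks) + 1L]] <- list(
        chrom = chrom,
        start = BiocGenerics::start(runs)[lo],
        end = BiocGenerics::end(runs)[hi],
        blocks = blocks,
        flag = flag
      )
    }
  }
  if (length(peaks) == 0L) {
    out <- GenomicRanges::GRanges()
    mcols(out)$name <- character(0)
    mcols(out)$blocks <- GenomicRanges::GRangesList()
    return(out)
  }
  out <- GenomicRanges::GRanges(
    vapply(peaks, `[[`, "", "chrom"),
    IRanges::IRanges(start = vapply(peaks, `[[`, numeric(1), "start"),
                     end = vapply(peaks, `[[`, numeric(1), "end"))
  )
  ord <- BiocGenerics::order(out)
  out <- out[ord]
  mcols(out)$name <- sprintf("peak_%d%s", seq_along(out),
                             vapply(peaks[ord], `[[`, "", "flag"))
  mcols(out)$blocks <- GenomicRanges::GRangesList(
    lapply(peaks[ord], `[[`, "blocks"))
  out
}

#' Score a peak by its maximum center-state coverage
#'
#' @param peak a single-element `GRanges` with a `blocks` column.
#' @param coverage a `coverage_track` (raw read coverage).
#' @return the maximum binned coverage over the peak's center blocks.
#' @export
score_peak <- function(peak, coverage) {
  stopifnot(inherits(coverage, "coverage_track"))
  blocks <- mcols(peak)$blocks[[1L]]
  centers <- blocks[mcols(blocks)$role == "center"]
  if (length(centers) == 0L) return(0)
  bs <- coverage$bin_size
  chrom <- as.character(seqnames(peak))[1L]
  v <- coverage$coverage[[chrom]]
  mx <- 0
  for (i in seq_along(centers)) {
    b0 <- (BiocGenerics::start(centers)[i] - 1L) %/% bs + 1L
    b1 <- min(length(v), (BiocGenerics::end(centers)[i] - 1L) %/% bs + 1L)
    mx <- max(mx, v[b0:b1])
  }
  mx
}

#' Score every peak in a set
#'
#' @param peaks `GRanges` from [assemble_peaks()].
#' @param coverage a `coverage_track`.
#' @return the `peaks` with a numeric `score` column added.
#' @export
score_peaks <- function(peaks, coverage) {
  mcols(peaks)$score <- vapply(seq_along(peaks), function(i) {
    score_peak(peaks[i], coverage)
  }, numeric(1))
  peaks
}

# Gaussian kernel over bins, radius = half the smoothing window;
# sigma = window / 6 so the window spans +-3 sigma.
.gauss_kernel <- function(window_bp, bin_size) {
  sigma_bins <- (window_bp / 6) / bin_size
  radius <- max(1L, as.integer(round((window_bp / 2) / bin_size)))
  k <- dnorm(seq(-radius, radius), sd = sigma_bins)
  k / sum(k)
}

.smooth_vec <- function(v, kernel) {
  n <- length(v)
  radius <- (length(kernel) - 1L) %/% 2L
  padded <- c(numeric(radius), v, numeric(radius))
  sm <- numeric(n)
  # renormalize at the edges so truncated kernels don't bias the argmax down
  ones <- c(numeric(radius), rep(1, n), numeric(radius))
  for (i in seq_len(n)) {
    win <- (i):(i + 2L * radius)
    wsum <- sum(kernel * ones[win])
    sm[i] <- sum(kernel * padded[win]) / wsum
  }
  sm
}

#' Locate the summit of a peak
#'
#' Smooths the read coverage across the peak's center block(s) with a
#' Gaussian kernel (`smooth_window` bp wide, sigma = window/6) and returns
#' the position of maximum smoothed coverage; ties go to the leftmost
#' position. Positions are 1-based (the start of the winning bin).
#'
#' @param peak single-element `GRanges` with a `blocks` column.
#' @param coverage a `coverage_track`.
#' @param smooth_window smoothing window in bp (default 120).
#' @return integer summit position (1-based bp).
#' @export
call_summit <- function(peak, coverage, smooth_window = 120) {
  stopifnot(inherits(coverage, "coverage_track"))
  blocks <- mcols(peak)$blocks[[1L]]
  centers <- blocks[mcols(blocks)$role == "center"]
  if (length(centers) == 0L) return(NA_integer_)
  bs <- coverage$bin_size
  chrom <- as.character(seqnames(peak))[1L]
  v <- coverage$coverage[[chrom]]
  kernel <- .gauss_kernel(smooth_window, bs)
  best_val <- -Inf
  best_pos <- NA_integer_
  for (i in seq_along(centers)) {
    b0 <- (BiocGenerics::start(centers)[i] - 1L) %/% bs + 1L
    b1 <- min(length(v), (BiocGenerics::end(centers)[i] - 1L) %/% bs + 1L)
    sm <- .smooth_vec(v[b0:b1], kernel)
    j <- which.max(sm)
    if (sm[j] > best_val + 1e-12) {
      best_val <- sm[j]
      best_pos <- as.integer((b0 + j - 2L) * bs + 1L)
    }
  }
  best_pos
}

#' Add summits to a peak set
#'
#' @inheritParams call_summit
#' @param peaks `GRanges` from [assemble_peaks()].
#' @return the `peaks` with an integer `summit` column (1-based bp).
#' @export
call_summits <- function(peaks, coverage, smooth_window = 120) {
  mcols(peaks)$summit <- vapply(seq_along(peaks), function(i) {
    call_summit(peaks[i], coverage, smooth_window)
  }, integer(1))
  peaks
}

#' Write peaks in gappedPeak format
#'
#' The gappedPeak dialect is 15-column BED12+3: the standard BED12 block
#' structure (blocks = the nucleosome/center state runs) plus signalValue,
#' pValue and qValue columns. The raw max-center-coverage score goes in
#' signalValue; the BED score column carries the same value clamped to
#' 0-1000. pValue/qValue are -1 (not computed). Block arithmetic is
#' validated before writing.
#'
#' @param peaks scored `GRanges` from [score_peaks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gappedpeak <- function(peaks, path) {
  rows <- lapply(seq_along(peaks), function(i) {
    p <- peaks[i]
    blocks <- mcols(p)$blocks[[1L]]
    bsizes <- BiocGenerics::width(blocks)
    bstarts <- BiocGenerics::start(blocks) - BiocGenerics::start(p)
    if (bstarts[1L] != 0L || sum(bsizes) != BiocGenerics::width(p) ||
        any(diff(bstarts) <= 0)) {
      stop("inconsistent block arithmetic for peak ", mcols(p)$name)
    }
    score <- if (is.null(mcols(p)$score)) 0 else mcols(p)$score
    data.frame(
      chrom = as.character(seqnames(p)),
      start = BiocGenerics::start(p) - 1L,
      end = BiocGenerics::end(p),
      name = mcols(p)$name,
      score = as.integer(pmin(1000, round(score))),
      strand = ".",
      thickStart = BiocGenerics::start(p) - 1L,
      thickEnd = BiocGenerics::end(p),
      itemRgb = "0",
      blockCount = length(blocks),
      blockSizes = paste(bsizes, collapse = ","),
      blockStarts = paste(bstarts, collapse = ","),
      signalValue = score,
      pValue = -1,
      qValue = -1
    )
  })
  df <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(matrix(nrow = 0, ncol = 15))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gappedPeak file written by [write_gappedpeak()]
#'
#' @param path gappedPeak path.
#' @return `GRanges` with `name`, `score` (signalValue) and block structure.
#' @export
read_gappedpeak <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track)", lines)]
  if (length(lines) == 0L) {
    out <- GenomicRanges::GRanges()
    mcols(out)$name <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 15L)) {
    stop("gappedPeak line ", which(lengths(fields) != 15L)[1],
         " does not have 15 columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- as.integer(vapply(fields, `[[`, "", 2L)) + 1L
  end <- as.integer(vapply(fields, `[[`, "", 3L))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  mcols(gr)$name <- vapply(fields, `[[`, "", 4L)
  mcols(gr)$score <- as.numeric(vapply(fields, `[[`, "", 13L))
  mcols(gr)$blocks <- GenomicRanges::GRangesList(lapply(seq_along(fields), function(i) {
    bsz <- as.integer(strsplit(fields[[i]][[11L]], ",")[[1L]])
    bst <- as.integer(strsplit(fields[[i]][[12L]], ",")[[1L]])
    GenomicRanges::GRanges(chrom[i],
                           IRanges::IRanges(start = start[i] + bst,
                                            width = bsz))
  }))
  gr
}

#' Write peak summits as BED4
#'
#' One record per peak: the summit base (0-based half-open on disk) named
#' after its peak.
#'
#' @param peaks `GRanges` with `summit` and `name` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summits <- function(peaks, path) {
  keep <- !is.na(mcols(peaks)$summit)
  df <- data.frame(
    chrom = as.character(seqnames(peaks))[keep],
    start = mcols(peaks)$summit[keep] - 1L,
    end = mcols(peaks)$summit[keep],
    name = paste0(mcols(peaks)$name[keep], "_summit")
  )
  df <- df[order(df$chrom, df$start), ]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
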