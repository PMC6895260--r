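#' Read ATAC-seq fragments from a paired-end BAM file
#'
#' Extracts one fragment per properly-paired read pair, applying the standard
#' ATAC-seq hygiene filters: secondary, supplementary, unmapped and QC-fail
#' alignments are always dropped; pairs where either mate has mapping quality
#' below `min_mapq` are removed; and duplicate pairs (exact same chromosome,
#' start and stop position) are collapsed to a single fragment when
#' `drop_duplicates` is `TRUE`. Each pair is counted once, from the
#' forward-strand mate with positive template length, so the fragment spans
#' the full sequenced insert and its width is the observed insertion length.
#'
#' @param bam_path path to a coordinate-sorted, indexed BAM file.
#' @param min_mapq minimum mapping quality required of *both* mates
#'   (default 30).
#' @param drop_duplicates collapse pairs sharing identical coordinates
#'   (default `TRUE`).
#' @return a sorted [GenomicRanges::GRanges] of fragments carrying the BAM
#'   header's sequence info; `width()` gives the insertion length in bp.
#' @export
read_fragments <- function(bam_path, min_mapq = 30, drop_duplicates = TRUE) {
  if (!file.exists(bam_path)) stop("BAM file not found: ", bam_path)
  idx <- paste0(bam_path, ".bai")
  if (!file.exists(idx) && !file.exists(sub("\\.bam$", ".bai", bam_path))) {
    stop("BAM index (.bai) not found for ", bam_path,
         "; the input must be coordinate-sorted and indexed")
  }
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]
  so <- grep("^@HD", names(unlist(hdr$text)), value = FALSE)
  hd <- hdr$text[["@HD"]]
  if (!is.null(hd) && !any(grepl("SO:coordinate", hd))) {
    stop("BAM is not coordinate-sorted (header @HD SO is not 'coordinate')")
  }
  flags <- Rsamtools::scanBamFlag(
    isPaired = TRUE, isProperPair = TRUE,
    isUnmappedQuery = FALSE, hasUnmappedMate = FALSE,
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
    isNotPassingQualityControls = FALSE
  )
  param <- Rsamtools::ScanBamParam(
    flag = flags, what = c("qname", "rname", "pos", "mapq", "isize")
  )
  rec <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  if (length(rec$pos) == 0L) {
    n_any <- Rsamtools::countBam(bam_path)$records
    if (n_any > 0L) {
      stop("no properly-paired alignments found: single-end libraries ",
           "cannot be analyzed; a paired-end BAM is required")
    }
    return(GenomicRanges::GRanges(seqinfo = .seqinfo_from_header(hdr)))
  }

  fw <- !is.na(rec$isize) & rec$isize > 0L
  rv <- !is.na(rec$isize) & rec$isize < 0L
  # MAPQ filter applies to both mates: look up the reverse mate by query name
  mate_mapq <- rec$mapq[rv][match(rec$qname[fw], rec$qname[rv])]
  ok <- fw
  ok[fw] <- !is.na(rec$mapq[fw]) & rec$mapq[fw] >= min_mapq &
    !is.na(mate_mapq) & mate_mapq >= min_mapq
  chrom <- as.character(rec$rname[ok])
  start <- rec$pos[ok]
  len <- rec$isize[ok]

  if (drop_duplicates) {
    key <- paste(chrom, start, len)
    keep <- !duplicated(key)
    chrom <- chrom[keep]; start <- start[keep]; len <- len[keep]
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, width = len),
    seqinfo = .seqinfo_from_header(hdr)
  )
  sort(gr)
}

.seqinfo_from_header <- function(hdr) {
  GenomeInfoDb::Seqinfo(names(hdr$targets), unname(hdr$targets))
}

#' Read a BED3+ file into a GRanges
#'
#' BED coordinates are 0-based half-open on disk and converted to the 1-based
#' closed convention of [GenomicRanges::GRanges] on read. Optional columns 4-6
#' (name, score, strand) are kept as metadata when present.
#'
#' @param path path to a BED file.
#' @return a `GRanges`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", lineno[which(nf < 3L)[1]],
         ": fewer than 3 tab-separated fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | end <= start | start < 0)
  if (length(bad) > 0L) {
    stop("malformed BED line ", lineno[bad[1]],
         ": require numeric 0 <= start < end")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  if (all(nf >= 4L)) mcols(gr)$name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5L)) {
    mcols(gr)$score <- suppressWarnings(
      as.numeric(vapply(fields, `[[`, "", 5L)))
  }
  if (all(nf >= 6L)) {
    st <- vapply(fields, `[[`, "", 6L)
    st[!st %in% c("+", "-")] <- "*"
    BiocGenerics::strand(gr) <- st
  }
  gr
}

#' Write a GRanges as BED
#'
#' Coordinates are converted back to the 0-based half-open BED convention;
#' `name`, `score` and strand columns are written when available so that
#' `read_bed(write_bed(x))` round-trips.
#'
#' @param intervals a `GRanges`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(
    chrom = as.character(seqnames(intervals)),
    start = BiocGenerics::start(intervals) - 1L,
    end = BiocGenerics::end(intervals)
  )
  has_name <- !is.null(mcols(intervals)$name)
  has_score <- !is.null(mcols(intervals)$score)
  has_strand <- any(as.character(BiocGenerics::strand(intervals)) != "*")
  if (has_name || has_score || has_strand) {
    df$name <- if (has_name) mcols(intervals)$name else "."
    if (has_score || has_strand) {
      df$score <- if (has_score) mcols(intervals)$score else 0
      if (has_strand) {
        st <- as.character(BiocGenerics::strand(intervals))
        st[st == "*"] <- "."
        df$strand <- st
      }
    }
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Validate that every range lies on a chromosome of the layout (a named
# vector of chromosome lengths); used by track building and the simulator.
.check_layout <- function(layout) {
  if (is.null(names(layout)) || any(!nzchar(names(layout)))) {
    stop("genome layout must be a named vector of chromosome lengths")
  }
  if (any(layout <= 0)) stop("chromosome lengths must be positive")
  invisible(layout)
}

.layout_seqinfo <- function(layout) {
  .check_layout(layout)
  GenomeInfoDb::Seqinfo(names(layout), unname(layout))
}
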