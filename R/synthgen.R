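#' Geometry of a planted accessible region
#'
#' An accessible region is a nucleosome-free core of `center_width` bp
#' flanked on each side by `n_flank_nucleosomes` phased nucleosomes with
#' dyads `nucleosome_spacing` bp apart; nucleosomal fragment midpoints
#' scatter around their dyads with standard deviation `dyad_sd` bp.
#'
#' @param center_width width of the NFR core (bp).
#' @param n_flank_nucleosomes phased nucleosomes per side.
#' @param nucleosome_spacing dyad-to-dyad distance (bp).
#' @param dyad_sd positional jitter of nucleosomal fragment midpoints (bp).
#' @return a list of class `region_geometry`.
#' @export
region_geometry <- function(center_width = 400, n_flank_nucleosomes = 2,
                            nucleosome_spacing = 200, dyad_sd = 20) {
  stopifnot(center_width > 0, n_flank_nucleosomes >= 1,
            nucleosome_spacing > 0, dyad_sd >= 0)
  structure(list(center_width = center_width,
                 n_flank_nucleosomes = n_flank_nucleosomes,
                 nucleosome_spacing = nucleosome_spacing,
                 dyad_sd = dyad_sd),
            class = "region_geometry")
}

#' Default generating mixture for simulations
#'
#' Exponential NFR lengths with mean 100 bp; nucleosomal Gaussians at
#' 195/396/693 bp with standard deviations 25/50/100 and weights
#' 0.7/0.2/0.1; half of all fragments are nucleosome-free.
#'
#' @return a [frag_mixture()].
#' @export
default_sim_mixture <- function() {
  frag_mixture(beta = 100, means = c(195, 396, 693), sds = c(25, 50, 100),
               weights = c(0.7, 0.2, 0.1), nfr_weight = 0.5)
}

.draw_lengths <- function(component, mixture) {
  n <- length(component)
  len <- numeric(n)
  is_nfr <- component == 1L
  len[is_nfr] <- rexp(sum(is_nfr), rate = 1 / mixture$beta)
  for (k in 1:3) {
    sel <- component == k + 1L
    len[sel] <- rnorm(sum(sel), mixture$means[k], mixture$sds[k])
  }
  pmax(10L, as.integer(round(len)))
}

#' Simulate a paired-end ATAC-seq dataset with known truth
#'
#' Plants `n_regions` non-overlapping accessible regions (NFR core flanked
#' by phased nucleosomes, see [region_geometry()]) on a small artificial
#' genome. Fragment lengths are drawn from the generating mixture; within a
#' region, nucleosome-free fragments fall uniformly across the core while
#' nucleosomal fragment midpoints are Gaussian around the covered dyads.
#' The remaining `background_frac` of fragments land uniformly anywhere.
#' Total fragment count is set so that summed fragment bp equals
#' `depth` times the genome size.
#'
#' @param layout named vector of chromosome lengths (default one 2-Mb
#'   chromosome).
#' @param n_regions number of planted accessible regions (default 20).
#' @param geometry a [region_geometry()].
#' @param mixture_truth generating [frag_mixture()].
#' @param depth mean genome-wide fragment coverage (default 30).
#' @param background_frac fraction of fragments placed uniformly genome-wide
#'   (default 0.75; the rest concentrate in the planted regions).
#' @param dup_rate fraction of fragments duplicated exactly (default 0).
#' @param seed RNG seed.
#' @param bam_path if non-NULL, fragments are also written as a sorted,
#'   indexed paired-end BAM at this path (MAPQ 60).
#' @return a list of class `sim_truth`: `fragments` (GRanges with
#'   `component` and `origin` labels), `centers` and `nucleosomes`
#'   (GRanges of planted spans), `layout`, `mixture`, `geometry`,
#'   `bam` (path or NULL).
#' @export
simulate_dataset <- function(layout = c(chrSim = 2000000),
                             n_regions = 20,
                             geometry = region_geometry(),
                             mixture_truth = default_sim_mixture(),
                             depth = 30,
                             background_frac = 0.75,
                             dup_rate = 0,
                             seed = NULL,
                             bam_path = NULL) {
  .check_layout(layout)
  if (depth <= 0) stop("depth must be positive")
  if (!is.null(seed)) set.seed(seed)
  g <- geometry
  flank_bp <- g$n_flank_nucleosomes * g$nucleosome_spacing
  region_span <- g$center_width + 2 * flank_bp

  # place regions on the largest chromosomes first, in equal slots with a
  # safety margin so training-region extension stays on-chromosome
  margin <- 10000
  placements <- list()
  remaining <- n_regions
  for (chrom in names(sort(layout, decreasing = TRUE))) {
    if (remaining == 0L) break
    len <- layout[[chrom]]
    usable <- len - 2 * margin
    n_here <- min(remaining,
                  max(0L, floor(usable / (region_span + 2 * margin))))
    if (n_here == 0L) next
    slot <- usable / n_here
    starts <- vapply(seq_len(n_here), function(i) {
      lo <- margin + (i - 1) * slot
      hi <- margin + i * slot - region_span
      round(runif(1, lo, hi))
    }, numeric(1))
    placements[[chrom]] <- starts
    remaining <- remaining - n_here
  }
  if (remaining > 0L) {
    stop("genome too small to place ", n_regions, " regions of span ",
         region_span, " bp")
  }

  chroms <- rep(names(placements), lengths(placements))
  reg_start <- unlist(placements, use.names = FALSE)   # 0-based flank start
  centers <- GenomicRanges::GRanges(
    chroms,
    IRanges::IRanges(start = reg_start + flank_bp + 1,
                     width = g$center_width),
    seqinfo = .layout_seqinfo(layout))
  left_flanks <- GenomicRanges::GRanges(
    chroms, IRanges::IRanges(start = reg_start + 1, width = flank_bp),
    seqinfo = .layout_seqinfo(layout))
  right_flanks <- GenomicRanges::GRanges(
    chroms,
    IRanges::IRanges(start = reg_start + flank_bp + g$center_width + 1,
                     width = flank_bp),
    seqinfo = .layout_seqinfo(layout))
  nucleosomes <- sort(c(left_flanks, right_flanks))

  genome_bp <- sum(layout)
  comp_prior <- c(mixture_truth$nfr_weight,
                  (1 - mixture_truth$nfr_weight) * mixture_truth$weights)
  mean_len <- sum(comp_prior * c(mixture_truth$beta, mixture_truth$means))
  n_frag <- max(1L, as.integer(round(depth * genome_bp / mean_len)))
  n_bg <- as.integer(round(background_frac * n_frag))
  n_fg <- n_frag - n_bg
  if (n_regions == 0L) {
    n_bg <- n_frag
    n_fg <- 0L
  }

  frag_chrom <- character(0); frag_mid <- numeric(0)
  frag_comp <- integer(0); frag_origin <- integer(0)

  if (n_fg > 0L) {
    origin <- sample.int(n_regions, n_fg, replace = TRUE)
    comp <- sample.int(4L, n_fg, replace = TRUE, prob = comp_prior)
    mid <- numeric(n_fg)
    c_start <- reg_start + flank_bp          # 0-based center span start
    dyad_offsets <- (seq_len(g$n_flank_nucleosomes) - 0.5) *
      g$nucleosome_spacing
    is_nfr <- comp == 1L
    mid[is_nfr] <- c_start[origin[is_nfr]] +
      runif(sum(is_nfr), 0, g$center_width)
    nuc <- which(!is_nfr)
    if (length(nuc) > 0L) {
      span_n <- comp[nuc] - 1L               # nucleosomes covered (1, 2 or 3)
      max_start <- pmax(1L, g$n_flank_nucleosomes - span_n + 1L)
      start_idx <- floor(runif(length(nuc)) * max_start) + 1L
      end_idx <- pmin(start_idx + span_n - 1L, g$n_flank_nucleosomes)
      anchor <- (dyad_offsets[start_idx] + dyad_offsets[end_idx]) / 2
      side <- sample(c(-1, 1), length(nuc), replace = TRUE)
      center_mid <- c_start[origin[nuc]] + g$center_width / 2
      half <- g$center_width / 2
      mid[nuc] <- center_mid + side * (half + anchor) +
        rnorm(length(nuc), 0, g$dyad_sd)
    }
    frag_chrom <- chroms[origin]
    frag_mid <- mid
    frag_comp <- comp
    frag_origin <- origin
  }

  if (n_bg > 0L) {
    chrom_prob <- layout / genome_bp
    bg_chrom <- sample(names(layout), n_bg, replace = TRUE, prob = chrom_prob)
    bg_mid <- runif(n_bg, 1, unname(layout[bg_chrom]))
    bg_comp <- sample.int(4L, n_bg, replace = TRUE, prob = comp_prior)
    frag_chrom <- c(frag_chrom, bg_chrom)
    frag_mid <- c(frag_mid, bg_mid)
    frag_comp <- c(frag_comp, bg_comp)
    frag_origin <- c(frag_origin, integer(n_bg))
  }

  len <- .draw_lengths(frag_comp, mixture_truth)
  start <- as.integer(round(frag_mid - len / 2))
  chrom_len <- unname(layout[frag_chrom])
  start <- pmax(1L, pmin(start, as.integer(chrom_len - len)))
  fragments <- GenomicRanges::GRanges(
    frag_chrom, IRanges::IRanges(start = start, width = len),
    component = c("nfr", "mono", "di", "tri")[frag_comp],
    origin = frag_origin,
    seqinfo = .layout_seqinfo(layout))

  if (dup_rate > 0) {
    n_dup <- as.integer(round(dup_rate * length(fragments)))
    if (n_dup > 0L) {
      fragments <- c(fragments,
                     fragments[sample.int(length(fragments), n_dup)])
    }
  }
  fragments <- sort(fragments)

  bam <- NULL
  if (!is.null(bam_path)) {
    bam <- write_fragments_bam(fragments, layout, bam_path)
  }

  structure(list(fragments = fragments, centers = centers,
                 nucleosomes = nucleosomes, layout = layout,
                 mixture = mixture_truth, geometry = g, bam = bam),
            class = "sim_truth")
}

#' Write fragments as a sorted, indexed paired-end BAM
#'
#' Each fragment becomes a properly-paired read pair (MAPQ 60): a forward
#' read at the fragment start and a reverse mate ending at the fragment end,
#' with template length equal to the fragment length. Coordinates-only
#' simulation: no base sequences are generated.
#'
#' @param fragments a `GRanges` of fragments.
#' @param layout named vector of chromosome lengths.
#' @param bam_path destination path (".bam" appended if missing).
#' @return the BAM path, invisibly.
#' @export
write_fragments_bam <- function(fragments, layout, bam_path) {
  .check_layout(layout)
  if (!grepl("\\.bam$", bam_path)) bam_path <- paste0(bam_path, ".bam")
  sam_path <- tempfile(fileext = ".sam")
  on.exit(unlink(sam_path))
  chrom <- as.character(seqnames(fragments))
  start <- BiocGenerics::start(fragments)
  len <- BiocGenerics::width(fragments)
  rl <- pmin(50L, len)
  mate_pos <- start + len - rl
  qname <- sprintf("frag%08d", seq_along(fragments))
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(layout), as.integer(layout))
  )
  fwd <- sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t*\t*",
                 qname, chrom, start, rl, mate_pos, len)
  rev <- sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t*\t*",
                 qname, chrom, mate_pos, rl, start, -len)
  writeLines(c(header, fwd, rev), sam_path)
  dest <- sub("\\.bam$", "", bam_path)
  out <- Rsamtools::asBam(sam_path, dest, overwrite = TRUE,
                          indexDestination = TRUE)
  invisible(out)
}

#' Per-bin truth state labels for a simulated dataset
#'
#' Bins overlapping a planted NFR core are labeled `center`, remaining bins
#' overlapping a flanking nucleosome span `nucleosome`, and everything else
#' `background`. Used as the oracle for genome-decoding accuracy.
#'
#' @param truth a `sim_truth` from [simulate_dataset()].
#' @param bin_size bin width in bp.
#' @return named list (per chromosome) of character label vectors.
#' @export
truth_state_labels <- function(truth, bin_size = 10) {
  stopifnot(inherits(truth, "sim_truth"))
  out <- lapply(names(truth$layout), function(chrom) {
    len <- truth$layout[[chrom]]
    bins <- .bin_ranges(len, bin_size)
    lab <- rep("background", length(bins))
    nuc <- truth$nucleosomes[as.character(seqnames(truth$nucleosomes)) == chrom]
    cen <- truth$centers[as.character(seqnames(truth$centers)) == chrom]
    if (length(nuc) > 0L) {
      lab[unique(queryHits(IRanges::findOverlaps(bins, ranges(nuc))))] <-
        "nucleosome"
    }
    if (length(cen) > 0L) {
      lab[unique(queryHits(IRanges::findOverlaps(bins, ranges(cen))))] <-
        "center"
    }
    lab
  })
  names(out) <- names(truth$layout)
  out
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "sim_truth: %d fragment(s), %d planted region(s) on %d chromosome(s)\n",
    length(x$fragments), length(x$centers), length(x$layout)))
  invisible(x)
}
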