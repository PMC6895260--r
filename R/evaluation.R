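#' Base-pair overlap counts between predictions and truth sets
#'
#' Inputs are coalesced (self-overlaps merged) before counting, then: TP is
#' the number of base pairs shared by predictions and positives, FP the base
#' pairs shared by predictions and negatives, PP/RP/RN the total base pairs
#' of each merged set.
#'
#' @param predictions,positives,negatives `GRanges` interval sets.
#' @return a named list with integer fields `TP`, `FP`, `PP`, `RP`, `RN`.
#' @export
basepair_counts <- function(predictions, positives, negatives) {
  pred <- GenomicRanges::reduce(GenomicRanges::granges(predictions))
  pos <- GenomicRanges::reduce(GenomicRanges::granges(positives))
  neg <- GenomicRanges::reduce(GenomicRanges::granges(negatives))
  bp <- function(x) sum(as.numeric(BiocGenerics::width(x)))
  list(
    TP = bp(GenomicRanges::intersect(pred, pos)),
    FP = bp(GenomicRanges::intersect(pred, neg)),
    PP = bp(pred),
    RP = bp(pos),
    RN = bp(neg)
  )
}

#' Merge nearby intervals into single regions
#'
#' Clusters of intervals lying within `gap` bp of each other are merged into
#' one region — the standard preprocessing applied to gold-standard sets
#' whose member sites cluster under broad enrichment.
#'
#' @param intervals a `GRanges`.
#' @param gap maximum separation to merge across (bp, default 2000).
#' @return a reduced `GRanges`.
#' @export
merge_nearby <- function(intervals, gap = 2000) {
  GenomicRanges::reduce(GenomicRanges::granges(intervals),
                        min.gapwidth = gap + 1L)
}

#' Precision, recall and false positive rate from base-pair counts
#'
#' PPV = TP/(TP+FP), TPR = TP/RP, FPR = FP/RN. Degenerate denominators are
#' defined as: TPR and FPR are 0 when their denominator is 0; PPV is 1 when
#' no base pair is predicted (PP = 0).
#'
#' @param counts a list from [basepair_counts()].
#' @return named numeric vector `c(ppv, tpr, fpr)`.
#' @export
prf <- function(counts) {
  tp <- counts$TP; fp <- counts$FP
  ppv <- if (counts$PP == 0) 1 else if (tp + fp == 0) 1 else tp / (tp + fp)
  tpr <- if (counts$RP == 0) 0 else tp / counts$RP
  fpr <- if (counts$RN == 0) 0 else fp / counts$RN
  c(ppv = ppv, tpr = tpr, fpr = fpr)
}

#' Sweep score cutoffs to build a performance curve
#'
#' For each cutoff, peaks with score at or above the cutoff are kept and
#' PPV/TPR/FPR are computed at base-pair resolution.
#'
#' @param peaks_with_scores `GRanges` with a numeric `score` column.
#' @param positives,negatives `GRanges` truth sets.
#' @param cutoffs numeric score cutoffs (default the decade 0, 5, ..., 45).
#' @return a data.frame with one row per cutoff: `cutoff`, `ppv`, `tpr`,
#'   `fpr`, `pp_bp`.
#' @export
sweep_cutoffs <- function(peaks_with_scores, positives, negatives,
                          cutoffs = seq(0, 45, by = 5)) {
  stopifnot(!is.null(mcols(peaks_with_scores)$score))
  rows <- lapply(cutoffs, function(ct) {
    kept <- peaks_with_scores[mcols(peaks_with_scores)$score >= ct]
    counts <- basepair_counts(kept, positives, negatives)
    p <- prf(counts)
    data.frame(cutoff = ct, ppv = p[["ppv"]], tpr = p[["tpr"]],
               fpr = p[["fpr"]], pp_bp = counts$PP)
  })
  do.call(rbind, rows)
}

#' Area under a ROC or PR curve with extreme points appended
#'
#' The measured points only span the cutoffs actually evaluated, so the
#' unreachable ends of each curve are completed before integration: for ROC,
#' the points (FPR 0, TPR 0) and (FPR 1, TPR 1); for PR, the points (TPR 0,
#' PPV 1) and (TPR 1, PPV = L_true / (L_true + L_false)), the precision of a
#' predictor that returns everything. Points are sorted by (x, y) and
#' integrated with trapezoids; points sharing an x-coordinate form a
#' vertical segment that contributes no area.
#'
#' @param points data.frame with columns `tpr`, `fpr`, `ppv` (as from
#'   [sweep_cutoffs()]); may be empty.
#' @param kind `"roc"` or `"pr"`.
#' @param L_true,L_false total base pairs of the positive and negative sets
#'   (required for `kind = "pr"`).
#' @return the area under the extreme-augmented curve.
#' @export
auc_with_extremes <- function(points, kind = c("roc", "pr"),
                              L_true = NULL, L_false = NULL) {
  kind <- match.arg(kind)
  if (kind == "roc") {
    x <- c(points$fpr, 0, 1)
    y <- c(points$tpr, 0, 1)
  } else {
    if (is.null(L_true) || is.null(L_false)) {
      stop("PR curves need L_true and L_false for the endpoint precision")
    }
    x <- c(points$tpr, 0, 1)
    y <- c(points$ppv, 1, L_true / (L_true + L_false))
  }
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Evaluate a scored peak set against positive/negative truth intervals
#'
#' Convenience wrapper: sweeps the cutoffs, then integrates the ROC and PR
#' curves with extreme points.
#'
#' @inheritParams sweep_cutoffs
#' @return a list with `curve` (the cutoff sweep), `auc_roc` and `auc_pr`.
#' @export
evaluate_peaks <- function(peaks_with_scores, positives, negatives,
                           cutoffs = seq(0, 45, by = 5)) {
  curve <- sweep_cutoffs(peaks_with_scores, positives, negatives, cutoffs)
  lt <- sum(as.numeric(BiocGenerics::width(GenomicRanges::reduce(
    GenomicRanges::granges(positives)))))
  lf <- sum(as.numeric(BiocGenerics::width(GenomicRanges::reduce(
    GenomicRanges::granges(negatives)))))
  list(curve = curve,
       auc_roc = auc_with_extremes(curve, "roc"),
       auc_pr = auc_with_extremes(curve, "pr", L_true = lt, L_false = lf))
}
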