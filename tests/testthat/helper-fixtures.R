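suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# Build a tiny paired-end BAM from a table of fragments
# (chrom, start0, end0, mapq_fwd, mapq_rev). Returns the BAM path.
make_pair_bam <- function(frags, layout = c(chr1 = 100000),
                          path = tempfile(fileext = ".bam")) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(layout), as.integer(layout)))
  recs <- character(0)
  if (nrow(frags) > 0) {
    for (i in seq_len(nrow(frags))) {
      chrom <- frags$chrom[i]
      start1 <- frags$start0[i] + 1L
      len <- frags$end0[i] - frags$start0[i]
      rl <- min(30L, len)
      mpos <- start1 + len - rl
      qn <- sprintf("q%03d", i)
      recs <- c(recs,
        sprintf("%s\t99\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t*\t*",
                qn, chrom, start1, frags$mapq_fwd[i], rl, mpos, len),
        sprintf("%s\t147\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t*\t*",
                qn, chrom, mpos, frags$mapq_rev[i], rl, start1, -len))
    }
  }
  sam <- tempfile(fileext = ".sam")
  writeLines(c(header, recs), sam)
  out <- Rsamtools::asBam(sam, sub("\\.bam$", "", path), overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  out
}

# Random hmm_spec with diagonal-dominant transitions and separated means.
rand_hmm_spec <- function(k = 3, d = 4) {
  trans <- matrix(runif(k * k), k)
  trans <- trans / rowSums(trans)
  init <- runif(k); init <- init / sum(init)
  means <- matrix(runif(k * d, 0, 5), k, d)
  covs <- replicate(k, {
    a <- matrix(runif(d * d, -0.2, 0.2), d)
    crossprod(a) + diag(runif(d, 0.5, 1.5))
  }, simplify = FALSE)
  hmm_spec(init, trans, means, covs)
}

# Exhaustive-enumeration Viterbi oracle: scores every possible state path.
brute_viterbi <- function(spec, obs) {
  k <- spec$n_states
  n <- nrow(obs)
  logb <- vapply(seq_len(k), function(j) {
    q <- t(obs) - spec$means[j, ]
    -0.5 * ncol(obs) * log(2 * pi) -
      0.5 * log(det(spec$covs[[j]])) -
      0.5 * colSums(solve(spec$covs[[j]], q) * q)
  }, numeric(n))
  if (n == 1L) logb <- matrix(logb, nrow = 1L)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  score <- log(spec$initial)[paths[, 1L]] + logb[cbind(1L, paths[, 1L])]
  if (n > 1L) {
    for (t in 2:n) {
      score <- score + log(spec$trans)[cbind(paths[, t - 1L], paths[, t])] +
        logb[cbind(t, paths[, t])]
    }
  }
  # first index among ties matches the decoder's lowest-state tie rule only
  # if enumeration order does; compare by score instead where needed
  as.integer(paths[which.max(score), ])
}

# Sample an observation sequence from a known HMM.
sample_hmm <- function(trans, means, sds, n, init = NULL) {
  k <- nrow(trans)
  if (is.null(init)) init <- rep(1 / k, k)
  s <- integer(n)
  s[1] <- sample.int(k, 1, prob = init)
  for (t in seq_len(n - 1L) + 1L) {
    s[t] <- sample.int(k, 1, prob = trans[s[t - 1L], ])
  }
  d <- ncol(means)
  obs <- matrix(rnorm(n * d, mean = t(means[s, ]), sd = t(sds[s, ])),
                n, d, byrow = TRUE)
  list(states = s, obs = obs)
}

# Random interval set on one chromosome (1-based closed GRanges).
rand_intervals <- function(n, chrom_len = 10000, max_w = 400,
                           chrom = "chr1") {
  start <- sample.int(chrom_len - max_w, n, replace = TRUE)
  w <- sample.int(max_w, n, replace = TRUE)
  GRanges(chrom, IRanges(start = start, width = w))
}

# Per-bp bitmap oracle for base-pair overlap counts on one chromosome.
bitmap_counts <- function(pred, pos, neg, chrom_len = 10000) {
  paint <- function(gr) {
    v <- logical(chrom_len)
    for (i in seq_along(gr)) {
      v[start(gr)[i]:min(end(gr)[i], chrom_len)] <- TRUE
    }
    v
  }
  p <- paint(pred); tps <- paint(pos); ngs <- paint(neg)
  list(TP = sum(p & tps), FP = sum(p & ngs),
       PP = sum(p), RP = sum(tps), RN = sum(ngs))
}

# Coverage track built directly from vectors (for training-module tests).
make_coverage <- function(values, bin_size = 10, chrom = "chr1") {
  if (!is.list(values)) values <- stats::setNames(list(values), chrom)
  layout <- vapply(values, function(v) length(v) * bin_size, numeric(1))
  structure(list(bin_size = bin_size, coverage = values, layout = layout),
            class = "coverage_track")
}

# State annotation built from a run-length description, e.g.
# make_annotation(c(background = 500, nucleosome = 300, center = 600)).
make_annotation <- function(run_widths, chrom = "chr1", offset = 0L) {
  ends <- cumsum(run_widths) + offset
  starts <- ends - run_widths + 1L
  GRanges(chrom, IRanges(starts, ends),
          state = NA_integer_, role = names(run_widths))
}
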