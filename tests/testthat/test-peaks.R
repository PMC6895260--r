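# Independent peak-assembly oracle: scan the run sequence directly.
brute_assemble <- function(runs, min_center_length) {
  role <- mcols(runs)$role
  n <- length(runs)
  retained <- which(role == "center" & width(runs) > min_center_length)
  if (length(retained) == 0L) return(IRanges())
  # grow each retained center through contiguous nucleosome/center runs
  spans <- lapply(retained, function(i) {
    lo <- i
    while (lo - 1L >= 1L && role[lo - 1L] %in% c("nucleosome", "center") &&
           end(runs)[lo - 1L] + 1L == start(runs)[lo]) lo <- lo - 1L
    hi <- i
    while (hi + 1L <= n && role[hi + 1L] %in% c("nucleosome", "center") &&
           start(runs)[hi + 1L] == end(runs)[hi] + 1L) hi <- hi + 1L
    # trim to the nucleosome immediately flanking the outermost retained center
    lo2 <- min(retained[retained >= lo & retained <= hi])
    hi2 <- max(retained[retained >= lo & retained <= hi])
    if (lo2 - 1L >= lo && role[lo2 - 1L] == "nucleosome") lo2 <- lo2 - 1L
    if (hi2 + 1L <= hi && role[hi2 + 1L] == "nucleosome") hi2 <- hi2 + 1L
    IRanges(start(runs)[lo2], end(runs)[hi2])
  })
  unique(do.call(c, spans))
}

test_that("a center run flanked by nucleosome runs forms one three-block peak", {
  ann <- make_annotation(c(background = 500, nucleosome = 300, center = 600,
                           nucleosome = 300, background = 800))
  peaks <- assemble_peaks(ann, min_center_length = 200)
  expect_length(peaks, 1L)
  expect_equal(start(peaks), 501L)
  expect_equal(end(peaks), 1700L)
  blocks <- mcols(peaks)$blocks[[1]]
  expect_equal(mcols(blocks)$role, c("nucleosome", "center", "nucleosome"))
  expect_equal(sum(width(blocks)), width(peaks))
})

test_that("short center runs are filtered and the filter is strict", {
  ann <- make_annotation(c(background = 500, nucleosome = 300, center = 150,
                           nucleosome = 300, background = 800))
  expect_length(assemble_peaks(ann, min_center_length = 200), 0L)
  # exactly at the threshold is still excluded (length must exceed it)
  ann2 <- make_annotation(c(background = 500, nucleosome = 300, center = 200,
                            nucleosome = 300, background = 800))
  expect_length(assemble_peaks(ann2, min_center_length = 200), 0L)
  expect_length(assemble_peaks(ann2, min_center_length = 199), 1L)
})

test_that("centers separated only by nucleosomes coalesce; flankless centers flagged", {
  ann <- make_annotation(c(background = 200, nucleosome = 100, center = 300,
                           nucleosome = 150, center = 400, nucleosome = 100,
                           background = 500, center = 250, background = 100))
  peaks <- assemble_peaks(ann, min_center_length = 200)
  expect_length(peaks, 2L)
  expect_equal(width(peaks)[1], 100 + 300 + 150 + 400 + 100)
  expect_match(mcols(peaks)$name[2], "noflank")
  expect_equal(width(peaks)[2], 250)
})

test_that("assembly equals a brute-force scan on random annotations", {
  set.seed(47)
  for (rep in 1:40) {
    n <- sample(5:25, 1)
    roles <- sample(c("background", "nucleosome", "center", "masked"),
                    n, TRUE, prob = c(.4, .25, .25, .1))
    # merge adjacent duplicates to honor the run-length invariant
    keep <- c(TRUE, roles[-1] != roles[-n])
    roles <- roles[keep]
    widths <- sample(c(50, 150, 250, 400), length(roles), TRUE)
    ann <- make_annotation(stats::setNames(widths, roles))
    got <- assemble_peaks(ann, min_center_length = 200)
    want <- brute_assemble(ann, 200)
    expect_equal(ranges(got), unname(want))
  }
})

test_that("raising the center-length threshold never increases the peak count", {
  set.seed(53)
  roles <- rep(c("background", "nucleosome", "center", "nucleosome"), 30)
  widths <- sample(c(100, 180, 220, 500), length(roles), TRUE)
  ann <- make_annotation(stats::setNames(widths, roles))
  counts <- vapply(c(0, 100, 200, 300, 600), function(ml) {
    length(assemble_peaks(ann, min_center_length = ml))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("peak score is the max coverage restricted to center blocks", {
  ann <- make_annotation(c(background = 500, nucleosome = 300, center = 600,
                           nucleosome = 300, background = 300))
  peaks <- assemble_peaks(ann, 200)
  flat <- make_coverage(rep(3, 200), bin_size = 10)
  expect_equal(score_peak(peaks[1], flat), 3)

  v <- rep(1, 200)
  v[60] <- 50     # inside the left nucleosome block (bp 591-600)
  v[100] <- 7     # inside the center block
  cov <- make_coverage(v, bin_size = 10)
  expect_equal(score_peak(peaks[1], cov), 7)

  set.seed(59)
  v2 <- runif(200, 0, 20)
  cov2 <- make_coverage(v2, bin_size = 10)
  expect_equal(score_peak(peaks[1], cov2), max(v2[81:140]))
})

test_that("summits sit at the smoothed coverage maximum, leftmost on ties", {
  ann <- make_annotation(c(background = 500, nucleosome = 300, center = 600,
                           nucleosome = 300, background = 300))
  peaks <- assemble_peaks(ann, 200)
  # symmetric triangle over the center block bins 81..140, apex at bin 110
  v <- rep(0, 200)
  v[81:140] <- 30 - abs(seq(81, 140) - 110)
  expect_equal(call_summit(peaks[1], make_coverage(v, 10)), (110 - 1) * 10 + 1)

  flat <- make_coverage(rep(2, 200), 10)
  expect_equal(call_summit(peaks[1], flat), 801)   # center block start

  # noisy two-bump profile vs a literal smoothed-argmax oracle
  set.seed(67)
  v2 <- rep(0, 200)
  v2[81:140] <- 5 + 4 * sin(seq(0, 3 * pi, length.out = 60)) + rnorm(60, 0, .5)
  got <- call_summit(peaks[1], make_coverage(v2, 10), smooth_window = 120)
  kern <- dnorm(-6:6, sd = 2)
  seg <- v2[81:140]
  sm <- vapply(seq_along(seg), function(i) {
    idx <- (i - 6):(i + 6)
    ok <- idx >= 1 & idx <= length(seg)
    sum(kern[ok] * seg[idx[ok]]) / sum(kern[ok])
  }, numeric(1))
  expect_equal(got, (81 + which.max(sm) - 2) * 10 + 1)
})

test_that("gappedPeak records satisfy the block arithmetic and round-trip", {
  ann <- make_annotation(c(background = 500, nucleosome = 300, center = 600,
                           nucleosome = 300, background = 300))
  peaks <- score_peaks(assemble_peaks(ann, 200),
                       make_coverage(rep(4, 200), 10))
  path <- tempfile(fileext = ".gappedPeak")
  write_gappedpeak(peaks, path)
  fields <- strsplit(readLines(path), "\t")[[1]]
  expect_length(fields, 15L)
  expect_equal(as.integer(fields[10]), 3L)                  # blockCount
  expect_equal(strsplit(fields[12], ",")[[1]][1], "0")      # blockStarts[0]
  sizes <- as.integer(strsplit(fields[11], ",")[[1]])
  expect_equal(sum(sizes), as.integer(fields[3]) - as.integer(fields[2]))

  back <- read_gappedpeak(path)
  expect_equal(ranges(back), ranges(peaks))
  expect_equal(mcols(back)$score, mcols(peaks)$score)
  expect_equal(ranges(mcols(back)$blocks[[1]]),
               ranges(mcols(peaks)$blocks[[1]]))

  # corrupting the block structure trips the writer's assertion
  broken <- peaks
  blocks <- mcols(broken)$blocks[[1]]
  start(blocks)[1] <- start(blocks)[1] + 5L
  mcols(broken)$blocks[[1]] <- blocks
  expect_error(write_gappedpeak(broken, tempfile()), "block")
})

test_that("summit BED is written per peak with matched names", {
  ann <- make_annotation(c(background = 500, nucleosome = 300, center = 600,
                           nucleosome = 300, background = 300))
  peaks <- call_summits(score_peaks(assemble_peaks(ann, 200),
                                    make_coverage(rep(4, 200), 10)),
                        make_coverage(rep(4, 200), 10))
  path <- tempfile(fileext = ".bed")
  write_summits(peaks, path)
  got <- read.table(path, sep = "\t")
  expect_equal(nrow(got), 1L)
  expect_equal(got$V3 - got$V2, 1)
  expect_match(got$V4, "^peak_1_summit$")
})
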