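# Wrap a plain observation matrix in a signal_tracks so the k-means and
# decoding entry points can be exercised directly.
tracks_from_matrix <- function(m, bin_size = 10, chrom = "chr1") {
  structure(list(bin_size = bin_size, transformed = TRUE,
                 signal = stats::setNames(list(m), chrom),
                 layout = stats::setNames(nrow(m) * bin_size, chrom)),
            class = "signal_tracks")
}

test_that("k-means initialization recovers well-separated cluster centers", {
  set.seed(61)
  centers <- rbind(c(0, 0, 0, 0), c(4, 4, 1, 1), c(8, 8, 8, 8))
  obs <- centers[rep(1:3, each = 400), ] + matrix(rnorm(4800, 0, 0.2), 1200)
  tr <- tracks_from_matrix(obs)
  region <- GRanges("chr1", IRanges(1, 12000))
  spec <- kmeans_init(tr, region, k = 3, seed = 9)
  got <- spec$means[order(rowSums(spec$means)), ]
  expect_lt(max(abs(got - centers)), 0.1)
  expect_equal(spec$initial, rep(1 / 3, 3))
  expect_equal(spec$trans, matrix(1 / 3, 3, 3))

  again <- kmeans_init(tr, region, k = 3, seed = 9)
  expect_identical(spec, again)
})

test_that("k-means on exactly k distinct repeated vectors hits them exactly", {
  obs <- rbind(matrix(1, 20, 4), matrix(5, 20, 4), matrix(9, 20, 4))
  tr <- tracks_from_matrix(obs)
  spec <- kmeans_init(tr, GRanges("chr1", IRanges(1, 600)), k = 3, seed = 1)
  expect_setequal(spec$means[, 1], c(1, 5, 9))
  for (j in 1:3) expect_equal(spec$covs[[j]], diag(1e-4, 4))
  expect_error(kmeans_init(tracks_from_matrix(matrix(1, 10, 4)),
                           GRanges("chr1", IRanges(1, 100)), k = 3),
               "distinct")
})

test_that("Viterbi matches exhaustive path enumeration on random instances", {
  set.seed(77)
  for (rep in 1:60) {
    k <- 3
    n <- sample(1:8, 1)
    spec <- rand_hmm_spec(k)
    obs <- matrix(rnorm(n * 4, 0, 3), n, 4)
    got <- viterbi(spec, obs)
    want <- brute_viterbi(spec, obs)
    expect_equal(got, want)
  }
})

test_that("Viterbi handles the trivial cases", {
  spec <- rand_hmm_spec(3)
  obs <- matrix(rnorm(4), 1, 4)
  lp <- log(spec$initial) + vapply(1:3, function(j) {
    q <- obs[1, ] - spec$means[j, ]
    -2 * log(2 * pi) - 0.5 * log(det(spec$covs[[j]])) -
      0.5 * sum(solve(spec$covs[[j]], q) * q)
  }, numeric(1))
  expect_equal(viterbi(spec, obs), which.max(lp))

  # near-identity transitions + observations at one state's mean: constant path
  sticky <- hmm_spec(rep(1 / 3, 3),
                     diag(0.97, 3) + 0.01,
                     rbind(c(0, 0, 0, 0), c(5, 5, 5, 5), c(10, 10, 10, 10)),
                     replicate(3, diag(1, 4), simplify = FALSE))
  obs2 <- matrix(5, 30, 4)
  expect_equal(viterbi(sticky, obs2), rep(2L, 30))
})

test_that("Baum-Welch improves likelihood monotonically and recovers transitions", {
  set.seed(83)
  A <- rbind(c(.85, .1, .05), c(.1, .8, .1), c(.05, .15, .8))
  mu <- rbind(c(0, 0, 0, 0), c(3, 3, 1, 1), c(6, 6, 6, 6))
  sds <- matrix(1, 3, 4)
  segs <- lapply(1:30, function(i) sample_hmm(A, mu, sds, 120)$obs)
  init <- hmm_spec(rep(1 / 3, 3), matrix(1 / 3, 3, 3),
                   mu + matrix(rnorm(12, 0, 0.3), 3),
                   replicate(3, diag(2, 4), simplify = FALSE))
  fit <- baum_welch(init, segs, max_iter = 50, tol = 1e-4)
  ll <- attr(fit, "loglik")
  expect_true(all(diff(ll) > -1e-6))
  expect_lt(max(abs(fit$trans - A)), 0.05)
  expect_equal(fit$initial, init$initial)   # initial probs never updated
})

test_that("Baum-Welch with an infinite tolerance performs zero updates", {
  set.seed(85)
  spec <- rand_hmm_spec(3)
  segs <- list(matrix(rnorm(80), 20, 4))
  out <- baum_welch(spec, segs, tol = Inf)
  expect_equal(attr(out, "iterations"), 0L)
  expect_equal(out$trans, spec$trans)
  expect_equal(out$means, spec$means)
})

test_that("Baum-Welch agrees with an independent reference implementation", {
  set.seed(99)
  A <- rbind(c(.9, .05, .05), c(.1, .8, .1), c(.05, .15, .8))
  mu <- rbind(c(0, 0, 0, 0), c(3, 3, 1, 1), c(6, 6, 6, 6))
  segs <- lapply(1:8, function(i) sample_hmm(A, mu, matrix(1, 3, 4), 120)$obs)
  init <- hmm_spec(rep(1 / 3, 3), matrix(1 / 3, 3, 3),
                   mu + matrix(rnorm(12, 0, 0.3), 3),
                   replicate(3, diag(1.5, 4), simplify = FALSE))
  fit <- baum_welch(init, segs, max_iter = 5, tol = 0)

  dump <- tempfile(fileext = ".json")
  outj <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(segs = lapply(segs, unname), init_trans = init$trans,
         init_means = init$means, init_covs = init$covs),
    dump, digits = NA, matrix = "rowmajor")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys, numpy as np",
    "from hmmlearn.hmm import GaussianHMM",
    "o = json.load(open(sys.argv[1]))",
    "segs = [np.array(s) for s in o['segs']]",
    "X = np.vstack(segs); lengths = [len(s) for s in segs]",
    "m = GaussianHMM(n_components=3, covariance_type='full', n_iter=5,",
    "                tol=0, init_params='', params='tmc',",
    "                implementation='scaling')",
    "m.startprob_ = np.ones(3)/3",
    "m.transmat_ = np.array(o['init_trans'])",
    "m.means_ = np.array(o['init_means'])",
    "m.covars_ = np.array(o['init_covs'])",
    "m.fit(X, lengths)",
    "json.dump({'trans': m.transmat_.tolist(),",
    "           'll': list(m.monitor_.history)}, open(sys.argv[2], 'w'))"
  ), script)
  status <- system2("python", c(script, dump, outj))
  expect_equal(status, 0L)
  ref <- jsonlite::read_json(outj, simplifyVector = TRUE)
  expect_equal(max(abs(fit$trans - ref$trans)), 0, tolerance = 1e-3)
  expect_equal(attr(fit, "loglik"), ref$ll, tolerance = 1e-4)
})

test_that("state roles follow overall emission enrichment, invariant to relabeling", {
  mk <- function(means) {
    hmm_spec(rep(1 / 3, 3), matrix(1 / 3, 3, 3), means,
             replicate(3, diag(1, 4), simplify = FALSE))
  }
  means <- rbind(c(2.5, 2.5, 2.5, 2.5), c(1, 1, 1, 1), c(0.1, 0.2, 0.1, 0.1))
  spec <- assign_state_roles(mk(means))
  expect_equal(spec$roles, c("center", "nucleosome", "background"))

  perm <- c(3, 1, 2)
  spec2 <- assign_state_roles(mk(means[perm, ]))
  expect_equal(spec2$roles, spec$roles[perm])

  # center not dominating one dimension triggers the model-sanity warning
  bad <- rbind(c(9, 1, 1, 1), c(1, 5, 5, 5), c(0, 0, 0, 0))
  expect_warning(assign_state_roles(mk(bad)), "stringent")
})

test_that("high-coverage masking finds extreme bins and merges the blacklist", {
  expect_length(mask_high_coverage(make_coverage(rep(2, 500))), 0L)

  v <- rep(1, 1000); v[301] <- 1e4
  masked <- mask_high_coverage(make_coverage(v), zscore_cutoff = 10)
  expect_length(masked, 1L)
  expect_equal(start(masked), 3001)
  expect_equal(end(masked), 3010)

  bl <- GRanges("chr1", IRanges(3011, 3500))
  both <- mask_high_coverage(make_coverage(v), zscore_cutoff = 10,
                             blacklist = bl)
  expect_length(both, 1L)            # adjacent intervals merge
  expect_equal(width(both), 500)

  # brute-force z computation oracle
  set.seed(19)
  v2 <- rexp(2000, 1 / 2)
  cut <- 2
  got <- mask_high_coverage(make_coverage(v2), zscore_cutoff = cut)
  idx <- which((v2 - mean(v2)) / stats::sd(v2) > cut)
  oracle <- reduce(IRanges(start = (idx - 1) * 10 + 1, width = 10))
  expect_equal(ranges(got), oracle)
})

test_that("windowed decoding is consistent and respects masks", {
  set.seed(29)
  A <- rbind(c(.95, .04, .01), c(.05, .9, .05), c(.01, .09, .9))
  mu <- rbind(c(0, 0, 0, 0), c(2, 2, 1, 1), c(5, 5, 4, 4))
  sim <- sample_hmm(A, mu, matrix(0.7, 3, 4), 400)
  spec <- assign_state_roles(
    hmm_spec(rep(1 / 3, 3), A, mu, replicate(3, diag(0.5, 4),
                                             simplify = FALSE)))
  tr <- tracks_from_matrix(sim$obs)

  one <- decode_genome(spec, tr, window_bins = 400)
  whole <- viterbi(spec, sim$obs)
  per_bin <- rep(mcols(one)$state, width(one) / 10)
  expect_equal(per_bin, whole)

  # a mask splits the chromosome: decode equals two independent decodes
  mask <- GRanges("chr1", IRanges(2001, 2200))   # bins 201-220
  ann <- decode_genome(spec, tr, masked = mask)
  left <- viterbi(spec, sim$obs[1:200, , drop = FALSE])
  right <- viterbi(spec, sim$obs[221:400, , drop = FALSE])
  per_bin2 <- rep(mcols(ann)$state, width(ann) / 10)
  expect_equal(per_bin2[1:200], left)
  expect_equal(per_bin2[221:400], right)
  expect_true(all(is.na(per_bin2[201:220])))
  expect_equal(unique(mcols(ann)$role[is.na(mcols(ann)$state)]), "masked")

  expect_error(decode_genome(spec, tr, window_bins = 1), "at least 2")
})

test_that("model JSON serialization round-trips", {
  set.seed(37)
  spec <- suppressWarnings(assign_state_roles(rand_hmm_spec(3)))
  path <- tempfile(fileext = ".json")
  write_model(spec, path)
  back <- read_model(path)
  expect_equal(back$trans, spec$trans)
  expect_equal(back$means, spec$means)
  expect_equal(back$covs, spec$covs)
  expect_equal(back$roles, spec$roles)
  expect_equal(back$initial, spec$initial)
})
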