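#' Construct a hidden Markov model specification
#'
#' The model has `k` hidden states with multivariate Gaussian emissions over
#' the 4-dimensional signal vector (nfr, mono, di, tri). Initial state
#' probabilities are held fixed during training.
#'
#' @param initial simplex vector of initial state probabilities.
#' @param trans row-stochastic transition matrix.
#' @param means k x 4 matrix of emission means.
#' @param covs list of k 4x4 emission covariance matrices.
#' @param roles optional character vector mapping each state to
#'   `"background"`, `"nucleosome"` or `"center"`.
#' @return an object of class `hmm_spec`.
#' @export
hmm_spec <- function(initial, trans, means, covs, roles = NULL) {
  k <- length(initial)
  stopifnot(nrow(trans) == k, ncol(trans) == k,
            nrow(means) == k, length(covs) == k)
  if (abs(sum(initial) - 1) > 1e-9) stop("initial probabilities must sum to 1")
  if (any(abs(rowSums(trans) - 1) > 1e-9)) {
    stop("transition matrix rows must sum to 1")
  }
  for (j in seq_len(k)) {
    if (any(abs(covs[[j]] - t(covs[[j]])) > 1e-8)) {
      stop("emission covariance ", j, " is not symmetric")
    }
  }
  structure(list(n_states = k, initial = as.numeric(initial),
                 trans = unname(as.matrix(trans)),
                 means = unname(as.matrix(means)), covs = covs,
                 roles = roles),
            class = "hmm_spec")
}

#' @export
print.hmm_spec <- function(x, ...) {
  cat(sprintf("hmm_spec: %d states, %d-d Gaussian emissions\n",
              x$n_states, ncol(x$means)))
  if (!is.null(x$roles)) cat("  roles:", paste(x$roles, collapse = ", "), "\n")
  invisible(x)
}

# Cholesky-based log density of a multivariate Gaussian, with diagonal
# regularization (+1e-4, repeated) when the covariance is not positive
# definite.
.regularize_chol <- function(cov, reg = 1e-4) {
  for (i in 0:6) {
    ch <- tryCatch(chol(cov + diag(reg * (2^i - 1), nrow(cov))),
                   error = function(e) NULL)
    if (!is.null(ch)) return(ch)
  }
  stop("emission covariance could not be regularized to positive definite")
}

.log_dmvnorm <- function(obs, mean, cov) {
  ch <- .regularize_chol(cov)
  d <- ncol(obs)
  centered <- sweep(obs, 2L, mean)
  z <- backsolve(ch, t(centered), transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

.emission_logdens <- function(spec, obs) {
  out <- vapply(seq_len(spec$n_states), function(j) {
    .log_dmvnorm(obs, spec$means[j, ], spec$covs[[j]])
  }, numeric(nrow(obs)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(obs))
  out
}

#' Initialize emission parameters by k-means clustering
#'
#' Clusters the 4-track observation vectors of the training regions into `k`
#' groups (random initialization) and uses each cluster's mean vector and
#' covariance matrix as that state's emission parameters. Initial and
#' transition probabilities are set uniform (proportional) at 1/k.
#'
#' @param tracks sqrt-transformed `signal_tracks`.
#' @param training_regions `GRanges` of training regions.
#' @param k number of states (default 3).
#' @param seed RNG seed for the clustering.
#' @param max_retries re-seeded attempts if a cluster comes back empty.
#' @return an untrained `hmm_spec` (roles unassigned).
#' @export
kmeans_init <- function(tracks, training_regions, k = 3, seed = NULL,
                        max_retries = 5) {
  obs <- do.call(rbind, segment_observations(tracks, training_regions))
  if (nrow(unique(obs)) < k) {
    stop("training regions contain fewer than ", k,
         " distinct observation vectors")
  }
  if (!is.null(seed)) set.seed(seed)
  fit <- NULL
  for (attempt in seq_len(max_retries)) {
    fit <- tryCatch(
      kmeans(obs, centers = k, nstart = 3, iter.max = 100),
      error = function(e) NULL
    )
    if (!is.null(fit) && all(tabulate(fit$cluster, k) > 0L)) break
    fit <- NULL
  }
  if (is.null(fit)) stop("k-means failed to produce ", k, " non-empty clusters")
  means <- fit$centers
  covs <- lapply(seq_len(k), function(j) {
    pts <- obs[fit$cluster == j, , drop = FALSE]
    if (nrow(pts) < 2L) {
      diag(1e-4, ncol(obs))
    } else {
      cv <- stats::cov(pts)
      # floor degenerate directions so the emission density is proper
      cv + diag(1e-4, ncol(obs))
    }
  })
  hmm_spec(initial = rep(1 / k, k),
           trans = matrix(1 / k, k, k),
           means = means, covs = covs)
}

# One scaled forward-backward pass over a single observation segment.
# Returns the log-likelihood and the sufficient statistics needed by the
# Baum-Welch M-step.
.forward_backward <- function(spec, obs) {
  n <- nrow(obs)
  k <- spec$n_states
  logb <- .emission_logdens(spec, obs)
  shift <- apply(logb, 1L, max)
  b <- exp(logb - shift)
  A <- spec$trans
  ah <- matrix(0, n, k)
  cvec <- numeric(n)
  a <- spec$initial * b[1L, ]
  cvec[1L] <- sum(a)
  ah[1L, ] <- a / cvec[1L]
  for (t in 2:n) {
    a <- as.numeric(ah[t - 1L, ] %*% A) * b[t, ]
    cvec[t] <- sum(a)
    ah[t, ] <- a / cvec[t]
  }
  bh <- matrix(0, n, k)
  bh[n, ] <- 1 / cvec[n]
  for (t in (n - 1L):1L) {
    bh[t, ] <- as.numeric(A %*% (b[t + 1L, ] * bh[t + 1L, ])) / cvec[t]
  }
  gamma <- ah * bh * cvec
  bb <- b * bh
  xi_num <- crossprod(ah[-n, , drop = FALSE], bb[-1L, , drop = FALSE]) * A
  list(loglik = sum(log(cvec)) + sum(shift),
       gamma = gamma,
       xi_num = xi_num)
}

#' Train transition and emission parameters with the Baum-Welch algorithm
#'
#' Runs EM over the supplied observation segments (one 4-track matrix per
#' training region). Initial state probabilities are not updated; transition
#' probabilities and the Gaussian emission means/covariances are re-estimated
#' each iteration. Training stops when the total log-likelihood improves by
#' less than `tol`, or after `max_iter` iterations. The per-iteration
#' log-likelihood trace is attached as attribute `"loglik"` and the number of
#' parameter updates as attribute `"iterations"`.
#'
#' @param spec an `hmm_spec` (e.g. from [kmeans_init()]).
#' @param observation_segments list of n x 4 observation matrices.
#' @param max_iter iteration cap (default 100).
#' @param tol log-likelihood convergence threshold (default 1e-3).
#' @return the trained `hmm_spec`.
#' @export
baum_welch <- function(spec, observation_segments, max_iter = 100, tol = 1e-3) {
  stopifnot(inherits(spec, "hmm_spec"), length(observation_segments) > 0L)
  observation_segments <- Filter(function(m) nrow(m) >= 2L,
                                 observation_segments)
  if (length(observation_segments) == 0L) {
    stop("no observation segment has at least 2 bins")
  }
  if (is.infinite(tol) && tol > 0) {
    attr(spec, "iterations") <- 0L
    attr(spec, "loglik") <- numeric(0)
    return(spec)
  }
  k <- spec$n_states
  d <- ncol(observation_segments[[1L]])
  ll_trace <- numeric(0)
  ll_prev <- NULL
  iters <- 0L
  for (iter in seq_len(max_iter)) {
    stats <- lapply(observation_segments, function(m) {
      .forward_backward(spec, m)
    })
    ll <- sum(vapply(stats, `[[`, numeric(1), "loglik"))
    ll_trace <- c(ll_trace, ll)
    if (!is.null(ll_prev) && ll - ll_prev < tol) break
    ll_prev <- ll
    xi_sum <- Reduce(`+`, lapply(stats, `[[`, "xi_num"))
    trans <- xi_sum / rowSums(xi_sum)
    gam_all <- do.call(rbind, lapply(stats, `[[`, "gamma"))
    obs_all <- do.call(rbind, observation_segments)
    wsum <- colSums(gam_all)
    means <- matrix(0, k, d)
    covs <- vector("list", k)
    for (j in seq_len(k)) {
      means[j, ] <- colSums(gam_all[, j] * obs_all) / wsum[j]
      centered <- sweep(obs_all, 2L, means[j, ])
      cv <- crossprod(centered * gam_all[, j], centered) / wsum[j]
      cv <- (cv + t(cv)) / 2
      covs[[j]] <- cv + diag(1e-6, d)
    }
    spec <- hmm_spec(spec$initial, trans, means, covs, roles = spec$roles)
    iters <- iter
  }
  attr(spec, "iterations") <- iters
  attr(spec, "loglik") <- ll_trace
  spec
}

#' Assign biological roles to the model states
#'
#' States are ranked by the sum of their emission mean vector: the state with
#' the highest overall enrichment of the four signals becomes the open-region
#' `center`, the lowest becomes `background`, and the state(s) in between
#' `nucleosome`. A warning is raised when the center state does not have the
#' largest mean in every one of the four signal dimensions — the model-sanity
#' symptom that calls for re-training with a more stringent fold-change band.
#'
#' @param spec an `hmm_spec`.
#' @return the `hmm_spec` with `roles` filled in.
#' @export
assign_state_roles <- function(spec) {
  stopifnot(inherits(spec, "hmm_spec"))
  k <- spec$n_states
  if (k != 3L) {
    warning("role assignment with ", k,
            " states is unsupported for peak calling; mapping only the ",
            "top state to center and the bottom to background")
  }
  tot <- rowSums(spec$means)
  ord <- order(tot)
  roles <- rep("nucleosome", k)
  roles[ord[1L]] <- "background"
  roles[ord[k]] <- "center"
  center <- ord[k]
  dominated <- all(vapply(seq_len(ncol(spec$means)), function(dim) {
    spec$means[center, dim] >= max(spec$means[, dim])
  }, logical(1)))
  if (!dominated) {
    warning("the center state does not have the highest mean in every ",
            "signal dimension; consider re-training with a more stringent ",
            "fold-change band (raise -u/-l)")
  }
  spec$roles <- roles
  spec
}

#' Most probable state path (Viterbi decoding)
#'
#' Log-space dynamic program returning the maximum-a-posteriori hidden state
#' path for an observation matrix; ties are broken toward the
#' lowest-numbered state.
#'
#' @param spec an `hmm_spec`.
#' @param observations n x 4 observation matrix.
#' @return integer vector of state indices, length n.
#' @export
viterbi <- function(spec, observations) {
  stopifnot(inherits(spec, "hmm_spec"))
  n <- nrow(observations)
  if (n == 0L) return(integer(0))
  k <- spec$n_states
  logb <- .emission_logdens(spec, observations)
  logA <- log(spec$trans)
  delta <- log(spec$initial) + logb[1L, ]
  psi <- matrix(0L, n, k)
  for (t in seq_len(n - 1L) + 1L) {
    cand <- delta + logA             # cand[i, j] = delta_i + log A_ij
    best <- max.col(t(cand), ties.method = "first")
    psi[t, ] <- best
    delta <- cand[cbind(best, seq_len(k))] + logb[t, ]
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1L) {
    for (t in (n - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  }
  path
}

#' Mask extreme-coverage bins and blacklisted intervals
#'
#' Bins whose z-scored coverage exceeds `zscore_cutoff` are merged into
#' intervals and unioned with the (optional) blacklist. These regions are
#' excised before Viterbi decoding, since a single extreme-coverage artifact
#' can derail the state path for the rest of a chromosome.
#'
#' @param coverage a `coverage_track`.
#' @param zscore_cutoff z-score threshold (default 100: only extreme
#'   artifacts mask).
#' @param blacklist optional `GRanges` of regions to always mask.
#' @return a reduced `GRanges` of masked intervals (possibly empty).
#' @export
mask_high_coverage <- function(coverage, zscore_cutoff = 100,
                               blacklist = NULL) {
  stopifnot(inherits(coverage, "coverage_track"))
  all_bins <- unlist(coverage$coverage, use.names = FALSE)
  mu <- mean(all_bins)
  sdv <- stats::sd(all_bins)
  bs <- coverage$bin_size
  masked <- GenomicRanges::GRanges()
  if (!is.na(sdv) && sdv > 0) {
    pieces <- lapply(names(coverage$coverage), function(chrom) {
      v <- coverage$coverage[[chrom]]
      hit <- (v - mu) / sdv > zscore_cutoff
      if (!any(hit)) return(NULL)
      idx <- which(hit)
      len <- coverage$layout[[chrom]]
      GenomicRanges::GRanges(
        chrom, IRanges::IRanges(start = (idx - 1L) * bs + 1L,
                                end = pmin(idx * bs, len)))
    })
    pieces <- Filter(Negate(is.null), pieces)
    if (length(pieces) > 0L) masked <- do.call(c, pieces)
  }
  if (!is.null(blacklist) && length(blacklist) > 0L) {
    bl <- GenomicRanges::GRanges(seqnames(blacklist), ranges(blacklist))
    masked <- c(masked, bl)
  }
  GenomicRanges::reduce(sort(masked))
}

#' Decode the genome into state annotations
#'
#' Runs Viterbi decoding over every chromosome of the signal tracks. Masked
#' intervals are excised (not zero-filled): decoding restarts after each
#' mask, and state runs never span one. Long chromosomes are decoded in
#' windows of `window_bins` bins; each window restarts from the initial
#' probabilities, so state is not propagated across window boundaries.
#'
#' @param spec a trained `hmm_spec` with roles assigned.
#' @param tracks sqrt-transformed `signal_tracks`.
#' @param masked optional `GRanges` from [mask_high_coverage()].
#' @param window_bins decoding window in bins (default 2,500,000 bins =
#'   25 Mb at 10-bp resolution).
#' @return a `GRanges` of merged same-state runs with metadata columns
#'   `state` (integer; `NA` in masked runs) and `role` (`"masked"` there).
#' @export
decode_genome <- function(spec, tracks, masked = NULL, window_bins = 2500000) {
  stopifnot(inherits(spec, "hmm_spec"), inherits(tracks, "signal_tracks"))
  if (is.null(spec$roles)) {
    stop("state roles are unassigned; call assign_state_roles() first")
  }
  if (window_bins < 2) stop("decoding window must be at least 2 bins")
  bs <- tracks$bin_size
  out <- list()
  for (chrom in names(tracks$signal)) {
    m <- tracks$signal[[chrom]]
    nb <- nrow(m)
    labels <- integer(nb)          # 0 = masked
    is_masked <- rep(FALSE, nb)
    if (!is.null(masked) && length(masked) > 0L) {
      on_chr <- masked[as.character(seqnames(masked)) == chrom]
      if (length(on_chr) > 0L) {
        hits <- IRanges::findOverlaps(.bin_ranges(tracks$layout[[chrom]], bs),
                                      ranges(on_chr))
        is_masked[unique(queryHits(hits))] <- TRUE
      }
    }
    runs <- rle(!is_masked)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (ri in which(runs$values)) {
      i0 <- starts[ri]; i1 <- ends[ri]
      w0 <- i0
      while (w0 <= i1) {
        w1 <- min(w0 + window_bins - 1L, i1)
        labels[w0:w1] <- viterbi(spec, m[w0:w1, , drop = FALSE])
        w0 <- w1 + 1L
      }
    }
    r <- rle(labels)
    rends <- cumsum(r$lengths)
    rstarts <- rends - r$lengths + 1L
    len <- tracks$layout[[chrom]]
    gr <- GenomicRanges::GRanges(
      chrom,
      IRanges::IRanges(start = (rstarts - 1L) * bs + 1L,
                       end = pmin(rends * bs, len)),
      state = ifelse(r$values == 0L, NA_integer_, r$values),
      role = ifelse(r$values == 0L, "masked", spec$roles[pmax(r$values, 1L)])
    )
    out[[chrom]] <- gr
  }
  ann <- do.call(c, unname(out))
  GenomeInfoDb::seqlevels(ann) <- names(tracks$layout)
  sort(ann)
}

#' Serialize / deserialize a model specification as JSON
#'
#' @param spec an `hmm_spec`.
#' @param path file path.
#' @return `write_model`: `path` invisibly; `read_model`: the `hmm_spec`.
#' @export
write_model <- function(spec, path) {
  stopifnot(inherits(spec, "hmm_spec"))
  obj <- list(
    n_states = spec$n_states,
    initial = spec$initial,
    trans = spec$trans,
    means = spec$means,
    covs = spec$covs,
    roles = spec$roles
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  covs <- obj$covs
  if (is.array(covs) && length(dim(covs)) == 3L) {
    covs <- lapply(seq_len(dim(covs)[1L]), function(j) covs[j, , ])
  }
  hmm_spec(initial = obj$initial,
           trans = matrix(unlist(obj$trans), nrow = obj$n_states,
                          byrow = !is.matrix(obj$trans)),
           means = matrix(unlist(obj$means), nrow = obj$n_states,
                          byrow = !is.matrix(obj$means)),
           covs = lapply(covs, function(m) {
             matrix(unlist(m), nrow = sqrt(length(unlist(m))), byrow = TRUE)
           }),
           roles = if (is.null(obj$roles)) NULL else unlist(obj$roles))
}
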