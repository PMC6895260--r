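#' Fragment-length mixture model
#'
#' The observed insertion length x of an ATAC-seq read pair is modeled as a
#' mixture of four distributions: an exponential with fixed mean `beta` for
#' nucleosome-free fragments, and three Gaussians for fragments spanning one,
#' two or three nucleosomes. Only the Gaussian parameters are updated by EM;
#' the exponential mean is fixed at runtime.
#'
#' `nfr_weight` is the prior probability that a fragment is nucleosome-free,
#' used when all four components compete in [responsibilities()]; [fit_em()]
#' sets it to the empirical fraction of fragments at or below
#' `nucleosomal_min_length`.
#'
#' @param beta mean of the exponential component (bp), fixed.
#' @param means,sds,weights Gaussian means (strictly increasing), standard
#'   deviations (> 0) and mixing proportions (sum to 1) for the mono-, di-
#'   and tri-nucleosomal components.
#' @param nfr_weight prior mass on the nucleosome-free component.
#' @return an object of class `frag_mixture`.
#' @export
frag_mixture <- function(beta = 100,
                         means = c(200, 400, 600),
                         sds = c(20, 50, 100),
                         weights = rep(1 / 3, 3),
                         nfr_weight = 0.25) {
  stopifnot(length(means) == 3L, length(sds) == 3L, length(weights) == 3L)
  if (beta <= 0) stop("beta must be positive")
  if (any(diff(means) <= 0)) stop("Gaussian means must be strictly increasing")
  if (any(sds <= 0)) stop("Gaussian standard deviations must be positive")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (any(weights < 0)) stop("weights must be nonnegative")
  structure(
    list(beta = beta, means = as.numeric(means), sds = as.numeric(sds),
         weights = as.numeric(weights), nfr_weight = nfr_weight),
    class = "frag_mixture"
  )
}

#' @export
print.frag_mixture <- function(x, ...) {
  cat("Fragment-length mixture\n")
  cat(sprintf("  NFR:  exponential, beta = %.1f bp (fixed), prior = %.3f\n",
              x$beta, x$nfr_weight))
  lab <- c("1Ns", "2Ns", "3Ns")
  for (i in 1:3) {
    cat(sprintf("  %s:  N(mu = %.1f, sigma = %.1f), weight = %.3f\n",
                lab[i], x$means[i], x$sds[i], x$weights[i]))
  }
  invisible(x)
}

#' Component densities of the fragment-length mixture
#'
#' Evaluates the four unweighted component densities at fragment length(s)
#' `x`: the exponential `(1/beta) exp(-x/beta)` for the nucleosome-free
#' component and the three Gaussian densities for the nucleosomal components.
#'
#' @param x nonnegative fragment length(s) in bp.
#' @param params a [frag_mixture()].
#' @return a numeric matrix with one row per length and columns
#'   `nfr`, `mono`, `di`, `tri`.
#' @export
component_density <- function(x, params) {
  stopifnot(inherits(params, "frag_mixture"), all(x >= 0))
  out <- cbind(
    nfr = dexp(x, rate = 1 / params$beta),
    mono = dnorm(x, params$means[1], params$sds[1]),
    di = dnorm(x, params$means[2], params$sds[2]),
    tri = dnorm(x, params$means[3], params$sds[3])
  )
  out
}

#' Posterior component responsibilities for fragment lengths
#'
#' Computes the posterior probability that each fragment belongs to each
#' mixture component: weighted densities normalized over the components in
#' play. With `include_nfr = FALSE` (the EM phase, applied to fragments
#' longer than 100 bp) only the three Gaussians compete and the
#' nucleosome-free column is zero. With `hard_assign_nfr = TRUE`, fragments
#' at or below `nfr_max_length` are assigned wholly to the nucleosome-free
#' component instead of sharing mass with the Gaussians.
#'
#' When every density underflows to zero the fragment is assigned to the
#' component whose mean is nearest its length.
#'
#' @inheritParams component_density
#' @param include_nfr include the exponential component in the normalization.
#' @param hard_assign_nfr hard-assign short fragments to the NFR component.
#' @param nfr_max_length length cutoff used by `hard_assign_nfr` (bp).
#' @return numeric matrix (rows = fragments, columns `nfr`,`mono`,`di`,`tri`)
#'   with rows summing to 1.
#' @export
responsibilities <- function(x, params, include_nfr = TRUE,
                             hard_assign_nfr = FALSE, nfr_max_length = 100) {
  dens <- component_density(x, params)
  w_g <- params$weights
  if (include_nfr) {
    w_nfr <- params$nfr_weight
    if (is.na(w_nfr)) w_nfr <- 0.25
    w <- c(w_nfr, (1 - w_nfr) * w_g)
  } else {
    w <- c(0, w_g)
  }
  post <- sweep(dens, 2L, w, `*`)
  tot <- rowSums(post)
  zero <- tot == 0
  if (any(zero)) {
    centers <- c(params$beta, params$means)
    active <- which(w > 0)
    for (i in which(zero)) {
      j <- active[which.min(abs(x[i] - centers[active]))]
      post[i, ] <- 0
      post[i, j] <- 1
    }
    tot[zero] <- 1
  }
  post <- post / tot
  if (hard_assign_nfr && include_nfr) {
    short <- x <= nfr_max_length
    post[short, ] <- 0
    post[short, 1L] <- 1
  }
  post
}

#' Fit the nucleosomal Gaussian mixture by expectation-maximization
#'
#' Fits the three Gaussian components to the nucleosomal fragment lengths
#' (those exceeding `nucleosomal_min_length`, default 100 bp) by EM. The
#' exponential mean `beta` is never updated. To reduce runtime a random
#' fraction of the fragments (default 10%) is drawn for training. Each
#' iteration computes weighted-probability responsibilities over the three
#' Gaussians, then re-estimates means, standard deviations and weights;
#' iteration stops when the largest absolute change in the means falls below
#' `epsilon` or after `max_iter` iterations. Components are sorted by mean on
#' return, and the NFR prior weight is set to the empirical fraction of
#' (all input) fragments at or below the nucleosomal cutoff.
#'
#' @param lengths fragment lengths in bp.
#' @param init_params starting [frag_mixture()].
#' @param epsilon convergence threshold on the means (bp).
#' @param subsample_frac fraction of fragments used for training.
#' @param nucleosomal_min_length only lengths strictly above this enter the
#'   Gaussian updates (bp).
#' @param seed RNG seed for the subsample (optional).
#' @param max_iter iteration cap.
#' @param sigma_floor lower bound on the standard deviations (bp).
#' @return a list with elements `mixture` (the fitted [frag_mixture()]),
#'   `trace` (a data.frame of per-iteration parameters and the observed-data
#'   log-likelihood) and `iterations`.
#' @export
fit_em <- function(lengths, init_params = frag_mixture(), epsilon = 0.5,
                   subsample_frac = 0.1, nucleosomal_min_length = 100,
                   seed = NULL, max_iter = 50, sigma_floor = 1.0) {
  stopifnot(inherits(init_params, "frag_mixture"))
  if (length(lengths) == 0L) stop("no fragment lengths supplied")
  if (subsample_frac <= 0 || subsample_frac > 1) {
    stop("subsample_frac must be in (0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  x_all <- lengths
  if (subsample_frac < 1) {
    x_all <- x_all[sample.int(length(x_all),
                              max(1L, round(subsample_frac * length(x_all))))]
  }
  x <- x_all[x_all > nucleosomal_min_length]
  if (length(x) < 9L) {
    stop("fewer than 9 nucleosomal fragment lengths (> ",
         nucleosomal_min_length, " bp) available for EM")
  }

  mu <- init_params$means
  sig <- init_params$sds
  w <- init_params$weights
  trace <- vector("list", max_iter)
  iter <- 0L
  floor_warned <- FALSE
  repeat {
    iter <- iter + 1L
    dens <- cbind(dnorm(x, mu[1], sig[1]),
                  dnorm(x, mu[2], sig[2]),
                  dnorm(x, mu[3], sig[3]))
    wd <- sweep(dens, 2L, w, `*`)
    tot <- rowSums(wd)
    ll <- sum(log(pmax(tot, .Machine$double.xmin)))
    trace[[iter]] <- data.frame(
      iter = iter, mu_m = mu[1], mu_d = mu[2], mu_t = mu[3],
      sigma_m = sig[1], sigma_d = sig[2], sigma_t = sig[3],
      w_m = w[1], w_d = w[2], w_t = w[3], loglik = ll
    )
    zero <- tot == 0
    if (any(zero)) {
      nearest <- max.col(-abs(outer(x[zero], mu, `-`)))
      wd[zero, ] <- 0
      wd[cbind(which(zero), nearest)] <- 1
      tot[zero] <- 1
    }
    resp <- wd / tot
    nk <- colSums(resp)
    mu_new <- mu
    sig_new <- sig
    for (k in 1:3) {
      if (nk[k] > 1e-8) {
        mu_new[k] <- sum(resp[, k] * x) / nk[k]
        sig_new[k] <- sqrt(sum(resp[, k] * (x - mu_new[k])^2) / nk[k])
      }
    }
    if (any(sig_new < sigma_floor)) {
      if (!floor_warned) {
        warning("mixture component standard deviation hit the floor (",
                sigma_floor, " bp)")
        floor_warned <- TRUE
      }
      sig_new <- pmax(sig_new, sigma_floor)
    }
    w_new <- nk / length(x)
    w_new <- w_new / sum(w_new)
    delta <- max(abs(mu_new - mu))
    mu <- mu_new; sig <- sig_new; w <- w_new
    if (delta < epsilon || iter >= max_iter) break
  }
  trace <- do.call(rbind, trace[seq_len(iter)])

  ord <- order(mu)
  mu_s <- mu[ord]
  # degenerate inputs can collapse two components onto the same mean; keep
  # the ordering strict so downstream code can rely on mono < di < tri
  for (k in 2:3) if (mu_s[k] <= mu_s[k - 1]) mu_s[k] <- mu_s[k - 1] + 1e-6
  mixture <- frag_mixture(
    beta = init_params$beta,
    means = mu_s, sds = sig[ord], weights = w[ord],
    nfr_weight = mean(lengths <= nucleosomal_min_length)
  )
  list(mixture = mixture, trace = trace, iterations = iter)
}
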