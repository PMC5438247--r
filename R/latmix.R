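# Maximum-likelihood fitting of mixtures of truncated Gaussians to response
# latency distributions, BIC component selection, bootstrap confidence
# intervals and constrained refits.
#
# Model: f(x) = sum_k p_k * phi(x; mu_k, sigma_k) / Z_k on [lower, upper],
# Z_k = Phi((upper-mu_k)/sigma_k) - Phi((lower-mu_k)/sigma_k), so every
# component density integrates to 1 on the truncation interval.
#
# The EM M-step for each component is one inner EM update of the weighted
# truncated-normal MLE (the classical "phantom sample" augmentation: the
# observed points are imagined alongside the expected mass of the untruncated
# normal falling outside the bounds). Both steps are EM steps, so the observed
# log-likelihood is non-decreasing across iterations.

trunc_comp_density <- function(x, mu, sigma, lower, upper) {
  z <- pmax(stats::pnorm(upper, mu, sigma) - stats::pnorm(lower, mu, sigma),
            1e-300)
  stats::dnorm(x, mu, sigma) / z
}

# one phantom-sample EM update of (mu, sigma) for a weighted truncated-normal
# MLE subproblem given weighted sample moments m1 = E_w[x], m2 = E_w[x^2]
tnorm_moment_update <- function(m1, m2, mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  z <- pmax(stats::pnorm(b) - stats::pnorm(a), 1e-12)
  pa <- stats::dnorm(a); pb <- stats::dnorm(b)
  e1_out <- mu * (1 - z) + sigma * (pb - pa)
  e2_out <- (mu^2 + sigma^2) * (1 - z) - sigma * pa * (mu + lower) +
    sigma * pb * (mu + upper)
  mu_new <- z * m1 + e1_out
  s2_new <- z * m2 + e2_out - mu_new^2
  c(mu_new, sqrt(max(s2_new, 1e-12)))
}

mixture_loglik <- function(x, p, mu, sigma, lower, upper) {
  dens <- vapply(seq_along(p), function(k)
    p[k] * trunc_comp_density(x, mu[k], sigma[k], lower, upper),
    numeric(length(x)))
  li <- if (length(p) == 1) dens[, 1] else rowSums(dens)
  sum(log(pmax(li, 1e-300)))
}

normalize_constraints <- function(constraints, k) {
  cc <- list(p = rep(NA_real_, k), mu = rep(NA_real_, k),
             sigma = rep(NA_real_, k))
  for (nm in names(constraints %||% list())) {
    v <- constraints[[nm]]
    if (length(v) != k) stopf("constraint '%s' must have length k", nm)
    cc[[nm]] <- as.numeric(v)
  }
  cc
}

n_free_params <- function(constr, k) {
  # mixing proportions lose one degree of freedom to the sum constraint
  # (fixed components pin the total mass available to the free ones)
  n_p <- max(sum(is.na(constr$p)) - 1L, 0L)
  n_p + sum(is.na(constr$mu)) + sum(is.na(constr$sigma))
}

em_truncgauss <- function(x, k, p, mu, sigma, lower, upper, constr,
                          max_iter = 8000, tol = 1e-7, sigma_floor = 1e-3,
                          trace = FALSE) {
  n <- length(x)
  ll_old <- -Inf
  ll_trace <- if (trace) numeric(0) else NULL
  converged <- FALSE
  fixed_p_mass <- sum(constr$p, na.rm = TRUE)
  free_p <- which(is.na(constr$p))
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      p[j] * trunc_comp_density(x, mu[j], sigma[j], lower, upper),
      numeric(n))
    li <- pmax(if (k == 1) dens[, 1] else rowSums(dens), 1e-300)
    ll <- sum(log(li))
    if (trace) ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * n) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    w <- dens / li
    nk <- colSums(w)
    if (length(free_p)) {
      raw <- nk[free_p] / n
      p[free_p] <- raw / sum(raw) * (1 - fixed_p_mass)
    }
    for (j in seq_len(k)) {
      if (nk[j] < 1e-8) next
      m1 <- sum(w[, j] * x) / nk[j]
      m2 <- sum(w[, j] * x^2) / nk[j]
      upd <- tnorm_moment_update(m1, m2, mu[j], sigma[j], lower, upper)
      if (is.na(constr$mu[j])) mu[j] <- upd[1]
      if (is.na(constr$sigma[j])) sigma[j] <- max(upd[2], sigma_floor)
    }
  }
  hit_floor <- any(is.na(constr$sigma) & sigma <= sigma_floor + 1e-12)
  list(p = p, mu = mu, sigma = sigma, log_lik = ll_old,
       converged = converged && !hit_floor, n_iter = it, ll_trace = ll_trace)
}

init_params <- function(x, k, constr, how = "kmeans") {
  if (k == 1) {
    mu <- mean(x); sigma <- max(stats::sd(x), 2e-3); p <- 1
  } else if (how == "kmeans") {
    km <- suppressWarnings(stats::kmeans(x, centers = k, nstart = 1))
    mu <- as.numeric(km$centers)
    sigma <- vapply(seq_len(k), function(j) {
      s <- stats::sd(x[km$cluster == j])
      if (!is.finite(s) || s < 2e-3) 2e-3 else s
    }, numeric(1))
    p <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / length(x)
    p <- pmax(p, 1e-3); p <- p / sum(p)
  } else {
    mu <- sort(stats::runif(k, min(x), max(x)))
    sigma <- rep(stats::sd(x) / k, k)
    p <- rep(1 / k, k)
  }
  o <- order(mu)
  mu <- mu[o]; sigma <- sigma[o]; p <- p[o]
  p[!is.na(constr$p)] <- constr$p[!is.na(constr$p)]
  if (any(is.na(constr$p))) {
    free <- is.na(constr$p)
    p[free] <- p[free] / sum(p[free]) * (1 - sum(constr$p, na.rm = TRUE))
  }
  mu[!is.na(constr$mu)] <- constr$mu[!is.na(constr$mu)]
  sigma[!is.na(constr$sigma)] <- constr$sigma[!is.na(constr$sigma)]
  list(p = p, mu = mu, sigma = sigma)
}

#' Fit a mixture of truncated Gaussians by maximum likelihood
#'
#' EM fit of a k-component Gaussian mixture in which every component is
#' truncated (and renormalized) on `bounds`. Initialization uses k-means
#' cluster assignments; the fit is reinitialized `n_restarts` times and the
#' best converged restart by log-likelihood is kept. Convergence requires the
#' per-observation log-likelihood change to fall below `tol`; fits that exhaust
#' `max_iter` or collapse onto the 1 ms sigma floor are flagged
#' `converged = FALSE`. Any subset of parameters can be frozen via
#' `constraints` (e.g. mixing proportions and the parameters of a slow third
#' component held at previously estimated values).
#'
#' @param x latencies (s) within `bounds`.
#' @param k number of components (requires `length(x) >= 5 * k`).
#' @param bounds truncation interval, default `c(0, 0.5)` s.
#' @param constraints optional list with elements `p`, `mu`, `sigma`, each a
#'   length-k vector with fixed values where frozen and NA where free.
#' @param n_restarts number of k-means reinitializations.
#' @param max_iter,tol EM iteration cap and per-observation tolerance.
#' @param init_at optional `mixture_fit` (or list with p, mu, sigma) used as a
#'   warm start instead of k-means initialization.
#' @param seed optional seed (k-means initialization is stochastic).
#' @param trace keep the per-iteration log-likelihood trace.
#' @return object of class `mixture_fit`: p, mu, sigma (sorted by increasing
#'   mu), log_lik, bic, n, k, converged, n_iter, bounds, constraints.
#' @export
fit_truncgauss_mixture <- function(x, k, bounds = c(0, 0.5),
                                   constraints = NULL, n_restarts = 5,
                                   max_iter = 8000, tol = 1e-7,
                                   init_at = NULL, seed = NULL,
                                   trace = FALSE) {
  x <- as.numeric(x)
  if (any(x < bounds[1] | x > bounds[2]))
    stopf("latencies outside the truncation bounds")
  if (length(x) < 5 * k) stopf("need at least 5 observations per component")
  constr <- normalize_constraints(constraints, k)
  runs <- with_seed(seed, {
    inits <- if (!is.null(init_at)) {
      list(list(p = init_at$p, mu = init_at$mu, sigma = init_at$sigma))
    } else {
      lapply(seq_len(n_restarts), function(i) init_params(x, k, constr))
    }
    lapply(inits, function(ini)
      em_truncgauss(x, k, ini$p, ini$mu, ini$sigma, bounds[1], bounds[2],
                    constr, max_iter, tol, trace = trace))
  })
  ok <- vapply(runs, `[[`, logical(1), "converged")
  pick <- if (any(ok)) which(ok)[which.max(vapply(runs[ok], `[[`, numeric(1),
                                                  "log_lik"))]
          else which.max(vapply(runs, `[[`, numeric(1), "log_lik"))
  best <- runs[[pick]]
  o <- order(best$mu)
  q <- n_free_params(normalize_constraints(constraints, k), k)
  structure(list(k = as.integer(k), p = best$p[o], mu = best$mu[o],
                 sigma = best$sigma[o],
                 log_lik = best$log_lik,
                 bic = -2 * best$log_lik + q * log(length(x)),
                 n = length(x), q = q,
                 converged = best$converged, n_iter = best$n_iter,
                 n_restarts = if (is.null(init_at)) n_restarts else 1L,
                 bounds = bounds, constraints = constraints,
                 ll_trace = best$ll_trace),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> k=%d n=%d logL=%.2f BIC=%.2f converged=%s\n",
              x$k, x$n, x$log_lik, x$bic, x$converged))
  print(data.frame(p = round(x$p, 3), mu_ms = round(1000 * x$mu, 1),
                   sigma_ms = round(1000 * x$sigma, 1)), row.names = FALSE)
  invisible(x)
}

#' Select the number of mixture components by BIC
#'
#' Fits the truncated-Gaussian mixture for each k in `k_range` and returns the
#' k minimizing `BIC = -2 logL + q log(n)` with `q = 3k - 1` free parameters
#' (truncation bounds fixed; constrained parameters reduce q). Values of k
#' with no converged fit are skipped with a message.
#'
#' @inheritParams fit_truncgauss_mixture
#' @param k_range candidate component counts.
#' @return list with `best_k`, `bic` (data.frame k, bic, converged) and the
#'   fitted models.
#' @export
select_k_by_bic <- function(x, k_range = 1:5, bounds = c(0, 0.5),
                            n_restarts = 5, seed = NULL, ...) {
  fits <- lapply(seq_along(k_range), function(i)
    fit_truncgauss_mixture(x, k_range[i], bounds = bounds,
                           n_restarts = n_restarts,
                           seed = child_seed(seed, i), ...))
  conv <- vapply(fits, `[[`, logical(1), "converged")
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  if (!any(conv)) stopf("no converged fit for any k")
  if (any(!conv))
    message("no converged fit for k = ",
            paste(k_range[!conv], collapse = ", "), "; skipped")
  best <- k_range[conv][which.min(bic[conv])]
  list(best_k = best,
       bic = data.frame(k = k_range, bic = bic, converged = conv),
       fits = fits)
}

#' Bootstrap distribution of the BIC-selected component count
#'
#' Resamples the latency sample with replacement and reruns BIC model selection
#' on every resample, returning how often each component count wins. Point fits
#' for each k (k-means initialized, multiply restarted) are computed once on
#' the original sample; resample refits are warm-started from them.
#'
#' @inheritParams select_k_by_bic
#' @param n_boot number of bootstrap resamples.
#' @return list with `modal_k`, `k_counts` (table over `k_range`) and the
#'   original-sample `selection`.
#' @export
bic_k_bootstrap <- function(x, k_range = 1:5, n_boot = 200, bounds = c(0, 0.5),
                            n_restarts = 5, seed = NULL) {
  sel <- select_k_by_bic(x, k_range, bounds = bounds, n_restarts = n_restarts,
                         seed = child_seed(seed, 0))
  n <- length(x)
  best <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      xb <- x[sample.int(n, n, replace = TRUE)]
      bic <- vapply(seq_along(k_range), function(i) {
        f <- try(fit_truncgauss_mixture(xb, k_range[i], bounds = bounds,
                                        init_at = sel$fits[[i]],
                                        max_iter = 2000), silent = TRUE)
        if (inherits(f, "try-error") || !f$converged) Inf else f$bic
      }, numeric(1))
      k_range[which.min(bic)]
    }, numeric(1))
  })
  counts <- table(factor(best, levels = k_range))
  list(modal_k = as.integer(names(counts)[which.max(counts)]),
       k_counts = counts, selection = sel)
}

#' Bootstrap confidence intervals for mixture parameters
#'
#' Resamples the latencies with replacement (`n_boot` equal-sized surrogate
#' samples), refits the mixture on each, and reports the 2.5th-97.5th
#' percentile of every parameter across converged refits. Components are
#' matched across resamples by increasing-mean ordering. Refits are
#' warm-started at the point estimate (a single EM run per resample); a
#' convergence rate below 50% triggers a warning.
#'
#' @inheritParams fit_truncgauss_mixture
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param point optional precomputed point fit.
#' @return object of class `mixture_boot`: the `point` fit, `ci` (data.frame
#'   parameter, component, lower, upper, point), `n_converged` and the raw
#'   bootstrap parameter draws.
#' @export
bootstrap_cis <- function(x, k, bounds = c(0, 0.5), constraints = NULL,
                          n_boot = 1000, n_restarts = 5, seed = NULL,
                          point = NULL) {
  if (stats::sd(x) < 1e-6) stopf("degenerate (near zero-variance) sample")
  point <- point %||% fit_truncgauss_mixture(x, k, bounds = bounds,
                                             constraints = constraints,
                                             n_restarts = n_restarts,
                                             seed = child_seed(seed, 1000))
  n <- length(x)
  draws <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      xb <- x[sample.int(n, n, replace = TRUE)]
      fit <- try(fit_truncgauss_mixture(xb, k, bounds = bounds,
                                        constraints = constraints,
                                        init_at = point, max_iter = 2000),
                 silent = TRUE)
      if (inherits(fit, "try-error") || !fit$converged) return(NULL)
      o <- order(fit$mu)
      c(fit$p[o], fit$mu[o], fit$sigma[o])
    })
  })
  good <- !vapply(draws, is.null, logical(1))
  if (mean(good) < 0.5)
    warning(sprintf("only %d/%d bootstrap refits converged", sum(good), n_boot))
  mat <- do.call(rbind, draws[good])
  par_names <- rep(c("p", "mu", "sigma"), each = k)
  comp <- rep(seq_len(k), times = 3)
  pt <- c(point$p, point$mu, point$sigma)
  ci <- data.frame(parameter = par_names, component = comp, point = pt,
                   lower = apply(mat, 2, stats::quantile, 0.025),
                   upper = apply(mat, 2, stats::quantile, 0.975))
  rownames(ci) <- NULL
  structure(list(point = point, ci = ci, n_converged = sum(good),
                 n_boot = n_boot, draws = mat),
            class = "mixture_boot")
}

#' Two-phase latency summary across concentrations
#'
#' Tabulates the means of the first and second mixture components per
#' concentration from a list of per-concentration fits with matching component
#' counts (components matched by increasing mean).
#'
#' @param fits named list of `mixture_fit` objects, one per concentration
#'   (names are the concentrations).
#' @param cis optional matching list of [bootstrap_cis()] results.
#' @return data.frame concentration, mu1, mu2 (s) with optional CI columns.
#' @export
two_phase_summary <- function(fits, cis = NULL) {
  ks <- vapply(fits, `[[`, integer(1), "k")
  if (length(unique(ks)) != 1)
    stopf("component counts differ across concentrations")
  out <- data.frame(concentration = suppressWarnings(as.numeric(names(fits))),
                    mu1 = vapply(fits, function(f) f$mu[1], numeric(1)),
                    mu2 = vapply(fits, function(f) f$mu[2], numeric(1)))
  if (!is.null(cis)) {
    pick <- function(b, comp, what) {
      r <- b$ci[b$ci$parameter == "mu" & b$ci$component == comp, ]
      r[[what]]
    }
    out$mu1_lo <- vapply(cis, pick, numeric(1), 1, "lower")
    out$mu1_hi <- vapply(cis, pick, numeric(1), 1, "upper")
    out$mu2_lo <- vapply(cis, pick, numeric(1), 2, "lower")
    out$mu2_hi <- vapply(cis, pick, numeric(1), 2, "upper")
  }
  rownames(out) <- NULL
  out
}

#' Constrained two-phase refit across concentrations
#'
#' Implements the constrained-refit protocol for stabilizing the early/late
#' component estimates: unconstrained k-component fits are obtained per
#' concentration, then each concentration is refit with the mixing proportions
#' of all components and all parameters of the last (slowest) component held at
#' the means of the unconstrained estimates across concentrations.
#'
#' @param samples named list of latency vectors, one per concentration.
#' @param k number of components (default 3).
#' @inheritParams fit_truncgauss_mixture
#' @return list with `unconstrained` and `constrained` fits (named by
#'   concentration) and the shared `constraints`.
#' @export
constrained_two_phase_fit <- function(samples, k = 3, bounds = c(0, 0.5),
                                      n_restarts = 5, seed = NULL) {
  un <- lapply(seq_along(samples), function(i)
    fit_truncgauss_mixture(samples[[i]], k, bounds = bounds,
                           n_restarts = n_restarts,
                           seed = child_seed(seed, i)))
  names(un) <- names(samples)
  pbar <- rowMeans(vapply(un, `[[`, numeric(k), "p"))
  mu3 <- mean(vapply(un, function(f) f$mu[k], numeric(1)))
  s3 <- mean(vapply(un, function(f) f$sigma[k], numeric(1)))
  constr <- list(p = pbar / sum(pbar),
                 mu = c(rep(NA_real_, k - 1), mu3),
                 sigma = c(rep(NA_real_, k - 1), s3))
  co <- lapply(seq_along(samples), function(i)
    fit_truncgauss_mixture(samples[[i]], k, bounds = bounds,
                           constraints = constr, n_restarts = n_restarts,
                           seed = child_seed(seed, 100 + i)))
  names(co) <- names(samples)
  list(unconstrained = un, constrained = co, constraints = constr)
}

#' Collect per-pair peak latencies for mixture fitting
#'
#' Applies the inclusion rule for latency modelling: cell-odor pairs of
#' concentration-series odorants enter only if a peak latency was defined at
#' every concentration; latencies are pooled across recordings.
#'
#' @param stats a [compute_response_stats()] data.frame.
#' @param region region to pool (e.g. `"PCx"`).
#' @return data.frame unit_id, odorant, concentration, latency_s.
#' @export
collect_latency_sample <- function(stats, region = "PCx") {
  st <- stats[stats$region == region, ]
  series <- names(which(table(unique(st[, c("odorant", "concentration")])$odorant) > 1))
  st <- st[st$odorant %in% series, ]
  key <- paste(st$unit_id, st$odorant)
  nconc <- length(unique(st$concentration))
  ok_pairs <- names(which(tapply(!is.na(st$peak_latency_s), key, sum) == nconc))
  st <- st[key %in% ok_pairs, ]
  out <- st[, c("unit_id", "odorant", "concentration", "peak_latency_s")]
  names(out)[4] <- "latency_s"
  rownames(out) <- NULL
  out
}
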