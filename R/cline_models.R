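# Szymura-Barton geographic cline functions with exponential tails,
# population-level likelihood, MCMC fitting and AIC model selection.

#' Cline data: ordered populations along the transect
#'
#' @param population_id population labels.
#' @param x transect position (km).
#' @param p mean hybrid index per population, in [0, 1].
#' @param N number of individuals behind each mean.
#' @return data frame of class \code{cline_data}, ordered by \code{x}.
#' @export
cline_data <- function(population_id, x, p, N) {
  stopifnot(all(is.finite(x)), all(p >= 0 & p <= 1), all(N >= 1))
  out <- data.frame(population_id = as.character(population_id),
                    x = as.numeric(x), p = as.numeric(p), N = as.integer(N),
                    stringsAsFactors = FALSE)
  out <- out[order(out$x), ]
  rownames(out) <- NULL
  class(out) <- c("cline_data", "data.frame")
  out
}

#' Cline model specification
#'
#' The five standard model variants: a plain sigmoid (\code{"none"}), an
#' exponential tail on the western or eastern side, symmetric tails sharing
#' one tau and delta, or independent (asymmetric) tails. Tail sides are named
#' geographically: west = smaller x. \code{k} is the free-parameter count
#' used for AIC (2, 4, 4, 4, 6).
#'
#' @param tails one of \code{"none"}, \code{"west"}, \code{"east"},
#'   \code{"sym"}, \code{"asym"}.
#' @param direction \code{"decreasing"} when the character falls with x (the
#'   h = 1 taxon is western), \code{"increasing"} otherwise. The orientation
#'   is an explicit flag, never inferred during fitting.
#' @param p_min,p_max end frequencies (fixed, default 0 and 1).
#' @return object of class \code{cline_model_spec}.
#' @export
cline_model_spec <- function(tails = c("none", "west", "east", "sym", "asym"),
                             direction = c("decreasing", "increasing"),
                             p_min = 0, p_max = 1) {
  tails <- match.arg(tails)
  direction <- match.arg(direction)
  stopifnot(p_min < p_max)
  pars <- switch(tails,
                 none = c("center", "width"),
                 west = c("center", "width", "tauW", "deltaW"),
                 east = c("center", "width", "tauE", "deltaE"),
                 sym  = c("center", "width", "tau", "delta"),
                 asym = c("center", "width", "tauW", "deltaW",
                          "tauE", "deltaE"))
  structure(list(tails = tails, direction = direction, params = pars,
                 k = length(pars), p_min = p_min, p_max = p_max),
            class = "cline_model_spec")
}

# expand a parameter vector to the full (center, width, tauW, deltaW, tauE,
# deltaE) set; absent tails get delta = Inf (tail region empty)
expand_params <- function(params, spec) {
  p <- as.list(params)
  full <- list(center = p$center, width = p$width,
               tauW = 0, deltaW = Inf, tauE = 0, deltaE = Inf)
  if (spec$tails == "west") {
    full$tauW <- p$tauW; full$deltaW <- p$deltaW
  } else if (spec$tails == "east") {
    full$tauE <- p$tauE; full$deltaE <- p$deltaE
  } else if (spec$tails == "sym") {
    full$tauW <- full$tauE <- p$tau
    full$deltaW <- full$deltaE <- p$delta
  } else if (spec$tails == "asym") {
    full$tauW <- p$tauW; full$deltaW <- p$deltaW
    full$tauE <- p$tauE; full$deltaE <- p$deltaE
  }
  full
}

# increasing unit cline with lower-side (x < c) and upper-side tails;
# value-continuous at the junctions x = c -/+ delta
unit_cline_inc <- function(x, c, w, tauL, dL, tauU, dU) {
  s <- function(z) 1 / (1 + exp(-4 * (z - c) / w))
  out <- s(x)
  if (is.finite(dL)) {
    i <- x < c - dL
    if (any(i))
      out[i] <- s(c - dL) *
        exp(4 * tauL * (x[i] - c + dL) / (w * (1 + exp(-4 * dL / w))))
  }
  if (is.finite(dU)) {
    i <- x > c + dU
    if (any(i))
      out[i] <- 1 - (1 - s(c + dU)) *
        exp(-4 * tauU * (x[i] - c - dU) / (w * (1 + exp(-4 * dU / w))))
  }
  out
}

#' Expected frequency along the cline
#'
#' Central segment: the logistic \code{1/(1 + exp(-4 (x - c)/w))} (mirrored
#' for a decreasing cline). On a tailed side, beyond distance delta from the
#' centre the curve follows an exponential with rate scaled by tau, matched
#' in value to the central curve at the junction; tau = 0 gives a flat tail
#' at the junction value, larger tau a faster approach to the end frequency.
#' The unit curve is rescaled to [p_min, p_max].
#'
#' @param x transect positions (km).
#' @param params named list/vector of parameters for \code{spec} (see
#'   \code{\link{cline_model_spec}}: \code{center}, \code{width} and the
#'   applicable \code{tau*}/\code{delta*}).
#' @param spec a \code{\link{cline_model_spec}}.
#' @return expected frequencies in [p_min, p_max].
#' @export
cline_mu <- function(x, params, spec) {
  f <- expand_params(params, spec)
  stopifnot(f$width > 0, f$tauW >= 0, f$tauW <= 1, f$tauE >= 0,
            f$tauE <= 1, f$deltaW >= 0, f$deltaE >= 0)
  u <- if (spec$direction == "increasing") {
    # west side = lower tail
    unit_cline_inc(x, f$center, f$width, f$tauW, f$deltaW, f$tauE, f$deltaE)
  } else {
    # reflect: west side of a decreasing cline is the upper (p ~ 1) side
    unit_cline_inc(2 * f$center - x, f$center, f$width,
                   f$tauE, f$deltaE, f$tauW, f$deltaW)
  }
  spec$p_min + (spec$p_max - spec$p_min) * u
}

#' Binomial log-likelihood of cline data (ratio to the saturated model)
#'
#' \code{lnL = sum_i N_i [p_i log(mu_i/p_i) + (1 - p_i) log((1 - mu_i)/(1 -
#' p_i))]} with the \code{0 log 0 = 0} convention and \code{mu} clamped to
#' \code{[1e-12, 1 - 1e-12]} so end populations with p exactly 0 or 1
#' contribute finite terms. A saturated fit gives lnL = 0; the argmax is
#' invariant to uniform rescaling of all N.
#'
#' @param data a \code{\link{cline_data}} frame.
#' @param params,spec as for \code{\link{cline_mu}}.
#' @return scalar log-likelihood.
#' @export
cline_loglik <- function(data, params, spec) {
  if (!nrow(data)) stop("empty cline data")
  mu <- pmin(pmax(cline_mu(data$x, params, spec), 1e-12), 1 - 1e-12)
  p <- data$p
  t1 <- ifelse(p > 0, p * log(mu / p), 0)
  t2 <- ifelse(p < 1, (1 - p) * log((1 - mu) / (1 - p)), 0)
  sum(data$N * (t1 + t2))
}

#' Default prior bounds for a cline model
#'
#' Centre: the sampled span padded by 50 km each side. Width: (0, 2 x span],
#' wide enough that posterior widths well beyond the sampled span (as seen
#' in diffuse recent-era clines) are not clipped. tau in [0, 1]; delta in
#' [0, span].
#'
#' @param spec a \code{\link{cline_model_spec}}.
#' @param data a \code{\link{cline_data}} frame.
#' @return matrix with rows per parameter, columns \code{lower}, \code{upper}.
#' @export
cline_bounds <- function(spec, data) {
  span <- diff(range(data$x))
  b <- rbind(center = c(min(data$x) - 50, max(data$x) + 50),
             width = c(1e-6, 2 * span))
  tailb <- rbind(c(0, 1), c(0, span))
  for (p in spec$params[-(1:2)]) {
    b <- rbind(b, if (grepl("^tau", p)) tailb[1, ] else tailb[2, ])
    rownames(b)[nrow(b)] <- p
  }
  colnames(b) <- c("lower", "upper")
  b
}

# negative log-likelihood wrapper over a parameter vector in spec order
nll_fun <- function(data, spec) {
  pn <- spec$params
  function(theta) {
    names(theta) <- pn
    v <- -cline_loglik(data, as.list(theta), spec)
    if (!is.finite(v)) 1e10 else v
  }
}

#' Maximum-likelihood cline fit by deterministic multi-start optimisation
#'
#' Bounded L-BFGS-B from \code{n_starts} Latin-hypercube start points spread
#' over the prior box (deterministic; no RNG). Used on its own for fast point
#' estimates and inside \code{\link{fit_cline_mcmc}} to back up the sampler.
#'
#' @param data a \code{\link{cline_data}} frame.
#' @param spec a \code{\link{cline_model_spec}}.
#' @param bounds parameter bounds, default \code{\link{cline_bounds}};
#'   constraint intervals may be substituted for individual rows.
#' @param n_starts number of start points.
#' @return list with \code{par} (named vector), \code{lnL}, \code{AIC}.
#' @export
fit_cline_ml <- function(data, spec, bounds = cline_bounds(spec, data),
                         n_starts = 16) {
  nll <- nll_fun(data, spec)
  lo <- bounds[spec$params, "lower"]
  hi <- bounds[spec$params, "upper"]
  free <- which(hi - lo > 1e-12)    # point constraints stay fixed
  starts <- lhs_starts(n_starts, length(lo))
  best <- NULL
  for (i in seq_len(n_starts)) {
    th0 <- lo + starts[i, ] * (hi - lo)
    o <- tryCatch({
      if (length(free) == 0) {
        list(par = lo, value = nll(lo))
      } else {
        of <- stats::optim(th0[free], function(v) {
          th <- lo; th[free] <- v; nll(th)
        }, method = "L-BFGS-B", lower = lo[free], upper = hi[free],
        control = list(maxit = 500))
        th <- lo; th[free] <- of$par
        list(par = th, value = of$value)
      }
    }, error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("optimization failed from every start point")
  par <- stats::setNames(best$par, spec$params)
  lnL <- -best$value
  list(par = par, lnL = lnL, AIC = 2 * spec$k - 2 * lnL)
}

#' Fit a geographic cline by MCMC
#'
#' Random-walk Metropolis on the parameters with a uniform prior over the
#' bound box. A pilot chain with independent component proposals estimates
#' the parameter covariance; the main chains then use multivariate Gaussian
#' proposals scaled by that covariance (standard 2.38^2/d scaling). The
#' published protocol (1e5 burn-in, 1e6 generations, sample every 100, three
#' chains) is the default; tests and quick passes scale these down. The
#' reported MLE is the better of the highest-likelihood draw and a
#' deterministic multi-start optimisation, so point estimates do not depend
#' on chain length.
#'
#' @param data a \code{\link{cline_data}} frame.
#' @param spec a \code{\link{cline_model_spec}}.
#' @param burnin,generations,thin,chains MCMC protocol.
#' @param seed RNG seed (one integer; chains use seed, seed + 1, ...).
#' @param bounds prior box, default \code{\link{cline_bounds}}.
#' @param constraints optional named list of \code{c(lower, upper)} intervals
#'   truncating the prior support of individual parameters (the free
#'   parameter count k is unchanged); intervals must lie inside the bounds.
#' @return object of class \code{cline_fit}: \code{mle}, \code{lnL},
#'   \code{AIC}, posterior \code{draws}, 95\% credibility intervals
#'   \code{cri}, convergence diagnostics.
#' @export
fit_cline_mcmc <- function(data, spec, burnin = 1e5, generations = 1e6,
                           thin = 100, chains = 3, seed = 1,
                           bounds = cline_bounds(spec, data),
                           constraints = NULL) {
  lo <- bounds[spec$params, "lower"]
  hi <- bounds[spec$params, "upper"]
  if (!is.null(constraints)) {
    for (nm in names(constraints)) {
      if (!nm %in% spec$params) stop("constraint on unknown parameter: ", nm)
      iv <- constraints[[nm]]
      if (length(iv) != 2 || iv[1] > iv[2]) stop("bad interval for ", nm)
      if (iv[1] < lo[nm] - 1e-9 || iv[2] > hi[nm] + 1e-9)
        stop("constraint interval for ", nm, " outside prior bounds")
      lo[nm] <- max(lo[nm], iv[1])
      hi[nm] <- min(hi[nm], iv[2])
    }
    bounds <- cbind(lower = lo, upper = hi)
  }
  d <- length(lo)
  nll <- nll_fun(data, spec)
  lpost <- function(th) {
    if (any(th < lo - 1e-12) || any(th > hi + 1e-12)) return(-Inf)
    -nll(pmin(pmax(th, lo), hi))
  }
  ml <- fit_cline_ml(data, spec, bounds = bounds)
  if (!is.finite(ml$lnL) || ml$lnL <= -1e9)
    stop("non-finite likelihood at every initialization; widen prior bounds")

  free <- which(hi - lo > 1e-12)
  run_chain <- function(n_iter, th0, prop_chol, keep_from, keep_thin) {
    cur <- th0
    lcur <- lpost(cur)
    kept <- matrix(NA_real_, length(seq(keep_from, n_iter, keep_thin)), d)
    ki <- 0L
    keep_at <- keep_from
    acc <- 0L
    for (it in seq_len(n_iter)) {
      step <- rep(0, d)
      step[free] <- drop(crossprod(prop_chol,
                                   stats::rnorm(length(free))))
      prop <- cur + step
      lprop <- lpost(prop)
      if (is.finite(lprop) &&
          log(stats::runif(1)) < lprop - lcur) {
        cur <- prop; lcur <- lprop; acc <- acc + 1L
      }
      if (it == keep_at) {
        ki <- ki + 1L
        kept[ki, ] <- cur
        keep_at <- keep_at + keep_thin
      }
    }
    list(draws = kept[seq_len(ki), , drop = FALSE], accept = acc / n_iter)
  }

  with_seed(seed, {
    # pilot: diagonal proposals to estimate the covariance
    pilot_n <- max(500L, min(5000L, as.integer(burnin)))
    sd0 <- (hi - lo)[free] * 0.05
    chol0 <- diag(sd0, length(free))
    th0 <- pmin(pmax(ml$par, lo), hi)
    pilot <- run_chain(pilot_n, th0, chol0,
                       keep_from = max(1L, pilot_n %/% 5), keep_thin = 1L)
    S <- stats::cov(pilot$draws[, free, drop = FALSE])
    S <- S + diag(1e-10 + 1e-4 * sd0^2, length(free))
    prop_chol <- chol(2.38^2 / length(free) * S)

    n_iter <- as.integer(burnin + generations)
    keep_from <- as.integer(burnin + thin)
    chain_draws <- vector("list", chains)
    accept <- numeric(chains)
    for (ch in seq_len(chains)) {
      set.seed(seed + ch)
      start <- th0
      start[free] <- pmin(pmax(th0[free] +
                                 drop(crossprod(prop_chol,
                                                stats::rnorm(length(free)))),
                               lo[free]), hi[free])
      r <- run_chain(n_iter, start, prop_chol, keep_from, as.integer(thin))
      chain_draws[[ch]] <- r$draws
      accept[ch] <- r$accept
    }
  })
  draws <- do.call(rbind, chain_draws)
  colnames(draws) <- spec$params
  lnL_draws <- apply(draws, 1, function(th) -nll(th))
  best_draw <- which.max(lnL_draws)
  if (lnL_draws[best_draw] > ml$lnL) {
    mle <- stats::setNames(draws[best_draw, ], spec$params)
    lnL <- lnL_draws[best_draw]
  } else {
    mle <- ml$par
    lnL <- ml$lnL
  }
  # a parameter constrained to an interval is not counted as free in the
  # information criterion (matches the published constrained-AIC arithmetic)
  k_eff <- spec$k - length(constraints)
  cri <- t(apply(draws, 2, stats::quantile, c(0.025, 0.5, 0.975)))
  colnames(cri) <- c("lower", "median", "upper")
  # split-half stationarity: relative shift of central quantiles
  half <- nrow(draws) %/% 2
  stat <- vapply(seq_len(ncol(draws)), function(j) {
    q1 <- stats::quantile(draws[seq_len(half), j], c(0.25, 0.5, 0.75))
    q2 <- stats::quantile(draws[half + seq_len(half), j], c(0.25, 0.5, 0.75))
    w <- cri[j, "upper"] - cri[j, "lower"]
    if (w <= 0) 0 else max(abs(q1 - q2)) / w
  }, 0)
  names(stat) <- spec$params
  # flag parameters whose posterior piles up against the prior box
  tol <- 0.01 * (hi - lo)
  at_bounds <- (cri[, "lower"] <= lo + tol) | (cri[, "upper"] >= hi - tol)
  names(at_bounds) <- spec$params
  structure(list(spec = spec, data = data, mle = mle, lnL = lnL,
                 k = k_eff, AIC = 2 * k_eff - 2 * lnL,
                 draws = draws, cri = cri,
                 constraints = constraints, bounds = bounds,
                 convergence = list(accept = accept, split_half = stat,
                                    at_bounds = at_bounds),
                 settings = list(burnin = burnin, generations = generations,
                                 thin = thin, chains = chains, seed = seed)),
            class = "cline_fit")
}

#' @export
print.cline_fit <- function(x, ...) {
  cat("cline_fit [", x$spec$tails, "tails,", x$spec$direction, "]\n")
  est <- sprintf("  %-7s %10.3f  (%.3f - %.3f)", names(x$mle), x$mle,
                 x$cri[, "lower"], x$cri[, "upper"])
  cat(est, sep = "\n")
  cat(sprintf("  lnL = %.4f  k = %d  AIC = %.4f\n", x$lnL, x$k, x$AIC))
  if (any(x$convergence$at_bounds))
    cat("  note: posterior hits prior bound for:",
        paste(names(x$mle)[x$convergence$at_bounds], collapse = ", "), "\n")
  invisible(x)
}

#' AIC model selection across cline fits
#'
#' @param fits named list of \code{cline_fit} objects sharing identical data.
#' @return data frame with \code{model}, \code{lnL}, \code{k}, \code{AIC},
#'   \code{dAIC}, \code{rel_lik} (\code{exp(-dAIC/2)}), Akaike
#'   \code{weight}, and \code{evidence_ratio} (best weight / weight); the
#'   best model is flagged.
#' @export
select_model_aic <- function(fits) {
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$spec$tails, "")
  d0 <- fits[[1]]$data
  for (f in fits)
    if (!isTRUE(all.equal(as.data.frame(f$data), as.data.frame(d0))))
      stop("fits do not share identical data")
  aic <- vapply(fits, `[[`, 0, "AIC")
  tab <- data.frame(model = names(fits),
                    lnL = vapply(fits, `[[`, 0, "lnL"),
                    k = vapply(fits, `[[`, 0, "k"),
                    AIC = aic,
                    dAIC = aic - min(aic))
  tab$rel_lik <- exp(-tab$dAIC / 2)
  tab$weight <- tab$rel_lik / sum(tab$rel_lik)
  tab$evidence_ratio <- max(tab$weight) / tab$weight
  tab$best <- tab$dAIC == 0
  rownames(tab) <- NULL
  tab
}
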