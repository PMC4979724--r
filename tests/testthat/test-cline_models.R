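spec_dec <- cline_model_spec("none", "decreasing")

test_that("sigmoid centre, symmetry, and closed-form evaluation", {
  spec_inc <- cline_model_spec("none", "increasing")
  par <- list(center = 100, width = 30)
  expect_equal(cline_mu(100, par, spec_inc), 0.5)
  expect_equal(cline_mu(100, par, spec_dec), 0.5)
  for (d in c(3, 11, 40))
    expect_equal(cline_mu(100 + d, par, spec_inc) +
                   cline_mu(100 - d, par, spec_inc), 1)
  # independent closed-form evaluation at published-scale parameters
  par2 <- list(center = 257.532, width = 13.977)
  x <- 263.314
  expect_equal(cline_mu(x, par2, spec_dec),
               1 / (1 + exp(4 * (x - 257.532) / 13.977)),
               tolerance = 1e-12)
})

test_that("tails join the central curve continuously", {
  eps <- 1e-9
  cases <- expand.grid(tails = c("west", "east", "sym", "asym"),
                       direction = c("increasing", "decreasing"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    sp <- cline_model_spec(cases$tails[i], cases$direction[i])
    par <- list(center = 100, width = 25, tau = 0.4, delta = 18,
                tauW = 0.3, deltaW = 12, tauE = 0.7, deltaE = 22)[
                  c("center", "width", sp$params[-(1:2)])]
    for (side in c(-1, 1)) {
      dpar <- grep("^delta", sp$params, value = TRUE)
      for (dp in dpar) {
        xj <- 100 + side * par[[dp]]
        expect_equal(cline_mu(xj - eps, par, sp), cline_mu(xj + eps, par, sp),
                     tolerance = 1e-6)
      }
    }
  }
  # tau = 0: tail flat at the junction value
  sp <- cline_model_spec("west", "decreasing")
  par <- list(center = 100, width = 25, tauW = 0, deltaW = 10)
  xs <- c(0, 40, 89.9)
  mu <- cline_mu(c(xs, 90), par, sp)
  expect_true(all(abs(mu - mu[4]) < 1e-12))
})

test_that("cline is monotone and bounded for random valid parameters", {
  set.seed(33)
  x <- seq(-50, 250, length.out = 400)
  for (tails in c("none", "west", "east", "sym", "asym")) {
    sp <- cline_model_spec(tails, "decreasing")
    for (r in 1:20) {
      par <- list(center = runif(1, 20, 180), width = runif(1, 1, 120),
                  tau = runif(1), delta = runif(1, 0, 80),
                  tauW = runif(1), deltaW = runif(1, 0, 80),
                  tauE = runif(1), deltaE = runif(1, 0, 80))[
                    c("center", "width", sp$params[-(1:2)])]
      mu <- cline_mu(x, par, sp)
      expect_true(all(mu >= 0 & mu <= 1))
      expect_true(all(diff(mu) <= 1e-12))  # decreasing orientation
    }
  }
})

test_that("binomial log-likelihood ratio behaves as specified", {
  d <- cline_data(c("a", "b", "c"), c(0, 100, 200), c(1, 0.5, 0), c(5, 8, 5))
  # saturated: mu = p at every point gives lnL = 0
  expect_equal(cline_loglik(d, list(center = 100, width = 1e-6), spec_dec),
               0, tolerance = 1e-6)
  # hand-computed single-population term
  d1 <- cline_data("a", 0, 0.5, 10)
  sp_inc <- cline_model_spec("none", "increasing")
  par <- list(center = 0 + 25 * log(3) / 4 * -1, width = 25)
  # choose x - c so that mu = 0.25 exactly: mu = 1/(1+exp(-4(x-c)/w))
  xc <- -25 * log(3) / 4
  d1$x <- xc
  par <- list(center = 0, width = 25)
  expect_equal(cline_loglik(d1, par, sp_inc),
               10 * (0.5 * log(0.25 / 0.5) + 0.5 * log(0.75 / 0.5)),
               tolerance = 1e-9)
  # doubling every N doubles lnL
  d2 <- d; d2$N <- d2$N * 2L
  par2 <- list(center = 90, width = 40)
  expect_equal(cline_loglik(d2, par2, spec_dec),
               2 * cline_loglik(d, par2, spec_dec))
  expect_error(cline_loglik(d[0, ], par2, spec_dec), "empty")
})

test_that("tailed models nest the plain sigmoid in maximised likelihood", {
  dh <- pearl_river_cline_data("historical")
  f0 <- fit_cline_ml(dh, spec_dec)
  for (tails in c("west", "east", "sym", "asym")) {
    ft <- fit_cline_ml(dh, cline_model_spec(tails, "decreasing"))
    expect_gte(ft$lnL, f0$lnL - 1e-4)
  }
})

test_that("MCMC recovers simulated truth and flags degenerate data", {
  # data simulated from a known no-tails cline
  set.seed(8)
  x <- seq(150, 350, length.out = 15)
  mu <- cline_mu(x, list(center = 250, width = 50), spec_dec)
  N <- rep(30L, 15)
  p <- rbinom(15, N, mu) / N
  d <- cline_data(paste0("s", 1:15), x, p, N)
  f <- fit_cline_mcmc(d, spec_dec, burnin = 2000, generations = 20000,
                      thin = 20, chains = 2, seed = 4)
  expect_true(f$cri["center", "lower"] <= 250 &
                250 <= f$cri["center", "upper"])
  expect_true(f$cri["width", "lower"] <= 50 & 50 <= f$cri["width", "upper"])
  expect_equal(unname(f$AIC), 2 * 2 - 2 * f$lnL, tolerance = 1e-6)
  # credibility intervals contain the posterior median
  expect_true(all(f$cri[, "lower"] <= f$cri[, "median"] &
                    f$cri[, "median"] <= f$cri[, "upper"]))

  # two populations at 0/1: centre between them, width runs to its prior
  d2 <- cline_data(c("a", "b"), c(0, 100), c(1, 0), c(10, 10))
  f2 <- fit_cline_mcmc(d2, spec_dec, burnin = 1000, generations = 5000,
                       thin = 10, chains = 1, seed = 2)
  expect_true(f2$mle["center"] > 0 && f2$mle["center"] < 100)
  expect_true(f2$convergence$at_bounds["width"])
})

test_that("posterior quantiles are stable between chain halves", {
  dh <- pearl_river_cline_data("historical")
  f <- fit_cline_mcmc(dh, spec_dec, burnin = 5000, generations = 60000,
                      thin = 20, chains = 2, seed = 11)
  expect_lt(f$convergence$split_half["center"], 0.05)
  expect_lt(f$convergence$split_half["width"], 0.05)
})

test_that("AIC model selection reproduces the published table arithmetic", {
  tab <- pearl_river_model_table()
  d0 <- pearl_river_cline_data("historical")
  for (ds in unique(tab$dataset)) {
    sub <- tab[tab$dataset == ds, ]
    fits <- lapply(seq_len(nrow(sub)), function(i)
      structure(list(spec = cline_model_spec(sub$model[i], "decreasing"),
                     data = d0, lnL = sub$lnL[i], k = sub$k[i],
                     AIC = 2 * sub$k[i] - 2 * sub$lnL[i]),
                class = "cline_fit"))
    names(fits) <- sub$model
    sel <- select_model_aic(fits)
    # all comparisons at the precision of the printed (rounded) inputs
    expect_lt(max(abs(sel$AIC - sub$AIC)), 5e-4)
    expect_lt(max(abs(sel$dAIC - sub$dAIC)), 5e-4)
    expect_lt(max(abs(sel$rel_lik - sub$rel_lik)), 5e-4)
    expect_lt(max(abs(sel$weight - sub$weight)), 5e-4)
    expect_lt(max(abs(sel$evidence_ratio - sub$evidence_ratio)), 0.05)
  }
  # degenerate single-model case
  one <- select_model_aic(list(none = structure(
    list(spec = spec_dec, data = d0, lnL = -1, k = 2, AIC = 6),
    class = "cline_fit")))
  expect_equal(one$weight, 1)
  expect_equal(one$dAIC, 0)
  # mismatched data refused
  d_other <- pearl_river_cline_data("recent")
  expect_error(select_model_aic(list(
    a = structure(list(spec = spec_dec, data = d0, lnL = -1, k = 2, AIC = 6),
                  class = "cline_fit"),
    b = structure(list(spec = spec_dec, data = d_other, lnL = -1, k = 2,
                       AIC = 6), class = "cline_fit"))),
    "identical data")
})
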