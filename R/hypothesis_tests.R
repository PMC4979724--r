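# Temporal comparisons: reciprocal constraint tests between eras and the
# stratified subsampling analysis.

#' Cline fit with parameters constrained to intervals
#'
#' Identical machinery to \code{\link{fit_cline_mcmc}}, with the prior
#' support of the named parameters truncated to the supplied intervals
#' (typically the 95\% credibility interval estimated from the other era).
#' Each constrained parameter is dropped from the free-parameter count used
#' for AIC (k decreases by one per constrained parameter), matching the
#' published constrained-AIC arithmetic for these tests.
#'
#' @param data a \code{\link{cline_data}} frame.
#' @param spec a \code{\link{cline_model_spec}}.
#' @param constraints named list of \code{c(lower, upper)} intervals; a
#'   degenerate interval \code{c(v, v)} fixes the parameter at v.
#' @param ... passed to \code{\link{fit_cline_mcmc}} (burnin, generations,
#'   thin, chains, seed, bounds).
#' @return a \code{cline_fit}.
#' @export
constrained_fit <- function(data, spec, constraints, ...) {
  if (!length(constraints) || is.null(names(constraints)))
    stop("constraints must be a named list of intervals")
  fit_cline_mcmc(data, spec, constraints = constraints, ...)
}

#' Reciprocal constraint test statistics
#'
#' Compares a constrained to an unconstrained fit of the same data:
#' \code{2LLR = 2 (lnL_con - lnL_uncon)} (non-positive when the constraint
#' excludes the unconstrained MLE, ~0 when it does not) and
#' \code{dAIC = AIC_uncon - AIC_con}.
#'
#' @param fit_uncon,fit_con \code{cline_fit} objects on identical data.
#' @return data frame with \code{lnL_uncon}, \code{lnL_con},
#'   \code{AIC_uncon}, \code{AIC_con}, \code{LLR2}, \code{dAIC}.
#' @export
reciprocal_constraint_test <- function(fit_uncon, fit_con) {
  if (!isTRUE(all.equal(as.data.frame(fit_uncon$data),
                        as.data.frame(fit_con$data))))
    stop("fits do not share the same data")
  data.frame(lnL_uncon = fit_uncon$lnL, lnL_con = fit_con$lnL,
             AIC_uncon = fit_uncon$AIC, AIC_con = fit_con$AIC,
             LLR2 = 2 * (fit_con$lnL - fit_uncon$lnL),
             dAIC = fit_uncon$AIC - fit_con$AIC)
}

#' Stratified subsampling comparison of two sampling eras
#'
#' Emulates the design-matching check for era comparisons: each historical
#' population is matched to one of a set of candidate recent populations,
#' individuals are subsampled without replacement so both members of a pair
#' have the same N (the smaller of the two), the per-population mean hybrid
#' index is recomputed on the subsample, both eras are refit with the
#' no-tails cline model, and a replicate scores a significant difference for
#' a parameter when the two 95\% credibility intervals do not overlap.
#'
#' @param hist,recent lists with elements \code{h} (per-individual hybrid
#'   index frame: \code{individual_id}, \code{population_id}, \code{h}, as
#'   returned by \code{\link{hybrid_index}}) and \code{meta} (population
#'   table with \code{transect_x}).
#' @param mapping named list: historical population id -> character vector of
#'   candidate recent population ids (one drawn uniformly per replicate).
#' @param reps number of replicates (default 100).
#' @param seed RNG seed.
#' @param direction cline orientation flag, see
#'   \code{\link{cline_model_spec}}.
#' @param mcmc list of MCMC settings per fit; the default short protocol
#'   (burnin 2000, 20000 generations, thin 20, 1 chain) keeps 100 replicates
#'   at desk scale, and can be raised to the full published protocol.
#' @return object of class \code{subsample_summary}: \code{replicates} data
#'   frame (per-replicate parameter estimates, CrIs and significance flags)
#'   and \code{summary} (means, ranges, tallies).
#' @export
stratified_subsample_analysis <- function(hist, recent, mapping, reps = 100,
                                          seed = 1,
                                          direction = "decreasing",
                                          mcmc = list(burnin = 2000,
                                                      generations = 20000,
                                                      thin = 20,
                                                      chains = 1)) {
  if (reps < 1) stop("reps must be >= 1")
  for (hp in names(mapping)) {
    if (!length(mapping[[hp]]))
      stop("empty candidate set for historical population ", hp)
    if (!hp %in% hist$h$population_id)
      stop("historical population not in data: ", hp)
    bad <- setdiff(mapping[[hp]], recent$h$population_id)
    if (length(bad))
      stop("candidate population(s) not in recent data: ",
           paste(bad, collapse = ", "))
  }
  spec <- cline_model_spec("none", direction = direction)
  hx <- hist$meta$transect_x[match(names(mapping),
                                   hist$meta$population_id)]
  if (anyNA(hx)) stop("historical population(s) lacking transect_x")

  one_rep <- function(r, rep_seed) {
    pick <- vapply(mapping, function(cand)
      if (length(cand) == 1) cand else sample(cand, 1), "")
    rows_h <- rows_r <- list()
    for (i in seq_along(pick)) {
      hp <- names(mapping)[i]
      ih <- which(hist$h$population_id == hp)
      ir <- which(recent$h$population_id == pick[i])
      n <- min(length(ih), length(ir))
      rows_h[[i]] <- if (length(ih) > n) sample(ih, n) else ih
      rows_r[[i]] <- if (length(ir) > n) sample(ir, n) else ir
    }
    mean_h <- function(df, rows) vapply(rows, function(ix)
      mean(df$h[ix]), 0)
    n_pair <- vapply(rows_h, length, 0L)
    rx <- recent$meta$transect_x[match(pick, recent$meta$population_id)]
    d_h <- cline_data(names(mapping), hx, pmin(1, pmax(0,
                                                       mean_h(hist$h, rows_h))), n_pair)
    d_r <- cline_data(pick, rx, pmin(1, pmax(0, mean_h(recent$h, rows_r))),
                      n_pair)
    f_h <- do.call(fit_cline_mcmc,
                   c(list(data = d_h, spec = spec, seed = rep_seed), mcmc))
    f_r <- do.call(fit_cline_mcmc,
                   c(list(data = d_r, spec = spec, seed = rep_seed + 1),
                     mcmc))
    no_overlap <- function(a, b) a["upper"] < b["lower"] ||
      b["upper"] < a["lower"]
    cc_h <- f_h$cri["center", ]; cc_r <- f_r$cri["center", ]
    cw_h <- f_h$cri["width", ];  cw_r <- f_r$cri["width", ]
    sig_c <- no_overlap(cc_h, cc_r)
    sig_w <- no_overlap(cw_h, cw_r)
    data.frame(rep = r,
               hist_center = f_h$mle["center"], hist_width = f_h$mle["width"],
               recent_center = f_r$mle["center"],
               recent_width = f_r$mle["width"],
               hist_center_lo = cc_h["lower"], hist_center_hi = cc_h["upper"],
               recent_center_lo = cc_r["lower"],
               recent_center_hi = cc_r["upper"],
               hist_width_lo = cw_h["lower"], hist_width_hi = cw_h["upper"],
               recent_width_lo = cw_r["lower"],
               recent_width_hi = cw_r["upper"],
               n_total = sum(n_pair),
               sig_east = sig_c && f_r$mle["center"] > f_h$mle["center"],
               sig_west = sig_c && f_r$mle["center"] < f_h$mle["center"],
               sig_wider = sig_w && f_r$mle["width"] > f_h$mle["width"],
               sig_narrower = sig_w && f_r$mle["width"] < f_h$mle["width"],
               row.names = NULL)
  }
  reps_df <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(reps), function(r)
      one_rep(r, rep_seed = seed + 13L * r)))
  })
  summ <- list(
    hist_center = c(mean = mean(reps_df$hist_center),
                    range = range(reps_df$hist_center)),
    recent_center = c(mean = mean(reps_df$recent_center),
                      range = range(reps_df$recent_center)),
    hist_width = c(mean = mean(reps_df$hist_width),
                   range = range(reps_df$hist_width)),
    recent_width = c(mean = mean(reps_df$recent_width),
                     range = range(reps_df$recent_width)),
    tallies = c(sig_east = sum(reps_df$sig_east),
                sig_west = sum(reps_df$sig_west),
                sig_wider = sum(reps_df$sig_wider),
                sig_narrower = sum(reps_df$sig_narrower)),
    reps = reps)
  structure(list(replicates = reps_df, summary = summ),
            class = "subsample_summary")
}

#' @export
print.subsample_summary <- function(x, ...) {
  s <- x$summary
  cat("stratified subsampling,", s$reps, "replicates\n")
  fmt <- function(v) sprintf("%.3f (%.3f-%.3f)", v[1], v[2], v[3])
  cat("  historical centre:", fmt(s$hist_center),
      " width:", fmt(s$hist_width), "\n")
  cat("  recent     centre:", fmt(s$recent_center),
      " width:", fmt(s$recent_width), "\n")
  cat("  significant replicates: east", s$tallies["sig_east"],
      "west", s$tallies["sig_west"],
      "wider", s$tallies["sig_wider"],
      "narrower", s$tallies["sig_narrower"], "\n")
  invisible(x)
}
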