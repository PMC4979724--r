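# Maximum-likelihood hybrid index (per-allele mixture likelihood), profile
# confidence intervals, classification rules, and population mean h.

#' Estimate parental allele frequencies from reference pools
#'
#' Pools the genotypes of the populations designated as the reference
#' (\code{h = 0}) and alternative (\code{h = 1}) parental ends and converts
#' counts to frequencies. An additive pseudocount is applied to every allele
#' observed anywhere in the dataset, so no observable allele has zero
#' frequency in both pools and individual likelihoods stay finite.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param reference_pops,alternative_pops disjoint, non-empty sets of
#'   population ids for the two parental ends.
#' @param pseudocount additive smoothing mass per allele (default 1e-6; large
#'   enough to avoid -Inf log-likelihoods, small enough to leave estimates
#'   unchanged to ~1e-5).
#' @return object of class \code{parental_freqs}: per locus a 2 x K frequency
#'   matrix with rows \code{ref} and \code{alt}, plus sampled gene counts.
#' @export
estimate_parental_frequencies <- function(gm, reference_pops,
                                          alternative_pops,
                                          pseudocount = 1e-6) {
  if (length(intersect(reference_pops, alternative_pops)))
    stop("reference and alternative pools share population(s): ",
         paste(intersect(reference_pops, alternative_pops), collapse = ", "))
  missing_pops <- setdiff(c(reference_pops, alternative_pops),
                          gm$population_id)
  if (length(missing_pops))
    stop("unknown population(s): ", paste(missing_pops, collapse = ", "))
  ref_rows <- gm$population_id %in% reference_pops
  alt_rows <- gm$population_id %in% alternative_pops
  freq <- lapply(seq_along(gm$loci), function(j) {
    alleles <- sort(unique(stats::na.omit(c(gm$a1[, j], gm$a2[, j]))))
    cnt <- function(rows) {
      g <- c(gm$a1[rows, j], gm$a2[rows, j])
      g <- g[!is.na(g)]
      tab <- table(factor(g, levels = alleles))
      as.numeric(tab)
    }
    cr <- cnt(ref_rows) + pseudocount
    ca <- cnt(alt_rows) + pseudocount
    m <- rbind(ref = cr / sum(cr), alt = ca / sum(ca))
    colnames(m) <- as.character(alleles)
    attr(m, "genes") <- c(ref = sum(cnt(ref_rows)), alt = sum(cnt(alt_rows)))
    m
  })
  structure(list(loci = gm$loci,
                 freq = stats::setNames(freq, gm$loci),
                 pseudocount = pseudocount),
            class = "parental_freqs")
}

#' @export
print.parental_freqs <- function(x, ...) {
  cat("parental_freqs:", length(x$loci), "loci, pseudocount",
      x$pseudocount, "\n")
  invisible(x)
}

# per-allele-copy parental frequencies for one individual's calls:
# returns matrix with columns f_ref, f_alt, one row per non-missing copy
copy_freqs <- function(calls, pf) {
  rows <- list()
  for (loc in names(calls)) {
    al <- calls[[loc]]
    if (is.null(al) || anyNA(al)) next
    fm <- pf$freq[[loc]]
    if (is.null(fm)) stop("locus absent from parental frequencies: ", loc)
    for (a in al) {
      k <- match(as.character(a), colnames(fm))
      if (is.na(k))
        stop("allele ", a, " at locus ", loc,
             " absent from parental frequency table")
      rows[[length(rows) + 1L]] <- fm[, k]
    }
  }
  if (!length(rows)) stop("individual has no non-missing locus")
  do.call(rbind, rows)
}

#' Maximum-likelihood hybrid index for one individual
#'
#' Treats each of the individual's allele copies as an independent draw from
#' the mixture \code{h f_alt + (1 - h) f_ref} and maximises
#' \code{lnL(h) = sum log(h f_alt + (1 - h) f_ref)} over \code{h} in [0, 1]
#' (the log-likelihood is concave in h). The 95\% interval is the profile set
#' \code{\{h : lnL(h) >= lnL(h*) - 1.92\}} (a chi-square(1)/2 drop),
#' intersected with [0, 1]. Exact ties in lnL are broken toward the boundary.
#'
#' @param calls named list, one entry per locus: an integer vector of the two
#'   allele lengths, or \code{NA}/\code{NULL} for missing.
#' @param pf a \code{\link{estimate_parental_frequencies}} result.
#' @return list with \code{h}, \code{lnL}, \code{ci_low}, \code{ci_high}.
#' @export
hybrid_index_ml <- function(calls, pf) {
  fm <- copy_freqs(calls, pf)
  f_ref <- fm[, "ref"]; f_alt <- fm[, "alt"]
  lnL <- function(h) sum(log(h * f_alt + (1 - h) * f_ref))
  if (any(f_ref == 0 & f_alt == 0))
    stop("likelihood identically zero: allele(s) with zero frequency in ",
         "both pools; use a positive pseudocount")
  opt <- stats::optimize(lnL, c(0, 1), maximum = TRUE, tol = 1e-9)
  cand_h <- c(opt$maximum, 0, 1)
  cand_l <- c(opt$objective, lnL(0), lnL(1))
  cand_l[!is.finite(cand_l)] <- -Inf
  # prefer a boundary when its lnL ties the interior optimum
  best <- which(cand_l >= max(cand_l) - 1e-9)
  pick <- if (any(best > 1)) max(best) else 1L
  h_hat <- cand_h[pick]
  l_max <- cand_l[pick]
  drop_to <- l_max - stats::qchisq(0.95, 1) / 2
  gfun <- function(h) lnL(h) - drop_to
  ci_low <- 0; ci_high <- 1
  if (h_hat > 0 && is.finite(gfun(0)) && gfun(0) < 0)
    ci_low <- stats::uniroot(gfun, c(0, h_hat), tol = 1e-9)$root
  else if (h_hat > 0 && !is.finite(gfun(0)))
    ci_low <- stats::uniroot(function(h) {
      v <- gfun(h); if (!is.finite(v)) -1e10 else v
    }, c(1e-12, h_hat), tol = 1e-9)$root
  if (h_hat < 1 && is.finite(gfun(1)) && gfun(1) < 0)
    ci_high <- stats::uniroot(gfun, c(h_hat, 1), tol = 1e-9)$root
  else if (h_hat < 1 && !is.finite(gfun(1)))
    ci_high <- stats::uniroot(function(h) {
      v <- gfun(h); if (!is.finite(v)) -1e10 else v
    }, c(h_hat, 1 - 1e-12), tol = 1e-9)$root
  list(h = h_hat, lnL = l_max, ci_low = ci_low, ci_high = ci_high)
}

#' Hybrid indices for every individual in a genotype matrix
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param pf parental frequencies from
#'   \code{\link{estimate_parental_frequencies}}.
#' @return data frame with columns \code{individual_id},
#'   \code{population_id}, \code{era}, \code{h}, \code{lnL}, \code{ci_low},
#'   \code{ci_high}.
#' @export
hybrid_index <- function(gm, pf) {
  rows <- lapply(seq_along(gm$individual_id), function(i) {
    calls <- stats::setNames(lapply(seq_along(gm$loci), function(j)
      c(gm$a1[i, j], gm$a2[i, j])), gm$loci)
    r <- hybrid_index_ml(calls, pf)
    data.frame(individual_id = gm$individual_id[i],
               population_id = gm$population_id[i],
               era = gm$era[i],
               h = r$h, lnL = r$lnL,
               ci_low = r$ci_low, ci_high = r$ci_high,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify individuals as hybrid or pure
#'
#' Two published rules: the cutoff rule calls an individual a hybrid when
#' \code{0.25 <= h <= 0.75} (laboratory F1s of related chorus frogs fall in
#' 0.5-0.75); the CI rule calls a hybrid when the 95\% interval excludes both
#' 0 and 1.
#'
#' @param results data frame from \code{\link{hybrid_index}}.
#' @param rule \code{"cutoff"} or \code{"ci"}.
#' @return \code{results} with added \code{class} column
#'   (\code{"pure_reference"}, \code{"pure_alternative"}, \code{"hybrid"});
#'   per-population hybrid proportions in \code{attr(, "proportions")}.
#' @export
classify_hybrids <- function(results, rule = c("cutoff", "ci")) {
  rule <- match.arg(rule)
  hyb <- if (rule == "cutoff")
    results$h >= 0.25 & results$h <= 0.75
  else
    results$ci_low > 0 & results$ci_high < 1
  results$class <- ifelse(hyb, "hybrid",
                          ifelse(results$h < 0.5, "pure_reference",
                                 "pure_alternative"))
  prop <- tapply(hyb, results$population_id, mean)
  attr(results, "proportions") <-
    data.frame(population_id = names(prop),
               hybrid_proportion = as.numeric(prop),
               stringsAsFactors = FALSE)
  results
}

#' Per-population mean hybrid index as cline data
#'
#' @param results data frame from \code{\link{hybrid_index}}.
#' @param meta population table with columns \code{population_id} and
#'   \code{transect_x}.
#' @return a \code{\link{cline_data}} frame ordered by transect position.
#' @export
population_mean_h <- function(results, meta) {
  pops <- unique(results$population_id)
  m <- meta[match(pops, meta$population_id), ]
  if (!("transect_x" %in% names(meta)) || anyNA(m$transect_x))
    stop("population(s) lacking transect_x: ",
         paste(pops[is.na(m$transect_x)], collapse = ", "))
  p <- tapply(results$h, results$population_id, mean)[pops]
  n <- tapply(results$h, results$population_id, length)[pops]
  cline_data(population_id = pops, x = m$transect_x,
             p = as.numeric(p), N = as.integer(n))
}
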