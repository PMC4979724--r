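# Synthetic microsatellite hybrid-zone generator with known truth.

#' Configuration for the synthetic hybrid-zone generator
#'
#' Defaults emulate the historical-era sampling design of the Pearl River
#' chorus-frog contact zone: 7 populations at the published transect
#' positions with N = 16, 4, 17, 25, 6, 30, 19; 11 microsatellite loci; two
#' strongly diverged parental pools; a decreasing no-tails cline (h = 1 taxon
#' in the west) with centre 257.5 km and width 14 km.
#'
#' @param loci number of loci.
#' @param alleles_per_locus inclusive range to draw allele counts from.
#' @param divergence in [0, 1]: 0 gives identical parental pools, values
#'   near 1 nearly fixed differences (controls the Dirichlet concentration
#'   tying each pool to a shared base frequency vector).
#' @param private_fraction fraction of each locus's alleles zeroed in exactly
#'   one pool (and renormalised), creating private alleles. The default 0.55
#'   matches the documented allele sharing between the two parental species
#'   (139 of 245 historical alleles private to one species).
#' @param positions transect positions x (km) of the populations.
#' @param N per-population diploid sample sizes.
#' @param true_params named list with \code{center} and \code{width} (and
#'   tail parameters if \code{true_spec} has tails).
#' @param true_spec a \code{\link{cline_model_spec}} for the true cline.
#' @param h_concentration beta concentration for individual admixture around
#'   the population expectation q: \code{h ~ Beta(q k, (1 - q) k)};
#'   \code{Inf} makes h deterministic (= q). The default 20 gives a spread
#'   (sd ~ 0.11 at q = 0.5) comparable to a population mixing parental,
#'   F1/F2 and backcross classes.
#' @param missing_rate per-call missing probability (scalar or one value per
#'   locus).
#' @param null_rate per-allele-copy dropout probability (a genotype with one
#'   dropped copy presents as a homozygote; both dropped = missing),
#'   emulating null alleles.
#' @param era era label for the generated populations.
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(loci = 11,
                              alleles_per_locus = c(4, 12),
                              divergence = 0.5,
                              private_fraction = 0.55,
                              positions = c(0, 233.259, 246.778, 253.849,
                                            257.601, 263.314, 299.728),
                              N = c(16, 4, 17, 25, 6, 30, 19),
                              true_params = list(center = 257.5, width = 14),
                              true_spec = cline_model_spec("none",
                                                           "decreasing"),
                              h_concentration = 20,
                              missing_rate = 0.02,
                              null_rate = 0,
                              era = "synthetic") {
  stopifnot(divergence >= 0, divergence <= 1,
            private_fraction >= 0, private_fraction <= 1,
            all(missing_rate >= 0), all(missing_rate <= 1),
            null_rate >= 0, null_rate <= 1,
            all(N >= 1), all(is.finite(positions)),
            length(N) == length(positions))
  structure(list(loci = loci, alleles_per_locus = alleles_per_locus,
                 divergence = divergence,
                 private_fraction = private_fraction,
                 positions = positions, N = as.integer(N),
                 true_params = true_params, true_spec = true_spec,
                 h_concentration = h_concentration,
                 missing_rate = missing_rate, null_rate = null_rate,
                 era = era),
            class = "simulation_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate diverged parental allele-frequency pools
#'
#' Per locus, a shared base frequency vector is drawn from a symmetric
#' Dirichlet; each pool's frequencies are then drawn from a Dirichlet centred
#' on the base with concentration \code{K (1 - d)/d} for divergence d, so the
#' pools coincide at d = 0 and decouple as d -> 1. A \code{private_fraction}
#' of alleles is then zeroed in exactly one pool (alternating pools) and the
#' frequencies renormalised.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @param seed RNG seed.
#' @return a \code{parental_freqs} object (rows \code{ref} = h = 0 pool,
#'   \code{alt} = h = 1 pool).
#' @export
simulate_parental_frequencies <- function(cfg, seed = 1) {
  rng <- cfg$alleles_per_locus
  if (cfg$private_fraction > 0 && max(rng) < 2)
    stop("private alleles require at least 2 alleles per locus")
  with_seed(seed, {
    freq <- lapply(seq_len(cfg$loci), function(j) {
      K <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
      base <- rdirichlet1(rep(1, K))
      if (cfg$divergence == 0) {
        fr <- fa <- base
      } else if (cfg$divergence == 1) {
        fr <- fa <- rep(0, K)
        fr[sample.int(K, 1)] <- 1
        fa[sample.int(K, 1)] <- 1
      } else {
        conc <- K * (1 - cfg$divergence) / cfg$divergence
        fr <- rdirichlet1(base * conc)
        fa <- rdirichlet1(base * conc)
      }
      npriv <- floor(cfg$private_fraction * K)
      if (npriv > 0) {
        priv <- sample.int(K, npriv)
        for (idx in seq_along(priv)) {
          if (idx %% 2 == 1) fa[priv[idx]] <- 0 else fr[priv[idx]] <- 0
        }
        if (sum(fr) == 0) fr[setdiff(seq_len(K), priv)[1]] <- 1
        if (sum(fa) == 0) fa[setdiff(seq_len(K), priv)[1]] <- 1
        fr <- fr / sum(fr)
        fa <- fa / sum(fa)
      }
      # allele "lengths": distinct positive integers per locus
      m <- rbind(ref = fr, alt = fa)
      colnames(m) <- as.character(100 + j * 50 + 2 * seq_len(K))
      attr(m, "genes") <- c(ref = Inf, alt = Inf)
      m
    })
    loci <- sprintf("locus_%02d", seq_len(cfg$loci))
    structure(list(loci = loci, freq = stats::setNames(freq, loci),
                   pseudocount = 0),
              class = "parental_freqs")
  })
}

#' Simulate a hybrid-zone genotype dataset with known truth
#'
#' Each population at position x has expected admixture q from the true
#' cline; each individual draws its own admixture \code{h ~ Beta(q k,
#' (1 - q) k)} (or h = q when the concentration is infinite), and each of its
#' 2 x loci allele copies independently comes from the mixture
#' \code{h f_alt + (1 - h) f_ref}. Missing-data and null-allele masking are
#' applied last.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @param pf parental frequencies (default: simulated from \code{cfg}).
#' @param seed RNG seed.
#' @return list with \code{genotypes} (a \code{\link{genotype_matrix}}),
#'   \code{meta} (population table with \code{transect_x} and true q), and
#'   \code{truth} (true parameters, per-individual h).
#' @export
simulate_hybrid_zone <- function(cfg, pf = NULL, seed = 1) {
  if (is.null(pf)) pf <- simulate_parental_frequencies(cfg, seed = seed)
  q <- cline_mu(cfg$positions, cfg$true_params, cfg$true_spec)
  stopifnot(all(q >= 0 & q <= 1))
  n_pop <- length(cfg$positions)
  pops <- sprintf("P%02d", seq_len(n_pop))
  with_seed(seed + 1L, {
    n_tot <- sum(cfg$N)
    pop_of <- rep(pops, cfg$N)
    q_of <- rep(q, cfg$N)
    h_i <- if (is.finite(cfg$h_concentration)) {
      a <- q_of * cfg$h_concentration
      b <- (1 - q_of) * cfg$h_concentration
      ifelse(q_of %in% c(0, 1), q_of, stats::rbeta(n_tot, a, b))
    } else q_of
    L <- length(pf$loci)
    a1 <- matrix(NA_integer_, n_tot, L)
    a2 <- matrix(NA_integer_, n_tot, L)
    for (j in seq_len(L)) {
      fm <- pf$freq[[j]]
      alleles <- as.integer(colnames(fm))
      K <- length(alleles)
      for (i in seq_len(n_tot)) {
        mix <- h_i[i] * fm["alt", ] + (1 - h_i[i]) * fm["ref", ]
        draw <- sample.int(K, 2, replace = TRUE, prob = mix)
        a1[i, j] <- alleles[draw[1]]
        a2[i, j] <- alleles[draw[2]]
      }
    }
    if (cfg$null_rate > 0) {
      d1 <- matrix(stats::runif(n_tot * L) < cfg$null_rate, n_tot, L)
      d2 <- matrix(stats::runif(n_tot * L) < cfg$null_rate, n_tot, L)
      a1[d1 & d2] <- NA_integer_           # both copies dropped
      a1[d1 & !d2] <- a2[d1 & !d2]         # apparent homozygote
      a2[!d1 & d2] <- a1[!d1 & d2]
      a2[d1 & d2] <- NA_integer_
    }
    if (any(cfg$missing_rate > 0)) {
      rate <- matrix(rep_len(cfg$missing_rate, L), n_tot, L, byrow = TRUE)
      miss <- matrix(stats::runif(n_tot * L), n_tot, L) < rate
      a1[miss] <- NA_integer_
      a2[miss] <- NA_integer_
    }
    gm <- genotype_matrix(sprintf("ind_%04d", seq_len(n_tot)),
                          collection_site = pop_of, population_id = pop_of,
                          era = cfg$era, loci = pf$loci, a1 = a1, a2 = a2)
  })
  # synthetic coordinates on an eastward line so projection also works
  meta <- data.frame(population_id = pops,
                     era = cfg$era,
                     latitude = 30.5,
                     longitude = -92 + cfg$positions /
                       (111.32 * cos(30.5 * pi / 180)),
                     N = cfg$N,
                     transect_x = cfg$positions,
                     true_q = q,
                     stringsAsFactors = FALSE)
  list(genotypes = gm, meta = meta,
       truth = list(params = cfg$true_params, spec = cfg$true_spec,
                    q = q, h = stats::setNames(h_i, gm$individual_id),
                    parental = pf))
}
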