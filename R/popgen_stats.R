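# Per-population diversity statistics, HWE/LD permutation tests, private
# alleles, and pairwise Weir-Cockerham FST.

#' Per-locus allele frequencies for one or all populations
#'
#' Missing calls are excluded per locus; frequencies are over observed alleles
#' and sum to 1. The number of sampled genes (2 x non-missing individuals) is
#' attached per locus. A locus with no non-missing call in a population is
#' flagged absent (\code{NULL} entry).
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param population a population id, or \code{NULL} for a list over all
#'   populations.
#' @return for one population, a list with one entry per locus:
#'   \code{list(freq = named numeric, genes = int)}; \code{NULL} where no
#'   calls exist. For \code{population = NULL}, a named list of such lists.
#' @export
allele_frequencies <- function(gm, population = NULL) {
  if (is.null(population)) {
    pops <- unique(gm$population_id)
    return(stats::setNames(lapply(pops, allele_frequencies, gm = gm), pops))
  }
  if (!population %in% gm$population_id)
    stop("unknown population: ", population)
  rows <- gm$population_id == population
  out <- lapply(seq_along(gm$loci), function(j) {
    g <- c(gm$a1[rows, j], gm$a2[rows, j])
    g <- g[!is.na(g)]
    if (!length(g)) return(NULL)
    tab <- table(g)
    list(freq = stats::setNames(as.numeric(tab) / length(g), names(tab)),
         genes = length(g))
  })
  stats::setNames(out, gm$loci)
}

#' Diversity summary table
#'
#' Per population, averaged over loci: number of alleles, effective number of
#' alleles (\code{1 / sum(p^2)}), allelic richness rarefied to \code{g} genes,
#' observed heterozygosity, expected heterozygosity, and the inbreeding
#' coefficient \code{G_IS = 1 - Ho/He}.
#'
#' Expected heterozygosity uses Nei's small-sample correction
#' \code{(2n/(2n-1)) (1 - sum p^2)} by default (\code{unbiased = FALSE} gives
#' the plain gene diversity). Rarefied richness at a locus with \code{2n}
#' sampled genes and allele counts \code{n_a} is
#' \code{sum_a [1 - choose(2n - n_a, g)/choose(2n, g)]}, the expected number
#' of distinct alleles in a subsample of \code{g} genes.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param rarefaction_g number of genes to rarefy to; default is the smallest
#'   per-locus gene count across populations.
#' @param unbiased use Nei's correction for expected heterozygosity.
#' @return data frame with one row per population (columns \code{population},
#'   \code{N}, \code{num_alleles}, \code{eff_num_alleles}, \code{AR},
#'   \code{Ho}, \code{He}, \code{GIS}); per-locus values in
#'   \code{attr(, "per_locus")}. \code{GIS} is \code{NA} when \code{He = 0}.
#' @export
diversity_summary <- function(gm, rarefaction_g = NULL, unbiased = TRUE) {
  pops <- unique(gm$population_id)
  af <- allele_frequencies(gm)
  min_genes <- min(unlist(lapply(af, function(p)
    vapply(p, function(l) if (is.null(l)) Inf else l$genes, 0))))
  if (is.null(rarefaction_g)) rarefaction_g <- min_genes
  if (rarefaction_g > min_genes)
    stop("rarefaction_g = ", rarefaction_g, " exceeds the smallest per-locus ",
         "gene count (", min_genes, "); choose g <= ", min_genes)
  per_locus <- list()
  rows <- lapply(pops, function(p) {
    sel <- gm$population_id == p
    pf <- af[[p]]
    stat <- t(vapply(seq_along(gm$loci), function(j) {
      l <- pf[[j]]
      if (is.null(l)) return(rep(NA_real_, 6))
      f <- l$freq
      genes <- l$genes
      sum_p2 <- sum(f^2)
      he <- 1 - sum_p2
      if (unbiased) he <- he * genes / (genes - 1)
      counts <- f * genes
      ar <- sum(1 - exp(lchoose(genes - counts, rarefaction_g) -
                          lchoose(genes, rarefaction_g)))
      both <- !is.na(gm$a1[sel, j])
      ho <- if (any(both))
        mean(gm$a1[sel, j][both] != gm$a2[sel, j][both]) else NA_real_
      c(k = length(f), eff = 1 / sum_p2, ar = ar, ho = ho, he = he,
        genes = genes)
    }, numeric(6)))
    rownames(stat) <- gm$loci
    per_locus[[p]] <<- stat
    ho <- mean(stat[, "ho"], na.rm = TRUE)
    he <- mean(stat[, "he"], na.rm = TRUE)
    data.frame(population = p, N = sum(sel),
               num_alleles = mean(stat[, "k"], na.rm = TRUE),
               eff_num_alleles = mean(stat[, "eff"], na.rm = TRUE),
               AR = mean(stat[, "ar"], na.rm = TRUE),
               Ho = ho, He = he,
               GIS = if (isTRUE(he > 0)) 1 - ho / he else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "per_locus") <- per_locus
  attr(out, "rarefaction_g") <- rarefaction_g
  out
}

#' Private alleles per species pool
#'
#' An allele is private to a pool when it is observed in that pool and in no
#' other. Populations mapped to \code{NA} (for example putative hybrids) are
#' ignored unless \code{require_full = TRUE}.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param species_assignment named character vector mapping population ids to
#'   pool labels (typically the two parental species); \code{NA} excludes a
#'   population.
#' @param require_full error if any population lacks an assignment.
#' @return matrix of private-allele counts, loci x pools, with a
#'   \code{"total"} row.
#' @export
private_alleles <- function(gm, species_assignment, require_full = FALSE) {
  pops <- unique(gm$population_id)
  unassigned <- setdiff(pops, names(species_assignment))
  if (length(unassigned) && require_full)
    stop("unassigned population(s): ", paste(unassigned, collapse = ", "))
  asg <- species_assignment[gm$population_id]
  pools <- unique(stats::na.omit(species_assignment))
  counts <- matrix(0L, length(gm$loci), length(pools),
                   dimnames = list(gm$loci, pools))
  for (j in seq_along(gm$loci)) {
    seen <- lapply(pools, function(pl) {
      rows <- !is.na(asg) & asg == pl
      unique(stats::na.omit(c(gm$a1[rows, j], gm$a2[rows, j])))
    })
    for (k in seq_along(pools)) {
      others <- unique(unlist(seen[-k]))
      counts[j, k] <- length(setdiff(seen[[k]], others))
    }
  }
  rbind(counts, total = colSums(counts))
}

# log conditional probability of a diploid genotype configuration given its
# allele counts (Levene's distribution); used as the ordering statistic for
# the exact HWE test.
hwe_log_prob <- function(g1, g2) {
  n <- length(g1)
  genes <- c(g1, g2)
  na <- table(genes)
  het <- sum(g1 != g2)
  geno <- table(paste(pmin(g1, g2), pmax(g1, g2)))
  lfactorial(n) + sum(lfactorial(na)) + het * log(2) -
    lfactorial(2 * n) - sum(lfactorial(geno))
}

#' Exact Hardy-Weinberg test by Monte Carlo
#'
#' For each locus x population cell, the exact-test p-value (probability
#' ordering) is estimated by repeatedly shuffling the sampled allele copies
#' into random diploid genotypes and counting arrangements no more probable
#' than the observed one under Levene's conditional distribution. Holm's
#' sequential Bonferroni is applied table-wide across all cells.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param reps Monte Carlo replicates (>= 1000).
#' @param seed RNG seed.
#' @return data frame with columns \code{population}, \code{locus}, \code{n},
#'   \code{k_alleles}, \code{p}, \code{p_holm}, \code{significant};
#'   monomorphic cells carry \code{NA} p-values.
#' @export
hwe_test <- function(gm, reps = 10000, seed = 1) {
  stopifnot(reps >= 1000)
  pops <- unique(gm$population_id)
  grid <- expand.grid(population = pops, locus = gm$loci,
                      stringsAsFactors = FALSE)
  with_seed(seed, {
    res <- lapply(seq_len(nrow(grid)), function(i) {
      rows <- gm$population_id == grid$population[i]
      j <- match(grid$locus[i], gm$loci)
      g1 <- gm$a1[rows, j]; g2 <- gm$a2[rows, j]
      ok <- !is.na(g1)
      g1 <- g1[ok]; g2 <- g2[ok]
      n <- length(g1)
      k <- length(unique(c(g1, g2)))
      if (n < 2 || k < 2)
        return(data.frame(n = n, k_alleles = k, p = NA_real_))
      obs <- hwe_log_prob(g1, g2)
      genes <- c(g1, g2)
      hits <- 0L
      for (r in seq_len(reps)) {
        s <- sample(genes)
        lp <- hwe_log_prob(s[seq_len(n)], s[n + seq_len(n)])
        if (lp <= obs + 1e-9) hits <- hits + 1L
      }
      data.frame(n = n, k_alleles = k, p = (hits + 1) / (reps + 1))
    })
  })
  out <- cbind(grid, do.call(rbind, res))
  out$p_holm <- NA_real_
  tested <- !is.na(out$p)
  out$p_holm[tested] <- stats::p.adjust(out$p[tested], method = "holm")
  out$significant <- !is.na(out$p_holm) & out$p_holm < 0.05
  out
}

# genotypic G statistic for a two-locus contingency table, pooled over
# populations; cells with zero observed count contribute nothing.
ld_g_stat <- function(t1, t2, pop) {
  g <- 0
  for (p in unique(pop)) {
    i <- pop == p
    tab <- table(t1[i], t2[i])
    if (nrow(tab) < 2 || ncol(tab) < 2) next
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    nz <- tab > 0
    g <- g + 2 * sum(tab[nz] * log(tab[nz] / e[nz]))
  }
  g
}

#' Linkage-disequilibrium G-test between locus pairs
#'
#' Per locus pair, a genotypic contingency G statistic is computed within each
#' population and summed; the null distribution comes from permuting one
#' locus's genotypes across individuals within populations. Standard
#' Bonferroni correction is applied across pairs.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param reps permutation replicates (>= 1000).
#' @param seed RNG seed.
#' @return data frame with columns \code{locus1}, \code{locus2}, \code{G},
#'   \code{p}, \code{p_bonferroni}; pairs with a dataset-monomorphic member
#'   are skipped (\code{NA}).
#' @export
ld_test <- function(gm, reps = 10000, seed = 1) {
  stopifnot(reps >= 1000)
  L <- length(gm$loci)
  if (L < 2) stop("need at least two loci")
  geno <- vapply(seq_len(L), function(j)
    ifelse(is.na(gm$a1[, j]), NA_character_,
           paste(pmin(gm$a1[, j], gm$a2[, j]),
                 pmax(gm$a1[, j], gm$a2[, j]))), character(nrow(gm$a1)))
  poly <- vapply(seq_len(L), function(j)
    length(unique(stats::na.omit(c(gm$a1[, j], gm$a2[, j])))) > 1, TRUE)
  pairs <- utils::combn(L, 2)
  with_seed(seed, {
    res <- lapply(seq_len(ncol(pairs)), function(pi) {
      j1 <- pairs[1, pi]; j2 <- pairs[2, pi]
      if (!poly[j1] || !poly[j2])
        return(data.frame(G = NA_real_, p = NA_real_))
      ok <- !is.na(geno[, j1]) & !is.na(geno[, j2])
      t1 <- geno[ok, j1]; t2 <- geno[ok, j2]; pop <- gm$population_id[ok]
      obs <- ld_g_stat(t1, t2, pop)
      hits <- 0L
      for (r in seq_len(reps)) {
        t2p <- t2
        for (p in unique(pop)) {
          i <- which(pop == p)
          t2p[i] <- t2[sample(i)]
        }
        if (ld_g_stat(t1, t2p, pop) >= obs - 1e-9) hits <- hits + 1L
      }
      data.frame(G = obs, p = (hits + 1) / (reps + 1))
    })
  })
  out <- cbind(data.frame(locus1 = gm$loci[pairs[1, ]],
                          locus2 = gm$loci[pairs[2, ]]),
               do.call(rbind, res))
  out$p_bonferroni <- pmin(1, out$p * sum(!is.na(out$p)))
  out
}

# Weir-Cockerham theta variance components summed over loci and alleles for a
# set of populations; returns c(a, abc) sums.
wc_components <- function(gm, rows_by_pop) {
  r <- length(rows_by_pop)
  A <- 0; ABC <- 0
  for (j in seq_along(gm$loci)) {
    dat <- lapply(rows_by_pop, function(rows) {
      a1 <- gm$a1[rows, j]; a2 <- gm$a2[rows, j]
      ok <- !is.na(a1)
      list(a1 = a1[ok], a2 = a2[ok], n = sum(ok))
    })
    n_i <- vapply(dat, `[[`, 0, "n")
    use <- n_i > 0
    if (sum(use) < 2) next
    dat <- dat[use]; n_i <- n_i[use]; ri <- length(dat)
    alleles <- unique(unlist(lapply(dat, function(d) c(d$a1, d$a2))))
    if (length(alleles) < 2) next
    nbar <- mean(n_i)
    nc <- (ri * nbar - sum(n_i^2) / (ri * nbar)) / (ri - 1)
    for (al in alleles) {
      p_i <- vapply(dat, function(d)
        sum(d$a1 == al, d$a2 == al) / (2 * d$n), 0)
      h_i <- vapply(dat, function(d)
        sum(xor(d$a1 == al, d$a2 == al)) / d$n, 0)
      pbar <- sum(n_i * p_i) / (ri * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((ri - 1) * nbar)
      hbar <- sum(n_i * h_i) / (ri * nbar)
      if (nbar <= 1) next
      a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (ri - 1) / ri * s2 -
                                hbar / 4) / (nbar - 1))
      b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (ri - 1) / ri * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      A <- A + a
      ABC <- ABC + a + b + cc
    }
  }
  c(a = A, abc = ABC)
}

#' Pairwise FST (Weir-Cockerham theta) with permutation tests
#'
#' Theta is computed per population pair over all loci (ratio of summed
#' variance components). Significance is assessed by permuting individuals
#' between the two populations; Holm's sequential Bonferroni is applied
#' across pairs. Pairs involving a single-individual population get an
#' estimate but no permutation p-value (with a warning).
#'
#' @param gm a \code{\link{genotype_matrix}} with >= 2 populations.
#' @param reps permutation replicates.
#' @param seed RNG seed.
#' @return list with symmetric matrices \code{theta}, \code{p},
#'   \code{p_holm}, and logical \code{significant}.
#' @export
pairwise_fst <- function(gm, reps = 999, seed = 1) {
  pops <- unique(gm$population_id)
  if (length(pops) < 2) stop("need at least two populations")
  k <- length(pops)
  theta <- p <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  diag(theta) <- 0
  with_seed(seed, {
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      rows_i <- which(gm$population_id == pops[i])
      rows_j <- which(gm$population_id == pops[j])
      comp <- wc_components(gm, list(rows_i, rows_j))
      th <- if (comp["abc"] > 0) comp["a"] / comp["abc"] else NA_real_
      theta[i, j] <- theta[j, i] <- th
      if (length(rows_i) < 2 || length(rows_j) < 2) {
        warning("population of one individual in pair ", pops[i], "-",
                pops[j], "; permutation p omitted")
        next
      }
      if (is.na(th)) next
      all_rows <- c(rows_i, rows_j)
      ni <- length(rows_i)
      hits <- 0L
      for (r in seq_len(reps)) {
        perm <- sample(all_rows)
        cp <- wc_components(gm, list(perm[seq_len(ni)], perm[-seq_len(ni)]))
        tp <- if (cp["abc"] > 0) cp["a"] / cp["abc"] else -Inf
        if (tp >= th - 1e-12) hits <- hits + 1L
      }
      p[i, j] <- p[j, i] <- (hits + 1) / (reps + 1)
    }
  })
  ut <- upper.tri(p)
  ph <- matrix(NA_real_, k, k, dimnames = dimnames(p))
  vals <- p[ut]
  adj <- rep(NA_real_, length(vals))
  adj[!is.na(vals)] <- stats::p.adjust(vals[!is.na(vals)], method = "holm")
  ph[ut] <- adj
  ph[lower.tri(ph)] <- t(ph)[lower.tri(ph)]
  list(theta = theta, p = p, p_holm = ph,
       significant = !is.na(ph) & ph < 0.05)
}
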