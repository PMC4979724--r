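# Shared fixture builders and independent oracles.

# Build a genotype_matrix from a compact spec: list of populations, each a
# list of individuals, each a list of c(a1, a2) calls per locus (NA allowed).
make_gm <- function(pops, loci = NULL, era = "recent") {
  n_loci <- length(pops[[1]][[1]])
  if (is.null(loci)) loci <- paste0("L", seq_len(n_loci))
  ids <- character(0); pop <- character(0)
  a1 <- NULL; a2 <- NULL
  for (pname in names(pops)) {
    for (i in seq_along(pops[[pname]])) {
      calls <- pops[[pname]][[i]]
      ids <- c(ids, paste0(pname, "_", i))
      pop <- c(pop, pname)
      a1 <- rbind(a1, vapply(calls, `[`, 0, 1))
      a2 <- rbind(a2, vapply(calls, `[`, 0, 2))
    }
  }
  genotype_matrix(ids, pop, pop, era, loci, a1, a2)
}

# Random genotype_matrix for round-trip tests.
random_gm <- function(n_pop = 3, n_ind = 5, n_loci = 4, seed = 1,
                      missing = 0.1) {
  set.seed(seed)
  n <- n_pop * n_ind
  a1 <- matrix(sample(100:140, n * n_loci, TRUE), n, n_loci)
  a2 <- matrix(sample(100:140, n * n_loci, TRUE), n, n_loci)
  miss <- matrix(runif(n * n_loci) < missing, n, n_loci)
  a1[miss] <- NA; a2[miss] <- NA
  genotype_matrix(sprintf("i%03d", 1:n), rep(paste0("p", 1:n_pop),
                                             each = n_ind),
                  rep(paste0("p", 1:n_pop), each = n_ind),
                  "recent", paste0("loc", 1:n_loci), a1, a2)
}

# Exact HWE p-value (probability ordering) for a biallelic sample by full
# enumeration of heterozygote counts under Levene's conditional distribution.
hwe_exact_biallelic <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  nB <- 2 * nBB + nAB
  hs <- seq(nA %% 2, min(nA, nB), by = 2)
  lp <- vapply(hs, function(h) {
    naa <- (nA - h) / 2; nbb <- (nB - h) / 2
    lfactorial(n) + lfactorial(nA) + lfactorial(nB) + h * log(2) -
      lfactorial(2 * n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb)
  }, 0)
  obs <- lp[match(nAB, hs)]
  sum(exp(lp[lp <= obs + 1e-9]))
}

# Brute-force Holm rejection set: reject smallest p first while
# p_(i) <= alpha / (m - i + 1), stop at the first failure.
holm_reject_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) reject[ord[i]] <- TRUE
    else break
  }
  reject
}

# Independent transcription of the Weir-Cockerham theta variance components
# for a single biallelic locus and two populations (used as a hand oracle).
wc_theta_biallelic_2pop <- function(p1, h1, n1, p2, h2, n2) {
  r <- 2
  theta_num <- 0; theta_den <- 0
  for (p_i in list(c(p1, h1, n1, p2, h2, n2),
                   c(1 - p1, h1, n1, 1 - p2, h2, n2))) {
    pa <- p_i[1]; ha <- p_i[2]; na <- p_i[3]
    pb <- p_i[4]; hb <- p_i[5]; nb <- p_i[6]
    nbar <- (na + nb) / 2
    nc <- (r * nbar - (na^2 + nb^2) / (r * nbar)) / (r - 1)
    pbar <- (na * pa + nb * pb) / (r * nbar)
    s2 <- (na * (pa - pbar)^2 + nb * (pb - pbar)^2) / ((r - 1) * nbar)
    hbar <- (na * ha + nb * hb) / (r * nbar)
    a <- nbar / nc *
      (s2 - 1 / (nbar - 1) *
         (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    theta_num <- theta_num + a
    theta_den <- theta_den + a + b + cc
  }
  theta_num / theta_den
}

# Grid-search oracle for the hybrid-index MLE.
hybrid_index_grid <- function(calls, pf, step = 0.001) {
  grid <- seq(0, 1, by = step)
  lnl <- vapply(grid, function(h) {
    s <- 0
    for (loc in names(calls)) {
      al <- calls[[loc]]
      if (anyNA(al)) next
      fm <- pf$freq[[loc]]
      for (a in al) {
        k <- match(as.character(a), colnames(fm))
        s <- s + log(h * fm["alt", k] + (1 - h) * fm["ref", k])
      }
    }
    s
  }, 0)
  list(h = grid[which.max(lnl)], lnL = max(lnl))
}
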