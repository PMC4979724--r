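test_that("allele frequencies match direct counts and flag empty loci", {
  gm <- make_gm(list(p1 = list(list(c(1, 1), c(NA, NA)),
                               list(c(1, 3), c(NA, NA)))))
  af <- allele_frequencies(gm, "p1")
  expect_equal(af$L1$freq, c("1" = 0.75, "3" = 0.25))
  expect_equal(af$L1$genes, 4)
  expect_null(af$L2)

  # 10-individual fixture vs independent tally
  set.seed(7)
  calls <- replicate(10, list(list(sample(1:4, 2, TRUE), sample(1:3, 2, TRUE))),
                     simplify = FALSE)
  gm2 <- make_gm(list(pA = lapply(calls, `[[`, 1)))
  af2 <- allele_frequencies(gm2, "pA")
  genes1 <- c(gm2$a1[, 1], gm2$a2[, 1])
  tally <- table(genes1) / length(genes1)
  expect_equal(af2$L1$freq, setNames(as.numeric(tally), names(tally)))
  expect_error(allele_frequencies(gm2, "nope"), "unknown population")
})

test_that("diversity summary: degenerate cases and rarefaction oracle", {
  # monomorphic locus: He = 0, eff alleles = 1, GIS undefined
  gm <- make_gm(list(p1 = list(list(c(5, 5)), list(c(5, 5)))))
  d <- diversity_summary(gm, rarefaction_g = 2)
  expect_equal(d$He, 0)
  expect_equal(d$eff_num_alleles, 1)
  expect_true(is.na(d$GIS))
  expect_equal(d$Ho, 0)

  # toy 5-individual, 3-allele locus: AR_g equals the exhaustive-subsample
  # mean number of distinct alleles over all C(2n, g) gene subsets
  gm2 <- make_gm(list(p1 = list(list(c(1, 1)), list(c(1, 2)), list(c(2, 3)),
                                list(c(3, 3)), list(c(1, 1)))))
  genes <- c(gm2$a1[, 1], gm2$a2[, 1])
  for (g in c(2, 4, 6)) {
    subs <- combn(length(genes), g)
    ar_oracle <- mean(apply(subs, 2, function(ix)
      length(unique(genes[ix]))))
    d2 <- diversity_summary(gm2, rarefaction_g = g)
    expect_equal(d2$AR, ar_oracle, tolerance = 1e-12)
  }
  # monotone non-decreasing in g; equals observed count at g = 2n
  ar <- vapply(2:10, function(g)
    diversity_summary(gm2, rarefaction_g = g)$AR, 0)
  expect_true(all(diff(ar) >= -1e-12))
  expect_equal(ar[9], 3)
  expect_error(diversity_summary(gm2, rarefaction_g = 11),
               "exceeds the smallest")
})

test_that("unbiased He and GIS follow their definitions", {
  # 2 individuals AB, AB: Ho = 1, plain He = 0.5, Nei-corrected = 0.5*4/3
  gm <- make_gm(list(p1 = list(list(c(1, 2)), list(c(1, 2)))))
  d <- diversity_summary(gm, rarefaction_g = 2)
  expect_equal(d$He, 0.5 * 4 / 3)
  expect_equal(d$GIS, 1 - 1 / d$He)
  d0 <- diversity_summary(gm, rarefaction_g = 2, unbiased = FALSE)
  expect_equal(d0$He, 0.5)
  # effective alleles <= observed count, equality iff uniform frequencies
  expect_equal(d$eff_num_alleles, 2)       # uniform 0.5/0.5
  gm2 <- make_gm(list(p1 = list(list(c(1, 1)), list(c(1, 2)))))
  d2 <- diversity_summary(gm2, rarefaction_g = 2)
  expect_lt(d2$eff_num_alleles, 2)
})

test_that("private alleles are set differences between species pools", {
  gm <- make_gm(list(
    west = list(list(c(1, 2), c(10, 10))),
    east = list(list(c(2, 3), c(10, 12)))))
  asg <- c(west = "sppW", east = "sppE")
  pa <- private_alleles(gm, asg)
  # locus 1: allele 1 private to W, 3 private to E, 2 shared
  expect_equal(unname(pa["L1", ]), c(1L, 1L))
  # locus 2: allele 12 private to E
  expect_equal(unname(pa["L2", ]), c(0L, 1L))
  expect_equal(unname(pa["total", ]), c(1L, 2L))
  expect_error(private_alleles(gm, c(west = "sppW"), require_full = TRUE),
               "unassigned")
  # set-difference oracle on a random two-pool fixture
  gm2 <- random_gm(n_pop = 2, n_ind = 6, n_loci = 3, seed = 11)
  asg2 <- c(p1 = "A", p2 = "B")
  pa2 <- private_alleles(gm2, asg2)
  for (j in 1:3) {
    inA <- unique(na.omit(c(gm2$a1[gm2$population_id == "p1", j],
                            gm2$a2[gm2$population_id == "p1", j])))
    inB <- unique(na.omit(c(gm2$a1[gm2$population_id == "p2", j],
                            gm2$a2[gm2$population_id == "p2", j])))
    expect_equal(unname(pa2[j, ]),
                 c(length(setdiff(inA, inB)), length(setdiff(inB, inA))))
  }
})

test_that("HWE Monte Carlo matches exact enumeration and flags deviation", {
  # perfect HWE composition: p near 1
  gm <- make_gm(list(p1 = c(
    replicate(25, list(list(c(1, 1)))),
    replicate(50, list(list(c(1, 2)))),
    replicate(25, list(list(c(2, 2)))))))
  r <- hwe_test(gm, reps = 2000, seed = 1)
  expect_gt(r$p, 0.5)

  # complete heterozygote deficit: tiny p
  gm2 <- make_gm(list(p1 = c(
    replicate(50, list(list(c(1, 1)))),
    replicate(50, list(list(c(2, 2)))))))
  r2 <- hwe_test(gm2, reps = 10000, seed = 1)
  expect_lt(r2$p, 0.001)

  # monomorphic locus skipped
  gm3 <- make_gm(list(p1 = list(list(c(1, 1)), list(c(1, 1)))))
  expect_true(is.na(hwe_test(gm3, reps = 1000)$p))

  # tiny biallelic samples: MC within 3 binomial SE of full enumeration
  cases <- list(c(2, 1, 2), c(3, 0, 2), c(1, 3, 1), c(0, 2, 3))
  for (cs in cases) {
    gm4 <- make_gm(list(p1 = c(
      replicate(cs[1], list(list(c(1, 1)))),
      replicate(cs[2], list(list(c(1, 2)))),
      replicate(cs[3], list(list(c(2, 2)))))))
    reps <- 4000
    r4 <- hwe_test(gm4, reps = reps, seed = 3)
    p_exact <- hwe_exact_biallelic(cs[1], cs[2], cs[3])
    se <- sqrt(p_exact * (1 - p_exact) / reps)
    expect_lt(abs(r4$p - p_exact), 3 * se + 2 / reps)
  }
})

test_that("Holm flags agree with the brute-force step-down oracle", {
  set.seed(42)
  for (rep in 1:20) {
    p <- runif(sample(3:12, 1))^sample(1:3, 1)
    got <- stats::p.adjust(p, method = "holm") < 0.05
    expect_equal(got, holm_reject_oracle(p, 0.05))
    # Holm rejects a subset of unadjusted rejections
    expect_true(all(!got | (p < 0.05)))
  }
})

test_that("LD G-test: hand-computed G, perfect association, null rate", {
  # 2x2 genotype table, G = 2 sum O log(O/E)
  g1 <- rep(c("11", "12"), c(6, 4))
  g2 <- c(rep("33", 5), "34", rep("34", 3), "33")
  tab <- table(g1, g2)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  G_hand <- 2 * sum(ifelse(tab > 0, tab * log(tab / e), 0))
  expect_equal(clinezone:::ld_g_stat(g1, g2, rep("p", 10)), G_hand)

  # duplicated locus: p at the permutation floor
  set.seed(5)
  calls <- lapply(1:12, function(i) {
    a <- sort(sample(1:2, 2, TRUE))
    list(a, a + 10)   # locus 2 duplicates locus 1
  })
  gm <- make_gm(list(p1 = calls))
  reps <- 1000
  r <- ld_test(gm, reps = reps, seed = 2)
  expect_equal(r$p, 1 / (reps + 1), tolerance = 5 / reps)

  # monomorphic member skipped
  gm2 <- make_gm(list(p1 = list(list(c(1, 1), c(2, 2)),
                                list(c(1, 2), c(2, 2)))))
  expect_true(is.na(ld_test(gm2, reps = 1000)$p))

  # independent loci: rejection rate near nominal alpha
  rej <- vapply(1:12, function(s) {
    set.seed(100 + s)
    calls <- lapply(1:15, function(i)
      list(sort(sample(1:3, 2, TRUE)), sort(sample(11:13, 2, TRUE))))
    ld_test(make_gm(list(p1 = calls)), reps = 1000, seed = s)$p < 0.05
  }, TRUE)
  expect_lte(sum(rej), 4)   # P(>4 of 12 at alpha .05) < 3e-4
})

test_that("pairwise FST: endpoints and the variance-component oracle", {
  # identical genotype multisets: theta ~ 0 (the unbiased estimator is
  # slightly negative at finite n, shrinking toward 0 as n grows)
  blk <- rep(list(list(c(1, 1)), list(c(1, 2)), list(c(2, 2)),
                  list(c(1, 2))), 10)
  gm <- make_gm(list(pA = blk, pB = blk))
  f <- pairwise_fst(gm, reps = 199, seed = 1)
  expect_lt(abs(f$theta["pA", "pB"]), 0.02)
  expect_gt(f$p["pA", "pB"], 0.5)

  # fixed difference at every locus: theta = 1
  gmF <- make_gm(list(pA = list(list(c(1, 1), c(5, 5)), list(c(1, 1), c(5, 5))),
                      pB = list(list(c(2, 2), c(6, 6)), list(c(2, 2), c(6, 6)))))
  fF <- pairwise_fst(gmF, reps = 199, seed = 1)
  expect_equal(fF$theta["pA", "pB"], 1)

  # hand oracle: one biallelic locus, two populations
  gmH <- make_gm(list(pA = list(list(c(1, 1)), list(c(1, 1)), list(c(1, 2))),
                      pB = list(list(c(1, 2)), list(c(2, 2)), list(c(2, 2)))))
  fH <- pairwise_fst(gmH, reps = 199, seed = 1)
  th_oracle <- wc_theta_biallelic_2pop(p1 = 5 / 6, h1 = 1 / 3, n1 = 3,
                                       p2 = 1 / 6, h2 = 1 / 3, n2 = 3)
  expect_equal(fH$theta["pA", "pB"], th_oracle, tolerance = 1e-12)

  # permutation p within Monte-Carlo error of full enumeration
  all_rows <- 1:6
  splits <- combn(all_rows, 3)
  th_all <- apply(splits, 2, function(ix)
    local({
      comp <- clinezone:::wc_components(gmH, list(ix, setdiff(all_rows, ix)))
      comp["a"] / comp["abc"]
    }))
  p_exact <- mean(th_all >= fH$theta["pA", "pB"] - 1e-12)
  reps <- 1999
  fMC <- pairwise_fst(gmH, reps = reps, seed = 7)
  se <- sqrt(p_exact * (1 - p_exact) / reps)
  expect_lt(abs(fMC$p["pA", "pB"] - p_exact), 3 * se + 2 / reps)

  # single-individual population: estimate with warning, p absent
  gm1 <- make_gm(list(pA = list(list(c(1, 1))),
                      pB = list(list(c(2, 2)), list(c(1, 2)))))
  expect_warning(f1 <- pairwise_fst(gm1, reps = 99), "one individual")
  expect_true(is.na(f1$p["pA", "pB"]))
})
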