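test_that("GenePop files parse: codes, missing, populations", {
  txt <- c("toy zone data",
           "locA", "locB",
           "Pop",
           "w1 , 001003 002002",
           "w2 , 001001 000000",
           "Pop",
           "e1 , 003003 004002",
           "Pop",
           "m1 , 001003 002004",
           "m2 , 003003 002002")
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(txt, f)
  gm <- read_genepop(f)
  expect_s3_class(gm, "genotype_matrix")
  expect_equal(gm$loci, c("locA", "locB"))
  expect_equal(sort(c(gm$a1["w1", "locA"], gm$a2["w1", "locA"])), c(1, 3))
  expect_true(is.na(gm$a1["w2", "locB"]) && is.na(gm$a2["w2", "locB"]))
  expect_equal(length(unique(gm$population_id)), 3)
  expect_equal(as.integer(table(gm$population_id)[unique(gm$population_id)]),
               c(2L, 1L, 2L))
  # 2-digit dialect
  writeLines(c("t", "locA", "Pop", "a1 , 0103", "a2 , 0000"), f)
  gm2 <- read_genepop(f)
  expect_equal(sort(c(gm2$a1[1, 1], gm2$a2[1, 1])), c(1, 3))
  expect_true(is.na(gm2$a1[2, 1]))
})

test_that("GenePop parse errors name the offence", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("t", "locA", "Pop", "x1 , 00103"), f)
  expect_error(read_genepop(f), "allele code width")
  writeLines(c("t", "locA", "Pop", "Pop", "x1 , 001003"), f)
  expect_error(read_genepop(f), "empty 'Pop'")
})

test_that("genotype matrices round-trip through GenePop exactly", {
  for (seed in 1:3) {
    gm <- random_gm(seed = seed)
    f <- withr::local_tempfile(fileext = ".gen")
    write_genepop(gm, f)
    back <- read_genepop(f, pop_names = unique(gm$population_id))
    expect_equal(unname(back$a1), unname(gm$a1))
    expect_equal(unname(back$a2), unname(gm$a2))
    expect_equal(back$population_id, gm$population_id)
  }
})

test_that("CSV genotypes read with metadata; malformed inputs error", {
  g <- data.frame(individual = rep(c("i1", "i2", "i3", "i4"), each = 2),
                  site = rep(c("s1", "s1", "s2", "s2"), each = 2),
                  locus = rep(c("L1", "L2"), 4),
                  allele1 = c(1, 2, 1, 2, 3, 4, 3, NA),
                  allele2 = c(1, 2, 3, 2, 3, 4, 1, NA))
  m <- data.frame(site = c("s1", "s2"), latitude = c(30, 31),
                  longitude = c(-90, -89), era = "recent")
  fg <- withr::local_tempfile(fileext = ".csv")
  fm <- withr::local_tempfile(fileext = ".csv")
  write.csv(g, fg, row.names = FALSE)
  write.csv(m, fm, row.names = FALSE)
  gm <- read_genotype_csv(fg, fm)
  expect_equal(length(gm$individual_id), 4)
  expect_true(is.na(gm$a1["i4", "L2"]))
  expect_equal(attr(gm, "meta")$site, c("s1", "s2"))

  # individual at a site absent from metadata
  write.csv(m[1, ], fm, row.names = FALSE)
  expect_error(read_genotype_csv(fg, fm), "i3")

  # half-missing call
  g2 <- g; g2$allele2[1] <- NA
  write.csv(g2, fg, row.names = FALSE)
  expect_error(read_genotype_csv(fg, fm), "half-missing")

  # duplicated individual x locus row
  g3 <- rbind(g, g[1, ])
  write.csv(g3, fg, row.names = FALSE)
  expect_error(read_genotype_csv(fg, fm), "duplicated")
})

test_that("half-missing calls are promoted to missing with a warning", {
  expect_warning(
    gm <- genotype_matrix("i1", "s", "p", "recent", c("L1"),
                          matrix(5L), matrix(NA_integer_)),
    "half-missing")
  expect_true(is.na(gm$a1[1, 1]) && is.na(gm$a2[1, 1]))
})

test_that("pooling reproduces the published weighted coordinates", {
  sites <- pearl_river_sites()
  # one dummy monomorphic locus; counts per site as published
  ids <- unlist(lapply(seq_len(nrow(sites)), function(i)
    paste0(sites$site[i], "_", seq_len(sites$n[i]))))
  site_of <- rep(sites$site, sites$n)
  n <- length(ids)
  gm <- genotype_matrix(ids, site_of, site_of, "recent", "L1",
                        matrix(100L, n), matrix(100L, n))
  expect_warning(
    res <- pool_collection_sites(gm, sites, radius_km = 4,
                                 pool_labels = LETTERS[1:16]),
    "M22")
  expect_equal(attr(res, "excluded"), "M22")
  expect_equal(nrow(res$meta), 16)
  # population C = M16 (n=5) + M15 (n=3)
  C <- res$meta[res$meta$sites %in% c("M16+M15", "M15+M16"), ]
  expect_equal(nrow(C), 1)
  expect_equal(C$latitude, 30.77479, tolerance = 1e-6)
  expect_equal(C$longitude, -90.74948, tolerance = 1e-6)
  expect_equal(C$N, 8)
  # conservation: pooled N sums to site n minus exclusions
  expect_equal(sum(res$meta$N), sum(sites$n) - 1)
  expect_equal(length(res$genotypes$individual_id), sum(sites$n) - 1)
  # published groupings reproduced from coordinates alone
  got <- res$meta$sites[match(LETTERS[1:16], res$meta$population_id)]
  want <- tapply(sites$site[!is.na(sites$population_id)],
                 sites$population_id[!is.na(sites$population_id)],
                 paste, collapse = "+")
  expect_equal(lapply(strsplit(got, "\\+"), sort),
               unname(lapply(strsplit(want[LETTERS[1:16]], "\\+"), sort)))
})

test_that("pooling uses single-linkage closure and respects geometry", {
  # chain: A-B 3 km, B-C 3 km, A-C 6 km -> one pool of three
  lat <- 30; km_per_deg <- 111.32
  lats <- lat + c(0, 3, 6) / km_per_deg
  sites <- data.frame(site = c("sA", "sB", "sC"), latitude = lats,
                      longitude = -90, era = "recent")
  gm <- genotype_matrix(paste0("i", 1:6), rep(sites$site, each = 2),
                        rep(sites$site, each = 2), "recent", "L1",
                        matrix(100L, 6), matrix(102L, 6))
  res <- pool_collection_sites(gm, sites, radius_km = 4)
  expect_equal(nrow(res$meta), 1)
  expect_equal(res$meta$N, 6)
  # weighted coordinates inside the convex hull of member sites
  expect_gte(res$meta$latitude, min(lats))
  expect_lte(res$meta$latitude, max(lats))
  # a single isolated site passes through unchanged
  res1 <- pool_collection_sites(
    genotype_matrix(c("a", "b"), "sA", "sA", "recent", "L1",
                    matrix(100L, 2), matrix(100L, 2)),
    sites[1, ], radius_km = 4)
  expect_equal(res1$meta$latitude, sites$latitude[1])
  expect_equal(res1$meta$N, 2)
})
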