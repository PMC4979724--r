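# Genotype container, GenePop / CSV readers, and geographic pooling.

#' Diploid microsatellite genotype matrix
#'
#' Container for diploid allele-length calls at a common set of loci, with
#' per-individual collection site, population and sampling-era labels.
#' Allele calls are stored as two integer matrices (individuals x loci);
#' a missing call has \code{NA} in both.
#'
#' @param individual_id character vector of unique individual labels.
#' @param collection_site character vector of collection-site labels.
#' @param population_id character vector of population labels.
#' @param era character vector; each population must belong to a single era
#'   (conventionally \code{"historical"} or \code{"recent"}).
#' @param loci character vector of locus names (column order is shared by all
#'   individuals).
#' @param a1,a2 integer matrices of allele lengths, one row per individual and
#'   one column per locus; \code{NA} marks a missing call. A half-missing call
#'   (one \code{NA}) is promoted to fully missing with a warning.
#' @return an object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(individual_id, collection_site, population_id,
                            era, loci, a1, a2) {
  individual_id <- as.character(individual_id)
  n <- length(individual_id)
  if (anyDuplicated(individual_id))
    stop("duplicated individual ids: ",
         paste(unique(individual_id[duplicated(individual_id)]),
               collapse = ", "))
  collection_site <- rep_len(as.character(collection_site), n)
  population_id <- rep_len(as.character(population_id), n)
  era <- rep_len(as.character(era), n)
  loci <- as.character(loci)
  a1 <- matrix(as.integer(a1), n, length(loci),
               dimnames = list(individual_id, loci))
  a2 <- matrix(as.integer(a2), n, length(loci),
               dimnames = list(individual_id, loci))
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    warning(sum(half), " half-missing call(s) promoted to missing")
    a1[half] <- NA_integer_
    a2[half] <- NA_integer_
  }
  ok <- is.na(a1) | (a1 > 0 & a2 > 0)
  if (!all(ok, na.rm = TRUE) || any(!is.na(a1) & is.na(ok)))
    stop("allele lengths must be positive integers")
  pe <- unique(data.frame(population_id, era))
  if (anyDuplicated(pe$population_id))
    stop("population assigned to more than one era: ",
         paste(pe$population_id[duplicated(pe$population_id)], collapse = ", "))
  structure(list(individual_id = individual_id,
                 collection_site = collection_site,
                 population_id = population_id,
                 era = era, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$individual_id), "individuals,",
      length(x$loci), "loci,",
      length(unique(x$population_id)), "populations\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("  eras: %s; missing calls: %.1f%%\n",
              paste(unique(x$era), collapse = ", "), 100 * miss))
  invisible(x)
}

#' Number of individuals per population
#' @param gm a \code{genotype_matrix}.
#' @return named integer vector.
#' @export
population_sizes <- function(gm) {
  tab <- table(gm$population_id)
  stats::setNames(as.integer(tab), names(tab))
}

# Subset a genotype_matrix by individual index or id.
subset_individuals <- function(gm, idx) {
  if (is.character(idx)) idx <- match(idx, gm$individual_id)
  genotype_matrix(gm$individual_id[idx], gm$collection_site[idx],
                  gm$population_id[idx], gm$era[idx], gm$loci,
                  gm$a1[idx, , drop = FALSE], gm$a2[idx, , drop = FALSE])
}

#' Read a GenePop genotype file
#'
#' Parses the standard GenePop text format: a title line, locus names (one per
#' line or comma-separated on one line), and populations separated by lines
#' reading \code{Pop}. Both the 2-digit and 3-digit diploid allele encodings
#' are accepted; \code{00}/\code{000} marks a missing allele.
#'
#' @param path path to a GenePop file.
#' @param era era label attached to all populations (default \code{"recent"}).
#' @param pop_names optional character vector of population labels, one per
#'   \code{Pop} block; defaults to the label of each block's first individual,
#'   falling back to \code{pop_1, pop_2, ...} on duplicates.
#' @return a \code{\link{genotype_matrix}}.
#' @export
read_genepop <- function(path, era = "recent", pop_names = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a GenePop file: too few lines")
  body <- lines[-1]                       # drop title
  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no 'Pop' separator found")
  locus_lines <- body[seq_len(first_pop - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("no locus names before first 'Pop'")
  block <- cumsum(is_pop)
  ind_lines <- body[!is_pop & block >= 1]
  ind_block <- block[!is_pop & block >= 1]
  n_blocks <- max(block)
  if (any(tabulate(ind_block, n_blocks) == 0))
    stop("empty 'Pop' block in GenePop file")

  n <- length(ind_lines)
  ids <- character(n)
  a1 <- matrix(NA_integer_, n, length(loci))
  a2 <- matrix(NA_integer_, n, length(loci))
  for (i in seq_len(n)) {
    parts <- strsplit(ind_lines[i], ",")[[1]]
    if (length(parts) < 2)
      stop("malformed GenePop individual line (no comma): ", ind_lines[i])
    ids[i] <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = " ")),
                      "\\s+")[[1]]
    if (length(codes) != length(loci))
      stop("individual '", ids[i], "': ", length(codes),
           " genotypes for ", length(loci), " loci")
    w <- nchar(codes)
    if (!all(w %in% c(4L, 6L)))
      stop("malformed allele code width at individual '", ids[i],
           "': ", codes[which(!(w %in% c(4L, 6L)))[1]])
    half <- w / 2
    x1 <- as.integer(substr(codes, 1, half))
    x2 <- as.integer(substr(codes, half + 1, w))
    if (anyNA(x1) || anyNA(x2))
      stop("non-numeric allele code at individual '", ids[i], "'")
    x1[x1 == 0L] <- NA_integer_
    x2[x2 == 0L] <- NA_integer_
    a1[i, ] <- x1
    a2[i, ] <- x2
  }
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  if (is.null(pop_names)) {
    pop_names <- vapply(seq_len(n_blocks),
                        function(b) ids[which(ind_block == b)[1]], "")
    if (anyDuplicated(pop_names))
      pop_names <- paste0("pop_", seq_len(n_blocks))
  }
  if (length(pop_names) != n_blocks)
    stop("need ", n_blocks, " population names")
  genotype_matrix(ids, collection_site = pop_names[ind_block],
                  population_id = pop_names[ind_block],
                  era = era, loci = loci, a1 = a1, a2 = a2)
}

#' Write a genotype matrix in GenePop format
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param path output file path.
#' @param digits allele-code width per allele (2 or 3).
#' @param title title line content.
#' @return \code{path}, invisibly.
#' @export
write_genepop <- function(gm, path, digits = 3, title = "clinezone export") {
  stopifnot(digits %in% c(2, 3))
  if (max(c(0, gm$a1, gm$a2), na.rm = TRUE) >= 10^digits)
    stop("allele lengths too large for ", digits, "-digit codes")
  fmt <- function(m) {
    v <- ifelse(is.na(m), 0L, m)
    matrix(formatC(v, width = digits, flag = "0"), nrow(m), ncol(m))
  }
  c1 <- fmt(gm$a1); c2 <- fmt(gm$a2)
  out <- c(title, gm$loci)
  for (p in unique(gm$population_id)) {
    out <- c(out, "Pop")
    for (i in which(gm$population_id == p)) {
      out <- c(out, paste0(gm$individual_id[i], " ,  ",
                           paste0(c1[i, ], c2[i, ], collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read genotypes and site metadata from CSV files
#'
#' The genotype table may be long (columns \code{individual}, \code{site},
#' \code{locus}, \code{allele1}, \code{allele2}) or wide (columns
#' \code{individual}, \code{site}, then \code{<locus>.a1}/\code{<locus>.a2}
#' pairs). The metadata table must carry one row per collection site with
#' columns \code{site}, \code{latitude}, \code{longitude}, \code{era} and
#' optionally \code{population_id} (defaults to the site label).
#'
#' @param path genotype CSV path.
#' @param meta metadata CSV path or data frame.
#' @return a \code{\link{genotype_matrix}} with an attached
#'   \code{attr(, "meta")} data frame of site coordinates.
#' @export
read_genotype_csv <- function(path, meta) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.data.frame(meta))
    meta <- utils::read.csv(meta, stringsAsFactors = FALSE)
  names(meta) <- tolower(names(meta))
  need <- c("site", "latitude", "longitude", "era")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  names(g) <- tolower(names(g))
  long <- all(c("individual", "site", "locus", "allele1", "allele2") %in%
                names(g))
  if (long) {
    g$allele1 <- suppressWarnings(as.integer(g$allele1))
    g$allele2 <- suppressWarnings(as.integer(g$allele2))
    if (any(xor(is.na(g$allele1), is.na(g$allele2))))
      stop("half-missing call(s) in CSV: both alleles must be given or empty")
    loci <- unique(g$locus)
    inds <- unique(g[, c("individual", "site")])
    if (anyDuplicated(inds$individual))
      stop("individual recorded at more than one site: ",
           paste(unique(inds$individual[duplicated(inds$individual)]),
                 collapse = ", "))
    key <- paste(g$individual, g$locus)
    if (anyDuplicated(key))
      stop("duplicated individual x locus rows in CSV")
    n <- nrow(inds)
    a1 <- matrix(NA_integer_, n, length(loci),
                 dimnames = list(inds$individual, loci))
    a2 <- a1
    ii <- match(g$individual, inds$individual)
    jj <- match(g$locus, loci)
    a1[cbind(ii, jj)] <- g$allele1
    a2[cbind(ii, jj)] <- g$allele2
  } else {
    if (!all(c("individual", "site") %in% names(g)))
      stop("genotype CSV must be long (individual, site, locus, allele1, ",
           "allele2) or wide (individual, site, <locus>.a1, <locus>.a2)")
    if (anyDuplicated(g$individual))
      stop("duplicated individual id: ",
           paste(unique(g$individual[duplicated(g$individual)]),
                 collapse = ", "))
    ac <- grep("\\.a[12]$", names(g), value = TRUE)
    loci <- unique(sub("\\.a[12]$", "", ac))
    miss <- setdiff(c(paste0(loci, ".a1"), paste0(loci, ".a2")), ac)
    if (length(miss)) stop("unpaired allele columns: ",
                           paste(miss, collapse = ", "))
    inds <- g[, c("individual", "site")]
    a1 <- as.matrix(g[, paste0(loci, ".a1"), drop = FALSE])
    a2 <- as.matrix(g[, paste0(loci, ".a2"), drop = FALSE])
    storage.mode(a1) <- storage.mode(a2) <- "integer"
    dimnames(a1) <- dimnames(a2) <- list(inds$individual, loci)
  }
  absent <- setdiff(unique(inds$site), meta$site)
  if (length(absent)) {
    bad <- inds$individual[inds$site %in% absent]
    stop("individual(s) with site absent from metadata: ",
         paste(bad, collapse = ", "))
  }
  m <- meta[match(inds$site, meta$site), ]
  pop <- if ("population_id" %in% names(m)) m$population_id else m$site
  gm <- genotype_matrix(inds$individual, inds$site, pop, m$era,
                        loci, a1, a2)
  attr(gm, "meta") <- meta
  gm
}

#' Pool collection sites within a distance threshold
#'
#' Sites are merged by single-linkage closure over great-circle distance: any
#' two sites within \code{radius_km} are linked, and connected components
#' become populations. Pooled coordinates are the individual-count-weighted
#' means of the member-site coordinates. Isolated sites with fewer than
#' \code{min_n} individuals are excluded (with a report) rather than carried
#' as 1-frog populations.
#'
#' @param gm a \code{\link{genotype_matrix}} whose \code{collection_site}
#'   labels match \code{meta$site}.
#' @param meta data frame with columns \code{site}, \code{latitude},
#'   \code{longitude} (and optionally \code{era}).
#' @param radius_km linkage threshold in kilometres (default 4, roughly 20-30
#'   annual dispersal distances for small hylid frogs).
#' @param fst_guard if \code{TRUE}, pairwise Weir-Cockerham FST with
#'   permutation p-values is computed for every within-pool site pair and
#'   pairs still significant after Holm correction are reported in
#'   \code{attr(, "fst_flags")} (merges are reported, not blocked).
#' @param min_n exclusion floor for isolated sites (default 2).
#' @param fst_reps,seed permutation settings for the FST guard.
#' @param pool_labels optional character vector of labels for the pooled
#'   populations in west-to-east (increasing longitude) order.
#' @return list with elements \code{genotypes} (repooled
#'   \code{genotype_matrix}) and \code{meta} (pooled population table with
#'   weighted coordinates and N). Attributes: \code{excluded} (sites dropped),
#'   \code{fst_flags} (if guarded).
#' @export
pool_collection_sites <- function(gm, meta, radius_km = 4, fst_guard = FALSE,
                                  min_n = 2, fst_reps = 999, seed = 1,
                                  pool_labels = NULL) {
  meta <- as.data.frame(meta)
  sites <- unique(gm$collection_site)
  if (!all(sites %in% meta$site))
    stop("sites missing from metadata: ",
         paste(setdiff(sites, meta$site), collapse = ", "))
  m <- meta[match(sites, meta$site), ]
  k <- length(sites)
  n_site <- as.integer(table(gm$collection_site)[sites])

  # single-linkage closure: connected components of the <= radius graph
  comp <- seq_len(k)
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      d <- haversine_km(m$latitude[i], m$longitude[i],
                        m$latitude[j], m$longitude[j])
      if (d <= radius_km) {
        old <- comp[j]
        comp[comp == old] <- comp[i]
      }
    }
  }
  comp <- match(comp, unique(comp))

  # orphan exclusion
  sizes <- tabulate(comp)
  excluded <- sites[sizes[comp] == 1 & n_site < min_n]
  if (length(excluded))
    warning("excluding isolated low-N site(s): ",
            paste(excluded, collapse = ", "))
  keep_site <- !(sites %in% excluded)

  comps <- unique(comp[keep_site])
  # order pools west to east by weighted longitude
  wlon <- vapply(comps, function(cc) {
    i <- which(comp == cc & keep_site)
    sum(m$longitude[i] * n_site[i]) / sum(n_site[i])
  }, 0)
  comps <- comps[order(wlon)]
  if (is.null(pool_labels)) pool_labels <- paste0("pool_", seq_along(comps))
  if (length(pool_labels) != length(comps))
    stop("need ", length(comps), " pool labels")

  pooled <- do.call(rbind, lapply(seq_along(comps), function(ci) {
    i <- which(comp == comps[ci] & keep_site)
    w <- n_site[i]
    data.frame(population_id = pool_labels[ci],
               sites = paste(sites[i], collapse = "+"),
               latitude = sum(m$latitude[i] * w) / sum(w),
               longitude = sum(m$longitude[i] * w) / sum(w),
               N = sum(w),
               era = if ("era" %in% names(m)) m$era[i][1] else gm$era[1],
               stringsAsFactors = FALSE)
  }))

  site_pool <- stats::setNames(rep(NA_character_, k), sites)
  for (ci in seq_along(comps))
    site_pool[sites[comp == comps[ci] & keep_site]] <- pool_labels[ci]
  keep_ind <- !(gm$collection_site %in% excluded)
  gm2 <- genotype_matrix(gm$individual_id[keep_ind],
                         gm$collection_site[keep_ind],
                         site_pool[gm$collection_site[keep_ind]],
                         pooled$era[match(site_pool[gm$collection_site[keep_ind]],
                                          pooled$population_id)],
                         gm$loci,
                         gm$a1[keep_ind, , drop = FALSE],
                         gm$a2[keep_ind, , drop = FALSE])

  out <- list(genotypes = gm2, meta = pooled)
  attr(out, "excluded") <- excluded
  if (fst_guard) {
    flags <- list()
    merged <- comps[vapply(comps, function(cc)
      sum(comp == cc & keep_site) > 1, TRUE)]
    for (cc in merged) {
      i <- which(gm$collection_site %in% sites[comp == cc & keep_site])
      sub <- genotype_matrix(gm$individual_id[i], gm$collection_site[i],
                             gm$collection_site[i], gm$era[i], gm$loci,
                             gm$a1[i, , drop = FALSE],
                             gm$a2[i, , drop = FALSE])
      if (length(unique(sub$population_id)) < 2) next
      f <- pairwise_fst(sub, reps = fst_reps, seed = seed)
      sig <- which(f$significant, arr.ind = TRUE)
      sig <- sig[sig[, 1] < sig[, 2], , drop = FALSE]
      if (nrow(sig))
        flags[[length(flags) + 1L]] <- data.frame(
          pool = site_pool[sites[comp == cc & keep_site][1]],
          site1 = rownames(f$theta)[sig[, 1]],
          site2 = rownames(f$theta)[sig[, 2]],
          theta = f$theta[sig],
          p = f$p[sig])
    }
    attr(out, "fst_flags") <-
      if (length(flags)) do.call(rbind, flags) else NULL
  }
  out
}
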