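# Published summary tables for the Pseudacris fouquettei / P. nigrita contact
# zone at the Pearl River (historical 1976 and recent 2001-2012 sampling).
# These printed values are the inputs for the cline refits and arithmetic
# checks; the raw genotypes themselves are not redistributed here.

#' Pearl River population table
#'
#' One row per analysis population: era, species designation, weighted
#' coordinates, sample size N, position along the published transect (km,
#' increasing eastward from the westernmost historical population), and the
#' published mean hybrid index (h = 1 is pure \emph{P. fouquettei}, the
#' western species; h = 0 pure \emph{P. nigrita}).
#'
#' @return data frame with columns \code{population_id}, \code{era},
#'   \code{species}, \code{latitude}, \code{longitude}, \code{N},
#'   \code{transect_x}, \code{mean_h}.
#' @export
pearl_river_populations <- function() {
  data.frame(
    population_id = c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J",
                      "K", "L", "M", "N", "O", "P",
                      paste0("H", 1:7)),
    era = c(rep("recent", 16), rep("historical", 7)),
    species = c("pure_fouquettei", rep("putative_hybrid", 11),
                rep("pure_nigrita", 4),
                "pure_fouquettei", rep("putative_hybrid", 4),
                "pure_nigrita", "pure_nigrita"),
    latitude = c(30.3309, 30.70434, 30.77479, 30.82229, 30.39453, 30.40007,
                 30.37421, 30.47999, 30.43316, 30.42711, 30.40376, 30.50104,
                 30.48225, 30.7371, 30.1437, 31.23799,
                 31.91924, 30.4318, 30.37827, 30.40496, 30.43631, 30.52175,
                 30.57552),
    longitude = c(-91.6964, -90.88263, -90.74948, -90.67302, -89.9557,
                  -89.90917, -89.75222, -89.68708, -89.65119, -89.59754,
                  -89.44613, -88.90835, -85.95448, -85.91129, -84.9766,
                  -84.50169,
                  -92.30716, -89.90839, -89.76851, -89.69406, -89.65414,
                  -89.59249, -89.21105),
    N = c(7L, 11L, 8L, 4L, 6L, 5L, 23L, 4L, 9L, 26L, 22L, 13L, 5L, 5L, 4L,
          9L, 16L, 4L, 17L, 25L, 6L, 30L, 19L),
    transect_x = c(62.242, 139.325, 151.918, 159.133, 228.813, 233.257,
                   248.348, 254.347, 257.891, 263.043, 277.598, 328.889,
                   611.863, 615.434, 706.278, 749.345,
                   0, 233.259, 246.778, 253.849, 257.601, 263.314, 299.728),
    mean_h = c(1, 0.604, 0.599, 0.547, 0.698, 0.66, 0.563, 0.595, 0.511,
               0.279, 0.323, 0.276, 0, 0, 0, 0,
               1, 0.911, 0.893, 0.824, 0.756, 0.087, 0),
    stringsAsFactors = FALSE)
}

#' Pearl River recent collection sites (pre-pooling)
#'
#' The 30 recent collection sites with their coordinates, per-site counts and
#' final population assignment, as used by the 4 km pooling rule (site M22,
#' n = 1, was discarded as geographically isolated).
#'
#' @return data frame with columns \code{site}, \code{population_id},
#'   \code{year}, \code{n}, \code{latitude}, \code{longitude}.
#' @export
pearl_river_sites <- function() {
  data.frame(
    site = c("M1", "M23", "M14", "M16", "M15", "M17", "M25", "M24", "M26",
             "M22", "M5", "M2", "M3", "M4", "M13", "M12", "M20", "M11",
             "M10", "M18", "M19", "M9", "M6", "M7", "M8", "M21", "M29",
             "M28", "M27", "M30"),
    population_id = c("A", "B", "B", "C", "C", "D", "E", "E", "F", NA,
                      "G", "G", "G", "G", "H", "H", "H", "I", "I",
                      "J", "J", "J", "K", "K", "K", "L", "M", "N", "O", "P"),
    year = c(2006, 2001, 2010, 2010, 2010, 2010, 2012, 2012, 2012, 2003,
             2003, 2003, 2006, 2006, 2003, 2006, 2012, 2003, 2003, 2012,
             2012, 2006, 2007, 2007, 2007, 2003, 2005, 2005, 2003, 2003),
    n = c(7L, 2L, 9L, 5L, 3L, 4L, 5L, 1L, 5L, 1L, 10L, 5L, 3L, 5L, 1L, 2L,
          1L, 3L, 6L, 5L, 5L, 16L, 4L, 8L, 10L, 13L, 5L, 5L, 4L, 9L),
    latitude = c(30.3309, 30.68889, 30.70778, 30.775, 30.77444, 30.82229,
                 30.40008, 30.36677, 30.40007, 30.56551, 30.384, 30.35981,
                 30.36296, 30.3758, 30.47576, 30.46701, 30.5102, 30.43992,
                 30.42978, 30.42554, 30.42898, 30.42702, 30.38572, 30.39767,
                 30.41585, 30.50104, 30.48225, 30.7371, 30.1437, 31.23799),
    longitude = c(-91.6964, -90.88944, -90.88111, -90.75917, -90.73333,
                  -90.67302, -89.95806, -89.94389, -89.90917, -89.87149,
                  -89.7554, -89.75119, -89.74986, -89.7483, -89.69263,
                  -89.68592, -89.68387, -89.65759, -89.64799, -89.60114,
                  -89.59735, -89.59648, -89.47497, -89.44804, -89.43307,
                  -88.90835, -85.95448, -85.91129, -84.9766, -84.50169),
    stringsAsFactors = FALSE)
}

#' Published cline data for one era
#'
#' Builds a \code{\link{cline_data}} frame from the published transect
#' positions, mean hybrid indices and sample sizes.
#'
#' @param era \code{"historical"} or \code{"recent"}.
#' @param exclude population ids to drop (for example \code{c("B", "C",
#'   "D")}, the western hybrid populations whose low mean h motivated a
#'   sensitivity refit).
#' @return a \code{\link{cline_data}} frame.
#' @export
pearl_river_cline_data <- function(era = c("historical", "recent"),
                                   exclude = NULL) {
  era <- match.arg(era)
  t1 <- pearl_river_populations()
  t1 <- t1[t1$era == era & !(t1$population_id %in% exclude), ]
  cline_data(t1$population_id, t1$transect_x, t1$mean_h, t1$N)
}

#' Published model-selection log-likelihoods
#'
#' The published maximised log-likelihoods and free-parameter counts for the
#' five cline models on each dataset, together with the published AIC
#' columns. Used as inputs for information-criterion arithmetic checks.
#'
#' @return data frame with columns \code{dataset}, \code{model}, \code{lnL},
#'   \code{k}, \code{AIC}, \code{dAIC}, \code{rel_lik}, \code{weight},
#'   \code{evidence_ratio}.
#' @export
pearl_river_model_table <- function() {
  data.frame(
    dataset = rep(c("historical", "recent", "recent_excBCD"), each = 5),
    model = rep(c("none", "west", "east", "sym", "asym"), 3),
    lnL = c(-3.8951, -0.4025, -3.8951, -1.8687, -0.1183,
            -4.7955, -4.7955, -4.7955, -4.7955, -4.7956,
            -2.5206, -2.5206, -1.6163, -2.5206, -1.9397),
    k = rep(c(2L, 4L, 4L, 4L, 6L), 3),
    AIC = c(11.7903, 8.8050, 15.7903, 11.7374, 12.2366,
            13.5909, 17.5911, 17.5910, 17.5909, 21.5911,
            9.0412, 13.0413, 11.2326, 13.0412, 15.8794),
    dAIC = c(2.9853, 0, 6.9853, 2.9324, 3.4316,
             0, 4.0001, 4.0001, 4.0000, 8.0002,
             0, 4.0000, 2.1913, 4.0000, 6.8381),
    rel_lik = c(0.2248, 1, 0.0304, 0.2308, 0.1798,
                1, 0.1353, 0.1353, 0.1353, 0.0183,
                1, 0.1353, 0.3343, 0.1353, 0.0327),
    weight = c(0.1349, 0.6003, 0.0183, 0.1386, 0.1080,
               0.7021, 0.0950, 0.0950, 0.0950, 0.0129,
               0.6106, 0.0826, 0.2041, 0.0826, 0.0200),
    evidence_ratio = c(4.4489, 1, 32.8731, 4.3327, 5.5612,
                       1, 7.3895, 7.3893, 7.3891, 54.6031,
                       1, 7.3892, 2.9912, 7.3889, 30.5410),
    stringsAsFactors = FALSE)
}

#' Published cline parameter estimates with credibility intervals
#'
#' Centre and width estimates (km) with 95\% credibility intervals for the
#' no-tails model on each dataset and the west-tail model on the historical
#' data. These intervals are the constraint sources for the reciprocal
#' constraint tests.
#'
#' @return data frame with columns \code{dataset}, \code{model},
#'   \code{center}, \code{center_lo}, \code{center_hi}, \code{width},
#'   \code{width_lo}, \code{width_hi}.
#' @export
pearl_river_cline_estimates <- function() {
  data.frame(
    dataset = c("historical", "historical", "recent", "recent_excBCD"),
    model = c("none", "west", "none", "none"),
    center = c(257.532, 258.789, 230.186, 239.819),
    center_lo = c(255.620, 255.619, 195.238, 221.395),
    center_hi = c(259.487, 259.487, 259.191, 268.026),
    width = c(13.977, 8.654, 349.830, 193.162),
    width_lo = c(9.898, 8.653, 232.372, 109.162),
    width_hi = c(21.074, 21.071, 582.217, 396.677),
    stringsAsFactors = FALSE)
}

#' Published reciprocal constraint-test table
#'
#' Unconstrained and constrained log-likelihoods and AICs for every
#' combination of base dataset, model, and constraint source, with the
#' published 2LLR and delta-AIC columns for the centre-, width- and
#' both-constrained analyses.
#'
#' @return data frame, one row per (dataset, model, constraint source).
#' @export
pearl_river_constraint_table <- function() {
  data.frame(
    dataset = c("historical", "historical", "historical", "historical",
                "recent", "recent", "recent_excBCD", "recent_excBCD"),
    model = c("none", "none", "west", "west", "none", "none", "none",
              "none"),
    constraint_source = c("recent", "recent_excBCD", "recent",
                          "recent_excBCD", "hist_none", "hist_west",
                          "hist_none", "hist_west"),
    lnL_uncon = c(-3.895, -3.895, -0.403, -0.403, -4.796, -4.796, -2.521,
                  -2.521),
    AIC_uncon = c(11.790, 11.790, 8.805, 8.805, 13.591, 13.591, 9.041,
                  9.041),
    lnL_con_center = c(-3.895, -2.323, -3.895, -1.646, -6.089, -6.088,
                       -2.695, -2.695),
    AIC_con_center = c(9.790, 6.647, 13.790, 9.292, 14.177, 14.176, 7.390,
                       7.389),
    LLR2_center = c(0.000, 3.143, -6.985, -2.487, -2.586, -2.585, -0.349,
                    -0.348),
    dAIC_center = c(2.000, 5.143, -4.985, -0.487, -0.586, -0.585, 1.651,
                    1.652),
    lnL_con_width = c(-30.220, -30.223, -22.820, -22.822, -248.311,
                      -248.352, -71.149, -71.162),
    AIC_con_width = c(62.440, 62.445, 51.639, 51.644, 498.621, 498.705,
                      144.297, 144.325),
    LLR2_width = c(-52.650, -52.655, -44.834, -44.839, -487.030, -487.114,
                   -137.256, -137.283),
    dAIC_width = c(-50.650, -50.655, -42.834, -42.839, -485.030, -485.114,
                   -135.256, -135.283),
    lnL_con_both = c(-30.220, -30.220, -22.821, -22.821, -249.220,
                     -249.254, -71.148, -71.161),
    AIC_con_both = c(60.440, 60.440, 49.642, 49.642, 498.440, 498.509,
                     142.296, 142.322),
    LLR2_both = c(-52.650, -52.650, -44.837, -44.837, -488.849, -488.918,
                  -137.255, -137.281),
    dAIC_both = c(-48.650, -48.650, -40.837, -40.837, -484.849, -484.918,
                  -133.255, -133.281),
    stringsAsFactors = FALSE)
}
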