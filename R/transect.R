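# Projection of population coordinates onto a one-dimensional transect.

#' Project populations onto a one-dimensional transect
#'
#' Fits an ordinary least-squares line (latitude on longitude) through all
#' population coordinates in a locally scaled planar frame (1 degree latitude
#' = 111.32 km; longitude scaled by cos of the mean latitude), projects each
#' population orthogonally onto that line, and reports the signed distance
#' along the line. With \code{origin_policy = "westmost"} the westernmost
#' projection is placed at x = 0 and x increases eastward.
#'
#' @param meta population table with columns \code{population_id},
#'   \code{latitude}, \code{longitude} (weighted coordinates for pooled
#'   populations).
#' @param origin_policy currently \code{"westmost"}.
#' @return \code{meta} with a \code{transect_x} column (km), ordered as
#'   input; the fitted line is in \code{attr(, "line")}.
#' @export
project_to_transect <- function(meta, origin_policy = c("westmost")) {
  origin_policy <- match.arg(origin_policy)
  if (nrow(unique(meta[, c("latitude", "longitude")])) < 2)
    stop("need at least two distinct coordinates")
  km_per_deg <- 111.32
  lat0 <- mean(meta$latitude)
  X <- meta$longitude * km_per_deg * cos(lat0 * pi / 180)
  Y <- meta$latitude * km_per_deg
  if (stats::var(X) == 0) {
    # meridional transect: regression of lat on lon undefined; use Y directly
    pos <- Y
  } else {
    fit <- stats::lm(Y ~ X)
    b <- stats::coef(fit)[2]
    # unit direction along the line, pointing east (increasing X)
    u <- c(1, b) / sqrt(1 + b^2)
    pos <- X * u[1] + Y * u[2]
  }
  meta$transect_x <- pos - min(pos)
  attr(meta, "line") <- list(lat0 = lat0, km_per_deg = km_per_deg)
  meta
}

#' Build a transect from a table of published distances
#'
#' Bypasses projection and attaches supplied transect positions verbatim, so
#' downstream cline fits do not depend on any planar-approximation choice.
#'
#' @param meta population table with \code{population_id}.
#' @param table data frame (or CSV path) with columns \code{population_id}
#'   and \code{transect_x}; must cover every population in \code{meta}.
#' @return \code{meta} with \code{transect_x} attached.
#' @export
load_printed_distances <- function(meta, table) {
  if (!is.data.frame(table))
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  idx <- match(meta$population_id, table$population_id)
  if (anyNA(idx))
    stop("population(s) absent from distance table: ",
         paste(meta$population_id[is.na(idx)], collapse = ", "))
  meta$transect_x <- table$transect_x[idx]
  meta
}
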