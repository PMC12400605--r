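#' Growing-region environmental table for the six Chinese soybean regions
#'
#' Loads the shipped region-by-variable environmental table: latitude plus,
#' for the vegetative and reproductive growth windows, daily average
#' temperature (deg C), accumulated temperature >= 15 deg C (deg C day),
#' diurnal temperature range (deg C), precipitation (mm) and daily solar
#' radiation (kJ m-2 day-1) for six soybean growing regions spanning the
#' north-south gradient of China.
#'
#' @return Data frame with 6 rows (regions, in row names) and 11 variables.
#' @export
#' @examples
#' env <- china_region_env()
#' env$lat
china_region_env <- function() {
  path <- system.file("extdata", "china_region_env.csv", package = "adaptscape",
                      mustWork = TRUE)
  tab <- read.csv(path)
  rownames(tab) <- tab$region
  tab$region <- NULL
  tab
}

#' Define a growing region for environmental aggregation
#'
#' @param region_id Region identifier.
#' @param cells Character or integer ids of cultivated grid cells.
#' @param vegetative,reproductive Growth windows as length-2 \code{"mm-dd"}
#'   strings (inclusive), e.g. \code{c("05-01", "06-30")}.
#' @return An object of class \code{region_definition}.
#' @export
region_definition <- function(region_id, cells, vegetative, reproductive) {
  if (length(cells) < 1L) stop2("region ", region_id, " has no cultivated cells")
  vw <- parse_window(vegetative)
  rw <- parse_window(reproductive)
  if (rw[1] <= vw[1])
    stop2("reproductive window must start after the vegetative window starts")
  structure(list(region_id = region_id, cells = as.character(cells),
                 vegetative = vw, reproductive = rw),
            class = "region_definition")
}

# "mm-dd" pair -> day-of-year interval (non-leap calendar)
parse_window <- function(w) {
  if (length(w) != 2L) stop2("window must have a start and an end")
  doy <- vapply(w, function(s) {
    p <- as.integer(strsplit(s, "-")[[1]])
    if (length(p) != 2L || anyNA(p)) stop2("bad window date: ", s)
    cumsum(c(0L, MONTH_DAYS))[p[1]] + p[2]
  }, numeric(1))
  if (doy[2] < doy[1]) stop2("window end precedes start")
  unname(doy)
}

MONTH_DAYS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

# days of month m falling inside the day-of-year interval win
month_overlap_days <- function(m, win) {
  s <- cumsum(c(0L, MONTH_DAYS))[m] + 1L
  e <- s + MONTH_DAYS[m] - 1L
  max(0L, min(e, win[2]) - max(s, win[1]) + 1L)
}

#' Derive per-region environmental variables from monthly climate values
#'
#' Aggregates monthly per-cell climate summaries into the region-by-variable
#' table used for the environmental PCA. Per region and growth window:
#' daily average temperature and solar radiation are day-weighted means over
#' the months intersecting the window; diurnal temperature range is the
#' day-weighted mean of \code{tmax - tmin}; precipitation is the monthly sum
#' prorated by the fraction of each month inside the window; accumulated
#' temperature counts \code{days_in_window * monthly_mean} only for months
#' whose mean is at least 15 deg C. Latitude is the unweighted mean over the
#' region's cultivated cells.
#'
#' @param monthly Data frame of monthly climate values per cell with columns
#'   \code{cell}, \code{month} (1-12), \code{tavg}, \code{tmin}, \code{tmax},
#'   \code{prec}, \code{srad}.
#' @param cells Data frame with columns \code{cell}, \code{lat}.
#' @param regions List of [region_definition()] objects.
#' @param t_base Threshold (deg C) for the accumulated-temperature variable.
#' @return Data frame with one row per region and the 11 standard columns
#'   (see [china_region_env()]).
#' @export
derive_region_variables <- function(monthly, cells, regions, t_base = 15) {
  need <- c("cell", "month", "tavg", "tmin", "tmax", "prec", "srad")
  if (!all(need %in% names(monthly)))
    stop2("'monthly' must have columns ", paste(need, collapse = ", "))
  rows <- lapply(regions, function(rg) {
    sub <- monthly[monthly$cell %in% rg$cells, , drop = FALSE]
    if (nrow(sub) == 0L)
      stop2("region ", rg$region_id, ": no climate data for its cells")
    # regional monthly means (unweighted over cultivated cells)
    agg <- aggregate(sub[c("tavg", "tmin", "tmax", "prec", "srad")],
                     by = list(month = sub$month), FUN = mean)
    one_window <- function(win) {
      days <- vapply(agg$month, month_overlap_days, numeric(1), win = win)
      if (sum(days) == 0)
        stop2("region ", rg$region_id, ": window outside climate coverage")
      mfrac <- days / MONTH_DAYS[agg$month]
      hot <- agg$tavg >= t_base
      c(tavg = weighted.mean(agg$tavg, days),
        tacc15 = sum((days * agg$tavg)[hot]),
        dtr = weighted.mean(agg$tmax - agg$tmin, days),
        prec = sum(agg$prec * mfrac),
        srad = weighted.mean(agg$srad, days))
    }
    lat <- mean(cells$lat[match(rg$cells, cells$cell)], na.rm = TRUE)
    v <- one_window(rg$vegetative)
    r <- one_window(rg$reproductive)
    data.frame(region = rg$region_id, lat = lat,
               tavg_veg = v["tavg"], tacc15_veg = v["tacc15"],
               dtr_veg = v["dtr"], prec_veg = v["prec"], srad_veg = v["srad"],
               tavg_rep = r["tavg"], tacc15_rep = r["tacc15"],
               dtr_rep = r["dtr"], prec_rep = r["prec"], srad_rep = r["srad"],
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$region
  out$region <- NULL
  out
}

#' Standardized principal component analysis of the environmental table
#'
#' Centers each variable, scales to unit variance with the population divisor
#' (R, the number of regions) and eigendecomposes the resulting correlation
#' matrix. Scores are the standardized matrix projected on unit-norm
#' eigenvectors, so eigenvalues sum to the number of variables and
#' \code{mean(score_k^2) = lambda_k}. Component signs are fixed by a named
#' loading convention (by default: PC1 has a positive loading on vegetative
#' daily average temperature, PC2 a negative loading on reproductive
#' accumulated temperature), since PCA sign is otherwise arbitrary.
#'
#' @param table Numeric region-by-variable data frame or matrix (no missing
#'   values; at least 3 rows; no constant column).
#' @param orient Named list fixing component orientation:
#'   \code{list(PC1 = c(variable, sign), ...)}.
#' @return An object of class \code{env_pca}: eigenvalues, variance
#'   fractions, unit-norm loadings, region scores, the applied orientation
#'   flips and the standardized input.
#' @export
#' @examples
#' p <- env_pca(china_region_env())
#' round(100 * p$var_frac[1:2], 1)
#' round(p$scores[, 1], 2)
env_pca <- function(table,
                    orient = list(PC1 = list("tavg_veg", +1),
                                  PC2 = list("tacc15_rep", -1))) {
  X <- as.matrix(table)
  if (!is.numeric(X)) stop2("environmental table must be numeric")
  if (anyNA(X)) stop2("environmental table has missing cells")
  R <- nrow(X)
  if (R < 3L) stop2("PCA needs at least 3 regions (got ", R, ")")
  sds <- apply(X, 2L, function(col) sqrt(mean((col - mean(col))^2)))
  if (any(sds == 0))
    stop2("constant column(s): ",
          paste(colnames(X)[sds == 0], collapse = ", "))

  Z <- sweep(sweep(X, 2L, colMeans(X)), 2L, sds, "/")
  C <- crossprod(Z) / R
  e <- eigen(C, symmetric = TRUE)
  V <- ncol(X)
  load <- e$vectors
  rownames(load) <- colnames(X)
  colnames(load) <- paste0("PC", seq_len(V))
  scores <- Z %*% load
  rownames(scores) <- rownames(X)

  flips <- setNames(rep(1, V), colnames(load))
  for (pc in names(orient)) {
    spec <- orient[[pc]]
    v <- spec[[1]]; sgn <- spec[[2]]
    if (!v %in% rownames(load)) next
    if (sign(load[v, pc]) != sign(sgn) && load[v, pc] != 0) {
      load[, pc] <- -load[, pc]
      scores[, pc] <- -scores[, pc]
      flips[pc] <- -1
    }
  }

  structure(list(eigenvalues = e$values,
                 var_frac = e$values / V,
                 loadings = load, scores = scores,
                 flips = flips, n_vars = V, n_regions = R,
                 standardized = Z),
            class = "env_pca")
}

#' @export
print.env_pca <- function(x, digits = 3, ...) {
  cat(sprintf("Environmental PCA: %d regions x %d variables\n",
              x$n_regions, x$n_vars))
  vf <- 100 * x$var_frac
  k <- min(4L, x$n_vars)
  cat("  variance explained (%):",
      paste(sprintf("PC%d %.1f", seq_len(k), vf[seq_len(k)]), collapse = ", "),
      "\n")
  cat("  scores:\n")
  print(round(x$scores[, seq_len(min(2L, ncol(x$scores))), drop = FALSE],
              digits))
  invisible(x)
}

#' Population covariates from environmental PC scores
#'
#' Maps each scan population to its growing region's score on the first
#' \code{k} principal components and standardizes each covariate to zero mean
#' and unit variance across populations (divisor P). Populations sharing a
#' region share scores before standardization.
#'
#' @param pca An [env_pca()] result.
#' @param k Number of components to return (default 2).
#' @param group_to_region Named vector mapping population name to region id
#'   (a row name of the score matrix).
#' @return P x k matrix of standardized covariates (populations in rows).
#' @export
scan_covariates <- function(pca, k = 2L, group_to_region) {
  stopifnot(inherits(pca, "env_pca"))
  if (k < 1L || k > ncol(pca$scores)) stop2("'k' out of range")
  reg <- as.character(group_to_region)
  missing <- setdiff(reg, rownames(pca$scores))
  if (length(missing) > 0)
    stop2("unmapped region(s) for populations: ",
          paste(names(group_to_region)[reg %in% missing], collapse = ", "))
  raw <- pca$scores[reg, seq_len(k), drop = FALSE]
  rownames(raw) <- names(group_to_region)
  out <- apply(raw, 2L, standardize_covariate)
  out <- matrix(out, nrow = nrow(raw),
                dimnames = list(rownames(raw), colnames(raw)))
  out
}
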