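# niche_overlap: post-processing of habitat-suitability surfaces —
# normalization, Schoener's D, Warren's I, presence-percentile
# thresholding, suitable-area change, and correlated-predictor pruning.

#' Construct a suitability grid
#'
#' @param values numeric matrix of suitabilities >= 0; NA = NODATA.
#' @param cell_area area per cell in km^2 (equal-area cells assumed; map
#'   projection handling is out of scope).
#' @return object of class \code{"suitability_grid"}: list with
#'   \code{values}, \code{mask} (TRUE = valid), \code{cell_area}.
#' @export
suitability_grid <- function(values, cell_area = 1) {
  if (!is.matrix(values)) stop_plastigap("niche_overlap", "values must be a matrix")
  mask <- !is.na(values)
  if (!any(mask)) stop_plastigap("niche_overlap", "grid has no valid cell")
  if (any(values[mask] < 0))
    stop_plastigap("niche_overlap", "suitabilities must be >= 0")
  structure(list(values = values, mask = mask, cell_area = cell_area),
            class = "suitability_grid")
}

#' @export
print.suitability_grid <- function(x, ...) {
  cat(sprintf("suitability_grid: %d x %d, %d valid cells, cell_area %g km^2\n",
              nrow(x$values), ncol(x$values), sum(x$mask), x$cell_area))
  invisible(x)
}

#' Read / write an ASCII grid
#'
#' Headered plain-text matrix (ESRI-ASCII style: ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value, then rows of values). Chosen so that
#' fixtures stay diffable; no GeoTIFF dependency.
#'
#' @param path file path.
#' @param cell_area km^2 per cell to attach on read.
#' @return \code{read_grid}: a \code{\link{suitability_grid}}.
#' @export
read_grid <- function(path, cell_area = 1) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- hdr$nodata_value %||% -9999
  m[m == nodata] <- NA
  suitability_grid(m, cell_area = cell_area)
}

#' @rdname read_grid
#' @param grid a \code{suitability_grid} to write.
#' @export
write_grid <- function(grid, path) {
  m <- grid$values
  m[!grid$mask] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
               "xllcorner 0", "yllcorner 0", "cellsize 1",
               "NODATA_value -9999"), con)
  writeLines(apply(m, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Normalize a grid to a probability surface
#'
#' Valid cells sum to 1; masked cells stay NA. Invariant to uniform
#' rescaling of the raw suitabilities.
#'
#' @param grid a \code{suitability_grid}.
#' @return a \code{suitability_grid} whose valid cells sum to 1.
#' @export
normalize_grid <- function(grid) {
  tot <- sum(grid$values[grid$mask])
  if (tot <= 0) stop_plastigap("niche_overlap", "all-zero grid cannot be normalized")
  out <- grid
  out$values[grid$mask] <- grid$values[grid$mask] / tot
  out
}

# shared-geometry check + normalized cell vectors on the intersection mask
.overlap_cells <- function(gx, gy) {
  if (!all(dim(gx$values) == dim(gy$values)))
    stop_plastigap("niche_overlap", "grids differ in shape")
  mask <- gx$mask & gy$mask
  if (!any(mask)) stop_plastigap("niche_overlap", "no jointly valid cells")
  px <- gx$values[mask]; py <- gy$values[mask]
  sx <- sum(px); sy <- sum(py)
  if (sx <= 0 || sy <= 0)
    stop_plastigap("niche_overlap", "a grid is all-zero on the shared mask")
  list(px = px / sx, py = py / sy)
}

#' Schoener's D niche overlap
#'
#' D = 1 - 1/2 sum |p_x,i - p_y,i| over the normalized surfaces; 1 means
#' identical niches, 0 disjoint. Cells NODATA in either grid are excluded
#' from both (intersection mask).
#'
#' @param gx,gy \code{suitability_grid}s of identical shape.
#' @return D in [0, 1].
#' @export
schoener_d <- function(gx, gy) {
  p <- .overlap_cells(gx, gy)
  1 - 0.5 * sum(abs(p$px - p$py))
}

#' Warren's I niche overlap
#'
#' I = 1 - 1/2 sum (sqrt(p_x,i) - sqrt(p_y,i))^2 (one minus half the
#' squared Hellinger distance); always >= Schoener's D.
#'
#' @inheritParams schoener_d
#' @return I in [0, 1].
#' @export
warren_i <- function(gx, gy) {
  p <- .overlap_cells(gx, gy)
  1 - 0.5 * sum((sqrt(p$px) - sqrt(p$py))^2)
}

#' Percentile training-presence threshold
#'
#' The suitability value below which \code{percentile}% of training-presence
#' suitabilities fall, by the nearest-rank rule (the ceil(p/100 * n)-th
#' order statistic; percentile 0 gives the minimum). With the default 10
#' this is the 10-percentile training presence (10TPL) threshold used to
#' binarize continuous suitability maps.
#'
#' @param presence numeric vector of presence-point suitabilities in [0,1].
#' @param percentile percentage in [0, 100].
#' @return the threshold value.
#' @export
tpl_threshold <- function(presence, percentile = 10) {
  if (!length(presence)) stop_plastigap("niche_overlap", "no presence values")
  if (any(presence < 0 | presence > 1))
    stop_plastigap("niche_overlap", "presence suitabilities must lie in [0,1]")
  s <- sort(presence)
  r <- max(1L, ceiling(percentile / 100 * length(s)))
  s[r]
}

#' Binary range map and suitable area
#'
#' A valid cell is suitable iff suitability >= threshold; the area is the
#' suitable-cell count times the grid's cell_area.
#'
#' @param grid a \code{suitability_grid}.
#' @param threshold suitability cutoff in [0, 1].
#' @return list with \code{map} (logical matrix; NA outside mask) and
#'   \code{area_km2}.
#' @export
binary_range <- function(grid, threshold) {
  if (threshold < 0 || threshold > 1)
    stop_plastigap("niche_overlap", "threshold must lie in [0,1]")
  map <- grid$values >= threshold
  map[!grid$mask] <- NA
  list(map = map, area_km2 = sum(map, na.rm = TRUE) * grid$cell_area,
       cell_area = grid$cell_area)
}

#' Range change between two binary maps
#'
#' Cellwise contingency of two binary range maps on shared geometry:
#' gained, lost and stable area, and the percent change
#' (area2 - area1)/area1 x 100 (NA, flagged, when area1 is zero).
#'
#' @param map1,map2 results of \code{\link{binary_range}} on grids of the
#'   same shape and cell area.
#' @return list with \code{gain_km2}, \code{loss_km2}, \code{stable_km2},
#'   \code{pct_change}.
#' @export
range_change <- function(map1, map2) {
  if (!all(dim(map1$map) == dim(map2$map)) ||
      map1$cell_area != map2$cell_area)
    stop_plastigap("niche_overlap", "maps differ in geometry")
  a <- map1$map; b <- map2$map
  gain <- sum(b & !a, na.rm = TRUE) * map1$cell_area
  loss <- sum(a & !b, na.rm = TRUE) * map1$cell_area
  stable <- sum(a & b, na.rm = TRUE) * map1$cell_area
  a1 <- sum(a, na.rm = TRUE) * map1$cell_area
  a2 <- sum(b, na.rm = TRUE) * map1$cell_area
  pct <- if (a1 == 0) { warning("baseline area is 0; percent change undefined",
                                call. = FALSE); NA_real_ }
         else (a2 - a1) / a1 * 100
  list(gain_km2 = gain, loss_km2 = loss, stable_km2 = stable,
       pct_change = pct)
}

#' Prune collinear predictors by contribution
#'
#' For each variable pair with |r| above the threshold, taken in decreasing
#' |r| order, the member with the lower percent contribution is dropped
#' (unless already dropped). Contribution ties keep the alphabetically
#' first name, with a warning. Deterministic.
#'
#' @param cor_matrix symmetric correlation matrix with dimnames.
#' @param contributions named numeric vector of percent contributions.
#' @param r_threshold correlation cutoff (default 0.8; pairs with
#'   |r| > threshold are pruned).
#' @return character vector of retained variable names.
#' @export
prune_predictors <- function(cor_matrix, contributions, r_threshold = 0.8) {
  vars <- rownames(cor_matrix)
  if (is.null(vars) || !all(vars %in% names(contributions)))
    stop_plastigap("niche_overlap",
                   "correlation matrix and contributions must share names")
  if (any(contributions < 0))
    stop_plastigap("niche_overlap", "contributions must be >= 0")
  prs <- which(upper.tri(cor_matrix) & abs(cor_matrix) > r_threshold,
               arr.ind = TRUE)
  if (nrow(prs)) {
    ord <- order(-abs(cor_matrix[prs]), vars[prs[, 1]], vars[prs[, 2]])
    prs <- prs[ord, , drop = FALSE]
  }
  dropped <- character(0)
  for (k in seq_len(nrow(prs))) {
    v1 <- vars[prs[k, 1]]; v2 <- vars[prs[k, 2]]
    if (v1 %in% dropped || v2 %in% dropped) next
    c1 <- contributions[[v1]]; c2 <- contributions[[v2]]
    if (c1 == c2) {
      warning(sprintf("contribution tie between %s and %s; keeping %s",
                      v1, v2, min(v1, v2)), call. = FALSE)
      dropped <- c(dropped, max(v1, v2))
    } else dropped <- c(dropped, if (c1 < c2) v1 else v2)
  }
  setdiff(vars, dropped)
}
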