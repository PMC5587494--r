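# Isoscape grid I/O (ESRI ASCII and long-format CSV) and reclassification of
# a precipitation isoscape into probability-of-origin categories.

#' Read an isoscape grid
#'
#' Accepts an ESRI ASCII grid (`.asc`) or a long-format CSV with columns
#' `lon`, `lat`, `d2h_p`. Cell coordinates are cell centres, longitudes in
#' -180..180.
#'
#' @param path File path.
#' @return An object of class `isoscape_grid`: list with `lon`, `lat`
#'   (ascending cell-centre coordinates), `values` (matrix, rows = lat,
#'   cols = lon, NA = no data) and `cellsize`.
#' @export
read_isoscape <- function(path) {
  if (grepl("\\.asc$", path, ignore.case = TRUE)) {
    read_esri_ascii(path)
  } else {
    df <- utils::read.csv(path)
    stopifnot(all(c("lon", "lat", "d2h_p") %in% names(df)))
    isoscape_from_long(df)
  }
}

isoscape_from_long <- function(df) {
  lon <- sort(unique(df$lon))
  lat <- sort(unique(df$lat))
  values <- matrix(NA_real_, length(lat), length(lon))
  values[cbind(match(df$lat, lat), match(df$lon, lon))] <- df$d2h_p
  cellsize <- if (length(lon) > 1L) min(diff(lon)) else NA_real_
  structure(list(lon = lon, lat = lat, values = values, cellsize = cellsize),
            class = "isoscape_grid")
}

read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  nodata <- hdr$nodata_value %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  stopifnot(length(vals) == nc * nr)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  cs <- hdr$cellsize
  # ESRI rows run north->south; store south->north (ascending lat)
  m <- m[nr:1, , drop = FALSE]
  x0 <- hdr$xllcorner %||% (hdr$xllcenter - cs / 2)
  y0 <- hdr$yllcorner %||% (hdr$yllcenter - cs / 2)
  structure(list(lon = x0 + cs * (seq_len(nc) - 0.5),
                 lat = y0 + cs * (seq_len(nr) - 0.5),
                 values = m, cellsize = cs),
            class = "isoscape_grid")
}

#' Write an isoscape grid as ESRI ASCII
#'
#' @param grid An `isoscape_grid`.
#' @param path Output path.
#' @param nodata No-data marker written for NA cells.
#' @export
write_esri_ascii <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "isoscape_grid"))
  m <- grid$values
  m[is.na(m)] <- nodata
  nr <- nrow(m); nc <- ncol(m)
  cs <- grid$cellsize
  hdr <- c(sprintf("ncols %d", nc),
           sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", grid$lon[1] - cs / 2),
           sprintf("yllcorner %.10g", grid$lat[1] - cs / 2),
           sprintf("cellsize %.10g", cs),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(m[nr:1, , drop = FALSE], 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Pooled probability density of precipitation-equivalent values for one
# destination's sample set: an equal-weight mixture over birds of the normal
# each bird's Monte-Carlo simulation draws from (mean = the bird's
# precipitation equivalent, SD = error_sd rescaled by the calibration slope).
pooled_origin_density <- function(d2h_f, error_sd, slope = CAL_SLOPE) {
  mu <- feather_to_precip(d2h_f)
  sd_p <- error_sd / slope
  function(x) {
    rowMeans(vapply(mu, function(m) stats::dnorm(x, m, sd_p),
                    numeric(length(x))))
  }
}

# highest-density thresholds: smallest density value d such that the region
# {x: f(x) >= d} encloses at least `level` probability mass
hdr_thresholds <- function(dens, levels, lower, upper, n_grid = 4096L) {
  x <- seq(lower, upper, length.out = n_grid)
  fx <- dens(x)
  dx <- x[2] - x[1]
  ord <- order(fx, decreasing = TRUE)
  cum <- cumsum(fx[ord]) * dx
  vapply(levels, function(lv) {
    k <- which(cum >= lv)[1]
    if (is.na(k)) min(fx[ord]) else fx[ord][k]
  }, numeric(1))
}

#' Reclassify an isoscape into probability-of-origin categories
#'
#' For each destination, pools the per-bird simulated origin densities of its
#' assigned birds into one probability density of precipitation-equivalent
#' delta-2H, finds highest-density thresholds enclosing each probability
#' level, and labels every grid cell by the smallest level whose
#' highest-density region contains the cell's isoscape value (0 = outside
#' all levels).
#'
#' @param grid An `isoscape_grid`.
#' @param samples_by_dest Named list (one per destination) of numeric
#'   vectors of feather delta-2H values.
#' @param error_sd Feather-scale error SD (per-mil).
#' @param levels Probability levels, default `c(0.50, 0.75, 0.90)`.
#' @return Named list (per destination) of category matrices (same shape as
#'   `grid$values`; entries 0/50/75/90, NA where the grid has no data), with
#'   the density thresholds as attribute `"thresholds"`.
#' @export
reclassify_isoscape <- function(grid, samples_by_dest, error_sd = 5.5,
                                levels = c(0.50, 0.75, 0.90)) {
  stopifnot(inherits(grid, "isoscape_grid"), length(samples_by_dest) >= 1L)
  if (all(is.na(grid$values))) stop("all-no-data grid", call. = FALSE)
  levels <- sort(levels)
  out <- list()
  for (lab in names(samples_by_dest)) {
    s <- samples_by_dest[[lab]]
    if (length(s) < 1L) stop("empty sample set for ", lab, call. = FALSE)
    dens <- pooled_origin_density(s, error_sd)
    mu <- feather_to_precip(s)
    span <- 8 * error_sd / CAL_SLOPE
    thr <- hdr_thresholds(dens, levels, min(mu) - span, max(mu) + span)
    fx <- matrix(NA_real_, nrow(grid$values), ncol(grid$values))
    ok <- !is.na(grid$values)
    fx[ok] <- dens(grid$values[ok])
    cls <- matrix(NA_real_, nrow(fx), ncol(fx))
    cls[ok] <- 0
    for (j in rev(seq_along(levels))) {   # widest level first, tighter overwrite
      cls[ok & fx >= thr[j]] <- 100 * levels[j]
    }
    attr(cls, "thresholds") <- stats::setNames(thr, paste0(100 * levels, "%"))
    out[[lab]] <- cls
  }
  out
}
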