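EARTH_RADIUS_KM <- 6371.393

#' Great-circle distance (haversine)
#'
#' `2R arcsin sqrt(sin^2(dphi/2) + cos(phi1) cos(phi2) sin^2(dlambda/2))`
#' with R the Earth radius in km.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees (vectorized)
#' @param radiusKm Earth radius (km)
#' @return distance in km
#' @export
greatCircleDistance <- function(lat1, lon1, lat2, lon2,
                                radiusKm = EARTH_RADIUS_KM) {
  .assert(all(abs(c(lat1, lat2)) <= 90) && all(abs(c(lon1, lon2)) <= 180),
          "coordinates out of range")
  toRad <- pi / 180
  p1 <- lat1 * toRad; p2 <- lat2 * toRad
  dphi <- (lat2 - lat1) * toRad
  dlam <- (lon2 - lon1) * toRad
  h <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * radiusKm * asin(pmin(1, sqrt(h)))
}

#' Meridional (latitudinal) distance
#'
#' Arc length along a meridian: `2 pi R |lat1 - lat2| / 360`.
#'
#' @inheritParams greatCircleDistance
#' @return distance in km
#' @export
latitudeDistance <- function(lat1, lat2, radiusKm = EARTH_RADIUS_KM) {
  2 * pi * radiusKm * abs(lat1 - lat2) / 360
}

#' Coastline raster of water/land cells
#'
#' A planar raster (rows = y, cols = x) of water (TRUE) and land (FALSE)
#' cells with a cell size in km and a planar origin. An equirectangular
#' projection anchored at (`lat0`, `lon0`) with scale latitude `latRef`
#' converts site coordinates to the plane; at the few-thousand-km scale any
#' locally length-preserving projection serves.
#'
#' @param mask logical matrix, TRUE = water
#' @param cellKm cell edge length (km)
#' @param lat0,lon0 geographic coordinates of the (1,1) cell corner
#' @param latRef latitude at which the lon scale is taken
#' @return object of class `coastGrid`
#' @export
coastGrid <- function(mask, cellKm, lat0 = 0, lon0 = 0, latRef = lat0) {
  structure(list(mask = mask, cellKm = cellKm,
                 lat0 = lat0, lon0 = lon0, latRef = latRef),
            class = "coastGrid")
}

# project lat/lon onto the grid plane (km east/north of grid origin)
.gridXY <- function(grid, lat, lon) {
  kmPerDeg <- 2 * pi * EARTH_RADIUS_KM / 360
  list(x = (lon - grid$lon0) * kmPerDeg * cos(grid$latRef * pi / 180),
       y = (lat - grid$lat0) * kmPerDeg)
}

# nearest water cell (row, col) to a planar point
.snapToWater <- function(grid, x, y) {
  nr <- nrow(grid$mask); ncl <- ncol(grid$mask)
  row <- pmin(pmax(1L, as.integer(floor(y / grid$cellKm)) + 1L), nr)
  col <- pmin(pmax(1L, as.integer(floor(x / grid$cellKm)) + 1L), ncl)
  wat <- which(grid$mask, arr.ind = TRUE)
  .assert(nrow(wat) > 0, "coast grid has no water cells")
  mapply(function(r, c2) {
    d2 <- (wat[, 1] - r)^2 + (wat[, 2] - c2)^2
    i <- which.min(d2)
    (wat[i, 2] - 1L) * nr + wat[i, 1]  # linear cell id
  }, row, col)
}

# lazily built igraph over water cells with 8-connected weighted edges
.gridGraph <- function(grid) {
  if (!is.null(attr(grid, "graph"))) return(attr(grid, "graph"))
  m <- grid$mask
  nr <- nrow(m); ncl <- ncol(m)
  id <- function(r, c2) (c2 - 1L) * nr + r
  edges <- list(); w <- list(); k <- 1L
  addE <- function(r1, c1, r2, c2, wt) {
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncl
    r1 <- r1[ok]; c1 <- c1[ok]; r2 <- r2[ok]; c2 <- c2[ok]
    sel <- m[cbind(r1, c1)] & m[cbind(r2, c2)]
    list(cbind(id(r1[sel], c1[sel]), id(r2[sel], c2[sel])),
         rep(wt, sum(sel)))
  }
  wat <- which(m, arr.ind = TRUE)
  r <- wat[, 1]; c2 <- wat[, 2]
  st <- grid$cellKm
  for (d in list(c(0L, 1L, st), c(1L, 0L, st),
                 c(1L, 1L, st * sqrt(2)), c(-1L, 1L, st * sqrt(2)))) {
    e <- addE(r, c2, r + d[1], c2 + d[2], d[3])
    edges[[k]] <- e[[1]]; w[[k]] <- e[[2]]; k <- k + 1L
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = nr * ncl, directed = FALSE)
  g <- igraph::add_edges(g, t(em))
  igraph::E(g)$weight <- unlist(w)
  g
}

#' Shortest water path (coastline) distance
#'
#' Sites snap to the nearest water cell; the distance is the length of the
#' shortest 8-connected path through water cells, with axial steps costing
#' one cell edge and diagonal steps `sqrt(2)` cells.
#'
#' @param lat1,lon1,lat2,lon2 site coordinates (decimal degrees, scalars)
#' @param grid a [coastGrid()]
#' @return distance in km
#' @export
coastlineDistance <- function(lat1, lon1, lat2, lon2, grid) {
  d <- coastlineDistanceMatrix(c(lat1, lat2), c(lon1, lon2), grid)
  d[1, 2]
}

#' All-pairs coastline distances for a set of sites
#'
#' @param lat,lon site coordinate vectors
#' @param grid a [coastGrid()]
#' @return symmetric matrix of path lengths (km)
#' @export
coastlineDistanceMatrix <- function(lat, lon, grid) {
  xy <- .gridXY(grid, lat, lon)
  cells <- .snapToWater(grid, xy$x, xy$y)
  g <- .gridGraph(grid)
  uc <- unique(cells)   # sites may snap to the same cell
  d0 <- igraph::distances(g, v = uc, to = uc)
  d <- d0[match(cells, uc), match(cells, uc), drop = FALSE]
  if (any(!is.finite(d)))
    stop("sites not connected through water")
  dimnames(d) <- NULL
  d
}

#' Read/write a coast raster as an ASCII grid
#'
#' Plain-text format: header lines `nrows`, `ncols`, `cellkm`, `lat0`,
#' `lon0`, `latref`, then one row of 0/1 (1 = water) per raster row.
#'
#' @param path file path
#' @return a [coastGrid()]
#' @export
readCoastGrid <- function(path) {
  ln <- readLines(path)
  hdr <- strsplit(ln[1:6], "\\s+")
  val <- vapply(hdr, function(x) as.numeric(x[2]), 0)
  names(val) <- vapply(hdr, `[`, "", 1)
  body <- ln[-(1:6)]
  m <- do.call(rbind, lapply(body, function(s)
    as.integer(strsplit(s, "")[[1]]) == 1L))
  .assert(nrow(m) == val["nrows"] && ncol(m) == val["ncols"],
          "coast grid dimensions disagree with header")
  coastGrid(m, val["cellkm"], val["lat0"], val["lon0"], val["latref"])
}

#' @rdname readCoastGrid
#' @param grid a [coastGrid()]
#' @export
writeCoastGrid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("nrows", nrow(grid$mask)),
               paste("ncols", ncol(grid$mask)),
               paste("cellkm", grid$cellKm),
               paste("lat0", grid$lat0),
               paste("lon0", grid$lon0),
               paste("latref", grid$latRef)), con)
  writeLines(apply(grid$mask * 1L, 1L, paste, collapse = ""), con)
  invisible(path)
}

#' Annual SST climatology for one site
#'
#' From a daily series: SST_max is the mean over calendar years of each
#' year's maximum daily value, SST_min the mean of annual minima, and
#' SST_med the median of all daily values. Supply series already averaged
#' within the site's grid cell when the source is gridded. Years with fewer
#' than 300 daily values are excluded from the annual extremes.
#'
#' @param dates `Date` vector
#' @param sst daily values (deg C), same length
#' @return named numeric: `sstMax`, `sstMin`, `sstMed`
#' @export
sstClimatology <- function(dates, sst) {
  .assert(length(dates) == length(sst), "dates and sst lengths differ")
  ok <- !is.na(sst)
  dates <- dates[ok]; sst <- sst[ok]
  .assert(as.numeric(diff(range(dates))) >= 364,
          "SST series must span at least one full year")
  yr <- as.integer(format(dates, "%Y"))
  cnt <- table(yr)
  full <- names(cnt)[cnt >= 300]
  .assert(length(full) >= 1, "no complete year in SST series")
  sel <- yr %in% as.integer(full)
  mx <- tapply(sst[sel], yr[sel], max)
  mn <- tapply(sst[sel], yr[sel], min)
  c(sstMax = mean(mx), sstMin = mean(mn), sstMed = median(sst))
}

#' Read per-site daily SST series from CSV
#'
#' Columns: `site`, `date` (YYYY-MM-DD), `sst`.
#'
#' @param path CSV file
#' @return data.frame
#' @export
readSstSeries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .assert(all(c("site", "date", "sst") %in% names(df)),
          "SST CSV needs columns site, date, sst")
  df$date <- as.Date(df$date)
  df
}

#' Per-site-pair geographic and climatic predictors
#'
#' Builds one row per unordered site pair with the three geographic
#' distances and the absolute SST climatology differences.
#'
#' @param sites data.frame with `site`, `lat`, `lon`
#' @param envs data.frame with `site`, `sstMax`, `sstMed`, `sstMin`
#' @param grid optional [coastGrid()]; when NULL `dCsl` is NA
#' @return data.frame (`SitePairTable` predictors): `site1`, `site2`,
#'   `dGcc`, `dCsl`, `dLat`, `dSstMax`, `dSstMed`, `dSstMin`
#' @export
pairPredictors <- function(sites, envs, grid = NULL) {
  .assert(all(sites$site %in% envs$site),
          "missing environment for site(s): ",
          paste(setdiff(sites$site, envs$site), collapse = ", "))
  envs <- envs[match(sites$site, envs$site), ]
  S <- nrow(sites)
  idx <- which(upper.tri(matrix(0, S, S)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  dCsl <- rep(NA_real_, nrow(idx))
  if (!is.null(grid)) {
    dm <- coastlineDistanceMatrix(sites$lat, sites$lon, grid)
    dCsl <- dm[idx]
  }
  data.frame(
    site1 = sites$site[i], site2 = sites$site[j],
    dGcc = greatCircleDistance(sites$lat[i], sites$lon[i],
                               sites$lat[j], sites$lon[j]),
    dCsl = dCsl,
    dLat = latitudeDistance(sites$lat[i], sites$lat[j]),
    dSstMax = abs(envs$sstMax[i] - envs$sstMax[j]),
    dSstMed = abs(envs$sstMed[i] - envs$sstMed[j]),
    dSstMin = abs(envs$sstMin[i] - envs$sstMin[j])
  )
}
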