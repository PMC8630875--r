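#' Lattice region geometry for synthetic studies
#'
#' Builds an `n_side` x `n_side` lattice of square regions over a bounding box
#' shaped like the Indian subcontinent's extent. Region ids are `R01`, `R02`,
#' ... in row-major order (west to east, south to north); centroids are the
#' cell centres. The construction is fully deterministic; `seed` is accepted
#' for interface uniformity with the stochastic generators.
#'
#' @param n_side lattice side length (>= 2); `n_side = 6` gives 36 regions,
#'   the number of states/UTs in the motivating analysis.
#' @param seed integer, recorded in the output.
#' @param bbox numeric `c(lon_min, lon_max, lat_min, lat_max)`.
#' @return object of class `region_set`: `centroids` (data frame `region_id`,
#'   `lon`, `lat`), `polygons` (named list of closed rings), `bbox`, `seed`.
#' @export
make_geography <- function(n_side = 6L,
                           seed = 1L,
                           bbox = c(68, 97, 8, 37)) {
  n_side <- as.integer(n_side)
  if (n_side < 2L) stop("n_side must be >= 2")
  lon_edges <- seq(bbox[1], bbox[2], length.out = n_side + 1L)
  lat_edges <- seq(bbox[3], bbox[4], length.out = n_side + 1L)
  n <- n_side^2
  ids <- sprintf("R%02d", seq_len(n))
  cx <- numeric(n)
  cy <- numeric(n)
  polys <- vector("list", n)
  idx <- 0L
  for (row in seq_len(n_side)) {       # south to north
    for (col in seq_len(n_side)) {     # west to east
      idx <- idx + 1L
      x0 <- lon_edges[col]; x1 <- lon_edges[col + 1L]
      y0 <- lat_edges[row]; y1 <- lat_edges[row + 1L]
      cx[idx] <- (x0 + x1) / 2
      cy[idx] <- (y0 + y1) / 2
      polys[[idx]] <- cbind(lon = c(x0, x1, x1, x0, x0),
                            lat = c(y0, y0, y1, y1, y0))
    }
  }
  names(polys) <- ids
  structure(
    list(centroids = data.frame(region_id = ids, lon = cx, lat = cy,
                                stringsAsFactors = FALSE),
         polygons = polys, bbox = bbox, n_side = n_side,
         seed = as.integer(seed)),
    class = "region_set"
  )
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %d regions, bbox lon [%g, %g] lat [%g, %g]\n",
              nrow(x$centroids), x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4]))
  invisible(x)
}

#' Write regions (and optional per-region properties) as GeoJSON
#'
#' Emits a GeoJSON FeatureCollection with one Polygon feature per region and
#' a `region_id` property. Extra columns of `properties` (joined by
#' `region_id`) are written as additional feature properties, which is how
#' posterior spatial summaries travel to mapping tools. Output is
#' byte-deterministic for identical inputs.
#'
#' @param regions a `region_set`.
#' @param path output file path.
#' @param properties optional data frame with a `region_id` column.
#' @return `path`, invisibly.
#' @export
write_geojson_regions <- function(regions, path, properties = NULL) {
  stopifnot(inherits(regions, "region_set"))
  ids <- regions$centroids$region_id
  feats <- lapply(seq_along(ids), function(i) {
    props <- list(region_id = ids[i])
    if (!is.null(properties)) {
      r <- match(ids[i], properties$region_id)
      if (!is.na(r)) {
        extra <- as.list(properties[r, setdiff(names(properties), "region_id"),
                                    drop = FALSE])
        props <- c(props, extra)
      }
    }
    ring <- regions$polygons[[ids[i]]]
    list(
      type = "Feature",
      properties = props,
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(r) unname(ring[r, ])))
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10,
                       pretty = FALSE)
  invisible(path)
}

#' Read a GeoJSON FeatureCollection of regions
#'
#' Expects Polygon features carrying a `region_id` property. Centroids are
#' computed as the mean of the distinct outer-ring vertices (a representative
#' point; adequate for convex administrative cells).
#'
#' @param path GeoJSON file path.
#' @return a `region_set` (without `bbox`/`n_side` provenance fields).
#' @export
read_geojson_regions <- function(path) {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$type) || fc$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection: ", path)
  }
  feats <- fc$features
  ids <- vapply(feats, function(f) as.character(f$properties$region_id), "")
  if (anyNA(ids) || any(ids == "")) stop("features without region_id in ", path)
  polys <- lapply(feats, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("lon", "lat")
    m
  })
  names(polys) <- ids
  cents <- t(vapply(polys, function(m) {
    open <- m[-nrow(m), , drop = FALSE]  # drop repeated closing vertex
    colMeans(open)
  }, c(lon = 0, lat = 0)))
  bbox <- c(min(cents[, 1]), max(cents[, 1]), min(cents[, 2]), max(cents[, 2]))
  structure(
    list(centroids = data.frame(region_id = ids, lon = cents[, "lon"],
                                lat = cents[, "lat"], row.names = NULL,
                                stringsAsFactors = FALSE),
         polygons = polys, bbox = bbox, n_side = NA_integer_, seed = NA_integer_),
    class = "region_set"
  )
}

#' Read a centroid table
#'
#' Delimited text with columns `region_id`, `longitude`/`lon`,
#' `latitude`/`lat`.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return data frame `region_id`, `lon`, `lat`.
#' @export
read_centroid_table <- function(path, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  names(tab)[names(tab) == "longitude"] <- "lon"
  names(tab)[names(tab) == "latitude"] <- "lat"
  if (!all(c("region_id", "lon", "lat") %in% names(tab))) {
    stop("centroid table needs columns region_id, longitude, latitude")
  }
  tab$region_id <- as.character(tab$region_id)
  tab[, c("region_id", "lon", "lat")]
}

#' Read an undirected edge list as an adjacency matrix
#'
#' Two whitespace- or comma-separated region ids per line, one undirected
#' edge each.
#'
#' @param path file path.
#' @param region_ids character vector fixing row/column order.
#' @return symmetric 0/1 adjacency matrix.
#' @export
read_adjacency <- function(path, region_ids) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(region_ids)
  A <- matrix(0L, n, n, dimnames = list(region_ids, region_ids))
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[,[:space:]]+")[[1]]
    if (length(parts) != 2L) stop("malformed edge line: '", ln, "'")
    i <- match(parts[1], region_ids)
    j <- match(parts[2], region_ids)
    if (is.na(i) || is.na(j)) stop("unknown region id in edge: '", ln, "'")
    A[i, j] <- 1L
    A[j, i] <- 1L
  }
  diag(A) <- 0L
  A
}
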