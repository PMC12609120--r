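#' Read an EO table from CSV
#'
#' Reads a per-object table (UTF-8, comma-delimited, `.` decimal) and
#' validates the columns the pipeline needs.  Unknown columns are preserved
#' as passthrough metadata.
#'
#' @param path Path to a CSV file with at least `object_id`, `area_um2`,
#'   `ins_area_um2`, `gluc_area_um2`.
#' @return Data frame of typed records (possibly zero rows).
#' @export
read_eo_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("object_id", "area_um2", "ins_area_um2", "gluc_area_um2")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  for (col in setdiff(required, "object_id")) {
    v <- df[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & v != "")
    if (length(bad))
      stop("non-numeric value in column '", col, "' at row ", bad[1],
           " ('", v[bad[1]], "')")
    df[[col]] <- num
  }
  df$object_id <- as.character(df$object_id)
  df
}

#' Write an EO table to CSV
#'
#' @param eo_table Data frame of objects; list columns (e.g. boundary
#'   polygons) are dropped.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_eo_table <- function(eo_table, path) {
  keep <- !vapply(eo_table, is.list, TRUE)
  write.csv(eo_table[keep], path, row.names = FALSE)
  invisible(path)
}

#' Read polygon annotations from GeoJSON
#'
#' Reads a GeoJSON FeatureCollection of Polygon features.  Outer rings are
#' closed automatically (with a warning) if the file left them open;
#' MultiPolygon features are split into one annotation per part with
#' suffixed ids.  Feature properties are preserved.
#'
#' @param path Path to a `.geojson` file.
#' @return List of annotations, each a list with `id`, `polygon` (2-column
#'   matrix of the closed outer ring), `holes` (list of inner rings), and
#'   `properties`.
#' @export
read_geojson_annotations <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  close_ring <- function(m, id) {
    m <- do.call(rbind, lapply(m, function(p) c(p[[1]], p[[2]])))
    if (!all(m[1, ] == m[nrow(m), ])) {
      warning("unclosed ring in annotation ", id, "; auto-closed")
      m <- rbind(m, m[1, ])
    }
    colnames(m) <- c("x", "y")
    m
  }
  out <- list()
  for (k in seq_along(gj$features)) {
    f <- gj$features[[k]]
    id <- as.character(f$id %||% f$properties$id %||% k)
    geom <- f$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = {
        message("MultiPolygon annotation ", id, " split into ",
                length(geom$coordinates), " parts")
        geom$coordinates
      },
      stop("unsupported geometry type: ", geom$type))
    for (pi in seq_along(polys)) {
      pid <- if (length(polys) > 1L) paste0(id, "_", pi) else id
      rings <- polys[[pi]]
      out[[length(out) + 1L]] <- list(
        id = pid,
        polygon = close_ring(rings[[1]], pid),
        holes = lapply(seq_along(rings)[-1],
                       function(h) close_ring(rings[[h]], pid)),
        properties = f$properties %||% list())
    }
  }
  out
}

#' Write polygon annotations to GeoJSON
#'
#' @param annotations List of annotations as returned by
#'   [read_geojson_annotations()], or a list of 2-column matrices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson_annotations <- function(annotations, path) {
  feats <- lapply(seq_along(annotations), function(k) {
    a <- annotations[[k]]
    if (!is.list(a) || is.null(a$polygon))
      a <- list(id = as.character(k), polygon = as.matrix(a),
                holes = list(), properties = list())
    ring <- a$polygon
    if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    coords <- c(list(lapply(seq_len(nrow(ring)),
                            function(i) unname(ring[i, ]))),
                lapply(a$holes %||% list(), function(h) {
                  if (!all(h[1, ] == h[nrow(h), ])) h <- rbind(h, h[1, ])
                  lapply(seq_len(nrow(h)), function(i) unname(h[i, ]))
                }))
    list(type = "Feature", id = a$id %||% as.character(k),
         properties = a$properties %||% list(),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an RGB image (PNG or TIFF)
#'
#' @param path Image path; format chosen by extension.
#' @return Integer array `h x w x 3` with values 0-255.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  array(as.integer(round(img * 255)), dim = dim(img))
}

#' Write an RGB image (PNG or TIFF)
#'
#' @param image Integer array `h x w x 3`, values 0-255.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  img <- image / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext))
  invisible(path)
}

#' Default run configuration
#'
#' The pipeline's tunable parameters with their standard values: the
#' 170 um^2 minimum object size, the 40 um^2 per-hormone positivity
#' threshold, 0.5 um/px scale, and the 0-9 bin reporting range.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(min_eo_area_um2 = 170,
       positivity_um2 = 40,
       microns_per_px = 0.5,
       max_bin = 9L,
       od_threshold = 0.15,
       od_floor = 0.05,
       seed = 1L)
}

#' Read a run configuration from YAML
#'
#' Unspecified keys fall back to [default_config()]; every override is
#' logged so deviations from the standard thresholds stay auditable.
#'
#' @param path Path to a YAML file (or `NULL` for pure defaults).
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (k in names(user)) {
    if (k %in% names(cfg) && !identical(user[[k]], cfg[[k]]))
      message("config override: ", k, " = ", user[[k]],
              " (default ", cfg[[k]], ")")
    cfg[[k]] <- user[[k]]
  }
  cfg
}

#' Write a provenance record for an output directory
#'
#' Records the configuration (and its MD5 hash), seed, package version, and
#' R version as machine-readable JSON, so every output directory carries
#' its own reproducibility metadata.
#'
#' @param dir Output directory (created if needed).
#' @param config Configuration list.
#' @param seed Integer seed used for the run.
#' @return Path of the provenance file, invisibly.
#' @export
write_provenance <- function(dir, config = default_config(), seed = config$seed) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  prov <- list(
    package = "eoquant",
    package_version = as.character(utils::packageVersion("eoquant")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    config_md5 = unname(tools::md5sum(tmp)))
  path <- file.path(dir, "provenance.json")
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
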