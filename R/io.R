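## Readers and writers for the formats the pipeline touches: multi-page
## TIFF video stacks (or directories of ordered PNG/TIFF frames),
## angiogram TIFFs with JSON sidecars, plate layouts, per-embryo endpoint
## CSVs and annotation JSON documents.
##
## Conventions: intensities on [0,1]; image coordinates 0-based
## (row, column) with origin at the top-left in interchange JSON;
## concentrations in µM everywhere.

frame_to_gray <- function(img) {
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3]),
                                               drop = FALSE], c(1, 2), mean)
  img
}

#' Read a video stack from disk
#'
#' Accepts a multi-page TIFF file or a directory of lexically ordered
#' single-frame PNG/TIFF files; intensities are returned on \[0,1\]
#' (the tiff/png readers already normalise by the bit depth).
#'
#' @param path TIFF file or frame directory.
#' @param frame_rate_fps metadata frame rate.
#' @return a [video_stack()].
#' @export
read_video_stack <- function(path, frame_rate_fps = 20) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 2) stopf("need at least 2 frames in %s", path)
    frames <- lapply(files, function(f) {
      img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
             else tiff::readTIFF(f)
      frame_to_gray(img)
    })
  } else {
    if (!file.exists(path)) stopf("no such file: %s", path)
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    if (length(frames) < 2) stopf("need at least 2 frames in %s", path)
    frames <- lapply(frames, frame_to_gray)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("frames have mixed shapes")
  video_stack(frames, frame_rate_fps)
}

#' Write a video stack as a multi-page TIFF
#'
#' @param stack a [video_stack()].
#' @param path output file.
#' @param bits_per_sample TIFF bit depth (8 or 16).
#' @return `path`, invisibly.
#' @export
write_video_stack <- function(stack, path, bits_per_sample = 16) {
  stopifnot(inherits(stack, "video_stack"))
  frames <- lapply(seq_len(dim(stack$frames)[3]),
                   function(t) stack$frames[, , t])
  tiff::writeTIFF(frames, path, bits.per.sample = bits_per_sample)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Write an angiogram as 16-bit TIFF plus JSON sidecar
#'
#' The motion counts are stored as a 16-bit single-page TIFF (counts
#' divided by 65535) and the parameters and frame count in a JSON sidecar
#' next to it, so the angiogram round-trips exactly.
#'
#' @param angiogram a [build_angiogram()] result.
#' @param path output TIFF path; the sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_angiogram <- function(angiogram, path) {
  stopifnot(inherits(angiogram, "angiogram"))
  tiff::writeTIFF(angiogram$counts / 65535, path, bits.per.sample = 16)
  meta <- list(n_frames = angiogram$n_frames,
               params = unclass(angiogram$params),
               coordinate_convention = "0-based (row, column), origin top-left",
               shape = dim(angiogram$counts))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an angiogram written by [write_angiogram()]
#'
#' @param path TIFF path with JSON sidecar.
#' @return an `angiogram`.
#' @export
read_angiogram <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stopf("missing sidecar: %s", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  counts <- round(tiff::readTIFF(path) * 65535)
  storage.mode(counts) <- "integer"
  params <- do.call(angiogram_params, meta$params[
    intersect(names(meta$params),
              names(formals(angiogram_params)))])
  structure(list(counts = counts, n_frames = meta$n_frames, params = params),
            class = "angiogram")
}

#' Read and validate a plate layout
#'
#' CSV with columns `well`, `compound`, `concentration_uM`, `replicate`
#' and optionally `exposure_window` (`"3-96"` or `"24-96"`).  Wells use
#' 96-well addressing A1-H12 and must be unique; every replicate must
#' contain controls (concentration 0).
#'
#' @param path CSV file.
#' @return data.frame of class `plate_layout` with an `is_control` column.
#' @export
read_plate_layout <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "compound", "concentration_uM", "replicate")
  if (!all(need %in% names(d)))
    stopf("plate layout needs columns: %s", paste(need, collapse = ", "))
  bad <- !grepl("^[A-H](1[0-2]|[1-9])$", d$well)
  if (any(bad)) stopf("unknown well label(s): %s",
                      paste(unique(d$well[bad]), collapse = ", "))
  key <- paste(d$well, d$replicate)
  if (anyDuplicated(key)) stopf("duplicate well(s): %s",
                                paste(unique(key[duplicated(key)]),
                                      collapse = ", "))
  if (any(d$concentration_uM < 0)) stopf("concentration < 0 in layout")
  d$is_control <- d$concentration_uM == 0
  ctrl <- tapply(d$is_control, d$replicate, any)
  if (!all(ctrl)) stopf("replicate(s) without controls: %s",
                        paste(names(ctrl)[!ctrl], collapse = ", "))
  structure(d, class = c("plate_layout", "data.frame"))
}

#' Read a per-embryo endpoint table
#'
#' CSV with columns embryo_id, compound, concentration_uM, replicate,
#' endpoint, value and optionally alive.
#'
#' @param path CSV file.
#' @param kind endpoint kind recorded as the `endpoint_kind` attribute.
#' @return an `endpoint_observations` data.frame.
#' @export
read_endpoint_csv <- function(path, kind = c("continuous", "quantal")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("no such file: %s", path)
  d <- as_observations(read.csv(path, stringsAsFactors = FALSE))
  structure(d, class = c("endpoint_observations", "data.frame"),
            endpoint_kind = kind)
}

## ---- annotation documents (FishInspector-style JSON) ----------------

#' Create an annotation document
#'
#' A light, JSON-serialisable description of named image features, each a
#' list of 0-based (row, column) coordinates with a smoothing factor —
#' schema-compatible in spirit with annotation files used by
#' high-content fish-embryo imaging tools.
#'
#' @param image_id image identifier.
#' @param features list of features, each `list(name =, coordinates =
#'   <n x 2 matrix>, smoothing_factor =)`.
#' @param image_shape optional `c(height, width)` used for bounds checks.
#' @param ... additional fields, preserved on round-trip.
#' @return an object of class `annotation_document`.
#' @export
annotation_document <- function(image_id, features = list(),
                                image_shape = NULL, ...) {
  for (f in features) {
    if (is.null(f$name) || is.null(f$coordinates))
      stopf("each feature needs `name` and `coordinates`")
    if (!is.null(image_shape) && length(f$coordinates)) {
      co <- f$coordinates
      if (any(co[, 1] < 0 | co[, 1] >= image_shape[1] |
                co[, 2] < 0 | co[, 2] >= image_shape[2]))
        stopf("feature '%s' has coordinates outside the image", f$name)
    }
  }
  structure(list(image_id = image_id, schema_version = "1.0",
                 coordinate_convention = "0-based (row, column), origin top-left",
                 image_shape = image_shape, features = features, ...),
            class = "annotation_document")
}

#' Write / read annotation JSON
#'
#' Lossless round-trip: `read_annotation_json(write_annotation_json(doc))`
#' reproduces the document, preserving unknown fields.
#'
#' @param doc an [annotation_document()].
#' @param path JSON file.
#' @return `path` invisibly (write); an `annotation_document` (read).
#' @export
write_annotation_json <- function(doc, path) {
  stopifnot(inherits(doc, "annotation_document"))
  jsonlite::write_json(unclass(doc), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_annotation_json
#' @export
read_annotation_json <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE),
                  error = function(e) stopf("malformed JSON in %s: %s",
                                            path, conditionMessage(e)))
  doc$features <- lapply(doc$features, function(f) {
    if (!is.null(f$coordinates)) {
      co <- f$coordinates
      if (is.list(co)) co <- do.call(rbind, co)
      if (is.null(dim(co))) co <- matrix(co, ncol = 2, byrow = TRUE)
      f$coordinates <- co
    }
    f
  })
  if (!is.null(doc$image_shape)) doc$image_shape <- as.numeric(doc$image_shape)
  class(doc) <- "annotation_document"
  doc
}

#' Annotation document for an ISV count result
#'
#' Emits one circle feature per counted ISV, centred on the scan line at
#' the detected column, with the configurable circle diameter (default
#' 113 px, the manual-annotation circle size the automated counter
#' replaces).
#'
#' @param result an `isv_count_result`.
#' @param image_id image identifier.
#' @param image_shape `c(height, width)`.
#' @param diameter_px circle diameter recorded as the smoothing factor.
#' @return an `annotation_document`.
#' @export
annotation_from_isv <- function(result, image_id, image_shape,
                                diameter_px = 113) {
  stopifnot(inherits(result, "isv_count_result"))
  features <- lapply(seq_along(result$isv_column_positions), function(i)
    list(name = sprintf("isv_%02d", i),
         coordinates = matrix(c(result$scan_row - 1,
                                result$isv_column_positions[i] - 1),
                              ncol = 2),
         smoothing_factor = diameter_px))
  annotation_document(image_id, features, image_shape = image_shape,
                      isv_count = result$isv_count,
                      qc_flags = as.list(result$qc_flags))
}

#' Write a provenance record
#'
#' Parameters, seed and software versions of a run, as JSON.  Contains no
#' timestamps so that repeated runs are byte-identical.
#'
#' @param path output JSON file.
#' @param parameters named list of run parameters.
#' @param seed RNG seed used.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, parameters = list(), seed = NULL) {
  jsonlite::write_json(list(
    package = "angiofish",
    package_version = as.character(packageVersion("angiofish")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed, parameters = parameters
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Write concentration-response results as a tidy CSV
#'
#' One row per analysed compound x endpoint with gate decisions, trend p,
#' and ECx estimates with confidence bounds.
#'
#' @param results named list of `cr_result` objects (names used as the
#'   compound/endpoint label).
#' @param path output CSV.
#' @return the tidy data.frame, invisibly.
#' @export
write_cr_results <- function(results, path) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    ec <- function(lv, col) {
      if (is.null(r$ecx)) return(NA_real_)
      i <- match(lv, r$ecx$x)
      if (is.na(i)) NA_real_ else r$ecx[[col]][i]
    }
    data.frame(label = nm, endpoint = r$endpoint %||% NA_character_,
               kind = r$kind, status = r$status,
               gate_trend = r$gates$trend, gate_aic = r$gates$aic,
               gate_magnitude = r$gates$magnitude,
               p_trend = r$trend$p_adjusted,
               ec10 = ec(10, "ecx"), ec10_lower = ec(10, "lower"),
               ec10_upper = ec(10, "upper"),
               ec50 = ec(50, "ecx"), ec50_lower = ec(50, "lower"),
               ec50_upper = ec(50, "upper"))
  })
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
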