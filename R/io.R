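# Readers and writers: images (PNG natively, JPEG via EBImage when
# installed), polygon annotation JSON, dataset manifests, saliency-map
# containers. All loaders are deterministic; images come back as
# [height, width, channel] arrays in [0, 1].

#' Load an image, resized and scaled to a spec
#'
#' Reads a PNG or JPEG, replicates grayscale to three channels (with a
#' warning), bilinearly resizes to the spec's spatial size and scales
#' intensities into the spec's value range.
#'
#' @param path Image file path.
#' @param spec An [input_spec()].
#' @return Image array `height x width x channels`.
#' @export
load_image <- function(path, spec = input_spec()) {
  if (!file.exists(path)) stop("I/O error: cannot read '", path, "'", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("png")) {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("I/O error: JPEG support requires the EBImage package", call. = FALSE)
    }
    e <- EBImage::readImage(path)
    a <- as.array(e)
    if (length(dim(a)) == 2) t(a) else aperm(a, c(2, 1, 3))
  } else {
    stop("I/O error: unsupported image format '", ext, "' for '", path, "'",
         call. = FALSE)
  }
  if (length(dim(img)) == 2) {
    warning("grayscale input replicated to 3 channels: ", path)
    img <- array(rep(img, 3), c(dim(img), 3))
  }
  if (dim(img)[3] > spec$channels) img <- img[, , seq_len(spec$channels), drop = FALSE]
  out <- array(0, c(spec$height, spec$width, spec$channels))
  for (ch in seq_len(spec$channels)) {
    out[, , ch] <- bilinear_upsample(img[, , ch], spec$height, spec$width)
  }
  lo <- spec$value_range[1]; hi <- spec$value_range[2]
  lo + pmin(pmax(out, 0), 1) * (hi - lo)
}

#' Write an image array to PNG
#' @param image `h x w x c` array in \[0, 1\] (clipped).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Save a saliency map (raw array + metadata, plus a viewable PNG)
#'
#' The raw floating-point attributions and metadata go to an RDS container
#' (lossless round trip); alongside it a min-max-scaled grayscale PNG of
#' `map2d` is written for visual inspection.
#'
#' @param sal A `saliency_map`.
#' @param path Output path for the container (`.rds`); the PNG gets the same
#'   stem.
#' @param png Also write the visualization PNG.
#' @return `path`, invisibly.
#' @export
save_saliency <- function(sal, path, png = TRUE) {
  stopifnot(inherits(sal, "saliency_map"))
  saveRDS(sal, path)
  if (png) {
    vis <- normalize_minmax(sal$map2d)
    png::writePNG(vis, paste0(tools::file_path_sans_ext(path), ".png"))
  }
  invisible(path)
}

#' Load a saved saliency map
#' @param path Container path written by [save_saliency()].
#' @return The `saliency_map`, bit-identical to what was saved.
#' @export
load_saliency <- function(path) {
  sal <- readRDS(path)
  stopifnot(inherits(sal, "saliency_map"))
  sal
}

#' Load polygon lesion annotations
#'
#' Reads the documented JSON schema: a list of
#' `{"lesion_class": ..., "vertices": [[row, col], ...]}` records (0-based
#' pixel coordinates) and rasterizes each polygon. An empty list yields empty
#' masks (the grade-0 convention).
#'
#' @param path JSON annotation file.
#' @param shape Integer `c(height, width)`.
#' @return A [lesion_mask_set()].
#' @examples
#' ann <- system.file("extdata", "example_annotations.json",
#'                    package = "fundusXAI")
#' masks <- load_annotations(ann, c(224, 224))
#' sum(masks$union)
#' @export
load_annotations <- function(path, shape) {
  if (!file.exists(path)) stop("I/O error: cannot read '", path, "'", call. = FALSE)
  anns <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  class_masks <- stats::setNames(
    lapply(LESION_CLASSES, function(cl) matrix(FALSE, shape[1], shape[2])),
    LESION_CLASSES)
  for (i in seq_along(anns)) {
    rec <- anns[[i]]
    if (is.null(rec$lesion_class) || !rec$lesion_class %in% LESION_CLASSES) {
      stop("parse error: record ", i, " has unknown lesion class '",
           rec$lesion_class %||% "<missing>", "'", call. = FALSE)
    }
    verts <- do.call(rbind, lapply(rec$vertices, unlist))
    m <- suppressWarnings(polygon_to_mask(verts, shape))
    class_masks[[rec$lesion_class]] <- class_masks[[rec$lesion_class]] | m
  }
  lesion_mask_set(class_masks)
}

#' Write polygon annotations to the JSON schema
#' @param annotations List of [polygon_annotation()] objects.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_annotations <- function(annotations, path) {
  recs <- lapply(annotations, function(a) {
    list(lesion_class = a$lesion_class,
         vertices = lapply(seq_len(nrow(a$vertices)),
                           function(i) as.numeric(a$vertices[i, ])))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Dataset manifest
#'
#' @param records Data frame with columns `image` (path), `grade` (0-4) and
#'   optional `annotation` / `mask` paths.
#' @param provenance Free-form provenance list.
#' @return Object of class `dataset_manifest`.
#' @export
dataset_manifest <- function(records, provenance = list()) {
  stopifnot(is.data.frame(records), all(c("image", "grade") %in% names(records)))
  if (!all(records$grade %in% 0:4)) {
    stop("contract error: grades must be in 0..4", call. = FALSE)
  }
  structure(list(records = records, provenance = provenance),
            class = "dataset_manifest")
}

#' Read / write a manifest as JSON
#' @param path Manifest path.
#' @return A `dataset_manifest`.
#' @export
load_manifest <- function(path) {
  obj <- jsonlite::fromJSON(path)
  dataset_manifest(as.data.frame(obj$records),
                   provenance = as.list(obj$provenance))
}

#' @rdname load_manifest
#' @param manifest A [dataset_manifest()].
#' @export
save_manifest <- function(manifest, path) {
  jsonlite::write_json(list(records = manifest$records,
                            provenance = manifest$provenance),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Per-grade counts and proportions of a manifest
#'
#' @param manifest A [dataset_manifest()], or an integer vector of per-grade
#'   counts (grades 0..4).
#' @return Data frame with `grade`, `count`, `proportion` (percent, full
#'   precision) and `proportion_display` (rounded to 2 decimals).
#' @export
summarize_manifest <- function(manifest) {
  counts <- if (inherits(manifest, "dataset_manifest")) {
    if (!nrow(manifest$records)) {
      stop("contract error: empty manifest", call. = FALSE)
    }
    as.integer(table(factor(manifest$records$grade, levels = 0:4)))
  } else {
    as.integer(manifest)
  }
  if (sum(counts) == 0) stop("contract error: empty manifest", call. = FALSE)
  prop <- 100 * counts / sum(counts)
  data.frame(grade = seq_along(counts) - 1L, count = counts,
             proportion = prop, proportion_display = round(prop, 2))
}
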