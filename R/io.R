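#' Write / read ECG images, masks, and sidecar metadata
#'
#' Images are written as lossless PNG (`.png`) or JPEG (`.jpg`/`.jpeg`,
#' for photo-like fixtures; quality configurable); masks as single-channel
#' PNG; metadata (labels, seed, layout, scale) as a YAML sidecar next to the
#' image.
#'
#' @param image An `ecg_image`.
#' @param path Output path; the extension selects the codec.
#' @param quality JPEG quality in `(0, 1]`.
#' @param sidecar Write `<path>.yaml` metadata.
#' @return `path`, invisibly.
#' @export
write_ecg_image <- function(image, path, quality = 0.9, sidecar = TRUE) {
  stop_if_not_image(image)
  arr <- clamp(image$pixels, 0, 255) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(arr, path)
  } else if (ext %in% c("jpg", "jpeg")) {
    jpeg::writeJPEG(arr, path, quality = quality)
  } else {
    abort(sprintf("Unsupported image extension '%s' (use png/jpg).", ext))
  }
  if (!is.null(image$signal_mask)) {
    png::writePNG(image$signal_mask * 1, mask_path(path))
  }
  if (sidecar) {
    meta <- list(
      mm_per_pixel = image$mm_per_pixel,
      domain_tag = image$domain_tag,
      provenance = image$provenance,
      record = image$record_meta,
      layout = list(rows = image$layout$rows, cols = image$layout$cols,
                    rhythm_lead = image$layout$rhythm_lead)
    )
    yaml::write_yaml(meta, paste0(path, ".yaml"))
  }
  invisible(path)
}

mask_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_mask.png")
}

#' @rdname write_ecg_image
#' @return `read_ecg_image()` returns an `ecg_image` (mask and metadata
#'   restored when their files exist).
#' @export
read_ecg_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") png::readPNG(path) else jpeg::readJPEG(path)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3]
  px <- arr * 255
  meta_file <- paste0(path, ".yaml")
  meta <- if (file.exists(meta_file)) yaml::read_yaml(meta_file) else list()
  mfile <- mask_path(path)
  mask <- if (file.exists(mfile)) {
    m <- png::readPNG(mfile)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m > 0.5
  } else {
    NULL
  }
  structure(
    list(pixels = px, signal_mask = mask,
         mm_per_pixel = meta$mm_per_pixel %||% NA_real_,
         layout = NULL,
         domain_tag = meta$domain_tag %||% "source",
         provenance = meta$provenance %||% "external",
         record_meta = meta$record),
    class = "ecg_image"
  )
}

#' Generate a seeded synthetic image corpus on disk
#'
#' Writes `n_per_condition` (image, mask, YAML metadata) triplets per
#' condition: PNG rasters, single-channel PNG masks, and a corpus-level
#' YAML manifest recording per-image seeds and labels. The same
#' (config, seed) yields a byte-identical corpus.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_per_condition Images per condition.
#' @param conditions Conditions to generate (default all supported).
#' @param seed Corpus seed.
#' @param mm_per_pixel Rendering scale.
#' @param layout An [ecg_layout()].
#' @return A tibble manifest (id, condition, seed, file paths), invisibly;
#'   also written as `manifest.yaml`.
#' @export
generate_corpus <- function(out_dir, n_per_condition,
                            conditions = ecg_conditions(), seed = 1L,
                            mm_per_pixel = 0.5, layout = ecg_layout()) {
  bad <- setdiff(conditions, ecg_conditions())
  if (length(bad)) {
    abort(sprintf("Unknown condition(s): %s.", paste(bad, collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  total <- n_per_condition * length(conditions)
  if (total == 0L) {
    manifest <- tibble(id = character(), condition = character(),
                       seed = integer(), image = character(),
                       mask = character())
    yaml::write_yaml(list(), file.path(out_dir, "manifest.yaml"))
    return(invisible(manifest))
  }
  seeds <- derive_seeds(seed, total)
  grid <- tidyr::expand_grid(condition = conditions,
                             rep = seq_len(n_per_condition))
  rows <- purrr::map(seq_len(total), function(i) {
    cond <- grid$condition[i]
    id <- sprintf("%s_%03d", cond, grid$rep[i])
    rec <- synthesize_record(cond, duration_s = 10, seed = seeds[i])
    img <- render_ecg_image(rec, layout = layout, mm_per_pixel = mm_per_pixel)
    f <- file.path(out_dir, paste0(id, ".png"))
    write_ecg_image(img, f)
    tibble(id = id, condition = cond, seed = seeds[i],
           image = f, mask = mask_path(f))
  })
  manifest <- dplyr::bind_rows(rows)
  yaml::write_yaml(purrr::transpose(as.list(manifest)),
                   file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Photo-augment a corpus directory
#'
#' Reads every PNG in `in_dir`, applies the shadow / perspective / flash
#' pipeline, and writes JPEGs plus warped masks and a YAML manifest of the
#' per-image seeds and shadow parameters.
#'
#' @param in_dir Directory of source PNGs (masks alongside are warped too).
#' @param out_dir Output directory.
#' @param config An [augment_config()].
#' @param seed Corpus-level augmentation seed.
#' @param quality JPEG quality.
#' @return The manifest tibble, invisibly.
#' @export
augment_corpus <- function(in_dir, out_dir, config = augment_config(),
                           seed = config$seed, quality = 0.9) {
  files <- sort(list.files(in_dir, pattern = "\\.png$", full.names = TRUE))
  files <- files[!grepl("_mask\\.png$", files)]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- if (length(files)) derive_seeds(seed, length(files)) else integer()
  rows <- purrr::map(seq_along(files), function(i) {
    img <- read_ecg_image(files[i])
    aug <- augment_photo(img, config, seeds[i])
    id <- tools::file_path_sans_ext(basename(files[i]))
    f <- file.path(out_dir, paste0(id, ".jpg"))
    write_ecg_image(aug, f, quality = quality)
    sp <- attr(aug, "shadow_params")
    tibble(id = id, seed = seeds[i], image = f,
           n_shadows = if (is.null(sp)) 0L else nrow(sp))
  })
  manifest <- dplyr::bind_rows(rows)
  yaml::write_yaml(purrr::transpose(as.list(manifest)),
                   file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
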