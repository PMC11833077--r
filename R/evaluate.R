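#' Agreement coefficient between two binary masks
#'
#' `C = (1 / (i * j)) * (i * j - sum(|a - b|))`: one minus the normalized L1
#' distance, i.e. the fraction of pixels on which the two masks agree
#' (marked by both, or by neither). `C = 1` for identical masks, `C = 0`
#' for complementary ones; always in `[0, 1]` and symmetric in its
#' arguments.
#'
#' @param a,b Logical (or 0/1) matrices of identical dimensions, e.g. an
#'   expert annotation mask and a binarized saliency mask.
#' @return Scalar agreement coefficient.
#' @export
agreement_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("Dimension mismatch: %s vs %s.",
                  paste(dim(a), collapse = "x"),
                  paste(dim(b), collapse = "x")))
  }
  n <- length(a)
  (n - sum(abs(as.numeric(a) - as.numeric(b)))) / n
}

#' Colocalization confusion call for one image
#'
#' Classifies the agreement between the network's signal features (the
#' binarized saliency restricted to signal pixels) and known clinical
#' feature regions: a true positive when at least `overlap_threshold` (90%)
#' of the saliency colocalizes with relevant clinical features, a false
#' positive when less than that; a true negative when at least 90% of the
#' saliency avoids irrelevant-feature regions, a false negative when 10% or
#' more of it lands on them. The positive and negative calls are made
#' independently (the same image can be both TP and TN). An empty saliency
#' mask yields an abstention (`NA` calls), to be excluded from counts.
#'
#' @param saliency_mask Binarized saliency (logical matrix).
#' @param relevant_mask Pixels belonging to the condition's clinical
#'   features.
#' @param irrelevant_mask Pixels of clinically irrelevant features (e.g. the
#'   rest of the trace); optional — when `NULL`, TN/FN are `NA`.
#' @param overlap_threshold Colocalization threshold (default 0.90).
#' @return A one-row tibble: `relevant_fraction`, `irrelevant_fraction`,
#'   logical `tp`, `fp`, `tn`, `fn`, and `abstained`.
#' @export
colocalization_confusion <- function(saliency_mask, relevant_mask,
                                     irrelevant_mask = NULL,
                                     overlap_threshold = 0.90) {
  if (!identical(dim(saliency_mask), dim(relevant_mask))) {
    abort("Masks must be registered to the same image (equal dimensions).")
  }
  n_sal <- sum(saliency_mask)
  if (n_sal == 0) {
    return(tibble(relevant_fraction = NA_real_,
                  irrelevant_fraction = NA_real_,
                  tp = NA, fp = NA, tn = NA, fn = NA, abstained = TRUE))
  }
  rel <- sum(saliency_mask & relevant_mask) / n_sal
  irr <- if (is.null(irrelevant_mask)) {
    NA_real_
  } else {
    sum(saliency_mask & irrelevant_mask) / n_sal
  }
  tibble(
    relevant_fraction = rel,
    irrelevant_fraction = irr,
    tp = rel >= overlap_threshold,
    fp = rel < overlap_threshold,
    tn = if (is.na(irr)) NA else (1 - irr) >= overlap_threshold,
    fn = if (is.na(irr)) NA else irr >= (1 - overlap_threshold),
    abstained = FALSE
  )
}

#' Score saliency maps against annotation masks
#'
#' The prospective scoring protocol: each image (unmarked) is forward-
#' propagated, its Jacobian map computed, scaled to 0-255, binarized above
#' the cutoff, and compared to the per-image annotation mask with the
#' agreement coefficient; results are summarized per condition as
#' mean +/- sd. Images without an annotation are skipped with a warning.
#'
#' @param images List of `ecg_image` objects.
#' @param annotation_masks List of logical matrices at the network input
#'   resolution (or `NULL` entries for missing annotations).
#' @param model A trained `ecg_net`.
#' @param conditions Character vector of per-image condition labels.
#' @param cutoff Binarization cutoff (default 20).
#' @return An `agreement_report`: list with `per_image` (tibble of id,
#'   condition, coefficient) and `per_condition` (tibble of condition,
#'   `mean_c`, `sd_c`, `n`).
#' @export
prospective_protocol <- function(images, annotation_masks, model,
                                 conditions = NULL, cutoff = 20) {
  if (length(images) != length(annotation_masks)) {
    abort("`images` and `annotation_masks` must have equal length.")
  }
  if (is.null(conditions)) {
    conditions <- purrr::map_chr(images, ~ .x$record_meta$condition %||% "unknown")
  }
  rows <- purrr::map(seq_along(images), function(i) {
    if (is.null(annotation_masks[[i]])) {
      warn(sprintf("Image %d has no annotation mask; skipped.", i))
      return(NULL)
    }
    ex <- explain_image(model, images[[i]], cutoff = cutoff)
    if (isTRUE(ex$skipped)) {
      warn(sprintf("Image %d skipped: %s.", i, ex$reason))
      return(NULL)
    }
    tibble(
      id = i, condition = conditions[i],
      coefficient = agreement_coefficient(annotation_masks[[i]], ex$mask)
    )
  })
  per_image <- dplyr::bind_rows(rows)
  per_condition <- per_image |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean_c = mean(.data$coefficient),
                     sd_c = sd(.data$coefficient), n = dplyr::n(),
                     .groups = "drop")
  structure(list(per_image = per_image, per_condition = per_condition),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  print(x$per_condition)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
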