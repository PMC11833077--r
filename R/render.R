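#' Describe a 12-lead ECG paper layout
#'
#' The default is the commonest clinical printout: 3 rows x 4 columns of
#' 2.5 s panels (columns show consecutive time windows) plus a full-width
#' 10 s lead-II rhythm strip. Panels are filled column-by-column with the
#' standard lead order (I, II, III | aVR, aVL, aVF | V1..V3 | V4..V6).
#'
#' @param rows,cols Panel grid dimensions; `rows * cols` must be 12.
#' @param panel_duration_s Seconds of signal shown per panel.
#' @param rhythm_lead Lead name for the rhythm strip, or `NULL` for none.
#' @param panel_height_mm Vertical extent of each panel row in mm.
#' @param calibration Draw a 1 mV / 0.2 s calibration pulse at the start of
#'   each row.
#' @return A list of class `ecg_layout`.
#' @export
ecg_layout <- function(rows = 3, cols = 4, panel_duration_s = 2.5,
                       rhythm_lead = "II", panel_height_mm = 24,
                       calibration = TRUE) {
  if (rows * cols != 12L) {
    abort("`rows * cols` must equal 12 so the layout covers all 12 leads.")
  }
  if (!is.null(rhythm_lead) && !rhythm_lead %in% ecg_lead_names()) {
    abort(sprintf("Unknown rhythm lead '%s'.", rhythm_lead))
  }
  structure(
    list(rows = rows, cols = cols, panel_duration_s = panel_duration_s,
         rhythm_lead = rhythm_lead, panel_height_mm = panel_height_mm,
         calibration = calibration,
         # column-major clinical ordering
         lead_grid = matrix(ecg_lead_names(), nrow = rows, ncol = cols)),
    class = "ecg_layout"
  )
}

ink_rgb <- c(5, 5, 8)          # near-black: luminance ~5.3 < 10/256 threshold

# Per-record print/scan style: paper tint, grid ink, baseline placement and
# grid phase vary across real printers and scanners. Sampling them (seeded
# from the record) keeps the background from being pixel-identical across a
# corpus — a classifier trained on such a corpus would otherwise never face
# any pressure to distinguish trace from stationery.
sample_render_style <- function() {
  list(
    paper = runif(1, 248, 255),
    minor = c(255, runif(1, 195, 225), runif(1, 195, 225)),
    major = c(runif(1, 243, 252), runif(1, 148, 175), runif(1, 148, 175)),
    baseline_frac = runif(1, 0.58, 0.66),
    grid_phase = runif(1, 0, 1)
  )
}

fixed_render_style <- function() {
  list(paper = 255, minor = c(255, 210, 210), major = c(250, 160, 160),
       baseline_frac = 0.62, grid_phase = 0)
}

# Rasterize y = f(x) given per-column y positions; consecutive columns are
# joined by vertical spans so the trace is connected. Returns row indices per
# column as a list.
trace_spans <- function(y_px) {
  n <- length(y_px)
  prev <- c(y_px[1], y_px[-n])
  purrr::map2(y_px, prev, function(cur, pr) {
    lo <- min(cur, pr)
    hi <- max(cur, pr)
    seq.int(lo, hi)
  })
}

#' Render an ECG record as a checkered-paper raster image
#'
#' Draws standard ECG paper (1 mm minor / 5 mm major grid) and the 12-lead
#' traces at 25 mm/s and 10 mm/mV, in near-black ink whose luminance falls
#' below the signal-segmentation threshold by construction. The returned
#' image carries an exact boolean mask of every trace pixel the rasterizer
#' touched.
#'
#' @param record An `ecg_record` from [synthesize_record()].
#' @param layout An `ecg_layout` (default [ecg_layout()]).
#' @param mm_per_pixel Paper millimetres per pixel (default 0.5, i.e. 50 px
#'   per second of signal). Rejected when coarser than 10 mm/px, where a 1 mV
#'   deflection would span less than one pixel.
#' @param domain_tag `"source"` (scan-like) or `"target"` (photo-like).
#' @param style_jitter Vary paper tint, grid ink, baseline placement and
#'   grid phase per record (seeded from the record), emulating printer and
#'   scanner variability; `FALSE` gives one fixed house style.
#' @return An object of class `ecg_image`: `pixels` (H x W x 3 array of
#'   0-255 intensities), `signal_mask` (H x W logical), `mm_per_pixel`,
#'   `layout`, `domain_tag`, `provenance`, and `record_meta` (condition,
#'   heart rate, seed).
#' @examples
#' img <- render_ecg_image(synthesize_record("normal", seed = 1))
#' dim(img$pixels)
#' @export
render_ecg_image <- function(record, layout = ecg_layout(),
                             mm_per_pixel = 0.5, domain_tag = "source",
                             style_jitter = TRUE) {
  if (!inherits(record, "ecg_record")) abort("`record` must be an <ecg_record>.")
  if (!inherits(layout, "ecg_layout")) abort("`layout` must be an <ecg_layout>.")
  if (mm_per_pixel > 10) {
    abort(sprintf(
      "mm_per_pixel = %g is too coarse: a 1 mV deflection (10 mm) would span %.2f px (< 1 px).",
      mm_per_pixel, 10 / mm_per_pixel
    ))
  }
  domain_tag <- match.arg(domain_tag, c("source", "target"))
  style <- if (style_jitter) {
    with_seed((record$meta$seed %||% 0) + 77003L, sample_render_style())
  } else {
    fixed_render_style()
  }
  mpp <- mm_per_pixel
  fs <- record$sampling_rate
  n_rows_total <- layout$rows + as.integer(!is.null(layout$rhythm_lead))
  panel_h_px <- round(layout$panel_height_mm / mpp)
  panel_w_px <- round(layout$panel_duration_s * 25 / mpp)
  H <- n_rows_total * panel_h_px
  W <- layout$cols * panel_w_px

  px <- array(style$paper, c(H, W, 3L))
  # --- grid ---------------------------------------------------------------
  # grid strokes are ~0.2 mm (minor) / 0.4 mm (major) wide; at coarse
  # scales a stroke covers only a fraction of a pixel, so lines are blended
  # by their pixel coverage instead of painted at full saturation
  phase <- style$grid_phase
  draw_grid <- function(step_mm, rgb, width_mm) {
    step <- step_mm / mpp
    if (step < 2) return()
    alpha <- min(1, width_mm / mpp)
    xs <- unique(clamp(round(seq(1 + phase * step, W, by = step)), 1, W))
    ys <- unique(clamp(round(seq(1 + phase * step, H, by = step)), 1, H))
    for (c in 1:3) {
      px[ys, , c] <<- (1 - alpha) * px[ys, , c] + alpha * rgb[c]
      px[, xs, c] <<- (1 - alpha) * px[, xs, c] + alpha * rgb[c]
    }
  }
  draw_grid(1, style$minor, 0.25)
  draw_grid(5, style$major, 0.45)

  mask <- matrix(FALSE, H, W)
  px_per_mv <- 10 / mpp
  draw_ink <- function(rows, col) {
    rows <- rows[rows >= 1 & rows <= H]
    mask[rows, col] <<- TRUE
    for (c in 1:3) px[rows, col, c] <<- ink_rgb[c]
  }

  get_lead <- function(name) record$leads$samples[[which(record$leads$lead == name)]]
  sample_at <- function(sig, t) {
    # linear interpolation in time, clipped to the record
    t <- clamp(t, 0, (length(sig) - 1) / fs)
    i <- t * fs
    i0 <- floor(i)
    frac <- i - i0
    (1 - frac) * sig[i0 + 1] + frac * sig[pmin(i0 + 2, length(sig))]
  }

  draw_panel <- function(lead, row, col0_px, width_px, t_start, t_dur,
                         with_cal) {
    baseline <- round((row - 1 + style$baseline_frac) * panel_h_px)
    sig <- get_lead(lead)
    cal_px <- if (with_cal) round(0.2 * 25 / mpp) else 0L
    if (with_cal) {
      # 1 mV calibration pulse: up, plateau, down
      top <- baseline - round(px_per_mv)
      draw_ink(seq.int(top, baseline), col0_px + 1L)
      for (x in seq_len(max(cal_px - 2L, 1L))) draw_ink(top, col0_px + 1L + x)
      draw_ink(seq.int(top, baseline), col0_px + cal_px)
    }
    n_cols <- width_px - cal_px
    ts <- t_start + (seq_len(n_cols) - 1) / (n_cols - 1) * t_dur
    y <- baseline - round(sample_at(sig, ts) * px_per_mv)
    y <- clamp(y, (row - 1) * panel_h_px + 1, row * panel_h_px)
    spans <- trace_spans(y)
    for (i in seq_along(spans)) draw_ink(spans[[i]], col0_px + cal_px + i)
  }

  for (r in seq_len(layout$rows)) {
    for (cc in seq_len(layout$cols)) {
      draw_panel(
        lead = layout$lead_grid[r, cc], row = r,
        col0_px = (cc - 1L) * panel_w_px,
        width_px = panel_w_px,
        t_start = (cc - 1) * layout$panel_duration_s,
        t_dur = layout$panel_duration_s,
        with_cal = layout$calibration && cc == 1L
      )
    }
  }
  if (!is.null(layout$rhythm_lead)) {
    draw_panel(
      lead = layout$rhythm_lead, row = n_rows_total, col0_px = 0L,
      width_px = W,
      t_start = 0,
      t_dur = min(record$duration_s, layout$cols * layout$panel_duration_s),
      with_cal = layout$calibration
    )
  }

  structure(
    list(
      pixels = px,
      signal_mask = mask,
      mm_per_pixel = mpp,
      layout = layout,
      domain_tag = domain_tag,
      provenance = "synthetic",
      record_meta = list(condition = record$condition,
                         heart_rate = record$heart_rate,
                         seed = record$meta$seed)
    ),
    class = "ecg_image"
  )
}

#' @export
print.ecg_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<ecg_image> %d x %d px (%s, %s), %.2f mm/px, %d signal pixels (%.1f%%)\n",
    d[1], d[2], x$domain_tag, x$provenance, x$mm_per_pixel,
    sum(x$signal_mask), 100 * mean(x$signal_mask)
  ))
  invisible(x)
}

new_ecg_image_like <- function(template, pixels, signal_mask = template$signal_mask,
                               provenance = template$provenance) {
  out <- template
  out$pixels <- pixels
  out$signal_mask <- signal_mask
  out$provenance <- provenance
  out
}
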