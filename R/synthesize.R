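#' Supported cardiac condition identifiers
#'
#' The generator produces records whose morphology satisfies the clinical
#' screening rule for each condition: sinus bradycardia (heart rate < 60 bpm),
#' sinus tachycardia (> 100 bpm), atrial fibrillation (absent P waves with an
#' irregularly irregular RR sequence), atrial flutter (a periodic saw-tooth
#' baseline replacing the P wave), an LBBB-like wide-QRS morphology
#' (QRS > 120 ms), and premature ventricular complexes (at least one early,
#' wide beat).
#'
#' @return Character vector of condition ids accepted by
#'   [synthesize_record()].
#' @export
ecg_conditions <- function() {
  c("normal", "sinus_bradycardia", "sinus_tachycardia", "atrial_fibrillation",
    "atrial_flutter", "lbbb_like", "pvc")
}

#' Canonical 12-lead names
#' @return Character vector of the 12 standard lead names.
#' @export
ecg_lead_names <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF", paste0("V", 1:6))
}

# Whole-beat scalar projection onto each lead. Crude but sufficient: the
# generator is a ground-truth harness, not a vectorcardiographic model.
lead_scales <- function() {
  c(I = 0.6, II = 1, III = 0.5, aVR = -0.8, aVL = 0.35, aVF = 0.75,
    V1 = 0.45, V2 = 0.7, V3 = 0.85, V4 = 1, V5 = 0.9, V6 = 0.75)
}

# Gaussian bump components of one beat, offsets in seconds relative to the R
# peak, amplitudes in mV on the reference lead (II).
beat_components <- function(type = c("normal", "wide", "pvc")) {
  type <- match.arg(type)
  switch(type,
    normal = data.frame(
      wave   = c("P", "Q", "R", "S", "T"),
      offset = c(-0.17, -0.030, 0, 0.030, 0.30),
      sd     = c(0.025, 0.008, 0.012, 0.008, 0.055),
      amp    = c(0.15, -0.10, 1.10, -0.25, 0.30)
    ),
    # wide, notched QRS (LBBB-like): broad R with a delayed R' and deep S
    wide = data.frame(
      wave   = c("P", "Q", "R", "R2", "S", "T"),
      offset = c(-0.21, -0.065, -0.01, 0.055, 0.095, 0.36),
      sd     = c(0.025, 0.018, 0.030, 0.025, 0.018, 0.060),
      amp    = c(0.13, -0.08, 0.95, 0.65, -0.35, -0.25)
    ),
    # premature ventricular beat: no P, broad bizarre QRS, discordant T
    pvc = data.frame(
      wave   = c("R", "S", "T"),
      offset = c(0, 0.075, 0.33),
      sd     = c(0.040, 0.030, 0.060),
      amp    = c(1.45, -0.55, -0.45)
    )
  )
}

# 3-sigma fiducial extents of a beat, in seconds relative to the R peak.
beat_fiducials <- function(comp) {
  qrs <- comp[comp$wave %in% c("Q", "R", "R2", "S"), ]
  tw <- comp[comp$wave == "T", ]
  p <- comp[comp$wave == "P", ]
  list(
    p_onset = if (nrow(p)) p$offset - 3 * p$sd else NA_real_,
    qrs_onset = min(qrs$offset - 3 * qrs$sd),
    qrs_offset = max(qrs$offset + 3 * qrs$sd),
    t_offset = if (nrow(tw)) tw$offset + 3 * tw$sd else max(qrs$offset + 3 * qrs$sd)
  )
}

#' Synthesize a 12-lead ECG record with known ground truth
#'
#' Builds each beat as a sum of Gaussian bumps (P, QRS, T) on a per-condition
#' parameter table, schedules beats from a condition-specific RR model, and
#' projects the reference waveform onto the 12 standard leads by scalar
#' weights. Every stochastic choice flows through `seed`, so identical
#' arguments give bit-identical records.
#'
#' @param condition One of [ecg_conditions()].
#' @param duration_s Record duration in seconds (>= 2.5; default 10, the
#'   length of a standard rhythm strip).
#' @param seed Integer seed controlling all randomness for this record.
#' @param sampling_rate Samples per second per lead (default 250).
#' @return An object of class `ecg_record`: a list with `leads` (tibble of
#'   `lead`, `samples`), `sampling_rate`, `duration_s`, `condition`,
#'   `heart_rate` (bpm, from the median RR interval), `beat_annotations`
#'   (tibble of per-beat fiducial sample indices), and `meta` (generator
#'   parameters such as the flutter rate and RR coefficient of variation).
#' @examples
#' rec <- synthesize_record("sinus_bradycardia", duration_s = 10, seed = 1)
#' rec$heart_rate # < 60
#' @export
synthesize_record <- function(condition, duration_s = 10, seed = 1,
                              sampling_rate = 250) {
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% ecg_conditions()) {
    abort(sprintf(
      "Unknown condition '%s'. Supported conditions: %s.",
      as.character(condition)[1], paste(ecg_conditions(), collapse = ", ")
    ))
  }
  if (!is.numeric(duration_s) || duration_s < 2.5) {
    abort("`duration_s` must be at least 2.5 seconds.")
  }
  with_seed(seed, {
    fs <- sampling_rate
    n <- round(duration_s * fs) + 1L
    t <- (seq_len(n) - 1L) / fs

    # --- RR schedule -------------------------------------------------------
    flutter_freq <- NA_real_
    rr_sigma <- 0.008 # mild physiological jitter for regular rhythms
    base_rr <- switch(condition,
      normal = 60 / runif(1, 65, 95),
      sinus_bradycardia = 60 / runif(1, 42, 56),
      sinus_tachycardia = 60 / runif(1, 106, 140),
      atrial_fibrillation = 60 / runif(1, 70, 110),
      atrial_flutter = {
        flutter_freq <- 300 / 60 # 300 flutter waves per minute
        conduction <- sample(c(3, 4), 1)
        conduction / flutter_freq
      },
      lbbb_like = 60 / runif(1, 62, 95),
      pvc = 60 / runif(1, 62, 95)
    )
    # the capture window starts at an arbitrary phase of the cardiac cycle
    # (0.3 s margin keeps the first beat's P wave inside the record)
    onset <- runif(1, 0.3, 0.3 + base_rr)
    n_beats_max <- ceiling(duration_s / base_rr) + 4L
    rr <- if (condition == "atrial_fibrillation") {
      base_rr * exp(rnorm(n_beats_max, 0, 0.25))
    } else if (condition == "atrial_flutter") {
      rep(base_rr, n_beats_max) # locked to the atrial rate
    } else {
      pmax(0.25, base_rr + rnorm(n_beats_max, 0, rr_sigma))
    }
    r_times <- onset + cumsum(c(0, rr))
    r_times <- r_times[r_times < duration_s - 0.35]

    beat_type <- rep(ifelse(condition == "lbbb_like", "wide", "normal"),
                     length(r_times))
    if (condition == "pvc" && length(r_times) >= 4L) {
      n_pvc <- sample(1:2, 1)
      idx <- sort(sample(2:(length(r_times) - 1L), n_pvc))
      beat_type[idx] <- "pvc"
      # premature coupling: the ectopic beat fires early; the following sinus
      # beat stays on the original grid (full compensatory pause)
      r_times[idx] <- r_times[idx - 1L] + 0.55 * base_rr
    }

    # --- reference-lead waveform ------------------------------------------
    ref <- numeric(n)
    ann <- vector("list", length(r_times))
    for (b in seq_along(r_times)) {
      comp <- beat_components(beat_type[b])
      if (condition %in% c("atrial_fibrillation", "atrial_flutter")) {
        comp <- comp[comp$wave != "P", , drop = FALSE]
      }
      # in flutter the T wave is obscured by the continuous atrial activity;
      # drop it so the inter-QRS baseline carries the saw-tooth alone
      if (condition == "atrial_flutter") {
        comp <- comp[comp$wave != "T", , drop = FALSE]
      }
      ctr <- r_times[b]
      win <- which(t >= ctr - 0.45 & t <= ctr + 0.60)
      for (k in seq_len(nrow(comp))) {
        ref[win] <- ref[win] +
          comp$amp[k] * exp(-((t[win] - ctr - comp$offset[k])^2) /
                              (2 * comp$sd[k]^2))
      }
      fid <- beat_fiducials(comp)
      to_sample <- function(off) {
        if (is.na(off)) return(NA_integer_)
        s <- round((ctr + off) * fs) + 1L
        if (s < 1L || s > n) NA_integer_ else as.integer(s)
      }
      ann[[b]] <- tibble(
        beat = b, type = beat_type[b],
        r_sample = to_sample(0),
        p_onset = to_sample(fid$p_onset),
        qrs_onset = to_sample(fid$qrs_onset),
        qrs_offset = to_sample(fid$qrs_offset),
        t_offset = to_sample(fid$t_offset),
        qrs_width_ms = (fid$qrs_offset - fid$qrs_onset) * 1000,
        premature = FALSE
      )
    }
    annotations <- dplyr::bind_rows(ann)
    if (nrow(annotations) > 2L) {
      rr_obs <- diff(annotations$r_sample) / fs
      annotations$premature <-
        c(FALSE, rr_obs < 0.85 * median(rr_obs, na.rm = TRUE))
    }

    # --- atrial baseline activity -----------------------------------------
    atrial <- numeric(n)
    if (condition == "atrial_fibrillation") {
      # low-amplitude irregular fibrillatory undulation (4-9 Hz mixture)
      for (f in runif(4, 4, 9)) {
        atrial <- atrial + runif(1, 0.01, 0.03) *
          sin(2 * pi * f * t + runif(1, 0, 2 * pi))
      }
    } else if (condition == "atrial_flutter") {
      # continuous saw-tooth at the atrial rate, replacing the P wave:
      # a descending ramp with a sharp reset each atrial cycle, +/- 0.2 mV
      phase <- (t * flutter_freq) %% 1
      atrial <- 0.20 * (1 - 2 * phase)
    }

    scales <- lead_scales()
    # leads where atrial activity is most visible (inferior + V1)
    atrial_vis <- c(I = 0.3, II = 1, III = 0.9, aVR = -0.6, aVL = 0.2,
                    aVF = 0.95, V1 = 0.8, V2 = 0.4, V3 = 0.3, V4 = 0.25,
                    V5 = 0.25, V6 = 0.25)
    leads <- tibble(
      lead = ecg_lead_names(),
      samples = purrr::map(ecg_lead_names(), function(l) {
        scales[[l]] * ref + atrial_vis[[l]] * atrial
      })
    )

    rr_obs <- diff(annotations$r_sample) / fs
    heart_rate <- 60 / median(rr_obs)
    structure(
      list(
        leads = leads,
        sampling_rate = fs,
        duration_s = duration_s,
        condition = condition,
        condition_labels = condition,
        heart_rate = heart_rate,
        beat_annotations = annotations,
        meta = list(
          seed = seed,
          flutter_freq_hz = flutter_freq,
          rr_cv = sd(rr_obs) / mean(rr_obs),
          base_rr_s = base_rr
        )
      ),
      class = "ecg_record"
    )
  })
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf(
    "<ecg_record> %s: %.0f s x 12 leads @ %d Hz, heart rate %.1f bpm, %d beats\n",
    x$condition, x$duration_s, x$sampling_rate, x$heart_rate,
    nrow(x$beat_annotations)
  ))
  invisible(x)
}

#' Check a record against its condition's morphological rule
#'
#' Applies the screening rule the generator promises for each condition:
#' bradycardia (heart rate < 60 bpm), tachycardia (> 100), atrial fibrillation
#' (no P annotations and RR coefficient of variation above `af_cv_floor`),
#' atrial flutter (dominant baseline oscillation at the atrial rate in the
#' longest QRS-free gap of lead II), LBBB-like (median QRS width > 120 ms),
#' PVC (at least one premature beat wider than 120 ms), and normal sinus
#' rhythm (rate 60-100, narrow QRS, P present). All checks are computed from
#' the signal and `beat_annotations`, not from stored flags.
#'
#' @param record An `ecg_record`.
#' @param af_cv_floor Minimum RR coefficient of variation that counts as
#'   "irregularly irregular" (default 0.1).
#' @return A one-row tibble with `condition`, `satisfied`, and a `detail`
#'   string of the measured quantities.
#' @export
check_condition_rule <- function(record, af_cv_floor = 0.1) {
  ann <- record$beat_annotations
  hr <- record$heart_rate
  rr <- diff(ann$r_sample) / record$sampling_rate
  cv <- sd(rr) / mean(rr)
  qrs_ms <- ann$qrs_width_ms
  ok <- switch(record$condition,
    normal = hr > 60 && hr < 100 && median(qrs_ms) <= 120 &&
      all(!is.na(ann$p_onset[ann$type == "normal"])),
    sinus_bradycardia = hr < 60,
    sinus_tachycardia = hr > 100,
    atrial_fibrillation = all(is.na(ann$p_onset)) && cv > af_cv_floor,
    atrial_flutter = all(is.na(ann$p_onset)) &&
      flutter_baseline_detected(record),
    lbbb_like = median(qrs_ms) > 120,
    pvc = any(ann$premature & qrs_ms > 120)
  )
  tibble(
    condition = record$condition,
    satisfied = isTRUE(ok),
    detail = sprintf("hr=%.1f bpm, rr_cv=%.3f, median_qrs=%.0f ms",
                     hr, cv, median(qrs_ms))
  )
}

# Detect a periodic saw-tooth baseline: take the longest gap of lead II lying
# strictly between QRS complexes (edges trimmed to drop QRS tails), remove a
# linear trend, and require the dominant periodogram frequency — evaluated on
# a fine grid, free of FFT bin quantization — to sit near the atrial rate.
flutter_baseline_detected <- function(record, rate_hz = 5, tol_hz = 1) {
  fs <- record$sampling_rate
  x <- record$leads$samples[[which(record$leads$lead == "II")]]
  ann <- record$beat_annotations
  trim <- round(0.05 * fs)
  lo <- ann$t_offset + trim
  hi <- dplyr::lead(ann$qrs_onset) - trim
  gaps <- which(!is.na(lo) & !is.na(hi) & hi - lo > 0.3 * fs)
  if (!length(gaps)) return(FALSE)
  g <- gaps[which.max(hi[gaps] - lo[gaps])]
  seg <- x[lo[g]:hi[g]]
  tt <- seq_along(seg) / fs
  seg <- stats::resid(stats::lm(seg ~ tt))
  freqs <- seq(1.5, 12, by = 0.25)
  power <- vapply(freqs, function(f) {
    sum(seg * sin(2 * pi * f * tt))^2 + sum(seg * cos(2 * pi * f * tt))^2
  }, numeric(1))
  abs(freqs[which.max(power)] - rate_hz) <= tol_hz
}

#' @rdname tidiers
#' @export
tidy.ecg_record <- function(x, ...) {
  fs <- x$sampling_rate
  tidyr::unnest(
    dplyr::mutate(
      x$leads,
      time_s = purrr::map(.data$samples, ~ (seq_along(.x) - 1) / fs)
    ),
    c("samples", "time_s")
  ) |>
    dplyr::transmute(
      lead = factor(.data$lead, levels = ecg_lead_names()),
      time_s = .data$time_s, mv = .data$samples
    )
}
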