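# Event pipeline: raw detected-signal streams + patient context -> sized,
# phase-labelled bubbles and per-patient summaries.

#' Patient monitoring record
#'
#' Patient context needed to size a bilateral TCD event stream: per-side MCA
#' diameters, the intra-operative haematocrit sampling series (drawn every
#' ~3 minutes on bypass), an optional blood-pressure trace, and probe
#' signal-loss intervals.
#'
#' @param id Patient label.
#' @param mca_diameter_left,mca_diameter_right MCA diameters in mm, in
#'   (1, 6).
#' @param procedure Procedure label (e.g. `"CABG"`, `"MVR"`, `"AVR"`,
#'   `"combined"`).
#' @param haematocrit_samples Data frame (`time_s`, `fraction`), time-sorted,
#'   fractions in (0.1, 0.6).
#' @param bp_trace Optional data frame (`time_s`, `mmhg`).
#' @param signal_loss_left,signal_loss_right Optional two-column matrices or
#'   data frames of (start, end) times in s.
#' @param monitoring_duration Total monitored time in s.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(id, mca_diameter_left, mca_diameter_right,
                           procedure = "CABG",
                           haematocrit_samples,
                           bp_trace = NULL,
                           signal_loss_left = NULL,
                           signal_loss_right = NULL,
                           monitoring_duration = NULL) {
  stopifnot(
    "MCA diameters must lie in (1, 6) mm" =
      mca_diameter_left > 1 && mca_diameter_left < 6 &&
      mca_diameter_right > 1 && mca_diameter_right < 6,
    "haematocrit_samples needs time_s and fraction columns" =
      all(c("time_s", "fraction") %in% names(haematocrit_samples)),
    "haematocrit samples must be time-sorted" =
      !is.unsorted(haematocrit_samples$time_s),
    "haematocrit values must lie in (0.1, 0.6)" =
      all(haematocrit_samples$fraction > 0.1 &
            haematocrit_samples$fraction < 0.6)
  )
  structure(
    list(id = id,
         mca_diameter_left = mca_diameter_left,
         mca_diameter_right = mca_diameter_right,
         procedure = procedure,
         haematocrit_samples = haematocrit_samples,
         bp_trace = bp_trace,
         signal_loss_left = signal_loss_left,
         signal_loss_right = signal_loss_right,
         monitoring_duration = monitoring_duration),
    class = "patient_record"
  )
}

#' Surgical timeline of ordered, contiguous stages
#'
#' @param stages Data frame with columns `label`, `start_s`, `end_s`;
#'   stages must be ordered, non-overlapping and contiguous.
#' @return An object of class `surgical_timeline`.
#' @export
surgical_timeline <- function(stages) {
  stopifnot(all(c("label", "start_s", "end_s") %in% names(stages)))
  if (nrow(stages) > 1) {
    if (any(stages$start_s[-1] != stages$end_s[-nrow(stages)])) {
      stop("stages must be contiguous and ordered", call. = FALSE)
    }
  }
  if (any(stages$end_s <= stages$start_s)) {
    stop("each stage must have end_s > start_s", call. = FALSE)
  }
  structure(list(stages = stages), class = "surgical_timeline")
}

# stage label at time t (NA outside the timeline)
.stage_at <- function(timeline, t) {
  st <- timeline$stages
  idx <- findInterval(t, st$start_s)
  lab <- rep(NA_character_, length(t))
  ok <- idx >= 1 & t <= st$end_s[pmax(idx, 1)]
  lab[ok] <- st$label[idx[ok]]
  lab
}

#' Filter detected signals by the embolic detection threshold
#'
#' Retains candidate signals whose MEBR meets or exceeds the detection
#' threshold (default 7 dB above background), preserving order. Input must
#' be time-sorted.
#'
#' @param candidates Data frame with columns `time_s`, `side`, `mebr_db`
#'   (extra columns pass through).
#' @param threshold Detection threshold in dB (default 7).
#' @return The retained rows, with class `embolic_events`.
#' @export
filter_detections <- function(candidates, threshold = 7) {
  stopifnot(all(c("time_s", "side", "mebr_db") %in% names(candidates)))
  if (is.unsorted(candidates$time_s)) {
    stop("candidates must be sorted by time_s", call. = FALSE)
  }
  if (any(!is.finite(candidates$mebr_db))) {
    stop("mebr_db must be finite", call. = FALSE)
  }
  out <- candidates[candidates$mebr_db >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("embolic_events", "data.frame")
  out
}

#' Detect embolic showers and set the background policy
#'
#' Marks contiguous runs of events whose rate exceeds 5 emboli/s in any
#' sliding 1 s window as showers (a window must contain at least 6 events).
#' Every event inside a shower is assigned the background reference time
#' just prior to shower onset, mirroring the practice of measuring one
#' pre-shower background for all emboli in a shower.
#'
#' @param events Time-sorted event data frame (`time_s`, ...).
#' @param rate_threshold Events per second above which a window is a shower
#'   (default 5; exceeded strictly).
#' @param window Window length in s (default 1).
#' @return `events` with added columns `shower_id` (NA outside showers) and
#'   `background_t` (the pre-shower background time for shower members,
#'   otherwise the event's own time).
#' @export
detect_showers <- function(events, rate_threshold = 5, window = 1) {
  if (is.unsorted(events$time_s)) {
    stop("events must be sorted by time_s", call. = FALSE)
  }
  n <- nrow(events)
  events$shower_id <- NA_integer_
  events$background_t <- events$time_s
  if (n == 0) return(events)
  t <- events$time_s
  need <- floor(rate_threshold * window) + 1 # > threshold, so >= 6 events
  in_shower <- logical(n)
  if (n >= need) {
    # event i starts a dense window if events i..i+need-1 span < window
    span_ok <- t[seq_len(n - need + 1) + need - 1] -
      t[seq_len(n - need + 1)] < window
    for (i in which(span_ok)) in_shower[i:(i + need - 1)] <- TRUE
  }
  # contiguous shower runs, split where the stream pauses for >= one window
  r <- rle(in_shower)
  id <- 0L
  pos <- 1L
  for (j in seq_along(r$lengths)) {
    len <- r$lengths[j]
    if (r$values[j]) {
      idx <- pos:(pos + len - 1)
      gap <- c(FALSE, diff(t[idx]) >= window)
      sub <- cumsum(gap)
      for (k in unique(sub)) {
        id <- id + 1L
        members <- idx[sub == k]
        events$shower_id[members] <- id
        events$background_t[members] <- t[members[1]] - window / 2
      }
    }
    pos <- pos + len
  }
  events
}

# merge possibly overlapping intervals given as a 2-column structure
.merge_intervals <- function(iv) {
  if (is.null(iv) || NROW(iv) == 0) return(matrix(numeric(0), ncol = 2))
  m <- as.matrix(iv)[, 1:2, drop = FALSE]
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
    } else {
      out <- rbind(out, m[i, ])
    }
  }
  out
}

#' Flag events inside curtain intervals
#'
#' Curtains are embolic showers so dense that individual signals cannot be
#' separated; only their durations are analysable. Events falling inside a
#' curtain interval are flagged (`curtain_member = TRUE`) and must be
#' excluded from sizing and simulation. Overlapping intervals are merged.
#'
#' @param events Event data frame (`time_s`, ...).
#' @param curtain_intervals Two-column matrix/data frame of (start, end) s,
#'   or NULL.
#' @return A list with `events` (flagged) and `curtain_duration` (total
#'   merged curtain time in s).
#' @export
mark_curtains <- function(events, curtain_intervals = NULL) {
  iv <- .merge_intervals(curtain_intervals)
  events$curtain_member <- FALSE
  if (nrow(iv) > 0 && nrow(events) > 0) {
    for (i in seq_len(nrow(iv))) {
      events$curtain_member <- events$curtain_member |
        (events$time_s >= iv[i, 1] & events$time_s <= iv[i, 2])
    }
  }
  list(events = events,
       curtain_duration = if (nrow(iv) > 0) sum(iv[, 2] - iv[, 1]) else 0)
}

#' Haematocrit at a given time
#'
#' Last-observation-carried-forward over the patient's haematocrit sampling
#' series; times before the first sample take the first value.
#'
#' @param patient A [patient_record()].
#' @param t Time(s) in s.
#' @return Haematocrit fraction(s).
#' @export
haematocrit_at <- function(patient, t) {
  hs <- patient$haematocrit_samples
  if (nrow(hs) == 0) stop("patient has no haematocrit samples", call. = FALSE)
  idx <- findInterval(t, hs$time_s)
  hs$fraction[pmax(idx, 1)]
}

#' Size a filtered event stream for one side
#'
#' For each event, builds an [acoustic_context()] from that side's MCA
#' diameter and the haematocrit at the event time, then inverts the MEBR to
#' a bubble diameter. Per-event acoustics failures are flagged, never
#' propagated (an intra-operative stream must not abort on one bad record).
#' Curtain-flagged events are excluded.
#'
#' @param events Filtered event data frame (`time_s`, `side`, `mebr_db`,
#'   optional `curtain_member`, `phase`).
#' @param patient A [patient_record()].
#' @param side `"left"` or `"right"`.
#' @param frequency Insonation frequency in Hz (default 2 MHz).
#' @return A data frame: the events of that side joined with the sized
#'   bubble columns (`diameter_um`, `rel_uncertainty`, `volume_ml`, `flag`).
#' @export
size_stream <- function(events, patient, side = c("left", "right"),
                        frequency = 2e6) {
  side <- match.arg(side)
  keep <- events$side == side
  if (!is.null(events$curtain_member)) keep <- keep & !events$curtain_member
  ev <- events[keep, , drop = FALSE]
  mca <- if (side == "left") patient$mca_diameter_left else
    patient$mca_diameter_right
  n <- nrow(ev)
  res <- data.frame(diameter_um = rep(NA_real_, n),
                    rel_uncertainty = NA_real_,
                    volume_ml = NA_real_,
                    flag = rep("error", n),
                    stringsAsFactors = FALSE)
  if (n > 0) {
    hct <- haematocrit_at(patient, ev$time_s)
    # events sharing a haematocrit value share an acoustic context
    for (h in unique(hct)) {
      rows <- which(hct == h)
      sized <- tryCatch({
        ctx <- acoustic_context(transmit_frequency = frequency,
                                vessel_diameter = mca, haematocrit = h)
        invert_mebr(ev$mebr_db[rows], ctx)
      }, error = function(e) NULL)
      if (!is.null(sized)) {
        res$diameter_um[rows] <- sized$diameter_um
        res$rel_uncertainty[rows] <- sized$rel_uncertainty
        res$volume_ml[rows] <- sized$volume_ml
        res$flag[rows] <- sized$flag
      }
    }
  }
  out <- cbind(ev, res)
  rownames(out) <- NULL
  out
}

#' Summarise a patient's sized streams
#'
#' Aggregates both sides into per-patient totals in the style of a cohort
#' summary table: event counts per side, total air volume, per-stage median
#' diameters, curtain and signal-loss durations, and (when supplied) the
#' peak and time-averaged percentage of affected arterioles from simulation
#' (the peak is the headline "affected arterioles" figure; the time average
#' summarises the whole monitored interval).
#'
#' @param sized_left,sized_right Sized streams from [size_stream()].
#' @param patient A [patient_record()].
#' @param timeline Optional [surgical_timeline()] for per-stage medians.
#' @param obstruction_left,obstruction_right Optional obstruction series
#'   (from [run_simulation()] or [run_ensemble()]).
#' @param curtain_duration_left,curtain_duration_right Curtain durations, s.
#' @return A list of class `patient_summary`.
#' @export
summarize_patient <- function(sized_left, sized_right, patient,
                              timeline = NULL,
                              obstruction_left = NULL,
                              obstruction_right = NULL,
                              curtain_duration_left = 0,
                              curtain_duration_right = 0) {
  loss_min <- function(iv) {
    m <- .merge_intervals(iv)
    if (nrow(m) == 0) 0 else sum(m[, 2] - m[, 1]) / 60
  }
  phase_medians <- NULL
  if (!is.null(timeline)) {
    all_sized <- rbind(sized_left, sized_right)
    if (nrow(all_sized) > 0) {
      stage <- .stage_at(timeline, all_sized$time_s)
      phase_medians <- tapply(all_sized$diameter_um, stage, stats::median)
    }
  }
  peak <- function(obs) {
    if (is.null(obs)) return(NA_real_)
    if (!is.null(obs$mean_pct)) max(obs$mean_pct) else max(obs$pct_unperfused)
  }
  time_avg <- function(obs) {
    if (is.null(obs)) return(NA_real_)
    y <- if (!is.null(obs$mean_pct)) obs$mean_pct else obs$pct_unperfused
    mean(y)
  }
  structure(
    list(
      id = patient$id,
      procedure = patient$procedure,
      n_emboli_left = nrow(sized_left),
      n_emboli_right = nrow(sized_right),
      total_volume_ml = sum(sized_left$volume_ml, na.rm = TRUE) +
        sum(sized_right$volume_ml, na.rm = TRUE),
      curtain_duration_left = curtain_duration_left,
      curtain_duration_right = curtain_duration_right,
      signal_loss_left_min = loss_min(patient$signal_loss_left),
      signal_loss_right_min = loss_min(patient$signal_loss_right),
      phase_medians_um = phase_medians,
      peak_affected_left_pct = peak(obstruction_left),
      peak_affected_right_pct = peak(obstruction_right),
      mean_affected_left_pct = time_avg(obstruction_left),
      mean_affected_right_pct = time_avg(obstruction_right)
    ),
    class = "patient_summary"
  )
}
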