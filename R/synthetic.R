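# Synthetic-surgery generator: stage-structured embolic event streams with
# showers, curtains, haematocrit/BP traces and retained ground truth, plus
# the forward-modelled raw MEBR stream the sizing pipeline consumes.

#' Fit a log-normal from its median and quartiles
#'
#' `meanlog = log(median)`, `sdlog = log(q3/q1) / (2 * qnorm(0.75))`.
#'
#' @param median_um Distribution median.
#' @param q1_um,q3_um Lower and upper quartiles.
#' @return Named list with `meanlog` and `sdlog`.
#' @examples
#' fit_lognormal_quartiles(28, 17, 51) # sdlog ~0.814
#' @export
fit_lognormal_quartiles <- function(median_um, q1_um, q3_um) {
  stopifnot(q1_um > 0, q3_um > q1_um, median_um > 0)
  list(meanlog = log(median_um),
       sdlog = log(q3_um / q1_um) / (2 * stats::qnorm(0.75)))
}

#' Stage specification for the synthetic generator
#'
#' @param label Stage label.
#' @param duration Stage duration in s.
#' @param base_rate Background embolic rate, events/s (both sides combined).
#' @param showers Data frame (`onset_s`, `duration_s`, `rate`, `bilateral`)
#'   of shower bursts; `rate` is per side, `onset_s` is relative to stage
#'   start. NULL for none.
#' @param diameter_median_um,diameter_sdlog Log-normal bubble-diameter law.
#' @param curtain_probability Probability that the stage's heaviest shower
#'   densifies into a curtain (default 0).
#' @return An object of class `stage_spec`.
#' @export
stage_spec <- function(label, duration, base_rate, showers = NULL,
                       diameter_median_um, diameter_sdlog,
                       curtain_probability = 0) {
  stopifnot(
    "duration must be > 0" = duration > 0,
    "base_rate must be >= 0" = base_rate >= 0,
    "diameter_median_um must be > 5" = diameter_median_um > 5,
    "diameter_sdlog must be > 0" = diameter_sdlog > 0,
    "curtain_probability must be in [0, 1]" =
      curtain_probability >= 0 && curtain_probability <= 1
  )
  structure(
    list(label = label, duration = duration, base_rate = base_rate,
         showers = showers, diameter_median_um = diameter_median_um,
         diameter_sdlog = diameter_sdlog,
         curtain_probability = curtain_probability),
    class = "stage_spec"
  )
}

# the two stage diameter laws: bypass bubbles are filtered by the 38-um
# aortic-line filter (median 28 um, IQR 17-51); bubbles after cross-clamp
# removal are unfiltered and larger (median 72 um, IQR 28-202)
.cpb_law <- function() fit_lognormal_quartiles(28, 17, 51)
.post_axc_law <- function() fit_lognormal_quartiles(72, 28, 202)

#' Default synthetic surgical protocols
#'
#' Returns the ordered stage specifications of a synthetic operation. Stage
#' rates are calibrated so that, in expectation, 73% of events occur before
#' aortic cross-clamp removal (drawn from a log-normal with median 28 um
#' fitted to IQR 17-51 um) and 27% after (median 72 um, IQR 28-202 um), with
#' heavy showers at bypass commencement, cross-clamp application/removal and
#' heart restart. Valve and combined protocols produce higher totals than
#' CABG-only, and may densify their post-clamp showers into curtains.
#'
#' @param kind `"CABG"`, `"valve"` or `"combined"`.
#' @return A list of [stage_spec()] objects (classes
#'   `surgical_protocol`, `list`).
#' @export
default_protocol <- function(kind = c("CABG", "valve", "combined")) {
  kind <- match.arg(kind)
  cpb <- .cpb_law()
  post <- .post_axc_law()
  # expected totals: CABG ~900, valve ~2400, combined ~3200 events, all with
  # a 0.73 / 0.27 pre/post cross-clamp-removal split in expectation
  # heavy showers (bypass commencement, cross-clamp removal) run above the
  # 5 emboli/s shower threshold per side; light ones (cross-clamp
  # application, heart restart) below it
  cfg <- switch(kind,
    CABG = list(cpb_base = 0.0858, cpb_sh = data.frame(
                  onset_s = c(0, 1800), duration_s = c(20, 15),
                  rate = c(6, 3), bilateral = TRUE),
                post_base = 0.012, post_sh = data.frame(
                  onset_s = c(0, 300), duration_s = c(15, 15),
                  rate = c(6, 1.5), bilateral = TRUE),
                curtain_p = 0),
    valve = list(cpb_base = 0.343, cpb_sh = data.frame(
                  onset_s = c(0, 1800), duration_s = c(30, 20),
                  rate = c(7, 2), bilateral = TRUE),
                post_base = 0.112, post_sh = data.frame(
                  onset_s = c(0, 300), duration_s = c(25, 20),
                  rate = c(8, 2), bilateral = TRUE),
                curtain_p = 0.4),
    combined = list(cpb_base = 0.505, cpb_sh = data.frame(
                  onset_s = c(0, 1800), duration_s = c(30, 20),
                  rate = c(7, 2), bilateral = TRUE),
                post_base = 0.256, post_sh = data.frame(
                  onset_s = c(0, 300), duration_s = c(25, 20),
                  rate = c(8, 2), bilateral = TRUE),
                curtain_p = 0.5)
  )
  stages <- list(
    stage_spec("pre-CPB", 600, 0.03, NULL,
               28, cpb$sdlog),
    stage_spec("CPB", 3600, cfg$cpb_base, cfg$cpb_sh,
               28, cpb$sdlog),
    stage_spec("post-AxC", 1500, cfg$post_base, cfg$post_sh,
               72, post$sdlog, curtain_probability = cfg$curtain_p)
  )
  structure(stages, class = c("surgical_protocol", "list"), kind = kind)
}

#' Generate a synthetic patient record
#'
#' MCA diameters drawn uniformly from 2.6-3.5 mm per side; haematocrit
#' evolves as a reflected random walk within 0.22-0.37 sampled every 3
#' minutes; blood pressure constant at 100 mmHg.
#'
#' @param id Patient label.
#' @param monitoring_duration Monitored time in s.
#' @param procedure Procedure label.
#' @return A [patient_record()].
#' @export
synthetic_patient <- function(id = "synth-1", monitoring_duration = 5700,
                              procedure = "CABG") {
  t_h <- seq(0, monitoring_duration, by = 180)
  h <- numeric(length(t_h))
  h[1] <- stats::runif(1, 0.26, 0.34)
  for (i in seq_along(h)[-1]) {
    step <- h[i - 1] + stats::rnorm(1, 0, 0.008)
    h[i] <- min(max(step, 0.22), 0.37)
  }
  patient_record(
    id = id,
    mca_diameter_left = stats::runif(1, 2.6, 3.5),
    mca_diameter_right = stats::runif(1, 2.6, 3.5),
    procedure = procedure,
    haematocrit_samples = data.frame(time_s = t_h, fraction = h),
    bp_trace = data.frame(time_s = 0, mmhg = 100),
    monitoring_duration = monitoring_duration
  )
}

#' Sample a synthetic operation
#'
#' Draws the embolic event stream of one operation: per stage, a Poisson
#' background process (split evenly between sides) plus Poisson shower
#' bursts whose onsets are shared between the left and right MCAs (bilateral
#' synchrony) with independent per-side draws. True bubble diameters are
#' drawn from the stage's log-normal, truncated to the physical sizing range
#' `[5 um, MCA diameter]`. A stage's heaviest shower may densify into a
#' curtain, emitted as an interval (its events are removed, as curtain
#' emboli cannot be individually analysed).
#'
#' @param protocol A [default_protocol()] (or list of [stage_spec()]).
#' @param patient A [patient_record()].
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `events` (time-sorted data frame `time_s`, `side`,
#'   `true_diameter_um`, `stage`), `curtains` (data frame `start_s`,
#'   `end_s`), `timeline` (a [surgical_timeline()]), and `ground_truth`
#'   (one row per emitted event, in bijection with `events`).
#' @export
sample_operation <- function(protocol, patient, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t0 <- 0
  ev <- list()
  curtains <- data.frame(start_s = numeric(0), end_s = numeric(0))
  tl <- data.frame(label = character(0), start_s = numeric(0),
                   end_s = numeric(0))
  for (st in protocol) {
    stage_events <- list()
    for (side in c("left", "right")) {
      n <- stats::rpois(1, st$base_rate / 2 * st$duration)
      if (n > 0) {
        stage_events[[side]] <- data.frame(
          time_s = t0 + sort(stats::runif(n, 0, st$duration)),
          side = side, stringsAsFactors = FALSE)
      }
    }
    if (!is.null(st$showers)) {
      for (j in seq_len(nrow(st$showers))) {
        sh <- st$showers[j, ]
        sides <- if (isTRUE(sh$bilateral)) c("left", "right") else
          sample(c("left", "right"), 1)
        for (side in sides) {
          n <- stats::rpois(1, sh$rate * sh$duration_s)
          if (n > 0) {
            stage_events[[paste0(side, "_sh", j)]] <- data.frame(
              time_s = t0 + sh$onset_s +
                sort(stats::runif(n, 0, sh$duration_s)),
              side = side, stringsAsFactors = FALSE)
          }
        }
      }
    }
    se <- do.call(rbind, stage_events)
    if (!is.null(se) && nrow(se) > 0) {
      mca <- ifelse(se$side == "left", patient$mca_diameter_left,
                    patient$mca_diameter_right)
      d <- stats::rlnorm(nrow(se), log(st$diameter_median_um),
                         st$diameter_sdlog)
      se$true_diameter_um <- pmin(pmax(d, 5.01), mca * 1e3)
      se$stage <- st$label
      ev[[st$label]] <- se
    }
    # the heaviest shower may densify into a curtain
    if (st$curtain_probability > 0 && !is.null(st$showers) &&
        stats::runif(1) < st$curtain_probability) {
      k <- which.max(st$showers$rate)
      cs <- t0 + st$showers$onset_s[k]
      ce <- cs + st$showers$duration_s[k] * stats::runif(1, 0.3, 0.7)
      curtains <- rbind(curtains, data.frame(start_s = cs, end_s = ce))
    }
    tl <- rbind(tl, data.frame(label = st$label, start_s = t0,
                               end_s = t0 + st$duration))
    t0 <- t0 + st$duration
  }
  events <- do.call(rbind, ev)
  events <- events[order(events$time_s), , drop = FALSE]
  if (nrow(curtains) > 0) {
    keep <- rep(TRUE, nrow(events))
    for (i in seq_len(nrow(curtains))) {
      keep <- keep & !(events$time_s >= curtains$start_s[i] &
                         events$time_s <= curtains$end_s[i])
    }
    events <- events[keep, , drop = FALSE]
  }
  rownames(events) <- NULL
  events$event_id <- seq_len(nrow(events))
  list(events = events, curtains = curtains,
       timeline = surgical_timeline(tl),
       ground_truth = events)
}

#' Synthesize a raw detected-signal stream from true diameters
#'
#' The inverse of the sizing pipeline: each true diameter is pushed through
#' the acoustic forward model with the patient's side-specific MCA diameter
#' and the haematocrit at the event time, with optional per-event jitter of
#' the Doppler sample length (uniform 8-12 mm) and angle (30 +/- 10
#' degrees), plus additive Gaussian dB noise. Events whose synthetic MEBR
#' falls below the detection threshold are still emitted; the analysis
#' pipeline is expected to filter them.
#'
#' @param events Events from [sample_operation()] (`time_s`, `side`,
#'   `true_diameter_um`).
#' @param patient A [patient_record()].
#' @param noise_sd_db Additive Gaussian MEBR noise, dB (default 1; 0 for a
#'   noise-free round trip).
#' @param jitter Jitter sample length and angle per event (default TRUE).
#' @param frequency Insonation frequency in Hz.
#' @return Data frame `time_s`, `side`, `mebr_db` (plus pass-through
#'   columns), time-sorted: the raw candidate stream.
#' @export
synthesize_stream <- function(events, patient, noise_sd_db = 1,
                              jitter = TRUE, frequency = 2e6) {
  n <- nrow(events)
  mca <- ifelse(events$side == "left", patient$mca_diameter_left,
                patient$mca_diameter_right)
  hct <- haematocrit_at(patient, events$time_s)
  sample_mm <- if (jitter) stats::runif(n, 8, 12) else rep(10, n)
  angle <- if (jitter) stats::runif(n, 20, 40) else rep(30, n)
  d <- pmin(pmax(events$true_diameter_um, 5), mca * 1e3)
  curve <- .sizing_curve(frequency)
  sig_db <- 10 / log(10) * curve$fwd(log(d * 1e-6))
  mebr <- sig_db - .offset_db(hct, mca, sample_mm, angle, frequency)
  if (noise_sd_db > 0) mebr <- mebr + stats::rnorm(n, 0, noise_sd_db)
  out <- events
  out$mebr_db <- mebr
  out[order(out$time_s), , drop = FALSE]
}

#' Sample true diameters from the calibrated two-stage mixture
#'
#' Draws bubble diameters from the mixture that emulates a whole operation:
#' with probability 0.73 from the bypass-stage log-normal (median 28 um,
#' quartile-fitted to IQR 17-51 um) and 0.27 from the post-cross-clamp
#' log-normal (median 72 um, IQR 28-202 um).
#'
#' @param n Number of diameters.
#' @param pre_fraction Mixture weight of the bypass stage (default 0.73).
#' @return Numeric vector of diameters in um.
#' @export
sample_mixture_diameters <- function(n, pre_fraction = 0.73) {
  cpb <- .cpb_law(); post <- .post_axc_law()
  pre <- stats::runif(n) < pre_fraction
  d <- numeric(n)
  d[pre] <- stats::rlnorm(sum(pre), cpb$meanlog, cpb$sdlog)
  d[!pre] <- stats::rlnorm(sum(!pre), post$meanlog, post$sdlog)
  d
}
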