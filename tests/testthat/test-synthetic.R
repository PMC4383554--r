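test_that("log-normal quartile fits match the closed form", {
  cpb <- fit_lognormal_quartiles(28, 17, 51)
  expect_equal(cpb$sdlog, log(51 / 17) / (2 * qnorm(0.75)), tolerance = 1e-12)
  expect_equal(cpb$sdlog, 0.8145, tolerance = 1e-3)
  post <- fit_lognormal_quartiles(72, 28, 202)
  expect_equal(post$sdlog, 1.465, tolerance = 1e-3)
  expect_equal(exp(post$meanlog), 72)
})

test_that("protocols put 73% of expected events before cross-clamp removal", {
  for (kind in c("CABG", "valve", "combined")) {
    proto <- default_protocol(kind)
    exp_stage <- vapply(proto, function(st) {
      base <- st$base_rate * st$duration
      sh <- if (!is.null(st$showers)) {
        sum(st$showers$rate * st$showers$duration_s *
              ifelse(st$showers$bilateral, 2, 1))
      } else 0
      base + sh
    }, numeric(1))
    labels <- vapply(proto, function(st) st$label, character(1))
    pre <- sum(exp_stage[labels != "post-AxC"])
    expect_equal(pre / sum(exp_stage), 0.73, tolerance = 0.005)
  }
  # intra-cardiac procedures produce more emboli than CABG-only
  tot <- function(kind) {
    sum(vapply(default_protocol(kind), function(st) {
      st$base_rate * st$duration +
        if (is.null(st$showers)) 0 else
          sum(st$showers$rate * st$showers$duration_s * 2)
    }, numeric(1)))
  }
  expect_gt(tot("valve"), tot("CABG"))
  expect_gt(tot("combined"), tot("valve"))
})

test_that("sampled operations are seed-reproducible with bilateral showers", {
  proto <- default_protocol("valve")
  set.seed(99)
  patient <- synthetic_patient("p1", procedure = "MVR")
  op1 <- sample_operation(proto, patient, seed = 5)
  op2 <- sample_operation(proto, patient, seed = 5)
  expect_identical(op1$events, op2$events)
  # ground truth and emitted events are in bijection
  expect_identical(op1$events$event_id, seq_len(nrow(op1$events)))
  expect_identical(op1$ground_truth, op1$events)
  # heavy showers land on both sides at the shared onset
  cpb_start <- op1$timeline$stages$start_s[2]
  early <- op1$events[op1$events$time_s >= cpb_start &
                        op1$events$time_s <= cpb_start + 30, ]
  expect_true(all(c("left", "right") %in% early$side))
  expect_gt(nrow(early), 100) # ~7/s/side for 30 s plus background
})

test_that("the event stream realises the calibrated stage structure", {
  # CABG protocol: no curtains, so the emitted stream keeps the calibrated
  # pre/post split (curtains censor post-clamp events by design)
  proto <- default_protocol("CABG")
  set.seed(1)
  patient <- synthetic_patient("p2", procedure = "CABG")
  op <- sample_operation(proto, patient, seed = 11)
  frac_pre <- mean(op$events$stage != "post-AxC")
  expect_lt(abs(frac_pre - 0.73), 0.05)
  # totals land in the plausible per-operation range (hundreds to thousands)
  expect_gt(nrow(op$events), 371)
  expect_lt(nrow(op$events), 6476)
  med <- tapply(op$events$true_diameter_um, op$events$stage, median)
  expect_lt(abs(med[["CPB"]] / 28 - 1), 0.15)
  expect_lt(abs(med[["post-AxC"]] / 72 - 1), 0.3)
})

test_that("valve curtains are emitted as intervals, not events", {
  proto <- default_protocol("valve")
  patient <- synthetic_patient("p3", procedure = "MVR")
  found <- FALSE
  for (seed in 1:10) {
    op <- sample_operation(proto, patient, seed = seed)
    if (nrow(op$curtains) > 0) {
      found <- TRUE
      for (i in seq_len(nrow(op$curtains))) {
        expect_false(any(op$events$time_s >= op$curtains$start_s[i] &
                           op$events$time_s <= op$curtains$end_s[i]))
      }
    }
  }
  expect_true(found)
})

test_that("synthetic patients stay inside the physiological ranges", {
  set.seed(4)
  for (i in 1:5) {
    p <- synthetic_patient()
    expect_true(p$mca_diameter_left >= 2.6 && p$mca_diameter_left <= 3.5)
    expect_true(p$mca_diameter_right >= 2.6 && p$mca_diameter_right <= 3.5)
    h <- p$haematocrit_samples$fraction
    expect_true(all(h >= 0.22 & h <= 0.37))
    expect_equal(diff(p$haematocrit_samples$time_s),
                 rep(180, length(h) - 1))
  }
})

test_that("recovered stage medians converge to the generator's targets", {
  # generator/analyser consistency at n = 10,000 under noise-free synthesis
  patient <- fixture_patient(hct = 0.30, mca_left = 3.0, mca_right = 3.0)
  set.seed(12)
  n <- 10000
  stage <- ifelse(runif(n) < 0.73, "CPB", "post-AxC")
  law <- list(CPB = fit_lognormal_quartiles(28, 17, 51),
              `post-AxC` = fit_lognormal_quartiles(72, 28, 202))
  d <- vapply(stage, function(s) {
    rlnorm(1, law[[s]]$meanlog, law[[s]]$sdlog)
  }, numeric(1))
  ev <- data.frame(time_s = seq_len(n), side = "left",
                   true_diameter_um = pmin(pmax(d, 5.01), 2999),
                   stage = stage)
  raw <- synthesize_stream(ev, patient, noise_sd_db = 0, jitter = FALSE)
  sized <- size_stream(raw, patient, "left")
  med <- tapply(sized$diameter_um, sized$stage, median)
  expect_lt(abs(med[["CPB"]] / 28 - 1), 0.10)
  expect_lt(abs(med[["post-AxC"]] / 72 - 1), 0.10)
})
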