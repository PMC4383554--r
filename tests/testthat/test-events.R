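test_that("detection filtering keeps the 7 dB threshold inclusive", {
  cand <- data.frame(time_s = c(1, 2, 3), side = "left",
                     mebr_db = c(6.9, 7.0, 12.0))
  kept <- filter_detections(cand)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$mebr_db, c(7.0, 12.0))
  # idempotent and empty-safe
  expect_equal(nrow(filter_detections(kept)), 2)
  expect_equal(nrow(filter_detections(cand[0, ])), 0)
  many <- data.frame(time_s = 1:100, side = "right", mebr_db = 20)
  expect_equal(nrow(filter_detections(many)), 100)
  expect_error(filter_detections(data.frame(time_s = c(2, 1), side = "l",
                                            mebr_db = c(9, 9))), "sorted")
})

test_that("shower detection marks dense windows and splits separated bursts", {
  burst <- data.frame(time_s = seq(0, 0.9, by = 0.1), side = "left",
                      mebr_db = 10)
  s1 <- detect_showers(burst)
  expect_true(all(!is.na(s1$shower_id)))
  expect_equal(length(unique(s1$shower_id)), 1)
  # all members share the pre-onset background reference
  expect_true(all(s1$background_t == s1$background_t[1]))
  expect_lt(s1$background_t[1], s1$time_s[1])

  sparse <- data.frame(time_s = 0:19, side = "left", mebr_db = 10)
  expect_true(all(is.na(detect_showers(sparse)$shower_id)))

  two <- data.frame(time_s = c(seq(0, 0.9, 0.1), seq(11, 11.9, 0.1)),
                    side = "left", mebr_db = 10)
  s2 <- detect_showers(two)
  expect_equal(sort(unique(stats::na.omit(s2$shower_id))), c(1, 2))
})

test_that("curtain intervals merge, flag and sum per the duration rule", {
  ev <- data.frame(time_s = c(3, 50, 103), side = "left", mebr_db = 10)
  mc <- mark_curtains(ev, rbind(c(0, 7), c(100, 107)))
  expect_equal(mc$curtain_duration, 14)
  expect_equal(mc$events$curtain_member, c(TRUE, FALSE, TRUE))
  expect_equal(mark_curtains(ev, NULL)$curtain_duration, 0)
  # overlapping intervals merge rather than double-count
  expect_equal(mark_curtains(ev, rbind(c(0, 10), c(5, 20)))$curtain_duration,
               20)
})

test_that("haematocrit lookup is last-observation-carried-forward", {
  p <- patient_record("p", 3, 3, "CABG",
                      data.frame(time_s = c(0, 180),
                                 fraction = c(0.30, 0.28)))
  expect_equal(haematocrit_at(p, 90), 0.30)
  expect_equal(haematocrit_at(p, -1), 0.30)
  expect_equal(haematocrit_at(p, 180), 0.28)
  expect_equal(haematocrit_at(p, 1e6), 0.28)
})

test_that("a noise-free synthetic stream round-trips through sizing", {
  patient <- fixture_patient(hct = 0.28, mca_left = 3.1, mca_right = 2.7)
  set.seed(42)
  n <- 400
  ev <- data.frame(
    time_s = sort(runif(n, 0, 3000)),
    side = sample(c("left", "right"), n, replace = TRUE),
    true_diameter_um = exp(runif(n, log(8), log(2000)))
  )
  raw <- synthesize_stream(ev, patient, noise_sd_db = 0, jitter = FALSE)
  sized <- rbind(size_stream(raw, patient, "left"),
                 size_stream(raw, patient, "right"))
  err <- abs(sized$diameter_um / sized$true_diameter_um - 1)
  expect_lt(stats::median(err), 0.001)
  expect_true(all(sized$diameter_um >= 5 &
                    sized$diameter_um <= 3.1 * 1e3 + 1e-6))
})

test_that("haematocrit mis-specification biases all sizes one way", {
  truth <- fixture_patient(hct = 0.30)
  wrong <- fixture_patient(hct = 0.37)
  set.seed(7)
  ev <- data.frame(time_s = 1:50, side = "left",
                   true_diameter_um = exp(runif(50, log(15), log(300))))
  raw <- synthesize_stream(ev, truth, noise_sd_db = 0, jitter = FALSE)
  sized <- size_stream(raw, wrong, "left")
  shift <- sized$diameter_um - ev$true_diameter_um
  expect_true(all(shift < 0) || all(shift > 0))
})

test_that("curtain-flagged events never reach the sized output", {
  patient <- fixture_patient()
  ev <- data.frame(time_s = c(1, 2, 3), side = "left", mebr_db = c(15, 15, 15))
  mc <- mark_curtains(ev, rbind(c(1.5, 2.5)))
  sized <- size_stream(mc$events, patient, "left")
  expect_equal(nrow(sized), 2)
  expect_false(any(sized$curtain_member))
})

test_that("patient summary aggregates counts, volume and stage medians", {
  patient <- fixture_patient()
  tl <- surgical_timeline(data.frame(
    label = c("CPB", "post-AxC"), start_s = c(0, 100), end_s = c(100, 200)))
  sl <- data.frame(time_s = c(10, 20), side = "left", mebr_db = 15,
                   diameter_um = c(1000, 30), volume_ml = volume_of(c(1000, 30)),
                   flag = "ok")
  sr <- data.frame(time_s = 150, side = "right", mebr_db = 15,
                   diameter_um = 80, volume_ml = volume_of(80), flag = "ok")
  ps <- summarize_patient(sl, sr, patient, timeline = tl,
                          curtain_duration_left = 7,
                          curtain_duration_right = 7)
  expect_equal(ps$n_emboli_left, 2)
  expect_equal(ps$n_emboli_right, 1)
  expect_equal(ps$total_volume_ml, sum(volume_of(c(1000, 30, 80))))
  expect_equal(unname(ps$phase_medians_um["CPB"]), 515)
  expect_equal(unname(ps$phase_medians_um["post-AxC"]), 80)
  expect_equal(ps$curtain_duration_left, 7)
  # single 1 mm bubble carries 5.236e-4 mL
  one <- summarize_patient(sl[1, ], sr[0, ], patient)
  expect_equal(one$total_volume_ml, 5.236e-4, tolerance = 1e-4)
})

test_that("total volume is permutation-invariant and additive over sides", {
  patient <- fixture_patient()
  set.seed(3)
  sl <- data.frame(time_s = 1:20, side = "left", mebr_db = 15,
                   diameter_um = exp(runif(20, log(10), log(500))))
  sl$volume_ml <- volume_of(sl$diameter_um)
  perm <- sl[sample(20), ]
  s0 <- data.frame(time_s = numeric(0), side = character(0),
                   mebr_db = numeric(0), diameter_um = numeric(0),
                   volume_ml = numeric(0))
  expect_equal(summarize_patient(sl, s0, patient)$total_volume_ml,
               summarize_patient(perm, s0, patient)$total_volume_ml)
  expect_equal(summarize_patient(sl[1:10, ], sl[11:20, ],
                                 patient)$total_volume_ml,
               summarize_patient(sl, s0, patient)$total_volume_ml)
})
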