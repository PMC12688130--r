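test_that("sample filtering applies assay sensitivity limits", {
  s <- tibble::tibble(
    female_id = "F1", date = 1:10,
    e1c = c(50, 50, 6.6, 5.0, 50, 50, 50, 50, 4, 50),
    pdg = c(10, 2.0, 10, 10, 10, 1.9, 10, 10, 10, 10),
    creatinine = 1
  )
  kept <- filter_samples(s)
  excl <- attr(kept, "exclusions")
  # pdg = 2.0 < 2.1 excluded; e1c = 6.6 exactly at the limit is retained
  expect_equal(nrow(kept), 6)
  expect_equal(nrow(excl), 4)
  expect_true(2 %in% excl$date)   # pdg 2.0
  expect_false(3 %in% excl$date)  # boundary kept
  expect_setequal(excl$date, c(2, 4, 6, 9))
  expect_true(all(grepl("below sensitivity", excl$reason)))
  expect_error(filter_samples(dplyr::mutate(s, pdg = -1)), "non-negative")
})

test_that("duplicate same-day samples are averaged to one record", {
  s <- tibble::tibble(female_id = "F1", date = c(1, 1, 2),
                      e1c = c(40, 60, 50), pdg = c(8, 12, 10),
                      creatinine = 1)
  kept <- filter_samples(s)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$pdg[kept$date == 1], 10)
})

test_that("trailing PdG baseline uses the 10 preceding days with sample SD", {
  s <- tibble::tibble(date = 1:10, pdg = rep(10, 10))
  b <- pdg_baseline(s, at_date = 11)
  expect_equal(b$mean, 10)
  expect_equal(b$sd, 0)
  expect_equal(b$n, 10)

  s2 <- tibble::tibble(date = c(3, 5, 8), pdg = c(8, 10, 12))
  b2 <- pdg_baseline(s2, at_date = 11)
  expect_equal(b2$mean, 10)
  expect_equal(b2$sd, 2)  # sample SD of {8, 10, 12}
  expect_equal(b2$n, 3)

  # window is strictly trailing: the day itself is excluded
  b3 <- pdg_baseline(tibble::tibble(date = 11, pdg = 99), at_date = 11)
  expect_equal(b3$n, 0)
  expect_false(b3$sufficient)
})

test_that("detector finds the day before a sustained step rise", {
  flat <- make_step_series(step_value = 10, noise_sd = 0)
  expect_equal(detect_ovulation(flat)$status, "anovulatory")

  s <- make_step_series(n_days = 20, step_day = 16, noise_sd = 0.5)
  call <- detect_ovulation(s)
  expect_equal(call$status, "ovulatory")
  expect_equal(call$ovulation_date, 15)
  expect_equal(call$rise_start_date, 16)

  # a 2-day blip is not a sustained rise
  blip <- make_step_series(n_days = 30, step_day = 16, noise_sd = 0.3)
  blip$pdg[blip$date >= 18] <- 10
  expect_equal(detect_ovulation(blip)$status, "anovulatory")
})

test_that("detector returns day-before-rise for every step position", {
  # direct-rule oracle check: an unambiguous (noise-free) step at any
  # position is dated to the day before the step
  for (step in 13:27) {
    s <- make_step_series(n_days = 32, step_day = step, noise_sd = 0,
                          seed = step)
    call <- detect_ovulation(s)
    expect_equal(call$status, "ovulatory")
    expect_equal(call$ovulation_date, step - 1)
  }
})

test_that("detection is invariant to uniform rescaling of PdG", {
  s <- make_step_series(n_days = 25, step_day = 14, noise_sd = 0.5)
  c1 <- detect_ovulation(s)
  s2 <- dplyr::mutate(s, pdg = pdg * 37.5)
  c2 <- detect_ovulation(s2)
  expect_equal(c1$ovulation_date, c2$ovulation_date)
  expect_equal(c1$status, c2$status)
})

test_that("sustained days must fall within a 7-day calendar span", {
  # elevated samples on days 16, 20, 24: three successive sampled days but
  # spanning 9 calendar days -> no call
  s <- tibble::tibble(
    female_id = "F1",
    date = c(1:15, 16, 20, 24),
    e1c = 50, pdg = c(rep(10, 15), 40, 40, 40), creatinine = 1
  )
  expect_equal(detect_ovulation(s)$status, "anovulatory")
  # compressed to days 16, 18, 20 (5-day span) -> detected
  s2 <- dplyr::mutate(s, date = c(1:15, 16, 18, 20))
  expect_equal(detect_ovulation(s2)$status, "ovulatory")
})

test_that("sparse coverage yields undetermined rather than anovulatory", {
  s <- tibble::tibble(female_id = "F1", date = c(1, 5, 9),
                      e1c = 50, pdg = 10, creatinine = 1)
  expect_equal(detect_ovulation(s)$status, "undetermined")
  expect_equal(detect_ovulation(s[0, ])$status, "undetermined")
})

test_that("fertile window is the 4 days ending on ovulation", {
  fw <- fertile_window(20)
  expect_equal(fw$start_date, 17)
  expect_equal(fw$end_date, 20)
  expect_equal(fw$day_offsets, -3:0)
  expect_equal(fw$end_date - fw$start_date + 1, 4)
})

test_that("cycle classification computes the signed ovulation-detumescence lag", {
  ph <- segment_phases(make_swelling(c(1, rep(3, 19), 2, 1)))
  expect_equal(ph$detumescence_date, 21)
  call <- tibble::tibble(female_id = "F1", cycle_id = "c1",
                         status = "ovulatory", ovulation_date = 19)
  rec <- classify_cycle(ph, call)
  expect_equal(rec$lag_days, 2)
  expect_false(rec$ovulation_outside_msp)

  # ovulation after detumescence: negative lag, flagged outside
  call2 <- dplyr::mutate(call, ovulation_date = 23)
  rec2 <- classify_cycle(ph, call2)
  expect_equal(rec2$lag_days, -2)
  expect_true(rec2$ovulation_outside_msp)

  call3 <- dplyr::mutate(call, female_id = "F9")
  expect_error(classify_cycle(ph, call3), "different females")
})
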