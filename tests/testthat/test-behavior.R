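test_that("infant-age code follows the ordinal half-year scheme", {
  part <- 1000
  # 3 months before parturition: late pregnancy
  expect_equal(infant_age_code(part - 91, part), -0.5)
  # parturition day: newborn
  expect_equal(infant_age_code(part, part), 0)
  # 3 years 2 months: floored to 3.0
  expect_equal(infant_age_code(part + round(3.17 * 365.25), part), 3.0)
  # 8 months: 0.5 bin
  expect_equal(infant_age_code(part + 244, part), 0.5)
  # capped at 5
  expect_equal(infant_age_code(part + 10 * 365, part), 5)
  # conception until 6 months pre-partum: -1
  expect_equal(infant_age_code(part - 230, part, conception_date = part - 240),
               -1)
  # before the conceptive detumescence: uncoded
  expect_true(is.na(infant_age_code(part - 300, part,
                                    conception_date = part - 240)))
})

test_that("standardization gives exact z-scores and is idempotent", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(2)
  x <- rnorm(50, 7, 3)
  z <- standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(rep(4, 10)), "constant")
})

test_that("intensive-following counts distinct qualifying males per female-day", {
  ev <- tibble::tibble(
    event_type = "intensive_follow",
    actor_id = c("M1", "M1", "M2", "M3", "M4"),
    target_id = c("F1", "F1", "F1", "F1", "F2"),
    date = 5,
    duration_min = c(10, 20, 4, 6, 30)
  )
  counts <- count_intensive_following(ev)
  # M1 twice counts once; M2's 4-min follow does not qualify
  expect_equal(counts$n_following_males[counts$female_id == "F1"], 2)
  expect_equal(counts$n_following_males[counts$female_id == "F2"], 1)

  # zero-fill over a supplied female-day grid
  states <- tidyr::crossing(female_id = c("F1", "F2", "F3"), date = 5:6)
  full <- count_intensive_following(ev, states)
  expect_equal(nrow(full), 6)
  expect_equal(sum(full$n_following_males), 3)
  expect_equal(full$n_following_males[full$female_id == "F3"], c(0, 0))
})

test_that("dyad-day assembly matches exhaustive enumeration on a small fixture", {
  males <- c("M1", "M2")
  females <- c("F1", "F2")
  cycles <- tibble::tibble(
    female_id = females, cycle_id = c("c1", "c2"),
    ovulation_date = c(30, 38)
  )
  # party: everyone present 4 h/day on days 10..45, except M2 absent on
  # day 25 and no party data at all on day 28
  party <- tidyr::crossing(date = setdiff(10:45, 28), hour = 1:4,
                           id = c(males, females))
  party <- party[!(party$id == "M2" & party$date == 25), ]
  ev <- tibble::tibble(
    event_type = c("copulation", "copulation", "solicitation",
                   "intervention", "copulation"),
    actor_id = c("M1", "M1", "M2", "M1", "M2"),
    target_id = c("F1", "F1", "F2", "M2", "F1"),
    date = c(30, 28, 35, 29, 100),  # day 28 has no party; day 100 off-window
    context_female_id = c(NA, NA, NA, "F1", NA)
  )
  meta <- tibble::tibble(id = c(males, females), sex = c("M", "M", "F", "F"),
                         rank = c(1, 2, NA, NA), age = c(20, 25, 22, 30))
  dd <- assemble_dyad_day(ev, party, cycles, metadata = meta)

  # brute force: 2 males x 15 in-window days x 2 cycles = 60 candidate
  # rows; day 28 (no party) lies in both windows (16..30 and 24..38), so 4
  # rows drop; M2 absent on day 25 zeroes shared hours with both females,
  # so 2 more rows drop
  expect_equal(nrow(dd), 60 - 4 - 2)
  expect_true(all(dd$day_from_ovulation >= -14 & dd$day_from_ovulation <= 0))
  expect_true(all(dd$hours_together > 0))

  # counts conserved: only in-window events with party data appear
  expect_equal(sum(dd$n_copulation), 1)   # day 30 M1-F1 only
  expect_equal(sum(dd$n_solicitation), 1) # day 35 M2-F2
  expect_equal(sum(dd$n_intervention), 1) # attributed to M1-F1 via context
  lg <- attr(dd, "log")
  expect_equal(lg$n[lg$stage == "no_party_record"], 4)
  expect_equal(lg$n[lg$stage == "zero_shared_hours"], 2)

  # order invariance
  dd2 <- assemble_dyad_day(ev[sample(nrow(ev)), ], party, cycles,
                           metadata = meta)
  expect_equal(dd$n_copulation, dd2$n_copulation)

  # dyad exclusion drops a mother-son pair entirely
  dd3 <- assemble_dyad_day(ev, party, cycles, metadata = meta,
                           excluded_dyads = tibble::tibble(
                             male_id = "M1", female_id = "F1"))
  expect_false(any(dd3$male_id == "M1" & dd3$female_id == "F1"))
})

test_that("interventions with female targets are excluded from counts", {
  cycles <- tibble::tibble(female_id = "F1", cycle_id = "c1",
                           ovulation_date = 20)
  party <- tidyr::crossing(date = 6:20, hour = 1:3,
                           id = c("M1", "M2", "F1"))
  ev <- tibble::tibble(
    event_type = "intervention",
    actor_id = "M1", target_id = c("M2", "F1"),
    date = c(15, 16), context_female_id = c("F1", "F1")
  )
  meta <- tibble::tibble(id = c("M1", "M2", "F1"), sex = c("M", "M", "F"))
  dd <- assemble_dyad_day(ev, party, cycles, metadata = meta)
  expect_equal(sum(dd$n_intervention), 1)
})

test_that("aggression rates divide by hours and square-root transform", {
  daily <- tibble::tibble(date = 1:4, n_aggression = c(0, 4, 9, 2),
                          hours = c(5, 4, 4, 0))
  out <- aggression_rate(daily)
  expect_equal(nrow(out), 3)  # zero-hour day dropped
  expect_equal(out$rate_sqrt, c(0, 1, 1.5))
  expect_equal(out$rate, c(0, 1, 2.25))
  expect_equal(attr(out, "log")$n[1], 1)
})

test_that("top-k copulation share matches the published skew arithmetic", {
  counts <- tibble::tibble(
    male_id = paste0("M", 1:10),
    n_copulation = c(70, 55, 40, 12, 10, 8, 6, 4, 3, 1),
    rank = 1:10
  )
  res <- top_k_copulation_share(counts, k = 3)
  expect_equal(res$top_count, 165)
  expect_equal(res$total, 209)
  expect_equal(round(res$share_pct, 1), 78.9)
  expect_equal(top_k_copulation_share(counts, k = 10)$share_pct, 100)
  # uniform counts: share is 100 k / m
  unif <- dplyr::mutate(counts, n_copulation = 5)
  expect_equal(top_k_copulation_share(unif, k = 4)$share_pct, 40)
  # monotone non-decreasing in k
  shares <- vapply(1:10, function(k) {
    top_k_copulation_share(counts, k)$share_pct
  }, numeric(1))
  expect_true(all(diff(shares) >= 0))
  expect_error(top_k_copulation_share(counts, k = 11), "exceeds")
})

test_that("hurdle subsets select maximal-swelling and multi-FMS days", {
  states <- tibble::tibble(
    female_id = rep(c("F1", "F2"), each = 4),
    date = rep(1:4, 2),
    swelling_score = c(1, 2, 3, 3, 3, 3, 2, 1),
    n_fms = c(1, 1, 2, 1, 2, 1, 2, 0)
  )
  hs <- hurdle_subsets(states)
  expect_equal(nrow(hs$full), 8)
  expect_equal(nrow(hs$msp_only), 4)
  expect_true(all(hs$msp_only$swelling_score == 3))
  expect_equal(nrow(hs$multi_fms), 3)
  expect_true(all(hs$multi_fms$n_fms >= 2))
  expect_equal(unname(hs$counts), c(8, 4, 3))
})
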