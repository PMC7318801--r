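test_that("zero logit dispersion gives exactly the cell means", {
  cells <- pd_cell_targets(1)
  spec <- cohort_spec(cells = cells, n_per_cell = 5, sd_logit = 0,
                      seed = 3)
  ch <- sample_cohort(spec)
  for (i in seq_len(nrow(cells))) {
    sub <- ch[ch$instrumentality == cells$instrumentality[i], ]
    expect_equal(unique(sub$D_true), cells$D_mean[i], tolerance = 1e-12)
    expect_equal(unique(sub$U_true), cells$U_mean[i], tolerance = 1e-12)
  }
})

test_that("cohort sampling is seed-deterministic and mean-calibrated", {
  spec <- cohort_spec(cells = pd_cell_targets(1), n_per_cell = 10000,
                      seed = 42)
  c1 <- sample_cohort(spec)
  c2 <- sample_cohort(spec)
  expect_identical(c1, c2)

  # logit-normal location is solved so large-sample means hit the targets
  cells <- pd_cell_targets(1)
  for (i in seq_len(nrow(cells))) {
    sub <- c1[c1$instrumentality == cells$instrumentality[i], ]
    expect_lt(abs(mean(sub$D_true) - cells$D_mean[i]), 0.011)
    expect_lt(abs(mean(sub$U_true) - cells$U_mean[i]), 0.011)
  }
})

test_that("unreachable cell means are rejected", {
  cells <- pd_cell_targets(1)
  cells$D_mean[1] <- 1
  expect_error(cohort_spec(cells = cells, n_per_cell = 5, sd_logit = 1),
               "unreachable")
  expect_silent(cohort_spec(cells = cells, n_per_cell = 5, sd_logit = 0))
})

test_that("degenerate latent values force deterministic responses", {
  b <- full_battery("means", "personal")
  all_reject <- simulate_trials(constant_cohort(D = 1, U = 0, n = 5), b,
                                seed = 1)
  expect_true(all(all_reject$response == "reject_harm"))

  split <- simulate_trials(constant_cohort(D = 0, U = 1, n = 5), b,
                           seed = 1)
  expect_true(all(split$response[split$congruency == "congruent"] ==
                    "reject_harm"))
  expect_true(all(split$response[split$congruency == "incongruent"] ==
                    "accept_harm"))
})

test_that("incongruent rejection rate matches the processing tree", {
  # p(reject | incongruent) = (1 - U) * D = 0.7 * 0.7... at (0.7, 0.3):
  # (1 - 0.3) * 0.7 = 0.49
  b <- full_battery("means", "personal")
  tr <- simulate_trials(constant_cohort(D = 0.7, U = 0.3, n = 2000), b,
                        seed = 5)
  inc <- tr[tr$congruency == "incongruent", ]
  expect_lt(abs(mean(inc$response == "reject_harm") - 0.49), 0.012)
  con <- tr[tr$congruency == "congruent", ]
  expect_lt(abs(mean(con$response == "reject_harm") - (0.3 + 0.7 * 0.7)),
            0.012)
})

test_that("every participant gets 10 + 10 trials with positions 1..20", {
  fx <- make_fixture("tiny-exp1")
  counts <- table(fx$trials$participant_id, fx$trials$congruency)
  expect_true(all(counts == 10))
  pos <- tapply(fx$trials$position, fx$trials$participant_id,
                function(p) identical(sort(p), 1:20))
  expect_true(all(unlist(pos)))
})

test_that("artifact injection is exact and labelled", {
  spec <- cohort_spec(cells = pd_cell_targets(1), n_per_cell = 20,
                      seed = 9)
  ch <- sample_cohort(spec)
  tr <- simulate_trials(ch, full_battery(personal_force = "personal"),
                        seed = 10)

  none <- inject_artifacts(ch, tr, spec)
  expect_equal(nrow(none$participants), nrow(ch))
  expect_false(any(none$participants$injected_duplicate))
  expect_false(any(none$participants$injected_outlier))

  spec2 <- cohort_spec(cells = pd_cell_targets(1), n_per_cell = 20,
                       n_duplicates = 1, n_outliers = 3, seed = 9)
  one <- inject_artifacts(ch, tr, spec2)
  expect_equal(nrow(one$participants), nrow(ch) + 1)
  expect_equal(sum(duplicated(one$participants$participant_id)), 1)
  expect_equal(sum(one$participants$injected_outlier), 3)
  # extreme times really are extreme relative to the lognormal bulk
  ext <- one$participants$total_time[one$participants$injected_outlier]
  expect_true(all(ext < 15 | ext > 3600))

  expect_error(cohort_spec(cells = pd_cell_targets(1), n_per_cell = 5,
                           duplicate_rate = 1.5), "duplicate_rate")
})

test_that("exact tree probabilities invert to the latent parameters", {
  # forward-inverse round trip without sampling noise
  D <- runif(200); U <- runif(200, 0, 0.999)
  p_c <- U + (1 - U) * D
  p_i <- (1 - U) * D
  est <- estimate_pd(data.frame(participant_id = as.character(1:200),
                                p_unacc_cong = p_c, p_unacc_incong = p_i))
  expect_equal(est$U, U, tolerance = 1e-12)
  expect_equal(est$D, D, tolerance = 1e-12)
})
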