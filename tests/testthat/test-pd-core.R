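test_that("the processing-tree equations invert observed proportions", {
  # complements of typical congruent/incongruent acceptance rates
  est <- estimate_pd(data.frame(participant_id = "x",
                                p_unacc_cong = 0.86,
                                p_unacc_incong = 0.45))
  expect_equal(est$U, 0.41, tolerance = 1e-12)
  expect_equal(est$D, 0.45 / 0.59, tolerance = 1e-12)
  expect_false(est$clamped)

  # equal proportions: all rejection is deontological
  est2 <- estimate_pd(data.frame(participant_id = "y",
                                 p_unacc_cong = 0.6,
                                 p_unacc_incong = 0.6))
  expect_equal(est2$U, 0)
  expect_equal(est2$D, 0.6)
})

test_that("negative raw U is clamped to zero before anything else", {
  est <- estimate_pd(data.frame(participant_id = "z",
                                p_unacc_cong = 0.4,
                                p_unacc_incong = 0.5))
  expect_equal(est$U_raw, -0.1, tolerance = 1e-12)
  expect_equal(est$U, 0)
  expect_equal(est$D, 0.5)       # denominator uses the clamped U
  expect_true(est$clamped)
  expect_equal(est$D_raw, 0.5 / 1.1, tolerance = 1e-12)
})

test_that("U_raw = 1 leaves D undefined and flagged", {
  est <- estimate_pd(data.frame(participant_id = "w",
                                p_unacc_cong = 1,
                                p_unacc_incong = 0))
  expect_true(est$d_undefined)
  expect_true(is.na(est$D))
  expect_true(is.na(est$grid_D))
  expect_equal(est$U, 1)
})

test_that("grid rounding matches the weight-20 conditioning rule", {
  expect_equal(round_to_grid(0.42, 20), 0.40)
  expect_equal(round_to_grid(0.44, 20), 0.45)
  expect_equal(round_to_grid(0.425, 20), 0.45)  # ties away from zero
  expect_error(round_to_grid(0.5, 0), "positive integer")

  # property: grid value times weight is an integer in [0, weight]
  for (w in c(10, 20)) {
    x <- runif(500)
    g <- round_to_grid(x, w)
    expect_true(all(abs(g * w - round(g * w)) < 1e-9))
    expect_true(all(g >= 0 & g <= 1))
    expect_true(all(abs(g - x) <= 1 / (2 * w) + 1e-9))
  }
})

test_that("conventional measure counts utilitarian responses at weight 10", {
  b <- full_battery("means", "personal")
  tr <- simulate_trials(constant_cohort(D = 1, U = 0, n = 3), b, seed = 2)
  cm <- conventional_measure(tr)
  expect_equal(cm$conventional, rep(0, 3))  # everything rejected
  expect_equal(unique(cm$weight), 10L)

  tr1 <- tr[tr$participant_id == tr$participant_id[1], ]
  idx <- which(tr1$congruency == "incongruent")[1:4]
  tr1$response[idx] <- "accept_harm"
  expect_equal(conventional_measure(tr1)$conventional, 0.4)

  # missing incongruent trials are flagged
  tr_short <- tr1[-idx[1], ]
  expect_true(conventional_measure(tr_short)$incomplete)
})

test_that("pooled group-level estimation matches the tree closed form", {
  b <- full_battery("means", "personal")
  tr <- simulate_trials(constant_cohort(D = 0.7, U = 0.3, n = 1500), b,
                        seed = 31)
  g <- pd_group_estimate(tr)
  expect_lt(abs(g$U - 0.3), 0.02)
  expect_lt(abs(g$D - 0.7), 0.02)
})

test_that("cell summaries report means, SDs and the D-U correlation", {
  participants <- data.frame(
    participant_id = c("a", "b", "c", "d"),
    instrumentality = "means", personal_force = "personal",
    stringsAsFactors = FALSE)
  est <- data.frame(participant_id = c("a", "b", "c", "d"),
                    U = c(0.2, 0.4, 0.1, 0.3), D = c(0.6, 0.8, 0.7, 0.5),
                    d_undefined = FALSE, stringsAsFactors = FALSE)
  cs <- cell_summaries(est, participants)
  expect_equal(cs$D_mean, 0.65)
  expect_equal(cs$U_mean, 0.25)
  expect_equal(cs$D_sd, sd(c(0.6, 0.8, 0.7, 0.5)))
  # correlation equals the hand-computed Pearson r
  r_hand <- cov(est$D, est$U) / (sd(est$D) * sd(est$U))
  expect_equal(cs$r_DU, r_hand, tolerance = 1e-12)

  # two-value check: mean 0.7, sample SD ~ 0.1414
  est2 <- est[1:2, ]; est2$D <- c(0.6, 0.8)
  cs2 <- suppressWarnings(
    cell_summaries(rbind(est2, est2), rbind(participants[1:2, ],
                                            participants[1:2, ])))
  expect_equal(cs2$D_mean, 0.7)

  # identical participants: SD 0, correlation undefined but not an error
  est3 <- est; est3$D <- 0.5; est3$U <- 0.2
  expect_warning(cs3 <- cell_summaries(est3, participants), "zero variance")
  expect_equal(cs3$D_sd, 0)
  expect_true(is.na(cs3$r_DU))
})

test_that("undefined-D participants reduce the effective n of a cell", {
  participants <- data.frame(
    participant_id = sprintf("p%d", 1:6),
    instrumentality = "means", personal_force = "personal",
    stringsAsFactors = FALSE)
  agg <- data.frame(participant_id = participants$participant_id,
                    p_unacc_cong = c(1, 0.9, 0.8, 0.7, 0.6, 0.5),
                    p_unacc_incong = c(0, 0.3, 0.4, 0.2, 0.5, 0.1))
  est <- estimate_pd(agg)
  cs <- cell_summaries(est, participants)
  expect_equal(cs$n, 6)
  expect_equal(cs$n_d_defined, 5)
})
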