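test_that("session has the configured frame count and gap structure", {
  m <- sticky_arhmm(K = 3, P = 3, seed = 1)
  sim <- simulate_arhmm_session(m, minutes = 20, fps = 30, seed = 2)
  expect_equal(nrow(sim$session$features), 36000)
  expect_length(sim$session$valid_mask, 36000)
  expect_length(sim$truth$states, 36000)   # states defined in gaps too
  expect_false(anyNA(sim$session$features[sim$session$valid_mask, ]))

  r <- rle(sim$session$valid_mask)
  blocks_s <- r$lengths[r$values] / 30
  gaps_s <- r$lengths[!r$values] / 30
  # interior valid blocks ~20 s, interruptions 1-2 s
  interior <- blocks_s[-length(blocks_s)]
  expect_true(all(interior >= 18 & interior <= 22))
  expect_true(all(gaps_s >= 0.9 & gaps_s <= 2.1))
})

test_that("identical seeds reproduce sessions exactly", {
  m <- sticky_arhmm(K = 2, P = 2, seed = 5)
  a <- simulate_arhmm_session(m, minutes = 1, seed = 9)
  b <- simulate_arhmm_session(m, minutes = 1, seed = 9)
  expect_identical(a, b)
  c <- simulate_arhmm_session(m, minutes = 1, seed = 10)
  expect_false(identical(a$session$features, c$session$features))
})

test_that("single-state model yields a constant state chain", {
  m <- random_arhmm(K = 1, P = 2, seed = 3)
  sim <- simulate_arhmm_session(m, minutes = 1, seed = 1)
  expect_true(all(sim$truth$states == 1L))
})

test_that("long-run occupancy matches the stationary distribution", {
  m <- sticky_arhmm(K = 3, P = 2, seed = 11)
  sim <- simulate_arhmm_session(m, minutes = 60, fps = 30, gaps = NULL,
                                seed = 4)
  occ <- tabulate(sim$truth$states, 3) / length(sim$truth$states)
  target <- stationary_distribution(m$trans)  # leading left eigenvector
  expect_true(all(abs(occ - target) < 0.02))
})

test_that("invalid models are rejected", {
  m <- sticky_arhmm(K = 2, P = 2, seed = 1)
  bad <- m
  bad$trans <- matrix(c(0.9, 0.3, 0.2, 0.8), 2)  # rows do not sum to 1
  expect_error(simulate_arhmm_session(bad, minutes = 1, seed = 1),
               "sum to 1")
})

test_that("cohorts support the study group sizes and derived seeds", {
  m <- sticky_arhmm(K = 2, P = 2, seed = 2)
  cohort <- make_cohort(m, n_per_genotype = c(wt = 6L, het = 10L, hom = 5L),
                        minutes = 0.2, seed = 1)
  expect_length(cohort, 21)
  genos <- vapply(cohort, function(x) x$session$genotype, "")
  expect_equal(as.vector(table(genos)[c("wt", "het", "hom")]), c(6, 10, 5))
  # animals differ (independent derived seeds)
  expect_false(identical(cohort[[1]]$session$features,
                         cohort[[2]]$session$features))
})

test_that("null genotype effect leaves the generating model unchanged", {
  m <- sticky_arhmm(K = 3, P = 2, seed = 2)
  c1 <- make_cohort(m, genotype_effects = list(mut = rep(1, 3)),
                    n_per_genotype = c(wt = 1L, mut = 1L),
                    minutes = 0.2, seed = 3)
  expect_identical(c1[[1]]$truth$model$trans, c1[[2]]$truth$model$trans)
})

test_that("occupancy multipliers shift occupancy in the right direction", {
  tm <- base_trans(4, 0.95)
  lower <- 0
  for (i in 1:100) {
    coh <- make_label_cohort(tm,
                             genotype_effects = list(mut = c(0.5, 1, 1, 1)),
                             n_per_genotype = c(wt = 1L, mut = 1L),
                             minutes = 2, seed = 100 + i)
    occ <- vapply(coh, function(s) mean(s$labels == 1L), numeric(1))
    lower <- lower + (occ[2] < occ[1])
  }
  expect_gte(lower / 100, 0.95)
})

test_that("extreme occupancy effects are rejected", {
  tm <- base_trans(3)
  expect_error(make_label_cohort(tm, genotype_effects = list(m = c(0, 1, 1)),
                                 n_per_genotype = c(wt = 1L, m = 1L),
                                 minutes = 0.1, seed = 1),
               "positive")
})

test_that("calibrated multiplier halves stationary occupancy", {
  tm <- base_trans(5, 0.95)
  mult <- occupancy_multiplier(tm, 1, 0.5)
  occ <- stationary_distribution(moseqr:::scale_transitions(tm, mult))[1]
  expect_equal(occ, 0.5 * stationary_distribution(tm)[1], tolerance = 1e-6)
})

test_that("EEG traces have the requested size, SD and ground truth", {
  sim <- simulate_eeg(60, 4000, 1, events = burst_events(10), seed = 3)
  expect_equal(ncol(sim$recording$samples), 240000)
  expect_equal(nrow(sim$truth), 10)

  # requested background SD is met (pre-injection trace)
  bg <- simulate_eeg(10, 4000, 1, background = list(sd = 35, slope = 1),
                     seed = 8)
  expect_equal(sd(bg$recording$samples[1, ]), 35, tolerance = 0.05 * 35)

  zero <- simulate_eeg(1, 4000, 2, background = list(sd = 0, slope = 1),
                       seed = 1)
  expect_true(all(zero$recording$samples == 0))

  expect_error(simulate_eeg(1, 4000, 1,
                            events = data.frame(time_s = 0.99, channel = 1,
                                                freq_hz = 300, n_cycles = 6,
                                                amplitude_ratio = 4),
                            seed = 1),
               "past trace end")
})

test_that("injected bursts are calibrated against the filtered baseline", {
  ev <- burst_events(5, dur = 30, ratio = 4)
  with_b <- simulate_eeg(30, 4000, 1, events = ev, seed = 6)
  no_b <- simulate_eeg(30, 4000, 1, events = NULL, seed = 6)
  sd_band <- sd(bandpass(no_b$recording$samples[1, ], 4000))
  injected <- with_b$recording$samples[1, ] - no_b$recording$samples[1, ]
  fb <- bandpass(injected, 4000)
  tr <- with_b$truth
  for (i in seq_len(nrow(tr))) {
    peak <- max(abs(fb[tr$start_sample[i]:tr$end_sample[i]]))
    expect_equal(peak, 4 * sd_band, tolerance = 0.10 * 4 * sd_band)
  }
})
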