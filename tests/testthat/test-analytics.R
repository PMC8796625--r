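test_that("bouts are maximal runs split by gaps", {
  lab <- c(0, 0, 1, 1, 1, 0) + 1L
  b <- extract_bouts(lab, fps = 30)
  expect_equal(b$syllable, c(1L, 2L, 1L))
  expect_equal(b$duration_s, c(2, 3, 1) / 30)

  lab2 <- rep(2L, 10)
  mask <- rep(TRUE, 10); mask[5] <- FALSE    # gap splits the run
  b2 <- extract_bouts(lab2, mask, fps = 30)
  expect_equal(nrow(b2), 2)
  expect_equal(b2$syllable, c(2L, 2L))

  expect_equal(nrow(extract_bouts(integer(0), logical(0), 30)), 0)
})

test_that("bout durations conserve total valid time", {
  set.seed(60)
  for (i in 1:5) {
    lab <- sample(1:4, 600, replace = TRUE)
    mask <- runif(600) > 0.1
    b <- extract_bouts(lab, mask, fps = 30)
    expect_equal(sum(b$duration_s), sum(mask) / 30)
  }
})

test_that("metrics follow their closed forms", {
  # one uninterrupted 20-minute bout
  b <- data.frame(syllable = 1L, start = 1L, end = 36000L,
                  n_frames = 36000L, duration_s = 1200)
  m <- compute_metrics(b, total_valid_minutes = 20)
  expect_equal(m$frequency, 0.05)
  expect_equal(m$mean_length, 1200)
  expect_equal(m$proportion, 100)

  # 3 bouts totaling 30 s in a 300 s session
  b3 <- data.frame(syllable = 1L, start = c(1, 400, 800),
                   end = c(300, 699, 1099), n_frames = rep(300L, 3),
                   duration_s = rep(10, 3))
  m3 <- compute_metrics(b3, total_valid_minutes = 5)
  expect_equal(m3$frequency, 0.6)
  expect_equal(m3$proportion, 10)

  # absent syllable: zero frequency and proportion, missing length
  mz <- compute_metrics(b, total_valid_minutes = 20, syllables = c(1L, 2L))
  expect_equal(mz$frequency[2], 0)
  expect_equal(mz$proportion[2], 0)
  expect_true(is.na(mz$mean_length[2]))
  expect_error(compute_metrics(b, 0), "positive")
})

test_that("frequency x mean_length = 0.6 x proportion on gap-free labels", {
  set.seed(61)
  for (i in 1:10) {
    lab <- sample(1:5, 1000, replace = TRUE)
    s <- list(list(labels = lab, valid_mask = rep(TRUE, 1000), fps = 30,
                   animal_id = "a", genotype = "wt"))
    m <- cohort_metrics(s)
    used <- m[m$n_bouts > 0, ]
    expect_true(all(abs(used$frequency * used$mean_length -
                          0.6 * used$proportion) < 1e-9))
    expect_equal(sum(m$proportion), 100, tolerance = 1e-9)
  }
})

test_that("identical groups are never flagged", {
  tm <- base_trans(3)
  coh <- make_label_cohort(tm, n_per_genotype = c(wt = 3L, mut = 3L),
                           minutes = 1, seed = 5)
  m <- cohort_metrics(coh)
  # overwrite: both genotypes byte-identical values
  for (s in unique(m$syllable)) {
    v <- m[m$genotype == "wt" & m$syllable == s, c("frequency", "mean_length",
                                                   "proportion")]
    m[m$genotype == "mut" & m$syllable == s,
      c("frequency", "mean_length", "proportion")] <- v
  }
  cmp <- compare_groups(m)
  expect_true(all(!cmp$significant))
  expect_true(all(cmp$p >= 0.9))      # fully tied data
  # degenerate constant metric: statistic 0, p = 1
  m$proportion <- 50
  cmp2 <- compare_groups(m, which_metrics = "proportion")
  expect_true(all(cmp2$kw_stat == 0 & cmp2$kw_p == 1))
})

test_that("Dunn z-tests match a permutation oracle on a fixed fixture", {
  set.seed(62)
  x <- c(rnorm(8, 0), rnorm(8, 0.6), rnorm(8, 1.2))
  g <- rep(c("wt", "het", "hom"), each = 8)
  dn <- dunn_test(x, g)
  for (i in seq_len(nrow(dn))) {
    pp <- dunn_perm_p(x, g, c(dn$group1[i], dn$group2[i]), n_perm = 10000,
                      seed = 63)
    expect_lt(abs(dn$p[i] - pp), 0.02)
  }
})

test_that("Dunn handles ties through the tie-corrected variance", {
  x <- c(1, 1, 2, 2, 3, 3, 4, 5, 5, 6)
  g <- rep(c("a", "b"), each = 5)
  dn <- dunn_test(x, g)
  # two-group Dunn z^2 equals the tie-corrected Kruskal-Wallis statistic
  kw <- kruskal.test(x, factor(g))
  expect_equal(dn$z^2, unname(kw$statistic), tolerance = 1e-8)
})

test_that("group comparison validates its inputs and honors BH adjustment", {
  tm <- base_trans(3)
  coh <- make_label_cohort(tm, n_per_genotype = c(wt = 6L, mut = 6L),
                           minutes = 1, seed = 8)
  m <- cohort_metrics(coh)
  expect_error(compare_groups(m[m$genotype == "wt", ]), "two genotype")
  cmp_raw <- compare_groups(m, p_adjust = "none", gate_on_omnibus = FALSE)
  cmp_bh <- compare_groups(m, p_adjust = "BH", gate_on_omnibus = FALSE)
  expect_true(all(cmp_bh$p_adj >= cmp_raw$p_adj - 1e-12))
})
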