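# small ensemble on well-separated 3-state data, reused across tests
small_ensemble <- function(R = 3, seed = 50) {
  m <- sticky_arhmm(K = 3, P = 3, seed = 21)
  sim <- simulate_arhmm_session(m, minutes = 1, seed = 22)
  s <- structure(list(animal_id = "a", genotype = "wt", fps = 30,
                      scores = sim$session$features,
                      valid_mask = sim$session$valid_mask,
                      session_minutes = 1),
                 class = "score_session")
  list(ens = run_ensemble(list(s), K = 3, R = R, master_seed = seed),
       truth = sim$truth$states)
}

test_that("signature catalog conserves frames and bounds unique count", {
  se <- small_ensemble(R = 1)
  sigs <- build_signatures(se$ens)
  expect_lte(length(sigs$catalog$key), 3)      # R = 1: at most K signatures
  expect_equal(sum(sigs$catalog$count), sigs$catalog$total_frames)
  expect_equal(sigs$catalog$total_frames,
               sum(!is.na(se$ens$fits[[1]]$state_seqs[[1]])))
})

test_that("label-permuted fits do not inflate the signature catalog", {
  se <- small_ensemble(R = 1)
  f1 <- se$ens$fits[[1]]
  perm <- c(2L, 3L, 1L)
  f2 <- f1
  f2$state_seqs <- lapply(f1$state_seqs, function(l) {
    out <- l; v <- !is.na(l); out[v] <- perm[l[v]]; out
  })
  ens2 <- se$ens
  ens2$fits <- list(f1, f2)
  ens2$R <- 2L
  sigs2 <- build_signatures(ens2)
  single_unique <- length(unique(
    f1$state_seqs[[1]][!is.na(f1$state_seqs[[1]])]))
  expect_equal(length(sigs2$catalog$key), single_unique)
})

test_that("mismatched frame coverage across fits is rejected", {
  se <- small_ensemble(R = 2)
  ens <- se$ens
  bad <- ens$fits[[2]]$state_seqs[[1]]
  bad[which(!is.na(bad))[1]] <- NA
  ens$fits[[2]]$state_seqs[[1]] <- bad
  expect_error(build_signatures(ens), "mismatched")
})

test_that("signature distance is the normalized Hamming distance", {
  expect_equal(signature_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(signature_distance(c(1, 2), c(3, 4)), 1)
  expect_equal(signature_distance(c(1, 1, 2, 2), c(1, 3, 2, 4)), 0.5)
  expect_error(signature_distance(1:3, 1:4), "equal length")
})

test_that("WPGMA linkage reproduces the hand-computed four-point tree", {
  cat4 <- four_point_catalog()
  map <- cluster_signatures(cat4, n_clusters = 2)
  # WPGMA recurrence: merge A,B at 2; C,D at 3; (AB),(CD) at
  # (4 + 6 + 4 + 6) / 4 = 5 (all distances in Hamming units, here / R = 6)
  expect_equal(sort(map$tree$height), c(2, 3, 5) / 6, tolerance = 1e-12)
  syl <- map$map$syllable
  names(syl) <- map$map$key
  expect_equal(syl[[cat4$key[1]]], syl[[cat4$key[2]]])
  expect_equal(syl[[cat4$key[3]]], syl[[cat4$key[4]]])
  expect_false(syl[[cat4$key[1]]] == syl[[cat4$key[3]]])
  # syllable 1 is the cluster with the larger frame count (A + B = 7 frames)
  expect_equal(syl[[cat4$key[1]]], 1L)
})

test_that("cutting at the catalog size gives the identity map", {
  cat4 <- four_point_catalog()
  map <- cluster_signatures(cat4, n_clusters = 4)
  expect_equal(sort(unique(map$map$syllable)), 1:4)
  expect_error(cluster_signatures(cat4, n_clusters = 5), "exceeds")
})

test_that("tree cuts are nested: more clusters only split, never merge", {
  se <- small_ensemble(R = 3)
  sigs <- build_signatures(se$ens)
  U <- length(sigs$catalog$key)
  maps <- lapply(2:min(U, 6), function(k)
    cluster_signatures(sigs$catalog, n_clusters = k))
  for (i in seq_len(length(maps) - 1)) {
    a <- maps[[i]]$map$syllable
    b <- maps[[i + 1]]$map$syllable
    # every finer cluster lies inside one coarser cluster
    expect_true(all(tapply(a, b, function(v) length(unique(v))) == 1))
  }
})

test_that("assignment is deterministic and signature-consistent", {
  se <- small_ensemble(R = 3)
  c1 <- consensus_syllables(se$ens, n_clusters = 3)
  c2 <- consensus_syllables(se$ens, n_clusters = 3)
  expect_identical(c1$map$map, c2$map$map)
  expect_identical(c1$labels, c2$labels)

  sigs <- build_signatures(se$ens)
  m <- sigs$signatures[[1]]
  lab <- c1$labels[[1]]
  v <- !is.na(lab)
  keys <- apply(m[v, , drop = FALSE], 1, paste, collapse = "-")
  # frames sharing a signature share a syllable (checked exhaustively)
  expect_true(all(tapply(lab[v], keys, function(x) length(unique(x))) == 1))
})

test_that("a single unique signature maps every frame to syllable 1", {
  se <- small_ensemble(R = 1)
  ens <- se$ens
  ens$fits[[1]]$state_seqs <- lapply(ens$fits[[1]]$state_seqs, function(l) {
    l[!is.na(l)] <- 2L; l
  })
  cons <- consensus_syllables(ens, n_clusters = 1)
  lab <- cons$labels[[1]]
  expect_true(all(lab[!is.na(lab)] == 1L))
})

test_that("unseen signatures fall back to the nearest catalogued one", {
  cat4 <- four_point_catalog()
  map <- cluster_signatures(cat4, n_clusters = 2)
  unseen <- matrix(c(1L, 1L, 0L, 0L, 0L, 3L), 1)  # Hamming 1 from B
  lab <- assign_syllables(unseen, map)
  expect_equal(attr(lab, "unseen"), 1L)
  expect_equal(as.integer(lab),
               map$map$syllable[map$map$key == cat4$key[2]])
})

test_that("consensus recovers generator states on small 3-state data", {
  se <- small_ensemble(R = 3)
  cons <- consensus_syllables(se$ens, n_clusters = 3)
  ari <- adjusted_rand_index(cons$labels[[1]], se$truth)
  expect_gte(ari, 0.8)
})

test_that("in-package ARI agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(33)
  for (i in 1:5) {
    a <- sample(1:4, 200, replace = TRUE)
    b <- ifelse(runif(200) < 0.7, a, sample(1:4, 200, replace = TRUE))
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})
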