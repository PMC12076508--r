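test_that("achiral construction yields no stereocenters", {
  for (i in 1:10) {
    m <- make_molecule(0, seed = i)
    expect_length(find_stereocenters(m), 0L)
    expect_identical(m$n_chiral_centers, 0L)
  }
})

test_that("generator and detector agree on count and labels (round trip)", {
  for (k in 1:4) {
    for (i in 1:25) {
      m <- make_molecule(k, seed = 31000 + 100 * k + i)
      sc <- find_stereocenters(m)
      expect_length(sc, k)
      expect_identical(vapply(sc, function(s) s$center, integer(1)),
                       vapply(m$stereocenters, function(s) s$center,
                              integer(1)))
      expect_identical(stereo_labels(sc), stereo_labels(m$stereocenters))
    }
  }
})

test_that("zero-jitter single-center molecules recover the intended label", {
  cfg <- generator_config(jitter_sd = 0)
  for (lab in c("R", "S")) {
    for (i in 1:10) {
      m <- make_molecule(1, seed = 900 + i, config = cfg, labels = lab)
      sc <- find_stereocenters(m)
      expect_length(sc, 1L)
      expect_identical(sc[[1]]$label, lab)
    }
  }
})

test_that("R- and S-forms share the element sequence (order is template-fixed)", {
  mr <- make_molecule(1, seed = 5, labels = "R")
  ms <- make_molecule(1, seed = 5, labels = "S")
  expect_identical(mr$elements, ms$elements)
  expect_gt(max(abs(mr$coords - ms$coords)), 0.1)
})

test_that("enantiomer pairs are exact mirrors with flipped labels", {
  for (i in 1:10) {
    k <- 1 + (i %% 4)
    pair <- make_enantiomer_pair(k, seed = 400 + i)
    expect_identical(pair[[1]]$elements, pair[[2]]$elements)
    expect_identical(stereo_labels(pair[[2]]$stereocenters),
                     chartr("RS", "SR", stereo_labels(pair[[1]]$stereocenters)))
    expect_identical(stereo_labels(find_stereocenters(pair[[2]])),
                     stereo_labels(pair[[2]]$stereocenters))
  }
})

test_that("surrogate rotation follows the signed weighted sum", {
  m <- make_molecule(1, seed = 77, labels = "R")
  expect_equal(assign_surrogate_rotation(m, weights = 10, noise_sd = 0), 10)
  m2 <- make_molecule(3, seed = 78, labels = c("R", "S", "S"))
  expect_equal(assign_surrogate_rotation(m2, weights = c(10, 5, 2),
                                         noise_sd = 0), 10 - 5 - 2)
  # enantiomer pair at zero noise: equal magnitude, opposite sign
  pair <- make_enantiomer_pair(2, seed = 79)
  v1 <- assign_surrogate_rotation(pair[[1]], noise_sd = 0)
  v2 <- assign_surrogate_rotation(pair[[2]], noise_sd = 0)
  expect_equal(v1, -v2)
  # achiral molecules get noise only; exactly zero without noise
  m0 <- make_molecule(0, seed = 80)
  expect_equal(assign_surrogate_rotation(m0, noise_sd = 0), 0)
})

test_that("achiral surrogate sign is a fair coin under noise", {
  m0 <- make_molecule(0, seed = 81)
  set.seed(82)
  vals <- replicate(10000, assign_surrogate_rotation(m0, noise_sd = 1))
  expect_lt(abs(mean(vals > 0) - 0.5), 0.015)
})

test_that("datasets honor requested composition and encode cleanly", {
  counts <- c(`0` = 30, `1` = 30, `2` = 20, `3` = 10, `4` = 10)
  recs <- make_dataset(counts, seed = 123)
  expect_length(recs, sum(counts))
  got <- table(vapply(recs, function(r) r$n_centers, numeric(1)))
  expect_equal(as.integer(got), as.integer(counts))
  x <- t(vapply(recs, function(r) flatten_ohecc(encode_ohecc(r$molecule)),
                numeric(216)))
  expect_true(all(is.finite(x)))
  # same seed reproduces; different seed does not
  recs2 <- make_dataset(counts, seed = 123)
  expect_identical(vapply(recs2, function(r) r$rotations[["589.3"]],
                          numeric(1)),
                   vapply(recs, function(r) r$rotations[["589.3"]],
                          numeric(1)))
  recs3 <- make_dataset(counts, seed = 124)
  expect_false(identical(recs3[[1]]$molecule$coords,
                         recs[[1]]$molecule$coords))
})

test_that("generated molecules stay within the encoding capacity", {
  for (k in 0:4) {
    m <- make_molecule(k, seed = 55 + k)
    expect_lte(n_atoms(m), 27L)
  }
  expect_error(make_molecule(4, seed = 1,
                             config = generator_config(max_atoms = 20L)),
               "capacity")
})
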