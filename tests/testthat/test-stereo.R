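test_that("atomic-number differences at sphere 1 decide priorities", {
  m <- ref_R_molecule()   # C bonded to F, O(H), N(H2), H
  r <- rank_substituents(m, m$bonds, 1L)
  expect_false(r$tie)
  expect_identical(r$order, c(2L, 3L, 5L, 8L))   # F > O > N > H
})

test_that("identical branches tie and a wrong degree errors", {
  # C bonded to two methyl groups and two hydrogens (isobutane-like center)
  dirs <- matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1), 4, 3,
                 byrow = TRUE) / sqrt(3)
  coords <- rbind(c(0, 0, 0),
                  1.54 * dirs[1, ], 1.54 * dirs[2, ],
                  1.09 * dirs[3, ], 1.09 * dirs[4, ],
                  1.54 * dirs[1, ] + c(1, 0, 0),
                  1.54 * dirs[2, ] + c(1, 0, 0))
  m <- molecule(c("C", "C", "C", "H", "H", "H", "H"), coords,
                bonds = list(c(2L, 3L, 4L, 5L), c(1L, 6L), c(1L, 7L),
                             1L, 1L, 2L, 3L))
  r <- rank_substituents(m, m$bonds, 1L)
  expect_true(r$tie)
  expect_error(rank_substituents(m, m$bonds, 2L), "exactly 4")
  expect_length(find_stereocenters(m), 0L)
})

test_that("deeper spheres rank CH2F over CH2OH over CH3", {
  # center C with branches CH2F, CH2OH, CH3, H: sphere 1 ties all three
  # carbons; sphere 2 multisets {F,H,H} > {O,H,H} > {H,H,H}
  dirs <- matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1), 4, 3,
                 byrow = TRUE) / sqrt(3)
  c0 <- c(0, 0, 0)
  b1 <- 1.54 * dirs[1, ]; b2 <- 1.54 * dirs[2, ]; b3 <- 1.54 * dirs[3, ]
  coords <- rbind(
    c0, b1, b2, b3, 1.09 * dirs[4, ],
    b1 + c(1.35, 0, 0), b1 + c(0, 1, 0), b1 + c(0, 0, 1),
    b2 + c(1.43, 0, 0), b2 + c(0, 1, 0), b2 + c(0, 0, 1),
    b2 + c(2.2, 0.4, 0),
    b3 + c(1, 0, 0), b3 + c(0, 1, 0), b3 + c(0, 0, 1))
  m <- molecule(c("C", "C", "C", "C", "H",
                  "F", "H", "H", "O", "H", "H", "H", "H", "H", "H"),
                coords,
                bonds = list(c(2L, 3L, 4L, 5L),        # center
                             c(1L, 6L, 7L, 8L),        # CH2F carbon
                             c(1L, 9L, 10L, 11L),      # CH2OH carbon
                             c(1L, 13L, 14L, 15L),     # CH3 carbon
                             1L, 2L, 2L, 2L,
                             c(3L, 12L), 3L, 3L, 9L,
                             4L, 4L, 4L))
  r <- rank_substituents(m, m$bonds, 1L)
  expect_false(r$tie)
  expect_identical(r$order, c(2L, 3L, 4L, 5L))
})

test_that("the frozen reference center is labeled R", {
  # label validated once against an independent CIP implementation
  m <- ref_R_molecule()
  sc <- find_stereocenters(m)
  expect_length(sc, 1L)
  expect_identical(sc[[1]]$label, "R")
  expect_identical(sc[[1]]$priorities, c(2L, 3L, 5L, 8L))
})

test_that("reflection flips labels; proper motions preserve them", {
  set.seed(21)
  n_checked <- 0L
  for (i in 1:60) {
    k <- sample(1:4, 1)
    m <- make_molecule(k, seed = 7000 + i)
    lab <- stereo_labels(find_stereocenters(m))
    mirrored <- reflect_molecule(m, rnorm(3))
    lab_m <- stereo_labels(find_stereocenters(mirrored))
    expect_identical(lab_m, chartr("RS", "SR", lab))
    moved <- transform_molecule(m, random_rotation(), rnorm(3))
    expect_identical(stereo_labels(find_stereocenters(moved)), lab)
    n_checked <- n_checked + length(lab)
  }
  expect_gte(n_checked, 100L)
})

test_that("swapping any two priorities flips the label", {
  m <- ref_R_molecule()
  pri <- c(2L, 3L, 5L, 8L)
  base <- assign_handedness(m, 1L, pri)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      swapped <- pri
      swapped[c(i, j)] <- swapped[c(j, i)]
      flipped <- assign_handedness(m, 1L, swapped)
      expect_false(flipped == base)
    }
  }
})

test_that("degenerate geometry is rejected and skipped candidates logged", {
  # four neighbors in a plane with the center
  m <- molecule(c("C", "F", "O", "N", "H"),
                rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                      c(-1, 0, 0), c(0, -1, 0)),
                bonds = list(2:5, 1L, 1L, 1L, 1L))
  expect_error(assign_handedness(m, 1L, c(2L, 3L, 4L, 5L)), "degenerate")
  sc <- find_stereocenters(m)
  expect_length(sc, 0L)
  skipped <- attr(sc, "skipped")
  expect_identical(skipped[[1]]$reason, "degenerate geometry")
})
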