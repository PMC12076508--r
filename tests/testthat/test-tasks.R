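make_test_records <- function() {
  make_dataset(c(`0` = 40, `1` = 60, `2` = 30, `3` = 25, `4` = 25),
               seed = 2024)
}

test_that("archive writer and reader round trip", {
  recs <- make_dataset(c(`0` = 6, `1` = 8, `2` = 4), seed = 9)
  dir <- withr::local_tempdir()
  write_orqm9(recs, dir)
  back <- load_orqm9(dir)
  expect_length(back, length(recs))
  expect_equal(vapply(back, function(r) r$n_centers, numeric(1)),
               vapply(recs, function(r) r$n_centers, numeric(1)))
  expect_equal(vapply(back, function(r) unname(r$rotations[["589.3"]]),
                      numeric(1)),
               vapply(recs, function(r) unname(r$rotations[["589.3"]]),
                      numeric(1)),
               tolerance = 1e-9)
  for (i in c(1L, 8L, 18L)) {
    expect_equal(back[[i]]$features,
                 flatten_ohecc(encode_ohecc(recs[[i]]$molecule)),
                 tolerance = 1e-9)
    expect_identical(back[[i]]$labels, unname(recs[[i]]$labels))
  }
  # class census preserved through the archive
  expect_equal(as.integer(table(vapply(back, function(r) r$n_centers,
                                       numeric(1)))),
               c(6L, 8L, 4L))
})

test_that("a malformed archive names the missing piece", {
  recs <- make_dataset(c(`1` = 3), seed = 10)
  dir <- withr::local_tempdir()
  write_orqm9(recs, dir)
  df <- utils::read.csv(file.path(dir, "records.csv"), check.names = FALSE)
  df$n_chiral_centers <- NULL
  utils::write.csv(df, file.path(dir, "records.csv"), row.names = FALSE)
  expect_error(load_orqm9(dir), "n_chiral_centers")
  expect_error(load_orqm9(withr::local_tempdir()), "manifest")
})

test_that("balanced binary task arithmetic: 100 per class, 80-20", {
  recs <- make_test_records()
  td <- build_task(recs, task_spec("existence", per_class = 40, seed = 3))
  expect_equal(nrow(td$x_train), 64)   # 2 * 32
  expect_equal(nrow(td$x_test), 16)
  expect_equal(as.integer(table(td$y_train)), c(32L, 32L))
  expect_equal(as.integer(table(td$y_test)), c(8L, 8L))
  expect_length(intersect(td$ids_train, td$ids_test), 0L)
  expect_identical(td$classes, c("0", "1+"))
})

test_that("balancing is exact for all six tasks on synthetic data", {
  recs <- make_test_records()
  per <- c(existence = 20L, zero_vs_one = 20L, R_vs_S = 15L,
           sign_one_center = 15L, sign_all = 20L,
           n_centers_multiclass = 15L)
  for (task in names(per)) {
    td <- build_task(recs, task_spec(task, per_class = per[[task]],
                                     seed = 11))
    k <- length(td$classes)
    pooled <- c(as.integer(table(td$y_train)) + as.integer(table(td$y_test)))
    expect_equal(pooled, rep(per[[task]], k))
    expect_length(intersect(td$ids_train, td$ids_test), 0L)
  }
})

test_that("the same seed reproduces membership; another seed changes it", {
  recs <- make_test_records()
  spec <- task_spec("zero_vs_one", per_class = 30, seed = 42)
  td1 <- build_task(recs, spec)
  td2 <- build_task(recs, spec)
  expect_identical(td1$ids_train, td2$ids_train)
  expect_identical(td1$x_test, td2$x_test)
  td3 <- build_task(recs, task_spec("zero_vs_one", per_class = 30,
                                    seed = 43))
  expect_false(identical(sort(td1$ids_train), sort(td3$ids_train)))
})

test_that("shortfalls are reported with the deficit", {
  recs <- make_test_records()
  expect_error(
    build_task(recs, task_spec("R_vs_S", per_class = 1000, seed = 1)),
    "need 1000")
})

test_that("sign tasks exclude zero rotations and keep signs strict", {
  recs <- make_dataset(c(`1` = 40), seed = 17, noise_sd = 0)
  # force a few exact zeros
  for (i in 1:5) recs[[i]]$rotations[["589.3"]] <- 0
  td <- build_task(recs, task_spec("sign_one_center", per_class = 10,
                                   seed = 2))
  expect_identical(attr(td, "excluded_zero_rotation"), 5L)
  rot_by_id <- stats::setNames(
    vapply(recs, function(r) r$rotations[["589.3"]], numeric(1)),
    vapply(recs, function(r) r$id, character(1)))
  expect_true(all(rot_by_id[td$ids_train] != 0))
  lab <- ifelse(rot_by_id[c(td$ids_train, td$ids_test)] > 0, "+", "-")
  expect_identical(unname(lab),
                   as.character(c(td$y_train, td$y_test)))
})

test_that("size partition at 17 atoms is exhaustive and boundary-correct", {
  recs <- make_test_records()
  sizes <- vapply(recs, record_n_atoms, numeric(1))
  part <- size_partition(recs, threshold = 17)
  expect_length(part$small, sum(sizes <= 17))
  expect_length(part$large, sum(sizes > 17))
  expect_equal(length(part$small) + length(part$large), length(recs))
  # a 17-atom molecule counts as small
  rec17 <- list(id = "m17",
                molecule = molecule(rep("C", 17), matrix(rnorm(51), 17, 3)))
  expect_length(size_partition(list(rec17), threshold = 17)$small, 1L)
  # feature-only records use the one-hot block to count atoms
  rec_feat <- list(id = "f",
                   features = flatten_ohecc(encode_ohecc(recs[[1]]$molecule)))
  expect_equal(record_n_atoms(rec_feat), record_n_atoms(recs[[1]]))
})
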