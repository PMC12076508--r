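# OR-QM9-style archive IO and the six classification task builders.

#' Number of atoms of a record
#'
#' Uses the molecule when present, otherwise counts the nonzero one-hot
#' rows of the record's flattened OHECC features.
#'
#' @param record A dataset record.
#' @param vocab,max_atoms OHECC shape assumed for feature-only records.
#' @return Integer atom count.
#' @export
record_n_atoms <- function(record, vocab = default_vocab(), max_atoms = 27L) {
  if (!is.null(record$molecule)) return(n_atoms(record$molecule))
  if (!is.null(record$features)) {
    m <- matrix(record$features, nrow = max_atoms,
                ncol = 3L + length(vocab), byrow = TRUE)
    return(sum(rowSums(m[, -(1:3), drop = FALSE]) > 0))
  }
  stop("record has neither a molecule nor features")
}

record_features <- function(record, vocab = default_vocab(),
                            max_atoms = 27L) {
  if (!is.null(record$features)) return(as.numeric(record$features))
  flatten_ohecc(encode_ohecc(record$molecule, vocab, max_atoms))
}

#' Write records as a schema-manifest archive
#'
#' Serializes dataset records to a plain-text archive: a CSV with one row
#' per record (index, InChI tag, stereocenter count, center table as JSON,
#' the three rotations, and the flattened OHECC features) plus a YAML
#' manifest mapping logical fields to column names. The manifest makes the
#' field layout data-driven, so archives with different internal naming can
#' be read by pointing the manifest at their columns.
#'
#' @param records List of records (see [make_dataset()]).
#' @param dir Output directory; created if needed.
#' @param vocab,max_atoms OHECC shape used to featurize records.
#' @return The directory path, invisibly.
#' @export
write_orqm9 <- function(records, dir, vocab = default_vocab(),
                        max_atoms = 27L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- 3L + length(vocab)
  fcols <- paste0("f", seq_len(max_atoms * p))
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    centers <- if (!is.null(r$molecule$stereocenters)) {
      lapply(r$molecule$stereocenters, function(s) {
        list(location = s$center, label = s$label)
      })
    } else if (length(r$labels)) {
      lapply(seq_along(r$labels), function(k) {
        list(location = NA, label = r$labels[[k]])
      })
    } else list()
    feats <- record_features(r, vocab, max_atoms)
    c(list(index = i,
           inchi = if (is.null(r$inchi)) paste0("synthetic:", r$id) else r$inchi,
           n_chiral_centers = r$n_centers,
           center_info = as.character(jsonlite::toJSON(centers,
                                                       auto_unbox = TRUE)),
           rot_355 = r$rotations[["355"]],
           rot_589.3 = r$rotations[["589.3"]],
           rot_633 = r$rotations[["633"]]),
      stats::setNames(as.list(feats), fcols))
  })
  df <- do.call(rbind, lapply(rows, function(x) as.data.frame(x, check.names = FALSE)))
  utils::write.csv(df, file.path(dir, "records.csv"), row.names = FALSE)
  manifest <- list(
    format = "ohecc-archive-v1",
    records = "records.csv",
    fields = list(index = "index", inchi = "inchi",
                  n_chiral_centers = "n_chiral_centers",
                  center_info = "center_info",
                  rotations = list(`355` = "rot_355", `589.3` = "rot_589.3",
                                   `633` = "rot_633"),
                  ohecc = list(prefix = "f", max_atoms = max_atoms,
                               vocab = as.list(vocab))))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Load an archive of molecule records
#'
#' Reads a schema-manifest archive written by [write_orqm9()] (or any
#' archive with a compatible `manifest.yaml` describing its columns).
#' Missing optional fields are tolerated; records always carry whatever
#' fields were present.
#'
#' @param dir Archive directory containing `manifest.yaml`.
#' @return List of records with fields `index`, `inchi`, `n_centers`,
#'   `labels`, `rotations` and `features`.
#' @export
load_orqm9 <- function(dir) {
  mf_path <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf_path)) stop("archive manifest not found: ", mf_path)
  mf <- yaml::read_yaml(mf_path)
  csv <- file.path(dir, mf$records)
  if (!file.exists(csv)) stop("archive records file not found: ", csv)
  df <- utils::read.csv(csv, check.names = FALSE)
  fl <- mf$fields
  need <- function(col) {
    if (!is.null(col) && !col %in% names(df)) {
      stop("archive is missing the '", col, "' column declared by its manifest")
    }
    col
  }
  fcols <- grep(paste0("^", fl$ohecc$prefix, "[0-9]+$"), names(df),
                value = TRUE)
  fcols <- fcols[order(as.integer(sub(fl$ohecc$prefix, "", fcols)))]
  lapply(seq_len(nrow(df)), function(i) {
    centers <- tryCatch(
      jsonlite::fromJSON(df[[need(fl$center_info)]][i],
                         simplifyDataFrame = FALSE),
      error = function(e) list())
    rot <- vapply(mf$fields$rotations, function(col) {
      if (col %in% names(df)) df[[col]][i] else NA_real_
    }, numeric(1))
    list(id = as.character(df[[need(fl$index)]][i]),
         index = df[[need(fl$index)]][i],
         inchi = df[[need(fl$inchi)]][i],
         n_centers = df[[need(fl$n_chiral_centers)]][i],
         labels = vapply(centers, function(s) as.character(s$label),
                         character(1)),
         rotations = rot,
         features = as.numeric(df[i, fcols]))
  })
}

#' Specification of a classification task
#'
#' The six chirality classification problems: `existence` (no chiral
#' center vs at least one), `zero_vs_one` (0 vs exactly 1), `R_vs_S`
#' (CIP label within single-center molecules), `sign_one_center` and
#' `sign_all` (sign of the 589.3 nm rotation, for single-center and all
#' molecules), and `n_centers_multiclass` (0-4 centers). Classes are
#' balanced by seeded downsampling to `per_class` before a stratified
#' train/test split.
#'
#' @param task Task name (see above).
#' @param per_class Samples drawn per class (without replacement).
#' @param split Training fraction, in (0, 1); default the standard 80-20.
#' @param seed Integer seed controlling sampling and splitting.
#' @param size_filter `"none"`, `"small"` (at most `size_threshold` atoms)
#'   or `"large"` (more).
#' @param size_threshold Atom-count boundary between small and large
#'   molecules.
#' @return A `task_spec` list.
#' @export
task_spec <- function(task = c("existence", "zero_vs_one", "R_vs_S",
                               "sign_one_center", "sign_all",
                               "n_centers_multiclass"),
                      per_class, split = 0.8, seed = 1L,
                      size_filter = c("none", "small", "large"),
                      size_threshold = 17L) {
  task <- match.arg(task)
  stopifnot(per_class >= 1, split > 0, split < 1)
  structure(list(task = task, per_class = as.integer(per_class),
                 split = split, seed = as.integer(seed),
                 size_filter = match.arg(size_filter),
                 size_threshold = as.integer(size_threshold)),
            class = "task_spec")
}

task_classes <- function(task) {
  switch(task,
         existence = c("0", "1+"),
         zero_vs_one = c("0", "1"),
         R_vs_S = c("R", "S"),
         sign_one_center = c("-", "+"),
         sign_all = c("-", "+"),
         n_centers_multiclass = c("0", "1", "2", "3", "4"))
}

# label each record for the task; NA = ineligible. Sign tasks strictly
# exclude zero-valued rotations (counted for the exclusion log).
task_label <- function(records, task) {
  n_centers <- vapply(records, function(r) as.numeric(r$n_centers), numeric(1))
  switch(
    task,
    existence = ifelse(n_centers == 0, "0", "1+"),
    zero_vs_one = ifelse(n_centers == 0, "0",
                         ifelse(n_centers == 1, "1", NA_character_)),
    R_vs_S = vapply(records, function(r) {
      if (as.numeric(r$n_centers) == 1 && length(r$labels) == 1L) {
        r$labels[[1]]
      } else NA_character_
    }, character(1)),
    sign_one_center = vapply(records, function(r) {
      v <- r$rotations[["589.3"]]
      if (as.numeric(r$n_centers) == 1 && is.finite(v) && v != 0) {
        if (v > 0) "+" else "-"
      } else NA_character_
    }, character(1)),
    sign_all = vapply(records, function(r) {
      v <- r$rotations[["589.3"]]
      if (is.finite(v) && v != 0) { if (v > 0) "+" else "-" }
      else NA_character_
    }, character(1)),
    n_centers_multiclass = ifelse(n_centers <= 4, as.character(n_centers),
                                  NA_character_)
  )
}

#' Build a balanced, split classification task
#'
#' Labels the records for the requested task, applies the size filter,
#' downsamples every class to exactly `spec$per_class` (seeded, without
#' replacement), pools, and makes a seeded label-stratified train/test
#' split. Records excluded for a zero rotation value in a sign task are
#' counted in the `excluded_zero_rotation` attribute.
#'
#' @param records List of records (from [make_dataset()] or
#'   [load_orqm9()]).
#' @param spec A [task_spec()].
#' @param vocab,max_atoms OHECC shape used to featurize records.
#' @return A `task_data` list: `x_train`, `y_train`, `x_test`, `y_test`
#'   (features are flattened OHECC rows; labels are factors over the task's
#'   class list in declaration order), `classes`, `ids_train`, `ids_test`
#'   and the spec.
#' @export
build_task <- function(records, spec, vocab = default_vocab(),
                       max_atoms = 27L) {
  classes <- task_classes(spec$task)
  labels <- task_label(records, spec$task)
  n_zero_excluded <- if (spec$task %in% c("sign_one_center", "sign_all")) {
    sum(vapply(records, function(r) {
      v <- r$rotations[["589.3"]]
      ok_class <- spec$task == "sign_all" || as.numeric(r$n_centers) == 1
      ok_class && is.finite(v) && v == 0
    }, logical(1)))
  } else 0L
  eligible <- which(!is.na(labels))
  if (spec$size_filter != "none") {
    sizes <- vapply(records[eligible], record_n_atoms, numeric(1),
                    vocab = vocab, max_atoms = max_atoms)
    keep <- if (spec$size_filter == "small") sizes <= spec$size_threshold
            else sizes > spec$size_threshold
    eligible <- eligible[keep]
  }
  by_class <- split(eligible, factor(labels[eligible], levels = classes))
  avail <- vapply(by_class, length, integer(1))
  short <- avail < spec$per_class
  if (any(short)) {
    stop("insufficient records for class(es) ",
         paste(sprintf("'%s' (need %d, have %d)", classes[short],
                       spec$per_class, avail[short]), collapse = ", "))
  }
  with_seed_(spec$seed, {
    sampled <- lapply(by_class, function(idx) {
      sort(idx[sample.int(length(idx), spec$per_class)])
    })
    n_train_per <- round(spec$split * spec$per_class)
    train_idx <- test_idx <- integer(0)
    for (cls in classes) {
      idx <- sampled[[cls]]
      tr <- sample.int(length(idx), n_train_per)
      train_idx <- c(train_idx, idx[tr])
      test_idx <- c(test_idx, idx[-tr])
    }
  })
  featurize <- function(idx) {
    x <- t(vapply(records[idx], record_features, numeric(max_atoms *
                                                           (3L + length(vocab))),
                  vocab = vocab, max_atoms = max_atoms))
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    x
  }
  ids <- vapply(records, function(r) as.character(r$id), character(1))
  out <- list(x_train = featurize(train_idx),
              y_train = factor(labels[train_idx], levels = classes),
              x_test = featurize(test_idx),
              y_test = factor(labels[test_idx], levels = classes),
              classes = classes,
              ids_train = ids[train_idx], ids_test = ids[test_idx],
              spec = spec)
  attr(out, "excluded_zero_rotation") <- n_zero_excluded
  class(out) <- "task_data"
  out
}

#' @export
print.task_data <- function(x, ...) {
  cat("<task_data '", x$spec$task, "': ", nrow(x$x_train), " train / ",
      nrow(x$x_test), " test, classes ", paste(x$classes, collapse = "/"),
      ">\n", sep = "")
  invisible(x)
}

#' Partition records by molecule size
#'
#' @param records List of records.
#' @param threshold Atom-count boundary: `small` holds molecules with at
#'   most `threshold` atoms, `large` the rest.
#' @param vocab,max_atoms OHECC shape assumed for feature-only records.
#' @return List with elements `small` and `large` (disjoint, exhaustive).
#' @export
size_partition <- function(records, threshold = 17L,
                           vocab = default_vocab(), max_atoms = 27L) {
  sizes <- vapply(records, record_n_atoms, numeric(1), vocab = vocab,
                  max_atoms = max_atoms)
  list(small = records[sizes <= threshold],
       large = records[sizes > threshold])
}
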