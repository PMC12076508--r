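#' One-hot encoded Cartesian coordinate (OHECC) matrix
#'
#' Encodes a molecule as a `max_atoms` x `(3 + length(vocab))` matrix: row i
#' holds the Cartesian coordinates of atom i followed by the one-hot encoding
#' of its element; rows beyond the molecule's atom count are zero padding.
#' At the defaults (27 atoms, H/C/N/O/F) the matrix is 27 x 8 and flattens to
#' a length-216 feature vector. Coordinates are used exactly as given — no
#' centering or alignment — so the encoding distinguishes enantiomers, unlike
#' isometry-invariant descriptors such as the Coulomb matrix.
#'
#' @param mol A [molecule()].
#' @param vocab Ordered element vocabulary; fixes the one-hot column order.
#' @param max_atoms Number of rows (padding capacity).
#' @return An `ohecc_matrix`: a numeric matrix with attributes `vocab` and
#'   `n_real_atoms`.
#' @export
encode_ohecc <- function(mol, vocab = default_vocab(), max_atoms = 27L) {
  n <- n_atoms(mol)
  if (n > max_atoms) {
    stop("molecule has ", n, " atoms but max_atoms is ", max_atoms)
  }
  bad <- setdiff(unique(mol$elements), vocab)
  if (length(bad)) {
    stop("element(s) outside encoding vocabulary: ",
         paste(bad, collapse = ", "))
  }
  m <- matrix(0, nrow = max_atoms, ncol = 3L + length(vocab))
  m[seq_len(n), 1:3] <- mol$coords
  m[cbind(seq_len(n), 3L + match(mol$elements, vocab))] <- 1
  structure(m, vocab = vocab, n_real_atoms = n, class = "ohecc_matrix")
}

#' @export
print.ohecc_matrix <- function(x, ...) {
  cat("<ohecc_matrix ", nrow(x), " x ", ncol(x), ", ",
      attr(x, "n_real_atoms"), " real atom rows, vocab ",
      paste(attr(x, "vocab"), collapse = ""), ">\n", sep = "")
  invisible(x)
}

#' Flatten an OHECC matrix to a feature vector
#'
#' Row-major flattening: the entry at row r, column c (1-based) lands at
#' index `(r - 1) * ncol + c`. At the default 27 x 8 shape the result has
#' length 216.
#'
#' @param m An `ohecc_matrix` (or any numeric matrix).
#' @return Numeric vector of length `nrow(m) * ncol(m)`.
#' @export
flatten_ohecc <- function(m) {
  as.vector(t(unclass(m)))
}

#' Coulomb matrix of a molecule
#'
#' The classic pairwise descriptor: diagonal entries `0.5 * Z_i^2.4`,
#' off-diagonal entries `Z_i * Z_j / |R_i - R_j|` with atomic numbers Z and
#' interatomic distances in Angstrom. The Coulomb matrix is invariant under
#' every isometry of the coordinates — rotations, translations and
#' reflections alike — so a molecule and its enantiomer have identical
#' Coulomb matrices. It is provided here as the counterexample motivating
#' the OHECC encoding, with no energy semantics claimed.
#'
#' @param mol A [molecule()].
#' @param min_distance Smallest allowed interatomic distance (Angstrom);
#'   closer pairs are treated as coincident atoms and raise an error.
#' @return A `coulomb_matrix`: symmetric n x n numeric matrix with attribute
#'   `atomic_numbers`.
#' @export
encode_coulomb <- function(mol, min_distance = 1e-6) {
  z <- atomic_number(mol$elements)
  n <- length(z)
  d <- as.matrix(stats::dist(mol$coords))
  off <- d[upper.tri(d)]
  if (n > 1L && any(off < min_distance)) {
    stop("coincident atoms: interatomic distance below ", min_distance, " A")
  }
  m <- tcrossprod(z) / ifelse(d > 0, d, 1)
  diag(m) <- 0.5 * z^2.4
  structure(m, atomic_numbers = z, class = "coulomb_matrix")
}

#' @export
print.coulomb_matrix <- function(x, ...) {
  cat("<coulomb_matrix ", nrow(x), " x ", ncol(x), ">\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Sorted Coulomb-matrix eigenvalue spectrum
#'
#' Eigenvalues of the Coulomb matrix sorted decreasingly. The spectrum is
#' invariant under simultaneous row/column permutation, so it gives an
#' atom-order-robust way to compare Coulomb matrices (e.g. of an enantiomer
#' pair whose files list atoms in different orders).
#'
#' @param cm A `coulomb_matrix` (or symmetric numeric matrix).
#' @return Numeric vector of eigenvalues, decreasing.
#' @export
coulomb_spectrum <- function(cm) {
  sort(eigen(unclass(cm), symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

#' Encode a list of molecules as a feature matrix
#'
#' Convenience wrapper: one flattened OHECC row per molecule.
#'
#' @param molecules List of [molecule()] objects.
#' @inheritParams encode_ohecc
#' @return Numeric matrix, `length(molecules)` x `max_atoms * (3 + |vocab|)`,
#'   with molecule ids as row names where available.
#' @export
encode_dataset <- function(molecules, vocab = default_vocab(),
                           max_atoms = 27L) {
  x <- t(vapply(molecules,
                function(m) flatten_ohecc(encode_ohecc(m, vocab, max_atoms)),
                numeric(max_atoms * (3L + length(vocab)))))
  ids <- vapply(molecules, function(m) m$id, character(1))
  if (any(nzchar(ids))) rownames(x) <- ids
  x
}
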