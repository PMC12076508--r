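# Atomic numbers for the elements this package can encounter. The default
# encoding vocabulary is the H/C/N/O/F subset, but the parser is lenient and
# other light elements are tolerated (they simply cannot be one-hot encoded).
ATOMIC_NUMBERS <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Br = 35, I = 53
)

#' Default element vocabulary
#'
#' Ordered element vocabulary used for one-hot encoding: hydrogen, carbon,
#' nitrogen, oxygen, fluorine. The order fixes the one-hot column order of
#' [encode_ohecc()].
#'
#' @return Character vector of element symbols.
#' @export
default_vocab <- function() c("H", "C", "N", "O", "F")

#' Atomic number lookup
#'
#' @param elements Character vector of element symbols.
#' @return Integer vector of atomic numbers.
#' @export
atomic_number <- function(elements) {
  z <- ATOMIC_NUMBERS[elements]
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(elements[is.na(z)]), collapse = ", "))
  }
  unname(as.integer(z))
}

#' Construct a molecule
#'
#' A molecule is an ordered list of atoms: element symbols plus Cartesian
#' coordinates in Angstrom. Atom order is significant and preserved by all
#' operations in this package; no centering or re-alignment is ever applied.
#'
#' @param elements Character vector of element symbols, one per atom.
#' @param coords Numeric n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param id Optional identifier string.
#' @param bonds Optional adjacency list: a list of integer vectors, one per
#'   atom, giving the indices of bonded atoms.
#' @param stereocenters Optional list of stereocenter records (see
#'   [find_stereocenters()]).
#' @param n_chiral_centers Optional integer count of chiral centers.
#' @param rotations Optional named numeric vector of specific rotations
#'   (degrees dm^-1 (g/cm^3)^-1), named by wavelength in nm
#'   (e.g. `"589.3"`).
#' @return An object of class `molecule`.
#' @export
molecule <- function(elements, coords, id = "", bonds = NULL,
                     stereocenters = NULL, n_chiral_centers = NULL,
                     rotations = NULL) {
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3L) {
    stop("coords must be an n x 3 matrix")
  }
  storage.mode(coords) <- "double"
  if (length(elements) != nrow(coords)) {
    stop("length(elements) must equal nrow(coords)")
  }
  if (length(elements) < 1L) stop("a molecule needs at least one atom")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (!is.null(stereocenters) && !is.null(n_chiral_centers) &&
      length(stereocenters) != n_chiral_centers) {
    stop("n_chiral_centers (", n_chiral_centers,
         ") does not match length(stereocenters) (",
         length(stereocenters), ")")
  }
  structure(
    list(elements = as.character(elements), coords = coords, id = id,
         bonds = bonds, stereocenters = stereocenters,
         n_chiral_centers = n_chiral_centers, rotations = rotations),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule", if (nzchar(x$id)) paste0(" '", x$id, "'"), ": ",
      length(x$elements), " atoms (",
      paste(names(sort(table(x$elements), decreasing = TRUE)),
            sort(table(x$elements), decreasing = TRUE),
            sep = "", collapse = " "),
      ")>\n", sep = "")
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol A `molecule`.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) length(mol$elements)

#' Read molecules from XYZ text
#'
#' Parses standard XYZ records (count line, comment line, then one
#' `element x y z` line per atom). Multiple concatenated records are
#' returned as separate molecules. The comment line, when non-empty, is
#' stored as the molecule id.
#'
#' @param source Path to an XYZ file, or a character scalar containing XYZ
#'   text (recognised by embedded newlines or a nonexistent path).
#' @param strict If `TRUE`, an element outside `vocab` is an error; the
#'   default is lenient (the atom is kept and flagged in the
#'   `unknown_elements` attribute of the result).
#' @param vocab Element vocabulary used for the strict check.
#' @return List of `molecule` objects.
#' @export
read_xyz <- function(source, strict = FALSE, vocab = default_vocab()) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- strsplit(paste(source, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  mols <- list()
  unknown <- character()
  i <- 1L
  # skip trailing blank lines between records but respect blank comment lines
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) {
      stop("XYZ parse error at line ", i, ": expected an atom count, got '",
           lines[i], "'")
    }
    if (i + 1L + n > length(lines)) {
      stop("XYZ parse error at line ", i, ": record declares ", n,
           " atoms but the file ends early")
    }
    comment <- if (i + 1L <= length(lines)) trimws(lines[i + 1L]) else ""
    elements <- character(n)
    coords <- matrix(0, n, 3L)
    for (k in seq_len(n)) {
      ln <- i + 1L + k
      parts <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
      if (length(parts) < 4L) {
        stop("XYZ parse error at line ", ln,
             ": expected 'element x y z', got '", lines[ln], "'")
      }
      xyz <- suppressWarnings(as.numeric(parts[2:4]))
      if (anyNA(xyz)) {
        stop("XYZ parse error at line ", ln, ": non-numeric coordinate")
      }
      elements[k] <- parts[1]
      coords[k, ] <- xyz
    }
    bad <- setdiff(unique(elements), vocab)
    if (length(bad) && strict) {
      stop("element(s) outside vocabulary in record starting at line ", i,
           ": ", paste(bad, collapse = ", "))
    }
    unknown <- union(unknown, bad)
    mols[[length(mols) + 1L]] <- molecule(elements, coords, id = comment)
    i <- i + 2L + n
  }
  if (length(unknown)) attr(mols, "unknown_elements") <- unknown
  mols
}

#' Write molecules as XYZ text
#'
#' @param molecules A `molecule` or list of molecules.
#' @param path Optional output file; when `NULL` the text is returned only.
#' @param digits Fixed number of decimal places for coordinates.
#' @return The XYZ text, invisibly when written to a file.
#' @export
write_xyz <- function(molecules, path = NULL, digits = 6) {
  if (inherits(molecules, "molecule")) molecules <- list(molecules)
  recs <- vapply(molecules, function(m) {
    if (!all(is.finite(m$coords))) stop("non-finite coordinate in molecule '",
                                        m$id, "'")
    fmt <- paste0("%.", digits, "f")
    body <- paste(sprintf("%s %s %s %s", m$elements,
                          sprintf(fmt, m$coords[, 1]),
                          sprintf(fmt, m$coords[, 2]),
                          sprintf(fmt, m$coords[, 3])),
                  collapse = "\n")
    paste0(length(m$elements), "\n", m$id, "\n", body)
  }, character(1))
  text <- paste0(paste(recs, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", text), path)
    return(invisible(text))
  }
  text
}

#' Apply a proper rigid motion to a molecule
#'
#' Maps every position p to `R p + t`. Elements, atom order and annotations
#' are unchanged. Improper operations (determinant -1) are rejected; use
#' [reflect_molecule()] for mirror images.
#'
#' @param mol A `molecule`.
#' @param rotation 3 x 3 proper orthogonal matrix (det +1 within 1e-8).
#' @param translation Length-3 numeric vector.
#' @return The transformed `molecule`.
#' @export
transform_molecule <- function(mol, rotation = diag(3),
                               translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3 x 3")
  if (abs(det(rotation) - 1) > 1e-8 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stop("rotation must be proper orthogonal (det +1); ",
         "use reflect_molecule() for improper operations")
  }
  out <- mol
  out$coords <- sweep(mol$coords %*% t(rotation), 2, translation, "+")
  out
}

#' Reflect a molecule through a plane
#'
#' Mirrors all positions through the plane through the origin with the given
#' normal. Atom order and elements are unchanged. This is the improper
#' isometry relating a chiral molecule to its enantiomer.
#'
#' @param mol A `molecule`.
#' @param plane_normal Nonzero length-3 normal vector of the mirror plane.
#' @return The reflected `molecule`.
#' @export
reflect_molecule <- function(mol, plane_normal = c(1, 0, 0)) {
  n <- as.numeric(plane_normal)
  nn <- sqrt(sum(n^2))
  if (!is.finite(nn) || nn == 0) stop("plane normal must be nonzero")
  n <- n / nn
  H <- diag(3) - 2 * tcrossprod(n)   # Householder reflection
  out <- mol
  out$coords <- mol$coords %*% t(H)
  out
}

#' Interatomic distance matrix
#' @param mol A `molecule`.
#' @return n x n symmetric matrix of Euclidean distances (Angstrom).
#' @export
distance_matrix <- function(mol) {
  as.matrix(stats::dist(mol$coords))
}
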