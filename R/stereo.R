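# Geometric stereocenter detection and R/S labeling for small acyclic
# molecules over the H/C/N/O/F vocabulary. Priorities use a simplified
# sphere-by-sphere comparison of atomic-number multisets (no isotopes, no
# double-bond duplication, none of the higher CIP rules); handedness is the
# sign of the tetrahedral volume spanned by the top three priorities.

#' Rank the four substituents of a candidate stereocenter
#'
#' Simplified priority ranking: each branch rooted at a neighbor of the
#' center is explored breadth-first (never re-entering the center), and at
#' each sphere the branches are compared by their sorted atomic-number
#' multisets, highest first; the first differing sphere decides. Two
#' branches identical through `max_depth` spheres tie, marking the center
#' as non-stereogenic. This resolves all acyclic substituents over
#' H/C/N/O/F that differ in constitution; it is not full CIP (isotopes,
#' duplicated atoms for multiple bonds, and like/unlike rules are out of
#' scope).
#'
#' @param mol A [molecule()].
#' @param bonds Adjacency list: `bonds[[i]]` holds the atom indices bonded
#'   to atom i.
#' @param center Index of the candidate center; must have exactly 4 bonds.
#' @param max_depth Deepest sphere compared.
#' @return A list with `order` (the 4 neighbor indices, highest priority
#'   first) and `tie` (logical: `TRUE` when two branches are
#'   indistinguishable).
#' @export
rank_substituents <- function(mol, bonds, center, max_depth = 6L) {
  nb <- bonds[[center]]
  if (length(nb) != 4L) {
    stop("atom ", center, " has ", length(nb),
         " bonded neighbors; a tetrahedral center needs exactly 4")
  }
  z <- atomic_number(mol$elements)
  # spheres[[b]][[k]]: sorted-decreasing atomic numbers at BFS depth k of
  # branch b (depth 1 = the neighbor itself), never crossing the center.
  spheres <- lapply(nb, function(root) {
    out <- vector("list", max_depth)
    frontier <- root
    visited <- c(center, root)
    for (k in seq_len(max_depth)) {
      out[[k]] <- sort(z[frontier], decreasing = TRUE)
      nxt <- setdiff(unique(unlist(bonds[frontier])), visited)
      if (!length(nxt)) {
        if (k < max_depth) out[(k + 1L):max_depth] <- list(numeric(0))
        break
      }
      visited <- c(visited, nxt)
      frontier <- nxt
    }
    out
  })
  # pairwise branch comparison: lexicographic over spheres, each sphere
  # compared elementwise on the sorted multiset (longer multiset wins a
  # shared prefix: more substituents outrank fewer at equal atoms).
  cmp <- function(a, b) {
    for (k in seq_len(max_depth)) {
      sa <- a[[k]]; sb <- b[[k]]
      l <- min(length(sa), length(sb))
      if (l > 0) {
        diff <- sa[seq_len(l)] - sb[seq_len(l)]
        nz <- which(diff != 0)
        if (length(nz)) return(sign(diff[nz[1]]))
      }
      if (length(sa) != length(sb)) return(sign(length(sa) - length(sb)))
    }
    0L
  }
  n <- 4L
  wins <- integer(n)
  tie <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      c_ij <- cmp(spheres[[i]], spheres[[j]])
      if (c_ij == 0L) tie <- TRUE
      wins[i] <- wins[i] + (c_ij > 0L)
      wins[j] <- wins[j] + (c_ij < 0L)
    }
  }
  list(order = nb[order(wins, decreasing = TRUE)], tie = tie)
}

#' Assign R/S handedness to a ranked stereocenter
#'
#' Let u1, u2, u3 be the unit vectors from the center atom to the
#' priority-1, -2 and -3 neighbors. The label is decided by the sign of the
#' scalar triple product `s = u1 . (u2 x u3)`: `s < 0` is R (priorities
#' 1 -> 2 -> 3 run clockwise when viewed from the side opposite priority 4),
#' `s > 0` is S. The sign-to-label convention was fixed once by validating
#' both parities of a constructed reference center against an independent
#' CIP implementation and is frozen here.
#'
#' @param mol A [molecule()].
#' @param center Index of the center atom.
#' @param priorities The 4 neighbor indices in decreasing priority order.
#' @param volume_tol Minimal tetrahedral volume (A^3) below which the
#'   geometry is rejected as degenerate.
#' @return `"R"` or `"S"`.
#' @export
assign_handedness <- function(mol, center, priorities, volume_tol = 1e-6) {
  if (length(priorities) != 4L || anyDuplicated(priorities)) {
    stop("priorities must be 4 distinct neighbor indices")
  }
  v <- mol$coords[priorities[1:3], , drop = FALSE] -
    matrix(mol$coords[center, ], 3L, 3L, byrow = TRUE)
  vol <- abs(det(v)) / 6
  if (!is.finite(vol) || vol < volume_tol) {
    stop("degenerate (near-coplanar) geometry at center ", center,
         ": tetrahedral volume ", format(vol), " A^3")
  }
  u <- v / sqrt(rowSums(v^2))
  s <- det(u)   # u1 . (u2 x u3)
  if (s < 0) "R" else "S"
}

#' Find and label all tetrahedral stereocenters
#'
#' Scans every atom with exactly four bonds, ranks its substituents with
#' [rank_substituents()] and labels tie-free, geometrically non-degenerate
#' centers with [assign_handedness()]. Candidates skipped for ties or
#' degenerate geometry are recorded in the `skipped` attribute.
#'
#' @param mol A [molecule()].
#' @param bonds Adjacency list; defaults to the molecule's own bond list.
#' @param max_depth Passed to [rank_substituents()].
#' @return List of stereocenter records, each with fields `center`,
#'   `neighbors`, `priorities` (neighbor indices, rank 1 first) and `label`.
#' @export
find_stereocenters <- function(mol, bonds = mol$bonds, max_depth = 6L) {
  if (is.null(bonds)) stop("a bond adjacency list is required")
  centers <- list()
  skipped <- list()
  for (i in seq_along(mol$elements)) {
    if (length(bonds[[i]]) != 4L) next
    r <- rank_substituents(mol, bonds, i, max_depth = max_depth)
    if (r$tie) {
      skipped[[length(skipped) + 1L]] <- list(center = i, reason = "tie")
      next
    }
    label <- tryCatch(assign_handedness(mol, i, r$order), error = function(e) NULL)
    if (is.null(label)) {
      skipped[[length(skipped) + 1L]] <- list(center = i,
                                              reason = "degenerate geometry")
      next
    }
    centers[[length(centers) + 1L]] <- list(center = i,
                                            neighbors = bonds[[i]],
                                            priorities = r$order,
                                            label = label)
  }
  if (length(skipped)) attr(centers, "skipped") <- skipped
  centers
}

#' Stereocenter labels of a molecule
#'
#' @param centers A list of stereocenter records.
#' @return Character vector of `"R"`/`"S"` labels, in center order.
#' @export
stereo_labels <- function(centers) {
  vapply(centers, function(s) s$label, character(1))
}

#' Write a stereocenter table as CSV
#'
#' @param records Named list: molecule id -> list of stereocenter records.
#' @param path Output CSV path (`mol_id,center_index,label`).
#' @return The data frame, invisibly.
#' @export
write_stereo_csv <- function(records, path) {
  rows <- do.call(rbind, lapply(names(records), function(id) {
    cs <- records[[id]]
    if (!length(cs)) return(NULL)
    data.frame(mol_id = id,
               center_index = vapply(cs, function(s) s$center, numeric(1)),
               label = stereo_labels(cs))
  }))
  if (is.null(rows)) {
    rows <- data.frame(mol_id = character(), center_index = numeric(),
                       label = character())
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(rows)
}
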