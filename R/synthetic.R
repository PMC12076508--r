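# Seeded generator of labeled 3D toy molecules over the H/C/N/O/F
# vocabulary. Molecules are chains of tetrahedral carbon stereocenters with
# substituents chosen so every priority ranking is tie-free by construction;
# intended R/S labels are realized geometrically, making the generator its
# own oracle for the stereo module.

## ---- geometry helpers -------------------------------------------------

# ideal tetrahedral unit directions
tetra_dirs <- function() {
  matrix(c(1, 1, 1,
           1, -1, -1,
           -1, 1, -1,
           -1, -1, 1), 4L, 3L, byrow = TRUE) / sqrt(3)
}

unitize <- function(v) v / sqrt(sum(v^2))

# deterministic unit vector perpendicular to v
perp_vector <- function(v) {
  a <- if (abs(v[1]) <= abs(v[2]) && abs(v[1]) <= abs(v[3])) c(1, 0, 0)
  else if (abs(v[2]) <= abs(v[3])) c(0, 1, 0) else c(0, 0, 1)
  unitize(a - sum(a * v) * v)
}

# rotation matrix mapping unit vector a onto unit vector b (Rodrigues)
rotation_from_to <- function(a, b) {
  a <- unitize(a); b <- unitize(b)
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {           # antiparallel: rotate pi about any perp
    p <- perp_vector(a)
    return(2 * tcrossprod(p) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2],
                 v[3], 0, -v[1],
                 -v[2], v[1], 0), 3L, 3L, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Uniform random rotation matrix
#'
#' Draws a rotation uniformly from SO(3) via a normalized random quaternion.
#' Uses the current RNG state.
#'
#' @return A 3 x 3 proper orthogonal matrix.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

# directions of the remaining bonds at an attached atom whose back-bond
# points along -d: tilted 109.47 deg from -d, at azimuths phase + k*360/n
fan_dirs <- function(d, n, phase = 0) {
  e1 <- perp_vector(d)
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  ang <- phase + 2 * pi * (seq_len(n) - 1) / n
  t(vapply(ang, function(a) {
    (1 / 3) * d + sqrt(8) / 3 * (cos(a) * e1 + sin(a) * e2)
  }, numeric(3)))
}

## ---- substituent group library ---------------------------------------

# Bond lengths (Angstrom) used for idealized geometry.
BOND_LEN <- c(`C-H` = 1.09, `C-C` = 1.54, `C-N` = 1.47, `C-O` = 1.43,
              `C-F` = 1.35, `O-H` = 0.96, `N-H` = 1.01)

# Build the atoms of a substituent group attached at position `pos` along
# outward unit direction `d`. Returns elements, coords (rows = atoms, first
# atom is the attachment root) and intra-group bond pairs (local indices).
build_group <- function(group, pos, d) {
  g <- function(elements, coords, bonds) {
    list(elements = elements, coords = coords, bonds = bonds)
  }
  switch(
    group,
    H = g("H", matrix(pos + BOND_LEN["C-H"] * d, 1L), list()),
    F = g("F", matrix(pos + BOND_LEN["C-F"] * d, 1L), list()),
    OH = {
      o <- pos + BOND_LEN["C-O"] * d
      h <- o + BOND_LEN["O-H"] * fan_dirs(d, 1L)[1, ]
      g(c("O", "H"), rbind(o, h), list(c(1L, 2L)))
    },
    NH2 = {
      n <- pos + BOND_LEN["C-N"] * d
      w <- fan_dirs(d, 2L)
      g(c("N", "H", "H"),
        rbind(n, n + BOND_LEN["N-H"] * w[1, ], n + BOND_LEN["N-H"] * w[2, ]),
        list(c(1L, 2L), c(1L, 3L)))
    },
    CH3 = {
      c1 <- pos + BOND_LEN["C-C"] * d
      w <- fan_dirs(d, 3L)
      g(c("C", "H", "H", "H"),
        rbind(c1,
              c1 + BOND_LEN["C-H"] * w[1, ],
              c1 + BOND_LEN["C-H"] * w[2, ],
              c1 + BOND_LEN["C-H"] * w[3, ]),
        list(c(1L, 2L), c(1L, 3L), c(1L, 4L)))
    },
    CH2F = {
      c1 <- pos + BOND_LEN["C-C"] * d
      w <- fan_dirs(d, 3L)
      g(c("C", "F", "H", "H"),
        rbind(c1,
              c1 + BOND_LEN["C-F"] * w[1, ],
              c1 + BOND_LEN["C-H"] * w[2, ],
              c1 + BOND_LEN["C-H"] * w[3, ]),
        list(c(1L, 2L), c(1L, 3L), c(1L, 4L)))
    },
    CH2OH = {
      c1 <- pos + BOND_LEN["C-C"] * d
      w <- fan_dirs(d, 3L)
      o <- c1 + BOND_LEN["C-O"] * w[1, ]
      h <- o + BOND_LEN["O-H"] * fan_dirs(w[1, ], 1L, phase = pi)[1, ]
      g(c("C", "O", "H", "H", "H"),
        rbind(c1, o, h,
              c1 + BOND_LEN["C-H"] * w[2, ],
              c1 + BOND_LEN["C-H"] * w[3, ]),
        list(c(1L, 2L), c(2L, 3L), c(1L, 4L), c(1L, 5L)))
    },
    stop("unknown substituent group: ", group)
  )
}

## ---- chain templates ---------------------------------------------------

# Per-center substituent plans for chains of 1..4 stereocenters. Each
# center lists its local groups in decreasing priority; "@" marks where the
# chain bond to the previous / next center ranks. The plans were chosen so
# that every center's four branches differ within two comparison spheres
# (tie-free by construction) and the whole chain fits in 27 atoms.
chain_plan <- function(k) {
  switch(as.character(k),
    `1` = list(list(locals = c("F", "OH", "NH2", "H"),
                    priority = c("F", "OH", "NH2", "H"))),
    `2` = list(
      list(locals = c("F", "OH", "NH2"),
           priority = c("F", "OH", "NH2", "next")),
      list(locals = c("F", "OH", "NH2"),
           priority = c("F", "OH", "NH2", "prev"))),
    `3` = list(
      list(locals = c("F", "OH", "NH2"),
           priority = c("F", "OH", "NH2", "next")),
      list(locals = c("F", "OH"),
           priority = c("F", "OH", "prev", "next")),
      list(locals = c("OH", "NH2", "CH3"),
           priority = c("OH", "NH2", "prev", "CH3"))),
    `4` = list(
      list(locals = c("F", "OH", "NH2"),
           priority = c("F", "OH", "NH2", "next")),
      list(locals = c("F", "OH"),
           priority = c("F", "OH", "prev", "next")),
      list(locals = c("F", "NH2"),
           priority = c("F", "NH2", "prev", "next")),
      list(locals = c("OH", "NH2", "CH3"),
           priority = c("OH", "NH2", "prev", "CH3"))),
    stop("chain templates cover 1..4 stereocenters, got ", k)
  )
}

# achiral templates: a candidate tetrahedral carbon with two identical
# substituents, so every ranking ties
ACHIRAL_TEMPLATES <- list(c("F", "F", "OH", "NH2"),
                          c("H", "H", "OH", "F"),
                          c("H", "H", "NH2", "CH3"))

## ---- configuration -----------------------------------------------------

#' Generator configuration
#'
#' Study-condition defaults for the synthetic molecule generator: up to 27
#' atoms over H/C/N/O/F, 0-4 tetrahedral stereocenters, idealized bond
#' geometry with a small positional jitter, and a signed surrogate rotation
#' whose sign is determined by the R/S configuration plus Gaussian noise.
#'
#' @param max_atoms Capacity of the downstream OHECC encoding.
#' @param vocab Element vocabulary.
#' @param jitter_sd Standard deviation (Angstrom) of isotropic positional
#'   jitter added to the ideal geometry.
#' @param orientation `"standard"` delivers each molecule in a deterministic
#'   canonical frame (charge-weighted centroid at the origin, principal
#'   axes), the way optimized geometries are deposited by quantum-chemistry
#'   programs; `"random"` leaves the molecule in a uniformly random
#'   orientation with a Gaussian translation.
#' @param translation_sd Standard deviation (Angstrom) per coordinate of the
#'   random translation (only visible under `orientation = "random"`).
#' @param rotation_weight Per-center weight w of the surrogate rotation
#'   `sum_k s_k w + noise`, with s_k = +1 for R and -1 for S.
#' @param rotation_noise_sd Standard deviation of the surrogate-rotation
#'   noise term.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(max_atoms = 27L, vocab = default_vocab(),
                             jitter_sd = 0.02,
                             orientation = c("standard", "random"),
                             translation_sd = 0.5,
                             rotation_weight = 10,
                             rotation_noise_sd = 1) {
  stopifnot(max_atoms >= 8L, jitter_sd >= 0, translation_sd >= 0,
            rotation_noise_sd >= 0)
  structure(list(max_atoms = as.integer(max_atoms), vocab = vocab,
                 jitter_sd = jitter_sd,
                 orientation = match.arg(orientation),
                 translation_sd = translation_sd,
                 rotation_weight = rotation_weight,
                 rotation_noise_sd = rotation_noise_sd),
            class = "generator_config")
}

# run code under a temporary RNG state seeded with `seed` (NULL = current)
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# canonical frame: charge-weighted centroid at origin, principal axes of the
# charge-weighted covariance as coordinate axes. Axis signs are fixed by the
# weighted third moment along each of the first two axes, and the third axis
# completes a right-handed frame, so the map is always a proper rigid motion
# (chirality is preserved).
canonical_orientation <- function(coords, z) {
  w <- z / sum(z)
  ctr <- colSums(coords * w)
  x <- sweep(coords, 2, ctr)
  cov <- crossprod(x * sqrt(w))
  ev <- eigen(cov, symmetric = TRUE)
  a1 <- ev$vectors[, 1]; a2 <- ev$vectors[, 2]
  s1 <- sum(w * (x %*% a1)^3); s2 <- sum(w * (x %*% a2)^3)
  if (s1 < 0) a1 <- -a1
  if (s2 < 0) a2 <- -a2
  a3 <- c(a1[2] * a2[3] - a1[3] * a2[2],
          a1[3] * a2[1] - a1[1] * a2[3],
          a1[1] * a2[2] - a1[2] * a2[1])
  x %*% cbind(a1, a2, a3)
}

## ---- molecule construction ---------------------------------------------

#' Generate one labeled toy molecule
#'
#' Builds a chain of `n_centers` tetrahedral carbon stereocenters (0 gives
#' an achiral molecule whose candidate center carries two identical
#' substituents). Each stereocenter's four branches sit at ideal
#' tetrahedral angles; the intended R/S label, drawn uniformly unless
#' given, is realized by the placement parity of the branches. Positions
#' get isotropic Gaussian jitter, a random proper rigid motion is applied,
#' and the result is expressed per `config$orientation`. Atom append order
#' is fixed by the template (never by geometry), so the R- and S-forms of a
#' template differ only in coordinates.
#'
#' @param n_centers Number of stereocenters, 0 to 4.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param config A [generator_config()].
#' @param labels Optional character vector of intended labels
#'   (`"R"`/`"S"`), length `n_centers`; drawn uniformly when `NULL`.
#' @return A [molecule()] with `bonds`, ground-truth `stereocenters`
#'   (including the intended labels) and `n_chiral_centers` set.
#' @export
make_molecule <- function(n_centers, seed = NULL,
                          config = generator_config(), labels = NULL) {
  stopifnot(n_centers %in% 0:4)
  with_seed_(seed, {
    if (n_centers == 0L) {
      template <- ACHIRAL_TEMPLATES[[sample.int(length(ACHIRAL_TEMPLATES), 1L)]]
      built <- build_achiral(template)
    } else {
      if (is.null(labels)) {
        labels <- sample(c("R", "S"), n_centers, replace = TRUE)
      }
      stopifnot(length(labels) == n_centers, all(labels %in% c("R", "S")))
      built <- build_chain(n_centers, labels)
    }
    if (length(built$elements) > config$max_atoms) {
      stop("generated molecule exceeds max_atoms capacity (",
           length(built$elements), " > ", config$max_atoms, ")")
    }
    coords <- built$coords
    if (config$jitter_sd > 0) {
      coords <- coords + matrix(stats::rnorm(length(coords), 0,
                                             config$jitter_sd),
                                nrow(coords), 3L)
    }
    rot <- random_rotation()
    coords <- coords %*% t(rot) +
      matrix(stats::rnorm(3, 0, config$translation_sd),
             nrow(coords), 3L, byrow = TRUE)
    if (config$orientation == "standard") {
      coords <- canonical_orientation(coords, atomic_number(built$elements))
    }
    molecule(built$elements, coords,
             id = built$id, bonds = built$bonds,
             stereocenters = built$stereocenters,
             n_chiral_centers = as.integer(n_centers))
  })
}

# assemble an achiral single-candidate-center molecule
build_achiral <- function(groups) {
  asm <- assembler()
  ci <- asm$add("C", c(0, 0, 0))
  dirs <- tetra_dirs()
  for (k in seq_len(4L)) {
    asm$attach(groups[k], ci, c(0, 0, 0), dirs[k, ])
  }
  c(asm$result(), list(id = paste0("achiral-", paste(groups, collapse = "")),
                       stereocenters = list()))
}

# assemble a chain of stereocenters realizing the intended labels
build_chain <- function(k, labels) {
  plan <- chain_plan(k)
  asm <- assembler()
  dirs0 <- tetra_dirs()
  centers <- integer(k)
  center_dirs <- vector("list", k)   # slot direction per branch name
  prev_dir <- NULL                   # direction prev -> this center
  pos <- c(0, 0, 0)
  truth <- vector("list", k)

  for (j in seq_len(k)) {
    p <- plan[[j]]
    ci <- asm$add("C", pos)
    centers[j] <- ci
    # orient this center's slot set: slot 4 points back along the chain
    if (is.null(prev_dir)) {
      dirs <- dirs0
      free <- 1:4
      fixed <- integer(0)
    } else {
      rot <- rotation_from_to(dirs0[4L, ], -prev_dir)
      dirs <- dirs0 %*% t(rot)
      free <- 1:3
      fixed <- 4L
    }
    # branch names in priority order; "prev"/"next" are chain bonds
    branches <- p$priority
    slot_of <- integer(4L)            # slot index per branch (priority order)
    if (length(fixed)) {
      bi <- match("prev", branches)
      slot_of[bi] <- fixed
      slot_of[setdiff(seq_len(4L), bi)] <- free
    } else {
      slot_of[] <- 1:4
    }
    # realized handedness: sign of det of the top-3 priority directions
    realized <- function() {
      u <- rbind(dirs[slot_of[1L], ], dirs[slot_of[2L], ], dirs[slot_of[3L], ])
      if (det(u) < 0) "R" else "S"
    }
    if (realized() != labels[j]) {
      # swap the placements of the two lowest-priority movable branches
      movable <- which(slot_of %in% setdiff(slot_of, fixed))
      sw <- utils::tail(movable, 2L)
      slot_of[sw] <- slot_of[rev(sw)]
    }
    # place local substituents; remember chain-out direction
    next_dir <- NULL
    neighbor_idx <- integer(4L)
    for (b in seq_len(4L)) {
      nm <- branches[b]
      d <- dirs[slot_of[b], ]
      if (nm == "prev") {
        neighbor_idx[b] <- centers[j - 1L]
      } else if (nm == "next") {
        next_dir <- d
        neighbor_idx[b] <- NA_integer_   # filled after next center exists
      } else {
        neighbor_idx[b] <- asm$attach(nm, ci, pos, d)
      }
    }
    truth[[j]] <- list(center = ci, priorities = neighbor_idx,
                       label = labels[j])
    center_dirs[[j]] <- next_dir
    if (j < k) {
      prev_dir <- next_dir
      pos <- pos + BOND_LEN["C-C"] * next_dir
    }
  }
  # chain bonds and deferred "next" neighbor indices
  for (j in seq_len(k)) {
    if (j < k) {
      asm$bond(centers[j], centers[j + 1L])
      truth[[j]]$priorities[is.na(truth[[j]]$priorities)] <- centers[j + 1L]
    }
    truth[[j]]$neighbors <- sort(truth[[j]]$priorities)
  }
  c(asm$result(),
    list(id = paste0("chiral-", k, "c-", paste(labels, collapse = "")),
         stereocenters = truth))
}

# mutable accumulator for atoms and bonds
assembler <- function() {
  elements <- character(0)
  coords <- matrix(numeric(0), 0L, 3L)
  pairs <- list()
  add <- function(el, pos) {
    elements[[length(elements) + 1L]] <<- el
    coords <<- rbind(coords, pos)
    length(elements)
  }
  bond <- function(i, j) pairs[[length(pairs) + 1L]] <<- c(i, j)
  attach <- function(group, center_idx, center_pos, dir) {
    gr <- build_group(group, center_pos, dir)
    base <- length(elements)
    for (i in seq_along(gr$elements)) add(gr$elements[i], gr$coords[i, ])
    bond(center_idx, base + 1L)
    for (bp in gr$bonds) bond(base + bp[1], base + bp[2])
    base + 1L   # index of the attachment root
  }
  result <- function() {
    n <- length(elements)
    adj <- rep(list(integer(0)), n)
    for (bp in pairs) {
      adj[[bp[1]]] <- c(adj[[bp[1]]], bp[2])
      adj[[bp[2]]] <- c(adj[[bp[2]]], bp[1])
    }
    rownames(coords) <- NULL
    list(elements = elements, coords = coords, bonds = adj)
  }
  list(add = add, bond = bond, attach = attach, result = result)
}

#' Generate an enantiomer pair
#'
#' Draws a chiral molecule (>= 1 stereocenter) and returns it together with
#' its mirror image (reflection through the yz plane). Atom order is
#' identical in the two molecules; every stereocenter label is flipped in
#' the second.
#'
#' @param n_centers Number of stereocenters (>= 1).
#' @param seed Integer seed.
#' @param config A [generator_config()].
#' @return List of two [molecule()] objects.
#' @export
make_enantiomer_pair <- function(n_centers = 1L, seed = NULL,
                                 config = generator_config()) {
  stopifnot(n_centers >= 1L)
  first <- make_molecule(n_centers, seed = seed, config = config)
  second <- reflect_molecule(first, c(1, 0, 0))
  second$id <- paste0(first$id, "-mirror")
  second$stereocenters <- lapply(first$stereocenters, function(s) {
    s$label <- if (s$label == "R") "S" else "R"
    s
  })
  list(first, second)
}

#' Surrogate optical rotation of a labeled molecule
#'
#' A learnable, chirality-determined stand-in for a computed specific
#' rotation: `alpha = sum_k s_k w_k + noise`, where `s_k` is +1 for an R
#' center and -1 for an S center, `w_k` the per-center weight and the noise
#' is Gaussian. Achiral molecules receive the noise term only, so their
#' sign is a fair coin for positive noise and exactly zero without noise.
#'
#' @param mol A [molecule()] whose `stereocenters` are set.
#' @param weights Per-center weight(s), recycled across centers.
#' @param noise_sd Noise standard deviation.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Signed numeric value.
#' @export
assign_surrogate_rotation <- function(mol, weights = 10, noise_sd = 1,
                                      seed = NULL) {
  labels <- stereo_labels(mol$stereocenters)
  with_seed_(seed, {
    s <- ifelse(labels == "R", 1, -1)
    w <- rep_len(weights, length(labels))
    sum(s * w) + if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
  })
}

#' Generate a labeled synthetic dataset
#'
#' Draws molecules with the requested stereocenter-count composition,
#' assigns each a surrogate rotation at the 589.3 nm tag, and returns them
#' as records consumable by [build_task()].
#'
#' @param counts Named integer vector: number of molecules per
#'   stereocenter count, e.g. `c("0" = 100, "1" = 100)`. Names must be in
#'   `"0"`..`"4"`.
#' @param seed Integer seed (mandatory: the dataset is defined by it).
#' @param config A [generator_config()].
#' @param noise_sd Surrogate-rotation noise passed to
#'   [assign_surrogate_rotation()]; defaults to the config value.
#' @return List of records; each record has `id`, `molecule`, `n_centers`,
#'   `labels` (R/S per center) and `rotations` (named by wavelength).
#' @export
make_dataset <- function(counts, seed, config = generator_config(),
                         noise_sd = config$rotation_noise_sd) {
  stopifnot(!is.null(names(counts)), all(names(counts) %in% as.character(0:4)))
  records <- vector("list", sum(counts))
  i <- 0L
  with_seed_(seed, {
    for (cls in names(counts)) {
      k <- as.integer(cls)
      for (r in seq_len(counts[[cls]])) {
        mol <- make_molecule(k, seed = NULL, config = config)
        rot <- assign_surrogate_rotation(mol, weights = config$rotation_weight,
                                         noise_sd = noise_sd, seed = NULL)
        mol$rotations <- c(`355` = rot * 2, `589.3` = rot,
                           `633` = rot * 0.9)
        i <- i + 1L
        mol$id <- sprintf("syn-%05d-%s", i, cls)
        records[[i]] <- list(id = mol$id, molecule = mol, n_centers = k,
                             labels = stereo_labels(mol$stereocenters),
                             rotations = mol$rotations)
      }
    }
  })
  records
}
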