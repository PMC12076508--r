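# Shared fixtures, all built in code.

# Reference stereocenter: fluoro(amino)(hydroxy)methane with substituents
# at ideal tetrahedral vertices. The (R)-configured coordinates below were
# validated once against an independent CIP implementation and frozen;
# priorities at the carbon are F > OH > NH2 > H.
ref_R_molecule <- function() {
  molecule(
    elements = c("C", "F", "O", "H", "N", "H", "H", "H"),
    coords = rbind(
      c(0.000000, 0.000000, 0.000000),    # C (center)
      c(0.779423, 0.779423, 0.779423),    # F
      c(-0.825611, 0.825611, -0.825611),  # O
      c(-1.379867, 1.379867, -1.379867),  # H (on O)
      c(0.848705, -0.848705, -0.848705),  # N
      c(1.588064, -1.335248, -1.335248),  # H (on N)
      c(1.524934, -1.173555, -1.524934),  # H (on N)
      c(-0.629312, -0.629312, 0.629312)), # H
    id = "ref-R",
    bonds = list(c(2L, 3L, 5L, 8L), 1L, c(1L, 4L), 3L,
                 c(1L, 6L, 7L), 5L, 5L, 1L))
}

# a plausible 10-atom methyloxirane-like geometry (C3H6O): structural
# shape only, not an optimized geometry
methyloxirane_molecule <- function() {
  ring_c1 <- c(0.000, 0.000, 0.000)
  ring_c2 <- c(1.470, 0.000, 0.000)
  ring_o <- c(0.735, 1.210, 0.000)
  methyl_c <- c(-0.770, -0.700, 1.100)
  molecule(
    elements = c("C", "C", "O", "C", "H", "H", "H", "H", "H", "H"),
    coords = rbind(
      ring_c1, ring_c2, ring_o, methyl_c,
      ring_c1 + c(-0.30, -0.90, -0.60),
      ring_c2 + c(0.60, -0.80, 0.50),
      ring_c2 + c(0.60, -0.30, -0.90),
      methyl_c + c(-1.00, -0.10, 0.30),
      methyl_c + c(-0.40, -1.00, 0.80),
      methyl_c + c(0.10, -1.20, 1.60)),
    id = "methyloxirane-like")
}

# tiny deterministic rigid motion fixtures
rot_z_90 <- function() matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)

expect_molecule_equal <- function(a, b, tol = 1e-8) {
  expect_identical(a$elements, b$elements)
  expect_lt(max(abs(a$coords - b$coords)), tol)
}
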