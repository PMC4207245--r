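# Shared fixture builders. All geometry fixtures are generated in code; the
# only stored fixtures are small plain-text excerpts under the package's
# extdata.

# A clean annotated helix fixture file on disk; returns the path.
helix_fixture_file <- function(n = 15, span = c(1, n), noise_sd = 0,
                               seed = NULL, dir = tempdir()) {
  h <- build_ideal_helix(n, noise_sd = noise_sd, seed = seed)
  path <- tempfile(tmpdir = dir, fileext = ".pdb")
  write_pdb_fixture(h, path, helix_span = span)
  path
}

# Independent Euclidean distance between two named atoms of a structure,
# computed directly from the atoms table (brute force; no measure_* code).
atom_dist <- function(structure, resno_a, atom_a, resno_b, atom_b,
                      chain = "A") {
  at <- structure$atoms
  a <- at[at$chain == chain & at$res_number == resno_a & at$atom == atom_a, ]
  b <- at[at$chain == chain & at$res_number == resno_b & at$atom == atom_b, ]
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
}

# Independent brute-force hydrophobic-moment oracle: explicit per-residue
# loop over wheel angles, written separately from the package's vectorized
# implementation.
moment_oracle <- function(residues, init_angle = 90) {
  sc <- hydrophobicity_scale()
  mx <- 0; my <- 0
  for (k in seq_along(residues)) {
    ang <- (init_angle - 100 * (k - 1)) * pi / 180
    h <- sc$value[sc$aa1 == residues[k]]
    mx <- mx + cos(ang) * h
    my <- my + sin(ang) * h
  }
  c(mx = mx, my = my, magnitude = sqrt(mx^2 + my^2))
}

# Random rigid-body transform of a structure's coordinates.
rigid_transform <- function(structure, seed) {
  set.seed(seed)
  # random rotation via QR of a Gaussian matrix, det forced to +1
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- rnorm(3, sd = 20)
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")]) %*% q
  structure$atoms$x <- xyz[, 1] + shift[1]
  structure$atoms$y <- xyz[, 2] + shift[2]
  structure$atoms$z <- xyz[, 3] + shift[3]
  structure
}

# A mis-annotated-helix fixture: an ideal helix in which a few residues are
# rigidly displaced by several Angstrom (the way bad HELIX records look:
# sound core, broken residues), rather than globally noised.
perturbed_helix <- function(n = 25, n_displaced = 2, shift = 5, seed = 1) {
  h <- build_ideal_helix(n)
  set.seed(seed)
  who <- sample(seq_len(n), n_displaced)
  for (r in who) {
    v <- rnorm(3)
    v <- v / sqrt(sum(v^2)) * shift
    sel <- h$atoms$res_number == r
    h$atoms$x[sel] <- h$atoms$x[sel] + v[1]
    h$atoms$y[sel] <- h$atoms$y[sel] + v[2]
    h$atoms$z[sel] <- h$atoms$z[sel] + v[3]
  }
  h
}

random_sequence <- function(n) {
  paste(sample(names(edmundson:::AA3), n, replace = TRUE), collapse = "")
}
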