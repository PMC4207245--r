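#' Place an atom from internal coordinates (NeRF)
#'
#' Given three previously placed atoms a, b, c, returns the position d with
#' bond length |cd|, angle b-c-d and torsion a-b-c-d. Angles in degrees.
#' @noRd
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' @noRd
pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Backbone geometry constants (Angstrom / degrees): standard peptide values.
.bb <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8
)

#' Generate an ideal alpha-helical backbone
#'
#' Builds backbone N, CA, C, O coordinates for an ideal right-handed alpha
#' helix by sequential internal-to-Cartesian placement with fixed torsions
#' (phi = -57, psi = -47, omega = 180 degrees) and standard bond
#' lengths/angles. These torsions produce the canonical helix geometry:
#' about 3.6 residues per turn (~100 degrees of twist per residue) and
#' ~1.5 Angstrom of rise per residue. The carbonyl oxygen is placed in the
#' peptide plane anti to the next amide nitrogen. Optional i.i.d. Gaussian
#' jitter models coordinate noise.
#'
#' @param n_residues Number of residues (>= 1).
#' @param sequence Optional one-letter sequence (string or vector) of length
#'   `n_residues`; default poly-alanine.
#' @param phi,psi,omega Backbone torsions in degrees; defaults are the
#'   canonical alpha-helix values.
#' @param noise_sd Standard deviation (Angstrom) of independent Gaussian
#'   jitter added to every coordinate; 0 (default) for an ideal helix.
#' @param seed Integer seed used when `noise_sd > 0`; required then, so that
#'   fixtures are reproducible.
#' @return A `helix_structure` whose `atoms` tibble has residues numbered
#'   1..n on chain "A" and whose `helices` table is empty (annotate with
#'   [helix_annotation()] or serialize with [pdb_fixture_text()]).
#' @examples
#' helx <- build_ideal_helix(10)
#' helx
#' @export
build_ideal_helix <- function(n_residues, sequence = NULL,
                              phi = -57, psi = -47, omega = 180,
                              noise_sd = 0, seed = NULL) {
  if (!is.numeric(n_residues) || length(n_residues) != 1L || n_residues < 1) {
    stop("n_residues must be a single integer >= 1", call. = FALSE)
  }
  n_residues <- as.integer(n_residues)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (noise_sd > 0 && is.null(seed)) {
    stop("a seed is required when noise_sd > 0", call. = FALSE)
  }
  if (is.null(sequence)) {
    residues <- rep("A", n_residues)
  } else {
    residues <- as_residues(sequence)
    if (length(residues) != n_residues) {
      stop("sequence length must equal n_residues", call. = FALSE)
    }
  }

  b <- .bb
  # rigid seed placement of residue 1's N, CA, C
  N1 <- c(0, 0, 0)
  CA1 <- c(b$b_n_ca, 0, 0)
  ang <- b$a_n_ca_c * pi / 180
  C1 <- CA1 + b$b_ca_c * c(-cos(ang), sin(ang), 0)

  coords <- vector("list", n_residues)
  N <- N1; CA <- CA1; C <- C1
  for (i in seq_len(n_residues)) {
    O <- place_atom(N, CA, C, b$b_c_o, b$a_ca_c_o, psi + 180)
    coords[[i]] <- rbind(N = N, CA = CA, C = C, O = O)
    if (i < n_residues) {
      Nn <- place_atom(N, CA, C, b$b_c_n, b$a_ca_c_n, psi)
      CAn <- place_atom(CA, C, Nn, b$b_n_ca, b$a_c_n_ca, omega)
      Cn <- place_atom(C, Nn, CAn, b$b_ca_c, b$a_n_ca_c, phi)
      N <- Nn; CA <- CAn; C <- Cn
    }
  }

  atoms <- tibble::tibble(
    chain = "A",
    res_number = rep(seq_len(n_residues), each = 4L),
    insert = "",
    res_name = rep(aa_to_three(residues), each = 4L),
    standard = TRUE,
    atom = rep(c("N", "CA", "C", "O"), times = n_residues),
    x = as.vector(vapply(coords, function(m) m[, 1], double(4))),
    y = as.vector(vapply(coords, function(m) m[, 2], double(4))),
    z = as.vector(vapply(coords, function(m) m[, 3], double(4)))
  )
  if (noise_sd > 0) {
    withr::with_seed(seed, {
      atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, noise_sd)
      atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, noise_sd)
      atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, noise_sd)
    })
  }
  structure(list(atoms = atoms, helices = empty_helices()),
            class = "helix_structure")
}

#' Serialize a structure as PDB-format text with one HELIX record
#'
#' Writes fixed-column ATOM records (and one HELIX header covering
#' `helix_span`, when given) for a structure, producing text that
#' [read_structure()] round-trips. Coordinates are written at 3 decimals,
#' the PDB column precision.
#'
#' @param structure A `helix_structure` (e.g. from [build_ideal_helix()]).
#' @param helix_span Optional integer pair `c(start, end)` of author residue
#'   numbers to annotate as a helix; must lie within the residue range.
#' @return A single string of PDB-format text.
#' @examples
#' cat(substr(pdb_fixture_text(build_ideal_helix(2), c(1, 2)), 1, 120))
#' @export
pdb_fixture_text <- function(structure, helix_span = NULL) {
  atoms <- structure$atoms
  lines <- character(0)
  if (!is.null(helix_span)) {
    stopifnot(length(helix_span) == 2L)
    rng <- range(atoms$res_number)
    if (helix_span[1] < rng[1] || helix_span[2] > rng[2] ||
        helix_span[1] > helix_span[2]) {
      stop("helix_span outside residue range", call. = FALSE)
    }
    ch <- atoms$chain[1]
    r1 <- atoms$res_name[match(helix_span[1], atoms$res_number)]
    r2 <- atoms$res_name[match(helix_span[2], atoms$res_number)]
    lines <- c(lines, sprintf(
      "HELIX    1   1 %3s %1s %4d  %3s %1s %4d  1%36d",
      r1, ch, helix_span[1], r2, ch, helix_span[2],
      helix_span[2] - helix_span[1] + 1L))
  }
  elem <- substr(atoms$atom, 1, 1)
  atom_lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)),
    sprintf(" %-3s", atoms$atom),
    atoms$res_name, atoms$chain, atoms$res_number,
    ifelse(nzchar(atoms$insert), atoms$insert, " "),
    atoms$x, atoms$y, atoms$z, 1, 0, elem)
  paste(c(lines, atom_lines, "END", ""), collapse = "\n")
}

#' Write a PDB fixture to disk
#'
#' @param path Output file path.
#' @inheritParams pdb_fixture_text
#' @return `path`, invisibly.
#' @export
write_pdb_fixture <- function(structure, path, helix_span = NULL) {
  txt <- pdb_fixture_text(structure, helix_span)
  writeLines(sub("\n$", "", txt), path)
  invisible(path)
}
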