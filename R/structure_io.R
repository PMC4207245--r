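#' Read a protein structure in PDB format
#'
#' Parses fixed-column ATOM records and HELIX header records. Only backbone
#' atoms (N, CA, C, O) are kept, since all downstream geometry uses them.
#' Only the first MODEL of a multi-model file is read; alternate locations
#' are resolved to the blank or 'A' conformer; HETATM records and waters are
#' ignored. Residues whose name is not one of the 20 standard amino acids
#' are kept but flagged (`standard = FALSE`) and excluded from (i, i+4)
#' pairing downstream.
#'
#' @param x Path to a PDB file, or PDB-format text (anything containing a
#'   newline is treated as text).
#' @return A list of class `helix_structure` with elements
#'   \describe{
#'     \item{atoms}{tibble, one row per backbone atom: `chain`, `res_number`
#'       (author numbering), `insert` (insertion code, `""` if none),
#'       `res_name` (3-letter), `standard`, `atom`, `x`, `y`, `z` (Angstrom).}
#'     \item{helices}{tibble, one row per HELIX record: `helix_index`,
#'       `chain`, `start_res`, `end_res`, `source` (`"pdb_header"`).}
#'   }
#' @examples
#' helx <- build_ideal_helix(8)
#' s <- read_structure(pdb_fixture_text(helx, helix_span = c(1, 8)))
#' s$helices
#' @export
read_structure <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (grepl("\n", x, fixed = TRUE)) {
    lines <- strsplit(x, "\n", fixed = TRUE)[[1]]
    src <- "input text"
  } else {
    if (!file.exists(x)) stop("file not found: ", x, call. = FALSE)
    lines <- readLines(x, warn = FALSE)
    src <- x
  }
  check_atom_records(lines, src)
  # first MODEL only: drop everything between the first ENDMDL and END
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  path <- tempfile(fileext = ".pdb")
  on.exit(unlink(path), add = TRUE)
  writeLines(lines, path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path, call. = FALSE)
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  at <- at[at$elety %in% c("N", "CA", "C", "O") & at$resid != "HOH", ,
           drop = FALSE]
  atoms <- tibble::tibble(
    chain = ifelse(is.na(at$chain), " ", at$chain),
    res_number = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", at$insert),
    res_name = at$resid,
    standard = at$resid %in% unname(AA3),
    atom = at$elety,
    x = at$x, y = at$y, z = at$z
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinate in ", path, call. = FALSE)
  }
  # one row per (chain, res, insert, atom): keep first occurrence (altloc dup)
  atoms <- dplyr::distinct(atoms, .data$chain, .data$res_number, .data$insert,
                           .data$atom, .keep_all = TRUE)
  helices <- parse_helix_records(lines)
  structure(list(atoms = atoms, helices = helices),
            class = "helix_structure")
}

#' Pre-scan ATOM lines for gross format errors
#' @noRd
check_atom_records <- function(lines, src) {
  is_atom <- startsWith(lines, "ATOM")
  if (!any(is_atom)) stop("no ATOM records in ", src, call. = FALSE)
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop("unparseable ATOM record at line ", i, ": too short", call. = FALSE)
    }
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords)))) {
      stop("unparseable ATOM record at line ", i, ": bad coordinate field",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Parse HELIX header records from PDB lines
#' @noRd
parse_helix_records <- function(lines) {
  hx <- lines[startsWith(lines, "HELIX")]
  if (!length(hx)) return(empty_helices())
  tibble::tibble(
    helix_index = seq_along(hx),
    chain = trimws(substr(hx, 20, 20)),
    start_res = as.integer(substr(hx, 22, 25)),
    end_res = as.integer(substr(hx, 34, 37)),
    source = "pdb_header"
  )
}

#' @noRd
empty_helices <- function() {
  tibble::tibble(helix_index = integer(), chain = character(),
                 start_res = integer(), end_res = integer(),
                 source = character())
}

#' Construct a user helix annotation table
#'
#' Use this to analyse a span that is not annotated in the PDB header, or to
#' override the header.
#'
#' @param chain Chain identifier(s).
#' @param start_res,end_res Author residue numbers of the span (inclusive);
#'   `start_res <= end_res`.
#' @param source Annotation provenance: `"user"`, `"pdb_header"` or
#'   `"corrected"`.
#' @return A helix annotation tibble as in [read_structure()]'s `helices`.
#' @export
helix_annotation <- function(chain, start_res, end_res, source = "user") {
  start_res <- as.integer(start_res)
  end_res <- as.integer(end_res)
  if (any(start_res > end_res)) {
    stop("start_res must be <= end_res", call. = FALSE)
  }
  tibble::tibble(
    helix_index = seq_along(start_res),
    chain = as.character(chain),
    start_res = start_res, end_res = end_res,
    source = source
  )
}

#' @export
print.helix_structure <- function(x, ...) {
  nres <- nrow(dplyr::distinct(x$atoms, .data$chain, .data$res_number,
                               .data$insert))
  cat("<helix_structure> ", nres, " residues, ",
      length(unique(x$atoms$chain)), " chain(s), ",
      nrow(x$helices), " helix annotation(s)\n", sep = "")
  invisible(x)
}
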