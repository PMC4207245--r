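#' Amino-acid code tables
#'
#' Internal one-letter / three-letter mappings for the 20 standard residues.
#' Three-letter codes are uppercase, as found in PDB `resid` fields.
#' @noRd
AA3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

#' @noRd
AA1 <- stats::setNames(names(AA3), AA3)

#' Convert between one- and three-letter residue codes
#'
#' @param x Character vector of residue codes.
#' @return Character vector of the converted codes; unknown codes map to `NA`.
#' @examples
#' aa_to_three(c("K", "L"))
#' aa_to_one(c("LYS", "LEU"))
#' @export
aa_to_three <- function(x) unname(AA3[toupper(x)])

#' @rdname aa_to_three
#' @export
aa_to_one <- function(x) unname(AA1[toupper(x)])

#' Default hydrophobicity scale
#'
#' Returns the package's default per-residue hydrophobicity values, a
#' dimensionless Jones-type scale in which positive values mark hydrophobic
#' residues and negative values polar/charged ones. The sign of the scale
#' value drives the wheel colour classification (see [classify_residue()]).
#'
#' @return A tibble with columns `aa3` (three-letter code), `aa1` (one-letter
#'   code) and `value` (dimensionless hydrophobicity), 20 rows, carrying a
#'   `provenance` attribute.
#' @seealso [read_scale()] for loading a custom scale from file.
#' @examples
#' hydrophobicity_scale()
#' @export
hydrophobicity_scale <- function() {
  tbl <- tibble::tibble(
    aa3 = c("MET", "ILE", "LEU", "VAL", "CYS", "ALA", "THR", "GLY", "SER",
            "HIS", "PRO", "PHE", "TRP", "TYR", "GLN", "ASN", "GLU", "LYS",
            "ASP", "ARG"),
    value = c(0.975, 0.913, 0.852, 0.811, 0.689, 0.607, 0.525, 0.484, 0.402,
              0.333, 0.239, 1.036, 0.668, 0.137, -0.558, -0.701, -1.396,
              -1.518, -1.600, -2.233)
  )
  tbl$aa1 <- aa_to_one(tbl$aa3)
  tbl <- tbl[, c("aa3", "aa1", "value")]
  attr(tbl, "provenance") <- "hydrophobicity scale, Jones-type, as printed"
  tbl
}

#' Read a custom hydrophobicity scale from a text file
#'
#' The file format is whitespace-delimited `AAA value` lines (three-letter
#' residue code then a number), one per residue; exactly the 20 standard
#' residues must be present. Lines starting with `#` are ignored.
#'
#' @param path Path to the scale file.
#' @return A tibble in the same shape as [hydrophobicity_scale()].
#' @export
read_scale <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\\s+")
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad)) {
    stop("malformed scale line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  aa3 <- toupper(vapply(parts, `[[`, character(1), 1L))
  val <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(val)) stop("non-numeric scale value(s)", call. = FALSE)
  unknown <- setdiff(aa3, unname(AA3))
  if (length(unknown)) {
    stop("unknown residue code(s) in scale: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(aa3)) stop("duplicated residue code in scale", call. = FALSE)
  missing <- setdiff(unname(AA3), aa3)
  if (length(missing)) {
    stop("scale must cover all 20 residues; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tbl <- tibble::tibble(aa3 = aa3, aa1 = aa_to_one(aa3), value = val)
  attr(tbl, "provenance") <- paste0("custom scale from ", path)
  tbl
}

#' Look up scale values for a sequence
#' @noRd
scale_values <- function(residues, scale = hydrophobicity_scale()) {
  idx <- match(residues, scale$aa1)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("residue '", residues[bad], "' at position ", bad,
         " is not in the hydrophobicity scale", call. = FALSE)
  }
  scale$value[idx]
}

#' Classify residues for wheel colouring
#'
#' Residues with a positive hydrophobicity value are hydrophobic (drawn red);
#' the hydrophilic residues split into cationic (Lys, Arg; dark blue),
#' anionic (Asp, Glu; medium blue) and amide (Asn, Gln; light blue).
#' Histidine has a positive scale value and is treated as hydrophobic, not
#' cationic. The classification is total over the 20 standard residues.
#'
#' @param code Character vector of one-letter residue codes (three-letter
#'   codes are accepted and converted).
#' @param scale A hydrophobicity scale tibble; the sign of its `value`
#'   column decides hydrophobic vs hydrophilic.
#' @return Factor with levels `hydrophobic_red`, `cationic_darkblue`,
#'   `anionic_mediumblue`, `amide_lightblue`.
#' @examples
#' classify_residue(c("L", "K", "D", "Q", "H"))
#' @export
classify_residue <- function(code, scale = hydrophobicity_scale()) {
  code <- toupper(code)
  code <- ifelse(nchar(code) == 3L, aa_to_one(code), code)
  if (anyNA(code) || !all(code %in% names(AA3))) {
    bad <- code[is.na(code) | !code %in% names(AA3)][1]
    stop("unknown residue code: ", if (is.na(bad)) "NA" else bad, call. = FALSE)
  }
  val <- scale_values(code, scale)
  cls <- ifelse(val > 0, "hydrophobic_red",
         ifelse(code %in% c("K", "R"), "cationic_darkblue",
         ifelse(code %in% c("D", "E"), "anionic_mediumblue",
                "amide_lightblue")))
  factor(cls, levels = color_classes())
}

#' The four wheel colour classes
#' @return Character vector of the class names in canonical order.
#' @export
color_classes <- function() {
  c("hydrophobic_red", "cationic_darkblue", "anionic_mediumblue",
    "amide_lightblue")
}
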