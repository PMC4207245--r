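#' Read a peptide sequence
#'
#' Accepts either FASTA text (a `>` header line followed by sequence lines)
#' or a bare one-letter string, or a path to a FASTA file. Lowercase letters
#' are uppercased; whitespace is stripped. Every letter must be one of the 20
#' standard one-letter amino-acid codes.
#'
#' @param x Character scalar: FASTA text, a raw sequence string, or a file
#'   path ending in `.fa`/`.fasta`/`.faa` (or any existing file).
#' @param name Optional peptide name; a FASTA header overrides it.
#' @return A tibble of class `peptide_sequence` with columns `index` and
#'   `residue` (one-letter code), carrying a `name` attribute.
#' @examples
#' read_peptide(">SP1-1\nRKKRLKLLKRL")
#' read_peptide("rkkr")
#' @export
read_peptide <- function(x, name = NULL) {
  stopifnot(is.character(x), length(x) >= 1L)
  if (length(x) == 1L && !grepl("[\n>]", x) && file.exists(x)) {
    x <- readLines(x, warn = FALSE)
  }
  lines <- unlist(strsplit(x, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[1], ">")) {
    name <- trimws(sub("^>", "", lines[1]))
    lines <- lines[-1]
  }
  seq <- gsub("[[:space:]]", "", paste(lines, collapse = ""))
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  residues <- toupper(strsplit(seq, "", fixed = TRUE)[[1]])
  bad <- which(!residues %in% names(AA3))
  if (length(bad)) {
    stop("unknown residue '", residues[bad[1]], "' at position ", bad[1],
         call. = FALSE)
  }
  new_peptide(residues, name %||% "")
}

#' @noRd
new_peptide <- function(residues, name = "") {
  out <- tibble::tibble(index = seq_along(residues), residue = residues)
  attr(out, "name") <- name
  class(out) <- c("peptide_sequence", class(out))
  out
}

#' Coerce sequence-like input to a peptide_sequence, keeping any name
#' @noRd
as_peptide <- function(seq) {
  if (inherits(seq, "peptide_sequence")) return(seq)
  if (is.character(seq) && length(seq) == 1L) return(read_peptide(seq))
  new_peptide(as_residues(seq))
}

#' Coerce sequence-like input to a residue vector
#' @noRd
as_residues <- function(seq) {
  if (inherits(seq, "peptide_sequence")) return(seq$residue)
  if (is.data.frame(seq) && "residue" %in% names(seq)) return(seq$residue)
  if (is.character(seq) && length(seq) == 1L) return(read_peptide(seq)$residue)
  if (is.character(seq)) {
    bad <- which(!toupper(seq) %in% names(AA3))
    if (length(bad)) {
      stop("unknown residue '", seq[bad[1]], "' at position ", bad[1],
           call. = FALSE)
    }
    return(toupper(seq))
  }
  stop("cannot interpret input as a peptide sequence", call. = FALSE)
}

#' @noRd
peptide_name <- function(seq) {
  nm <- attr(seq, "name")
  if (is.null(nm) || !nzchar(nm)) "peptide" else nm
}
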