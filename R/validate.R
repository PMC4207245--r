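#' Batch validation of the helix distance property
#'
#' Runs the full pipeline over a set of structures: parses each file,
#' enumerates every (i, i+4) pair, splits pairs into the helix and non-helix
#' populations using the HELIX annotations, optionally applies the
#' hydrogen-bond correction to the annotations, and summarizes the delta
#' (= |d_ca - d_o|) distribution of each population. In genuine alpha
#' helices delta is near zero; the non-helix population is broader.
#'
#' @param paths Character vector of PDB file paths (>= 1). Unreadable files
#'   are skipped with a warning; if none parse, an error is raised.
#' @param cutoff Hydrogen-bond distance cutoff in Angstrom (default 3.6).
#' @param correct Apply annotation correction and report the
#'   `helix_corrected` population (default `TRUE`).
#' @return An object of class `helix_validation`: a list with
#'   \describe{
#'     \item{summaries}{tibble of [summarize_deltas()] rows for `helix`,
#'       `non_helix` and (when `correct`) `helix_corrected`.}
#'     \item{pairs}{per-pair tibble with a `structure` id column.}
#'     \item{rejected}{tibble of residues rejected by the correction.}
#'     \item{skipped}{character vector of unreadable inputs.}
#'     \item{meta}{list: `cutoff`, `correct`, `n_structures`.}
#'   }
#' @examples
#' p <- tempfile(fileext = ".pdb")
#' write_pdb_fixture(build_ideal_helix(15), p, helix_span = c(1, 15))
#' run_validate(p)
#' @export
run_validate <- function(paths, cutoff = 3.6, correct = TRUE) {
  stopifnot(length(paths) >= 1L)
  all_pairs <- list()
  corr_pairs <- list()
  rejected <- list()
  skipped <- character(0)
  for (p in paths) {
    s <- tryCatch(read_structure(p), error = function(e) {
      warning("skipping ", p, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(s)) { skipped <- c(skipped, p); next }
    id <- sub("\\.(pdb|ent)$", "", basename(p))
    pr <- measure_pairs(s, cutoff = cutoff)
    if (nrow(pr)) pr$structure <- id
    all_pairs[[p]] <- pr
    if (correct) {
      cr <- correct_helices(s, cutoff = cutoff)
      cp <- measure_pairs(s, cr$helices, cutoff = cutoff)
      cp <- cp[cp$in_helix, , drop = FALSE]
      if (nrow(cp)) cp$structure <- id
      corr_pairs[[p]] <- cp
      if (nrow(cr$rejected)) {
        cr$rejected$structure <- id
        rejected[[p]] <- cr$rejected
      }
    }
  }
  pairs <- dplyr::bind_rows(all_pairs)
  if (!nrow(pairs)) stop("no structures could be parsed", call. = FALSE)
  summaries <- dplyr::bind_rows(
    summarize_deltas(pairs[pairs$in_helix, , drop = FALSE], "helix"),
    summarize_deltas(pairs[!pairs$in_helix, , drop = FALSE], "non_helix")
  )
  if (correct) {
    summaries <- dplyr::bind_rows(
      summaries,
      summarize_deltas(dplyr::bind_rows(corr_pairs), "helix_corrected")
    )
  }
  structure(list(
    summaries = summaries,
    pairs = pairs,
    rejected = dplyr::bind_rows(rejected),
    skipped = skipped,
    meta = list(cutoff = cutoff, correct = correct,
                n_structures = length(paths) - length(skipped))
  ), class = "helix_validation")
}

#' @export
print.helix_validation <- function(x, ...) {
  cat("<helix_validation> ", x$meta$n_structures, " structure(s), ",
      nrow(x$pairs), " pairs, H-bond cutoff ", x$meta$cutoff, " A\n",
      sep = "")
  print(x$summaries)
  if (nrow(x$rejected)) {
    cat("rejected residues:", nrow(x$rejected), "\n")
  }
  invisible(x)
}

#' Tidy a validation report
#'
#' @param x A `helix_validation`.
#' @param ... Unused.
#' @return `tidy()`: the per-population summary tibble. `glance()`: a
#'   one-row tibble of headline numbers.
#' @export
tidy.helix_validation <- function(x, ...) x$summaries

#' @rdname tidy.helix_validation
#' @export
glance.helix_validation <- function(x, ...) {
  g <- function(lab, col) {
    v <- x$summaries[[col]][x$summaries$label == lab]
    if (length(v)) v else NA_real_
  }
  tibble::tibble(
    n_structures = x$meta$n_structures,
    n_pairs = nrow(x$pairs),
    helix_mean_delta = g("helix", "mean_delta"),
    non_helix_mean_delta = g("non_helix", "mean_delta"),
    corrected_mean_delta = g("helix_corrected", "mean_delta"),
    n_rejected = nrow(x$rejected)
  )
}

#' Tidy a wheel layout
#'
#' @param x A `wheel_layout`.
#' @param ... Unused.
#' @return `tidy()`: the per-residue tibble (without the class). `glance()`:
#'   one row with the moment components, magnitude, direction and RPNR.
#' @export
tidy.wheel_layout <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "wheel_layout")
  out
}

#' @rdname tidy.wheel_layout
#' @export
glance.wheel_layout <- function(x, ...) {
  m <- wheel_moment(x)
  tibble::tibble(
    name = attr(x, "name"), n_residues = nrow(x),
    mx = m[["mx"]], my = m[["my"]], magnitude = m[["magnitude"]],
    direction_deg = m[["direction_deg"]],
    rpnr = suppressWarnings(rpnr(x$residue))
  )
}

#' Plot an Edmundson wheel
#'
#' @param object A `wheel_layout`.
#' @param ... Unused.
#' @return A ggplot: the wheel circle, residues coloured by class, and the
#'   hydrophobic-moment arrow from the centre.
#' @export
autoplot.wheel_layout <- function(object, ...) {
  r <- attr(object, "radius")
  m <- wheel_moment(object)
  circ <- tibble::tibble(t = seq(0, 2 * pi, length.out = 256))
  circ$x <- r * cos(circ$t); circ$y <- r * sin(circ$t)
  fill_map <- c(hydrophobic_red = "#d62728", cationic_darkblue = "#1f3d99",
                anionic_mediumblue = "#4477cc", amide_lightblue = "#a3c1e6")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = circ, colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(fill = .data$color_class),
                        shape = 21, size = 9, colour = "black") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$residue,
                                                   .data$index)),
                       size = 3) +
    ggplot2::scale_fill_manual(values = fill_map, drop = FALSE,
                               name = "class") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = attr(object, "name")) +
    ggplot2::theme_minimal()
  if (m[["magnitude"]] > 1e-9) {
    p <- p + ggplot2::annotate(
      "segment", x = 0, y = 0, xend = m[["mx"]], yend = m[["my"]],
      arrow = ggplot2::arrow(length = ggplot2::unit(0.25, "cm")),
      linewidth = 0.8)
  }
  p
}

#' Plot the delta distributions of a validation report
#'
#' @param object A `helix_validation`.
#' @param ... Unused.
#' @return A ggplot of the delta densities for the helix and non-helix
#'   populations.
#' @export
autoplot.helix_validation <- function(object, ...) {
  df <- object$pairs
  df$population <- ifelse(df$in_helix, "helix", "non_helix")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta,
                                   colour = .data$population)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = expression(delta ~ "=" ~ "|" * D(C * alpha / C * alpha)
                                 - D(O / O) * "|" ~ ("Å")),
                  y = "density") +
    ggplot2::theme_minimal()
}

#' Analyze one input end to end
#'
#' The per-peptide workflow: computes wheel layouts (one per helix for a
#' structure, one overall for a sequence), the hydrophobic moment and RPNR
#' of each, and writes the requested outputs to `out_dir`.
#'
#' @param input Path to a PDB file, a FASTA file, or a raw one-letter
#'   sequence string.
#' @param out_dir Output directory (created if needed).
#' @param tikz,pymol,tsv Which outputs to write. `pymol` and `tsv` need a
#'   structure input.
#' @param helix Optional integer pair `c(start, end)`: analyse this span of
#'   a structure instead of its HELIX records.
#' @param radius,scale Passed to [wheel_layout()].
#' @param cutoff Hydrogen-bond cutoff for the pair table.
#' @return Tibble listing the wheels analysed: `name`, `n_residues`,
#'   `magnitude`, `direction_deg`, `rpnr`, plus a `files` attribute with the
#'   written paths.
#' @export
run_analyze <- function(input, out_dir = ".", tikz = TRUE, pymol = FALSE,
                        tsv = FALSE, helix = NULL, radius = 5,
                        scale = hydrophobicity_scale(), cutoff = 3.6) {
  is_structure <- file.exists(input) && grepl("\\.(pdb|ent)$", input,
                                              ignore.case = TRUE)
  if (!is_structure && (pymol || tsv)) {
    stop("PyMOL/TSV output requires a structure (PDB) input", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (is_structure) {
    s <- read_structure(input)
    ann <- if (!is.null(helix)) {
      helix_annotation(unique(s$atoms$chain)[1], helix[1], helix[2])
    } else s$helices
    wheels <- structure_wheels(s, ann, radius = radius, scale = scale)
    stem <- file.path(out_dir, sub("\\.(pdb|ent)$", "", basename(input),
                                   ignore.case = TRUE))
    if (pymol) {
      f <- paste0(stem, ".pml")
      write_pymol(s, ann, pdb_path = basename(input), path = f,
                  scale = scale)
      files <- c(files, f)
    }
    if (tsv) {
      f <- paste0(stem, "_pairs.tsv")
      write_pair_table(measure_pairs(s, ann, cutoff = cutoff), path = f)
      files <- c(files, f)
    }
  } else {
    pep <- read_peptide(input)
    wheels <- list(peptide = wheel_layout(pep, radius = radius,
                                          scale = scale))
    stem <- file.path(out_dir, peptide_name(pep))
  }
  if (tikz) {
    for (nm in names(wheels)) {
      f <- file.path(out_dir, paste0(if (length(wheels) > 1L)
        paste0(basename(stem), "_", nm) else basename(stem), ".tex"))
      write_tikz(wheels[[nm]], path = f)
      files <- c(files, f)
    }
  }
  out <- dplyr::bind_rows(lapply(wheels, glance))
  attr(out, "files") <- files
  out
}

#' Fetch PDB entries by accession
#'
#' Optional convenience: downloads `<id>.pdb` files from the RCSB archive.
#' Requires network access; nothing else in the package does.
#'
#' @param ids Character vector of 4-character PDB identifiers.
#' @param dir Destination directory.
#' @return Character vector of downloaded file paths (named by id); entries
#'   that could not be fetched are `NA`.
#' @export
fetch_pdb <- function(ids, dir = tempdir()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(ids, function(id) {
    dest <- file.path(dir, paste0(toupper(id), ".pdb"))
    if (file.exists(dest)) return(dest)
    url <- paste0("https://files.rcsb.org/download/", toupper(id), ".pdb")
    ok <- tryCatch({
      utils::download.file(url, dest, quiet = TRUE, mode = "wb")
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (ok && file.exists(dest) && file.size(dest) > 0) dest
    else { unlink(dest); NA_character_ }
  }, character(1))
}
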