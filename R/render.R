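#' Rendering configuration
#'
#' Colour names and arrow scaling used by the TikZ and PyMOL writers.
#'
#' @param colors Named character vector mapping every colour class (see
#'   [color_classes()]) to a colour name understood by the target program.
#' @param arrow_scale Multiplier applied to the moment magnitude to get the
#'   drawn arrow length (drawing units per hydrophobicity unit).
#' @param label_style TikZ node options for residue labels.
#' @return A list of class `render_config`.
#' @export
render_config <- function(colors = c(hydrophobic_red = "red",
                                     cationic_darkblue = "blue!80!black",
                                     anionic_mediumblue = "blue!60",
                                     amide_lightblue = "blue!30"),
                          arrow_scale = 1,
                          label_style = "circle, draw, minimum size=7mm") {
  if (!all(color_classes() %in% names(colors))) {
    stop("colors must map all four colour classes", call. = FALSE)
  }
  structure(list(colors = colors, arrow_scale = arrow_scale,
                 label_style = label_style),
            class = "render_config")
}

#' PyMOL colour names for the four classes
#' @noRd
pymol_colors <- c(hydrophobic_red = "red", cationic_darkblue = "density",
                  anionic_mediumblue = "blue", amide_lightblue = "lightblue")

#' Write TikZ source for an Edmundson wheel
#'
#' Emits a deterministic `tikzpicture`: the wheel circle, one labelled node
#' per residue at its wheel position filled with its class colour, and one
#' arrow from the centre along the hydrophobic-moment vector (omitted when
#' the magnitude is below 1e-9). Identical inputs give byte-identical text.
#'
#' @param layout A [wheel_layout()].
#' @param path Optional output path; when given the text is also written
#'   there.
#' @param config A [render_config()].
#' @return The TikZ source as a single string (invisibly when `path` is
#'   given).
#' @examples
#' cat(write_tikz(wheel_layout("MKL")))
#' @export
write_tikz <- function(layout, path = NULL, config = render_config()) {
  stopifnot(inherits(layout, "wheel_layout"))
  if (nrow(layout) < 1L) stop("layout has no residues", call. = FALSE)
  r <- attr(layout, "radius")
  m <- wheel_moment(layout)
  lines <- c(
    sprintf("%% Edmundson wheel: %s", attr(layout, "name")),
    "\\begin{tikzpicture}",
    sprintf("  \\draw[thin, gray] (0,0) circle (%.4f);", r),
    sprintf("  \\node[%s, fill=%s] at (%.4f,%.4f) {%s%d};",
            config$label_style,
            unname(config$colors[as.character(layout$color_class)]),
            layout$x, layout$y, layout$residue, layout$index)
  )
  if (m[["magnitude"]] > 1e-9) {
    s <- config$arrow_scale
    lines <- c(lines, sprintf(
      "  \\draw[->, very thick] (0,0) -- (%.4f,%.4f);",
      s * m[["mx"]], s * m[["my"]]))
  }
  lines <- c(lines, "\\end{tikzpicture}")
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", txt), path)
    return(invisible(txt))
  }
  txt
}

#' Write a PyMOL script colouring a structure by residue class
#'
#' Emits a deterministic command script that loads the structure file, shows
#' its surface, and colours residues by their wheel colour class, merging
#' consecutive same-class residues of a chain into a single selection so
#' that every residue appears in exactly one colour command. When
#' `annotations` is given, only annotated spans are coloured (anything the
#' annotations reference but the structure lacks is reported as `#
#' warning:` comment lines and skipped).
#'
#' @inheritParams measure_pairs
#' @param pdb_path The structure file name the script should `load`.
#' @param path Optional output path.
#' @param config A [render_config()] (colour-class names are translated to
#'   PyMOL colours).
#' @param scale Hydrophobicity scale used for classification.
#' @return The script text as a single string (invisibly when `path` is
#'   given).
#' @export
write_pymol <- function(structure, annotations = NULL,
                        pdb_path = "structure.pdb", path = NULL,
                        config = render_config(),
                        scale = hydrophobicity_scale()) {
  atoms <- as_atoms(structure)
  res <- dplyr::distinct(atoms[atoms$insert == "" & atoms$standard, ,
                               drop = FALSE],
                         .data$chain, .data$res_number, .data$res_name)
  res <- res[order(res$chain, res$res_number), , drop = FALSE]
  warn <- character(0)
  if (!is.null(annotations) && nrow(annotations)) {
    keep <- rep(FALSE, nrow(res))
    for (k in seq_len(nrow(annotations))) {
      sel <- res$chain == annotations$chain[k] &
        res$res_number >= annotations$start_res[k] &
        res$res_number <= annotations$end_res[k]
      span <- seq.int(annotations$start_res[k], annotations$end_res[k])
      absent <- setdiff(span, res$res_number[res$chain == annotations$chain[k]])
      if (length(absent)) {
        warn <- c(warn, sprintf(
          "# warning: annotation %d references absent residue(s) %s on chain %s",
          annotations$helix_index[k],
          paste(absent, collapse = ","), annotations$chain[k]))
      }
      keep <- keep | sel
    }
    res <- res[keep, , drop = FALSE]
  }
  if (!nrow(res)) stop("no residues to colour", call. = FALSE)
  cls <- as.character(classify_residue(res$res_name, scale))
  run_id <- cumsum(c(1L, (cls[-1] != cls[-length(cls)]) |
                          (res$chain[-1] != res$chain[-nrow(res)])))
  runs <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(run_id, chain = res$chain,
                                   resno = res$res_number, cls),
                    run_id),
    chain = .data$chain[1], from = min(.data$resno), to = max(.data$resno),
    cls = .data$cls[1], .groups = "drop"
  )
  color_cmds <- sprintf("color %s, (chain %s and resi %d-%d)",
                        pymol_colors[runs$cls], runs$chain,
                        runs$from, runs$to)
  lines <- c(sprintf("load %s", pdb_path),
             "hide everything",
             "show surface",
             "bg_color white",
             warn,
             color_cmds)
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", txt), path)
    return(invisible(txt))
  }
  txt
}

#' Write a TSV table of pair measurements
#'
#' One row per (i, i+4) pair with the columns `helix_id`, `pair`, `d_hbond`,
#' `d_ca`, `d_o`, `delta`. Distances are printed to 1 decimal place and the
#' `delta` column is recomputed from the rounded `d_ca` and `d_o` values, so
#' the printed table is internally consistent.
#'
#' @param pairs A pair-measurement tibble from [measure_pairs()].
#' @param path Optional output path.
#' @return The TSV text as a single string (invisibly when `path` is given).
#' @export
write_pair_table <- function(pairs, path = NULL) {
  header <- "helix_id\tpair\td_hbond\td_ca\td_o\tdelta"
  if (nrow(pairs)) {
    helix_id <- if ("helix_index" %in% names(pairs)) {
      ifelse(is.na(pairs$helix_index), "-",
             paste0("helix", pairs$helix_index))
    } else rep("-", nrow(pairs))
    pair_lab <- paste0(title_case3(pairs$name_i), pairs$res_i, "-",
                       title_case3(pairs$name_j), pairs$res_j)
    rca <- round(pairs$d_ca, 1)
    ro <- round(pairs$d_o, 1)
    rows <- sprintf("%s\t%s\t%.1f\t%.1f\t%.1f\t%.1f",
                    helix_id, pair_lab, round(pairs$d_hbond, 1), rca, ro,
                    abs(rca - ro))
  } else rows <- character(0)
  txt <- paste0(paste(c(header, rows), collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", txt), path)
    return(invisible(txt))
  }
  txt
}

#' @noRd
title_case3 <- function(x) {
  paste0(substr(x, 1, 1), tolower(substr(x, 2, 3)))
}
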