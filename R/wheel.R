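#' Edmundson-wheel layout and hydrophobic moment
#'
#' Projects a peptide onto the Edmundson helical wheel: residue k sits on a
#' circle of the given radius at angle `90 - 100 * (k - 1)` degrees (residue
#' 1 at 12 o'clock, each subsequent residue advanced by 100 degrees, since
#' 3.6 residues make one helical turn), so residues k and k+18 coincide.
#' The hydrophobic moment is the raw vector sum over residues of the unit
#' vector from the wheel centre to the residue position scaled by the
#' residue's hydrophobicity value; a large magnitude means the hydrophobic
#' residues cluster on one face (amphipathicity). A per-residue mean
#' (`magnitude / n`) is also reported as a convenience.
#'
#' @param seq A peptide: a one-letter string, FASTA text, a character vector
#'   of one-letter codes, or a [read_peptide()] tibble.
#' @param radius Wheel radius in drawing units (default 5).
#' @param scale Hydrophobicity scale tibble (default [hydrophobicity_scale()]).
#' @param init_angle_deg Angle of residue 1 in degrees (default 90, i.e. the
#'   point (0, radius)). Changing it rotates the whole wheel and the moment
#'   vector rigidly; the moment magnitude is unchanged.
#' @return A tibble of class `wheel_layout`, one row per residue: `index`,
#'   `residue`, `angle_deg` (wrapped to [0, 360)), `x`, `y`, `hydrophobicity`,
#'   `color_class`. Attributes: `moment` (named vector `mx`, `my`,
#'   `magnitude`, `direction_deg`, `mean_magnitude`), `radius`, `name`.
#' @examples
#' w <- wheel_layout("RKKRLKLLKRL")
#' wheel_moment(w)
#' @export
wheel_layout <- function(seq, radius = 5, scale = hydrophobicity_scale(),
                         init_angle_deg = 90) {
  seq <- as_peptide(seq)
  residues <- seq$residue
  if (!length(residues)) stop("empty sequence", call. = FALSE)
  k <- seq_along(residues)
  angle <- init_angle_deg - 100 * (k - 1)
  rad <- angle * pi / 180
  h <- scale_values(residues, scale)
  ux <- cos(rad)
  uy <- sin(rad)
  mx <- sum(ux * h)
  my <- sum(uy * h)
  mag <- sqrt(mx^2 + my^2)
  out <- tibble::tibble(
    index = k,
    residue = residues,
    angle_deg = angle %% 360,
    x = radius * ux,
    y = radius * uy,
    hydrophobicity = h,
    color_class = classify_residue(residues, scale)
  )
  attr(out, "moment") <- c(
    mx = mx, my = my, magnitude = mag,
    direction_deg = if (mag > 0) atan2(my, mx) * 180 / pi else NA_real_,
    mean_magnitude = mag / length(k)
  )
  attr(out, "radius") <- radius
  attr(out, "name") <- peptide_name(seq)
  class(out) <- c("wheel_layout", class(out))
  out
}

#' Extract the moment vector of a wheel layout
#'
#' @param layout A `wheel_layout`.
#' @return Named numeric vector `mx`, `my`, `magnitude`, `direction_deg`,
#'   `mean_magnitude`.
#' @export
wheel_moment <- function(layout) {
  stopifnot(inherits(layout, "wheel_layout"))
  attr(layout, "moment")
}

#' Hydrophobic moment of a peptide
#'
#' Convenience wrapper around [wheel_layout()] returning the moment as a
#' one-row tibble.
#'
#' @inheritParams wheel_layout
#' @return One-row tibble: `name`, `n_residues`, `mx`, `my`, `magnitude`,
#'   `direction_deg`, `mean_magnitude`.
#' @examples
#' hydrophobic_moment("KRIVQRIKDFLR")
#' @export
hydrophobic_moment <- function(seq, radius = 5,
                               scale = hydrophobicity_scale()) {
  w <- wheel_layout(seq, radius = radius, scale = scale)
  m <- wheel_moment(w)
  tibble::tibble(
    name = attr(w, "name"), n_residues = nrow(w),
    mx = m[["mx"]], my = m[["my"]], magnitude = m[["magnitude"]],
    direction_deg = m[["direction_deg"]],
    mean_magnitude = m[["mean_magnitude"]]
  )
}

#' Ratio of positive to negative residues (RPNR)
#'
#' A positional-order-free summary of the sign composition of the charged
#' residues of a helix: `n_pos / (n_pos + n_neg)`, with `n_pos` the count of
#' Lys and Arg and `n_neg` the count of Asp and Glu. Histidine is not
#' counted as charged. The ratio is 1 for an all-cationic peptide, 0 for an
#' all-anionic one, and undefined (`NA`, with a warning) when the peptide
#' carries no charged residues at all. Unlike a "charge moment" (a vector
#' sum of charges over wheel positions), RPNR distinguishes a peptide from a
#' variant in which one cationic residue is swapped for an anionic one at a
#' position that leaves the vector sum unchanged.
#'
#' @inheritParams wheel_layout
#' @return A single number in [0, 1], or `NA` when undefined.
#' @examples
#' rpnr("RKKRLKLLKRL")   # 1: no anionic residues
#' rpnr("KRIVQRIKDFLR")  # 5/6
#' @export
rpnr <- function(seq) {
  residues <- as_residues(seq)
  n_pos <- sum(residues %in% c("K", "R"))
  n_neg <- sum(residues %in% c("D", "E"))
  if (n_pos + n_neg == 0L) {
    warning("RPNR is undefined: no charged residues (K, R, D, E) in sequence",
            call. = FALSE)
    return(NA_real_)
  }
  n_pos / (n_pos + n_neg)
}

#' One wheel per annotated helix of a structure
#'
#' Extracts the residue sequence of each helix annotation (author-number
#' order, standard residues with blank insertion codes) and lays each out on
#' its own Edmundson wheel.
#'
#' @inheritParams measure_pairs
#' @inheritParams wheel_layout
#' @return A named list of `wheel_layout` objects, one per annotation, named
#'   `helix<index>`.
#' @export
structure_wheels <- function(structure, annotations = NULL, radius = 5,
                             scale = hydrophobicity_scale()) {
  atoms <- as_atoms(structure)
  ann <- as_helices(structure, annotations)
  if (!nrow(ann)) stop("no helix annotations to analyse", call. = FALSE)
  out <- list()
  for (k in seq_len(nrow(ann))) {
    seq1 <- helix_sequence(atoms, ann$chain[k], ann$start_res[k],
                           ann$end_res[k])
    if (!length(seq1)) next
    nm <- paste0("helix", ann$helix_index[k])
    out[[nm]] <- wheel_layout(new_peptide(seq1, nm), radius = radius,
                              scale = scale)
  }
  if (!length(out)) stop("no annotated residues found in structure",
                         call. = FALSE)
  out
}

#' @noRd
helix_sequence <- function(atoms, chain, start_res, end_res) {
  a <- atoms[atoms$chain == chain & atoms$insert == "" & atoms$standard &
             atoms$res_number >= start_res & atoms$res_number <= end_res, ,
             drop = FALSE]
  if (!nrow(a)) return(character(0))
  res <- dplyr::distinct(a, .data$res_number, .data$res_name)
  res <- res[order(res$res_number), , drop = FALSE]
  aa_to_one(res$res_name)
}

#' @export
print.wheel_layout <- function(x, ...) {
  m <- wheel_moment(x)
  cat("<wheel_layout> '", attr(x, "name"), "', ", nrow(x), " residues, ",
      "moment magnitude ", sprintf("%.4f", m[["magnitude"]]),
      if (!is.na(m[["direction_deg"]]))
        sprintf(" at %.1f deg", m[["direction_deg"]]) else "",
      "\n", sep = "")
  NextMethod()
}
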