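#' Backbone coordinate lookup for one chain
#'
#' Returns a per-residue wide table (one row per author residue number with a
#' blank insertion code) with the backbone atom coordinates as columns.
#' Residues with non-blank insertion codes or non-standard names are dropped:
#' (i, i+4) pairing is defined over author-number arithmetic on standard
#' residues.
#' @noRd
chain_backbone <- function(atoms, chain) {
  a <- atoms[atoms$chain == chain & atoms$insert == "" & atoms$standard, ,
             drop = FALSE]
  if (!nrow(a)) return(NULL)
  a <- a[a$atom %in% c("N", "CA", "O"), , drop = FALSE]
  wide <- tidyr::pivot_wider(
    a[, c("res_number", "res_name", "atom", "x", "y", "z")],
    names_from = "atom", values_from = c("x", "y", "z"),
    values_fn = function(v) v[1]
  )
  wide[order(wide$res_number), , drop = FALSE]
}

#' @noRd
euclid <- function(x1, y1, z1, x2, y2, z2) {
  unname(sqrt((x1 - x2)^2 + (y1 - y2)^2 + (z1 - z2)^2))
}

#' Measure the (i, i+4) backbone distances for one residue pair
#'
#' For residue i and its partner i+4 (author numbering, same chain) computes
#' the three distances at the heart of the helix test: `d_hbond`, from the
#' carbonyl oxygen O(i) to the amide nitrogen N(i+4) (the helix hydrogen
#' bond, typically <= 3.6 Angstrom); `d_ca`, between the two Calpha atoms;
#' and `d_o`, between the two carbonyl oxygens. `delta = |d_ca - d_o|` is
#' the empirical helix property: near zero in a genuine alpha helix.
#'
#' @param structure A `helix_structure`, or its `atoms` tibble.
#' @param chain Chain identifier.
#' @param res_i Author residue number of residue i.
#' @param cutoff Hydrogen-bond distance cutoff in Angstrom (default 3.6).
#' @return A one-row tibble: `chain`, `res_i`, `res_j`, `name_i`, `name_j`,
#'   `d_hbond`, `d_ca`, `d_o`, `delta`, `hbond_ok`.
#' @examples
#' helx <- build_ideal_helix(9)
#' measure_pair(helx, "A", 1)
#' @export
measure_pair <- function(structure, chain, res_i, cutoff = 3.6) {
  atoms <- as_atoms(structure)
  bb <- chain_backbone(atoms, chain)
  out <- measure_pairs_on_chain(bb, chain, as.integer(res_i))
  if (nrow(out) == 0L) {
    stop("cannot measure pair (", res_i, ", ", res_i + 4L, ") on chain ",
         chain, ": missing residue or backbone atom", call. = FALSE)
  }
  out$hbond_ok <- !is.na(out$d_hbond) & out$d_hbond <= cutoff
  out
}

#' @noRd
as_atoms <- function(structure) {
  if (inherits(structure, "helix_structure")) return(structure$atoms)
  if (is.data.frame(structure)) return(structure)
  stop("expected a helix_structure or an atoms tibble", call. = FALSE)
}

#' @noRd
as_helices <- function(structure, annotations = NULL) {
  if (!is.null(annotations)) return(annotations)
  if (inherits(structure, "helix_structure")) return(structure$helices)
  empty_helices()
}

#' Vectorized measurement over residue numbers of one chain
#' @noRd
measure_pairs_on_chain <- function(bb, chain, res_i) {
  if (is.null(bb)) return(empty_pairs())
  ii <- match(res_i, bb$res_number)
  jj <- match(res_i + 4L, bb$res_number)
  ok <- !is.na(ii) & !is.na(jj)
  ii <- ii[ok]; jj <- jj[ok]; ri <- res_i[ok]
  if (!length(ii)) return(empty_pairs())
  have <- !is.na(bb$x_CA[ii]) & !is.na(bb$x_O[ii]) &
          !is.na(bb$x_CA[jj]) & !is.na(bb$x_O[jj]) & !is.na(bb$x_N[jj])
  ii <- ii[have]; jj <- jj[have]; ri <- ri[have]
  if (!length(ii)) return(empty_pairs())
  tibble::tibble(
    chain = chain,
    res_i = ri,
    res_j = ri + 4L,
    name_i = bb$res_name[ii],
    name_j = bb$res_name[jj],
    d_hbond = euclid(bb$x_O[ii], bb$y_O[ii], bb$z_O[ii],
                     bb$x_N[jj], bb$y_N[jj], bb$z_N[jj]),
    d_ca = euclid(bb$x_CA[ii], bb$y_CA[ii], bb$z_CA[ii],
                  bb$x_CA[jj], bb$y_CA[jj], bb$z_CA[jj]),
    d_o = euclid(bb$x_O[ii], bb$y_O[ii], bb$z_O[ii],
                 bb$x_O[jj], bb$y_O[jj], bb$z_O[jj]),
    delta = abs(d_ca - d_o)
  )
}

#' @noRd
empty_pairs <- function() {
  tibble::tibble(chain = character(), res_i = integer(), res_j = integer(),
                 name_i = character(), name_j = character(),
                 d_hbond = double(), d_ca = double(), d_o = double(),
                 delta = double())
}

#' Enumerate all (i, i+4) pair measurements in a structure
#'
#' Measures every residue pair (i, i+4) on every chain where both residues
#' and the required backbone atoms exist, and labels each pair as in-helix
#' when the full interval [i, i+4] lies inside a single helix annotation on
#' that chain; pairs straddling an annotation boundary count as non-helix.
#'
#' @inheritParams measure_pair
#' @param annotations Optional helix annotation tibble; defaults to the
#'   structure's own `helices`.
#' @return A tibble of pair measurements with the columns of
#'   [measure_pair()] plus `in_helix` and `helix_index` (`NA` for non-helix
#'   pairs).
#' @examples
#' helx <- build_ideal_helix(12)
#' ann <- helix_annotation("A", 1, 6)
#' measure_pairs(helx, ann)
#' @export
measure_pairs <- function(structure, annotations = NULL, cutoff = 3.6) {
  atoms <- as_atoms(structure)
  ann <- as_helices(structure, annotations)
  chains <- unique(atoms$chain)
  res <- lapply(chains, function(ch) {
    bb <- chain_backbone(atoms, ch)
    if (is.null(bb)) return(empty_pairs())
    measure_pairs_on_chain(bb, ch, bb$res_number)
  })
  out <- dplyr::bind_rows(res)
  out$hbond_ok <- !is.na(out$d_hbond) & out$d_hbond <= cutoff
  out$helix_index <- NA_integer_
  if (nrow(ann) && nrow(out)) {
    for (k in seq_len(nrow(ann))) {
      inside <- out$chain == ann$chain[k] &
        out$res_i >= ann$start_res[k] & out$res_j <= ann$end_res[k]
      out$helix_index[inside & is.na(out$helix_index)] <- ann$helix_index[k]
    }
  }
  out$in_helix <- !is.na(out$helix_index)
  out
}

#' Correct helix annotations with the hydrogen-bond distance criterion
#'
#' Within each annotated helix, a residue i is rejected when its measured
#' O(i) to N(i+4) distance exceeds `cutoff` (whether the partner lies inside
#' or outside the annotation); residues whose partner cannot be measured are
#' retained. Remaining runs of consecutively numbered accepted residues of
#' length >= `min_run` become corrected annotations (a helix needs at least
#' one i, i+4 hydrogen bond, hence the default minimum of 5 residues).
#'
#' @inheritParams measure_pairs
#' @param min_run Minimum corrected-run length (default 5).
#' @return A list with `helices` (annotation tibble, `source = "corrected"`)
#'   and `rejected` (tibble of rejected residues: `helix_index`, `chain`,
#'   `res_number`, `d_hbond`).
#' @examples
#' helx <- build_ideal_helix(12)
#' correct_helices(helx, helix_annotation("A", 1, 12))$helices
#' @export
correct_helices <- function(structure, annotations = NULL, cutoff = 3.6,
                            min_run = 5L) {
  atoms <- as_atoms(structure)
  ann <- as_helices(structure, annotations)
  rejected <- list()
  corrected <- list()
  next_idx <- 1L
  for (k in seq_len(nrow(ann))) {
    ch <- ann$chain[k]
    span <- seq.int(ann$start_res[k], ann$end_res[k])
    bb <- chain_backbone(atoms, ch)
    present <- span[span %in% (if (is.null(bb)) integer() else bb$res_number)]
    m <- measure_pairs_on_chain(bb, ch, present)
    bad <- m$res_i[m$d_hbond > cutoff]
    if (length(bad)) {
      rejected[[length(rejected) + 1L]] <- tibble::tibble(
        helix_index = ann$helix_index[k], chain = ch, res_number = bad,
        d_hbond = m$d_hbond[match(bad, m$res_i)]
      )
    }
    keep <- setdiff(present, bad)
    if (!length(keep)) next
    runs <- split(keep, cumsum(c(1L, diff(keep) != 1L)))
    for (r in runs) {
      if (length(r) >= min_run) {
        corrected[[length(corrected) + 1L]] <- tibble::tibble(
          helix_index = next_idx, chain = ch,
          start_res = min(r), end_res = max(r), source = "corrected"
        )
        next_idx <- next_idx + 1L
      }
    }
  }
  list(
    helices = if (length(corrected)) dplyr::bind_rows(corrected)
              else empty_helices(),
    rejected = if (length(rejected)) dplyr::bind_rows(rejected)
               else tibble::tibble(helix_index = integer(), chain = character(),
                                   res_number = integer(), d_hbond = double())
  )
}

#' Summarize the delta distribution of a set of pairs
#'
#' Computes the count, arithmetic mean and population standard deviation
#' (divide by n) of `delta = |d_ca - d_o|` over the supplied pair
#' measurements. With no pairs the statistics are `NA` (flagged by
#' `n_pairs = 0`).
#'
#' @param pairs A pair-measurement tibble from [measure_pairs()].
#' @param label Distribution label, e.g. `"helix"`, `"non_helix"`,
#'   `"helix_corrected"`.
#' @return A one-row tibble: `label`, `n_pairs`, `mean_delta`, `sd_delta`.
#' @examples
#' helx <- build_ideal_helix(20)
#' summarize_deltas(measure_pairs(helx, helix_annotation("A", 1, 20)), "helix")
#' @export
summarize_deltas <- function(pairs, label = "helix") {
  n <- nrow(pairs)
  if (n == 0L) {
    return(tibble::tibble(label = label, n_pairs = 0L,
                          mean_delta = NA_real_, sd_delta = NA_real_))
  }
  m <- mean(pairs$delta)
  tibble::tibble(
    label = label, n_pairs = n, mean_delta = m,
    sd_delta = sqrt(mean((pairs$delta - m)^2))
  )
}
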