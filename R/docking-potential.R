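# Knowledge-based pair potential: distance-binned scores per atom-type
# pair, derived from observed protein-ligand contacts against a radial-mean
# reference (pairs distributed uniformly over spherical shells).

PAIR_TYPES <- c("C", "N", "O", "S", "P", "X")  # X = halogen

#' Map element symbols to potential atom types
#'
#' Heavy-atom element classes used by the pair potential: C, N, O, S, P and
#' a pooled halogen class "X". Hydrogens and unsupported elements map to
#' `NA` and are ignored by the scorer.
#'
#' @param elements character vector of element symbols.
#' @return character vector of atom types (NA for untyped atoms).
#' @export
pair_atom_type <- function(elements) {
  t <- ifelse(elements %in% HALOGENS, "X",
              ifelse(elements %in% c("C", "N", "O", "S", "P"), elements, NA))
  t
}

#' Derive a pair potential from protein-ligand complexes
#'
#' For every atom-type pair and distance bin the score is
#' `-log((observed + 1) / (reference + 1))` where `observed` counts
#' protein-ligand heavy-atom pairs of that type pair in that bin, and
#' `reference` distributes the same per-type-pair total over the bins in
#' proportion to the spherical-shell volume (r^2 dr, the radial mean).
#' Bins with contacts enriched over the radial mean therefore score
#' negative (favorable); the potential is zero beyond the cutoff.
#'
#' Distance bins below the shortest observed contact of a type pair are
#' assigned a fixed repulsive value (`repulsion`), the usual
#' excluded-volume convention of statistical potentials: approaches closer
#' than anything seen in the training complexes are penalized rather than
#' scored as neutral.
#'
#' @param complexes list; each element a list with `protein_coords`,
#'   `protein_elements`, `ligand_coords`, `ligand_elements`.
#' @param bin_width bin width in Angstrom (default 0.5).
#' @param cutoff interaction cutoff in Angstrom (default 6.0).
#' @return an object of class `invdock_potential`: 3D array
#'   `values[type1, type2, bin]` (symmetric in the type pair) plus
#'   `bin_width` and `cutoff`.
#' @export
derive_pair_potential <- function(complexes, bin_width = 0.5, cutoff = 6.0,
                                  repulsion = 3.0) {
  if (!length(complexes)) stop("empty training set")
  nb <- as.integer(round(cutoff / bin_width))
  nt <- length(PAIR_TYPES)
  obs <- array(0, dim = c(nt, nt, nb),
               dimnames = list(PAIR_TYPES, PAIR_TYPES, NULL))
  for (cx in complexes) {
    pt <- pair_atom_type(cx$protein_elements)
    lt <- pair_atom_type(cx$ligand_elements)
    keep_p <- !is.na(pt); keep_l <- !is.na(lt)
    if (!any(keep_p) || !any(keep_l)) next
    d <- cross_dist(cx$ligand_coords[keep_l, , drop = FALSE],
                    cx$protein_coords[keep_p, , drop = FALSE])
    lt2 <- lt[keep_l]; pt2 <- pt[keep_p]
    hit <- which(d < cutoff, arr.ind = TRUE)
    if (!nrow(hit)) next
    bin <- pmin(nb, floor(d[hit] / bin_width) + 1L)
    t1 <- match(lt2[hit[, 1]], PAIR_TYPES)
    t2 <- match(pt2[hit[, 2]], PAIR_TYPES)
    for (k in seq_along(bin)) {
      obs[t1[k], t2[k], bin[k]] <- obs[t1[k], t2[k], bin[k]] + 1
      if (t1[k] != t2[k]) {
        obs[t2[k], t1[k], bin[k]] <- obs[t2[k], t1[k], bin[k]] + 1
      }
    }
  }
  # radial-mean reference: per type pair, total count spread over bins
  # proportionally to shell volume
  edges <- seq(0, cutoff, by = bin_width)
  shell <- diff(edges^3)
  shell <- shell / sum(shell)
  values <- array(0, dim = dim(obs), dimnames = dimnames(obs))
  for (a in seq_len(nt)) for (b in seq_len(nt)) {
    tot <- sum(obs[a, b, ])
    ref <- tot * shell
    values[a, b, ] <- -log((obs[a, b, ] + 1) / (ref + 1))
    # excluded-volume repulsion below the shortest observed contact
    if (tot > 0) {
      first <- which(obs[a, b, ] > 0)[1]
      if (first > 1) values[a, b, seq_len(first - 1)] <- repulsion
    }
  }
  structure(list(values = values, bin_width = bin_width, cutoff = cutoff),
            class = "invdock_potential")
}

#' @export
print.invdock_potential <- function(x, ...) {
  cat("<invdock_potential>", dim(x$values)[3], "bins of", x$bin_width,
      "A, cutoff", x$cutoff, "A\n")
  invisible(x)
}

#' A potential with all-zero values (useful as a null reference)
#' @param bin_width,cutoff as in [derive_pair_potential()].
#' @export
zero_potential <- function(bin_width = 0.5, cutoff = 6.0) {
  nb <- as.integer(round(cutoff / bin_width))
  nt <- length(PAIR_TYPES)
  structure(list(values = array(0, c(nt, nt, nb),
                                dimnames = list(PAIR_TYPES, PAIR_TYPES, NULL)),
                 bin_width = bin_width, cutoff = cutoff),
            class = "invdock_potential")
}

#' Score a ligand pose against a protein
#'
#' Sum of the pair-potential values over all protein-ligand heavy-atom
#' pairs within the cutoff. Lower is better; units are arbitrary.
#'
#' @param pot an `invdock_potential`.
#' @param ligand_coords n x 3 matrix.
#' @param ligand_elements length-n element symbols.
#' @param protein list with `coords` and `elements` (see
#'   [protein_for_docking()]).
#' @param interpolate when TRUE the potential is linearly interpolated
#'   between bin centers (and tapered to zero at the cutoff), giving a
#'   continuous score surface; the docking engine minimizes on this
#'   surface. Default FALSE: plain binned lookup.
#' @return numeric score (arb. units).
#' @export
score_pose <- function(pot, ligand_coords, ligand_elements, protein,
                       interpolate = FALSE) {
  lt <- pair_atom_type(ligand_elements)
  keep_l <- !is.na(lt)
  pt <- protein$types %||% pair_atom_type(protein$elements)
  keep_p <- !is.na(pt)
  if (!any(keep_l) || !any(keep_p)) return(0)
  d <- cross_dist(ligand_coords[keep_l, , drop = FALSE],
                  protein$coords[keep_p, , drop = FALSE])
  score_from_dist(pot, d, match(lt[keep_l], PAIR_TYPES),
                  match(pt[keep_p], PAIR_TYPES), interpolate = interpolate)
}

# Per-pair potential values for distances dd and type indices t1, t2.
pair_values <- function(pot, dd, t1, t2, interpolate = FALSE) {
  nb <- dim(pot$values)[3]
  if (!interpolate) {
    bin <- pmin(nb, floor(dd / pot$bin_width) + 1L)
    return(pot$values[cbind(t1, t2, bin)])
  }
  # piecewise-linear in d: nodes at bin centers, value 0 at the cutoff
  h <- dd / pot$bin_width - 0.5
  i0 <- floor(h)
  w <- h - i0
  lo <- pmax(1L, pmin(nb, i0 + 1L))
  hi <- pmin(nb, i0 + 2L)
  vlo <- pot$values[cbind(t1, t2, lo)]
  vhi <- ifelse(i0 + 2L > nb, 0, pot$values[cbind(t1, t2, hi)])
  w <- ifelse(i0 < 0, 0, w)                     # below first center: flat
  (1 - w) * vlo + w * vhi
}

# Core lookup: d is an (n_lig x n_prot) distance matrix, ti/tj type indices.
score_from_dist <- function(pot, d, ti, tj, interpolate = FALSE) {
  hit <- which(d < pot$cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(0)
  sum(pair_values(pot, d[hit], ti[hit[, 1]], tj[hit[, 2]],
                  interpolate = interpolate))
}

#' Protein atom set used for docking
#'
#' Heavy atoms of the selected chains (protein ATOM records), with
#' precomputed potential atom types.
#'
#' @param entry an `invdock_entry`.
#' @param chains chain identifiers (default: all).
#' @return list with `coords`, `elements`, `types`.
#' @export
protein_for_docking <- function(entry, chains = NULL) {
  at <- entry$atom
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  el <- normalize_element(at$elesy, at$elety)
  heavy <- el != "H"
  list(coords = as.matrix(at[heavy, c("x", "y", "z")]),
       elements = el[heavy],
       types = pair_atom_type(el[heavy]))
}

# Training-complex view of an entry/chain/ligand triple.
complex_from_entry <- function(entry, chain_id, het) {
  prot <- protein_for_docking(entry, chain_id)
  heavy <- het$elements != "H"
  list(protein_coords = prot$coords, protein_elements = prot$elements,
       ligand_coords = het$coords[heavy, , drop = FALSE],
       ligand_elements = het$elements[heavy])
}
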