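# Geometric protein-ligand interaction profiling: the seven interaction
# types commonly reported for docked poses, detected from distances and
# angles with configurable windows.

#' Detection windows for interaction profiling
#'
#' Defaults follow widely used geometric criteria for protein-ligand
#' interaction profiling; every window is a config key.
#'
#' @param hbond_dist max donor-acceptor distance, Angstrom (3.5).
#' @param hbond_angle min D-H...A angle, degrees (120); checked only when
#'   an explicit hydrogen is present on the donor.
#' @param hydrophobic_min,hydrophobic_max carbon-carbon distance window
#'   between apolar atoms (3.3-4.0).
#' @param pistack_dist max ring-centroid distance (5.0).
#' @param pistack_parallel max interplanar angle for parallel stacking
#'   (30); T-shaped stacking accepted between `pistack_tmin` (60) and 90.
#' @param pication_dist max centroid-cation distance (5.0).
#' @param saltbridge_dist max charged-group centroid distance (5.0).
#' @param halogen_dist max X...acceptor distance (3.8).
#' @param halogen_angle min C-X...acceptor angle, degrees (140).
#' @return list of class `invdock_interaction_params`.
#' @export
interaction_params <- function(hbond_dist = 3.5, hbond_angle = 120,
                               hydrophobic_min = 3.3, hydrophobic_max = 4.0,
                               pistack_dist = 5.0, pistack_parallel = 30,
                               pistack_tmin = 60, pication_dist = 5.0,
                               saltbridge_dist = 5.0, halogen_dist = 3.8,
                               halogen_angle = 140) {
  structure(as.list(environment()), class = "invdock_interaction_params")
}

AROMATIC_RING_ATOMS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CE2", "CD2", "CE3", "CZ3", "CH2", "CZ2")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2"))
)
HYDROPHOBIC_RES <- c("ALA", "VAL", "LEU", "ILE", "PHE", "MET", "PRO", "TRP")

vec_angle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

ring_geometry <- function(coords) {
  ctr <- colMeans(coords)
  sv <- svd(sweep(coords, 2, ctr))
  list(center = ctr, normal = sv$v[, 3])
}

# Aromatic ring atom-index sets of a molecule (via ring perception).
mol_aromatic_rings <- function(mol) {
  if (!any(mol$aromatic)) return(list())
  r <- tryCatch(
    suppressWarnings(ChemmineR::rings(mol_to_sdf(mol), type = "all",
                                      arom = TRUE)),
    error = function(e) NULL
  )
  if (is.null(r) || !length(r$RINGS)) return(list())
  out <- list()
  for (k in seq_along(r$RINGS)) {
    if (isTRUE(r$AROMATIC[[k]])) {
      out[[length(out) + 1L]] <- as.integer(sub("^[A-Za-z]+_", "",
                                                r$RINGS[[k]]))
    }
  }
  out
}

#' Profile protein-ligand interactions of a pose
#'
#' Detects hydrogen bonds, hydrophobic contacts, pi-stacking, pi-cation
#' interactions, salt bridges, water bridges and halogen bonds between a
#' posed ligand and a protein structure, from distances and angles only.
#' Hydrogen-bond angles are checked when the ligand carries explicit
#' hydrogens; donors without explicit hydrogen are accepted on the
#' distance criterion (the hydrogen position is then unresolved but
#' inferable along the donor-acceptor axis).
#'
#' @param mol an `invdock_mol` whose coordinates are the docked pose
#'   (explicit hydrogens optional).
#' @param entry an `invdock_entry` providing protein atoms and residues.
#' @param waters optional matrix of water oxygen coordinates (defaults to
#'   the entry's waters).
#' @param config an [interaction_params()].
#' @return data.frame with columns `kind`, `residue`, `ligand_atoms`,
#'   `distance`, `angle` (NA where not applicable), ordered by residue
#'   then kind.
#' @export
profile_interactions <- function(mol, entry, waters = NULL,
                                 config = interaction_params()) {
  at <- entry$atom
  at$element <- normalize_element(at$elesy, at$elety)
  at$key <- residue_key(at$chain, at$resno, at$insert)
  waters <- waters %||% entry$waters
  lig_xyz <- mol$coords
  lig_el <- mol$elements
  heavy <- lig_el != "H"

  has_h <- any(lig_el == "H")
  h_neighbors <- function(i) {
    nb <- c(mol$bonds$j[mol$bonds$i == i], mol$bonds$i[mol$bonds$j == i])
    nb[lig_el[nb] == "H"]
  }
  heavy_neighbors <- function(i) {
    nb <- c(mol$bonds$j[mol$bonds$i == i], mol$bonds$i[mol$bonds$j == i])
    nb[lig_el[nb] != "H"]
  }

  rec <- list()
  add <- function(kind, residue, atoms, distance, angle = NA_real_) {
    rec[[length(rec) + 1L]] <<- data.frame(
      kind = kind, residue = residue,
      ligand_atoms = paste(atoms, collapse = ","),
      distance = distance, angle = angle)
  }

  ## hydrogen bonds -----------------------------------------------------
  lig_polar <- which(lig_el %in% c("N", "O"))
  prot_polar <- which(at$element %in% c("N", "O"))
  prot_don <- at$element == "N" |
    (at$element == "O" & at$resid %in% c("SER", "THR", "TYR") &
       at$elety %in% c("OG", "OG1", "OH"))
  prot_acc <- at$element == "O" |
    (at$element == "N" & at$resid == "HIS" & at$elety %in% c("ND1", "NE2"))
  if (length(lig_polar) && length(prot_polar)) {
    d <- cross_dist(lig_xyz[lig_polar, , drop = FALSE],
                    as.matrix(at[prot_polar, c("x", "y", "z")]))
    hit <- which(d <= config$hbond_dist & d >= 2.0, arr.ind = TRUE)
    for (k in seq_len(nrow(hit))) {
      li <- lig_polar[hit[k, 1]]; pi_ <- prot_polar[hit[k, 2]]
      dist_da <- d[hit[k, 1], hit[k, 2]]
      # ligand as donor: require a decent D-H...A angle if H is explicit
      angle <- NA_real_
      ok <- FALSE
      hs <- h_neighbors(li)
      if (length(hs)) {
        for (h in hs) {
          a <- vec_angle(lig_xyz[li, ] - lig_xyz[h, ],
                         as.numeric(at[pi_, c("x", "y", "z")]) - lig_xyz[h, ])
          if (a >= config$hbond_angle) { ok <- TRUE; angle <- a; break }
        }
        # explicit-H ligand that fails as donor can still accept
        if (!ok && prot_don[pi_]) { ok <- TRUE; angle <- NA_real_ }
      } else {
        # no explicit H: distance criterion with donor/acceptor roles
        ok <- prot_don[pi_] || prot_acc[pi_]
      }
      if (ok) add("hydrogen_bond", at$key[pi_], li, dist_da, angle)
    }
  }

  ## hydrophobic contacts ------------------------------------------------
  lig_apolar <- which(lig_el == "C" & vapply(seq_along(lig_el), function(i) {
    all(lig_el[heavy_neighbors(i)] == "C")
  }, logical(1)))
  prot_apolar <- which(at$element == "C" &
                         !(at$elety %in% c("C", "CA")) &
                         (at$resid %in% HYDROPHOBIC_RES | at$elety == "CB"))
  if (length(lig_apolar) && length(prot_apolar)) {
    d <- cross_dist(lig_xyz[lig_apolar, , drop = FALSE],
                    as.matrix(at[prot_apolar, c("x", "y", "z")]))
    hit <- which(d >= config$hydrophobic_min & d <= config$hydrophobic_max,
                 arr.ind = TRUE)
    if (nrow(hit)) {
      pairs <- data.frame(li = lig_apolar[hit[, 1]],
                          key = at$key[prot_apolar[hit[, 2]]],
                          dist = d[hit])
      # one record per (residue, ligand atom): closest contact
      pairs <- pairs[order(pairs$key, pairs$li, pairs$dist), ]
      pairs <- pairs[!duplicated(pairs[, c("key", "li")]), ]
      for (k in seq_len(nrow(pairs))) {
        add("hydrophobic", pairs$key[k], pairs$li[k], pairs$dist[k])
      }
    }
  }

  ## aromatic rings ------------------------------------------------------
  lig_rings <- lapply(mol_aromatic_rings(mol), function(idx) {
    ring_geometry(lig_xyz[idx, , drop = FALSE])
  })
  lig_ring_atoms <- mol_aromatic_rings(mol)
  prot_rings <- list()
  for (res in split(at, at$key)) {
    tmpl <- AROMATIC_RING_ATOMS[[res$resid[1]]]
    if (is.null(tmpl)) next
    for (atoms in tmpl) {
      sel <- res[match(atoms, res$elety), , drop = FALSE]
      if (any(is.na(sel$x))) next
      prot_rings[[length(prot_rings) + 1L]] <- c(
        ring_geometry(as.matrix(sel[, c("x", "y", "z")])),
        list(key = res$key[1]))
    }
  }

  ## pi-stacking ---------------------------------------------------------
  for (li in seq_along(lig_rings)) for (pr in prot_rings) {
    dctr <- sqrt(sum((lig_rings[[li]]$center - pr$center)^2))
    if (dctr > config$pistack_dist) next
    ang <- vec_angle(lig_rings[[li]]$normal, pr$normal)
    ang <- min(ang, 180 - ang)
    if (ang <= config$pistack_parallel ||
        (ang >= config$pistack_tmin && ang <= 90)) {
      add("pi_stacking", pr$key, lig_ring_atoms[[li]], dctr, ang)
    }
  }

  ## pi-cation -----------------------------------------------------------
  prot_cations <- at[(at$resid == "LYS" & at$elety == "NZ") |
                       (at$resid == "ARG" & at$elety == "CZ"), , drop = FALSE]
  for (li in seq_along(lig_rings)) {
    if (nrow(prot_cations)) {
      d <- sqrt(rowSums((as.matrix(prot_cations[, c("x", "y", "z")]) -
                           matrix(lig_rings[[li]]$center,
                                  nrow(prot_cations), 3, byrow = TRUE))^2))
      for (k in which(d <= config$pication_dist)) {
        add("pi_cation", prot_cations$key[k], lig_ring_atoms[[li]], d[k])
      }
    }
  }
  lig_cations <- which(mol$formal_charge > 0)
  for (pr in prot_rings) {
    if (length(lig_cations)) {
      d <- sqrt(rowSums((lig_xyz[lig_cations, , drop = FALSE] -
                           matrix(pr$center, length(lig_cations), 3,
                                  byrow = TRUE))^2))
      for (k in which(d <= config$pication_dist)) {
        add("pi_cation", pr$key, lig_cations[k], d[k])
      }
    }
  }

  ## salt bridges --------------------------------------------------------
  neg_groups <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  pos_groups <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                     HIS = c("ND1", "NE2"))
  group_centroid <- function(res, atoms) {
    sel <- res[res$elety %in% atoms, , drop = FALSE]
    if (!nrow(sel)) return(NULL)
    colMeans(as.matrix(sel[, c("x", "y", "z")]))
  }
  lig_pos <- which(mol$formal_charge > 0)
  lig_neg <- which(mol$formal_charge < 0)
  for (res in split(at, at$key)) {
    rn <- res$resid[1]
    if (rn %in% names(neg_groups) && length(lig_pos)) {
      ctr <- group_centroid(res, neg_groups[[rn]])
      if (!is.null(ctr)) {
        d <- sqrt(rowSums((lig_xyz[lig_pos, , drop = FALSE] -
                             matrix(ctr, length(lig_pos), 3, byrow = TRUE))^2))
        for (k in which(d <= config$saltbridge_dist)) {
          add("salt_bridge", res$key[1], lig_pos[k], d[k])
        }
      }
    }
    if (rn %in% names(pos_groups) && length(lig_neg)) {
      ctr <- group_centroid(res, pos_groups[[rn]])
      if (!is.null(ctr)) {
        d <- sqrt(rowSums((lig_xyz[lig_neg, , drop = FALSE] -
                             matrix(ctr, length(lig_neg), 3, byrow = TRUE))^2))
        for (k in which(d <= config$saltbridge_dist)) {
          add("salt_bridge", res$key[1], lig_neg[k], d[k])
        }
      }
    }
  }

  ## water bridges -------------------------------------------------------
  if (!is.null(waters) && nrow(waters) && length(lig_polar) &&
      length(prot_polar)) {
    dw_l <- cross_dist(waters, lig_xyz[lig_polar, , drop = FALSE])
    dw_p <- cross_dist(waters, as.matrix(at[prot_polar, c("x", "y", "z")]))
    for (w in seq_len(nrow(waters))) {
      li_ok <- which(dw_l[w, ] <= config$hbond_dist & dw_l[w, ] >= 2.0)
      pi_ok <- which(dw_p[w, ] <= config$hbond_dist & dw_p[w, ] >= 2.0)
      for (li in li_ok) for (pi_ in pi_ok) {
        add("water_bridge", at$key[prot_polar[pi_]], lig_polar[li],
            max(dw_l[w, li], dw_p[w, pi_]))
      }
    }
  }

  ## halogen bonds -------------------------------------------------------
  lig_hal <- which(lig_el %in% HALOGENS)
  prot_acc_x <- which(at$element %in% c("O", "N", "S"))
  for (x in lig_hal) {
    cnb <- heavy_neighbors(x)
    if (!length(cnb)) next
    d <- sqrt(rowSums((as.matrix(at[prot_acc_x, c("x", "y", "z")]) -
                         matrix(lig_xyz[x, ], length(prot_acc_x), 3,
                                byrow = TRUE))^2))
    for (k in which(d <= config$halogen_dist)) {
      a <- vec_angle(lig_xyz[cnb[1], ] - lig_xyz[x, ],
                     as.numeric(at[prot_acc_x[k], c("x", "y", "z")]) -
                       lig_xyz[x, ])
      if (a >= config$halogen_angle) {
        add("halogen_bond", at$key[prot_acc_x[k]], x, d[k], a)
      }
    }
  }

  if (!length(rec)) {
    return(data.frame(kind = character(0), residue = character(0),
                      ligand_atoms = character(0), distance = numeric(0),
                      angle = numeric(0)))
  }
  out <- do.call(rbind, rec)
  out <- out[order(out$residue, out$kind, out$ligand_atoms), , drop = FALSE]
  rownames(out) <- NULL
  out
}
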