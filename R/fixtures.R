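# Seeded generators for every input the toolkit needs: toy protein-ligand
# complexes in PDB format, the stored curcumin structure, and labeled
# score tables. All generators are deterministic per seed, so fixtures are
# reproducible and never downloaded.

#' Generate a toy protein-ligand complex as PDB text
#'
#' Builds a pocket as a chemically complementary imprint of a small rigid
#' ligand: across every ligand heavy atom sits a wall atom of matching
#' polarity (a hydrogen-bond partner at 2.8 Angstrom across ligand N/O,
#' an apolar carbon at 3.6 Angstrom across ligand C), each carried by a
#' pseudo-residue whose C-alpha lies 1.5 Angstrom further out, plus an
#' outer shell of CA/CB residues for bulk. The crystal placement is
#' therefore the contact-optimal pose, which makes re-docking recovery a
#' well-posed check. The geometry is trivially auditable: no physics,
#' just distances that exercise the extraction filters, grids, docking
#' and clustering. Residue names vary with the imprint chemistry and
#' seed, so sequences and residue labels differ between seeds.
#'
#' The ligand's rigid core is a distorted box (edges 1.4/1.5/1.6; every
#' vertex has three neighbors at bond range, so the perceived graph is
#' cyclic and rigid) plus one protruding atom; the distortion, the
#' protrusion and the element pattern leave no element-preserving proper
#' rotation, so pose recovery is unambiguous. Sizes above 9 grow a
#' flexible tail (rotatable bond); sizes below 9 take a connected subset
#' of the box.
#'
#' @param seed RNG seed; the same seed always yields byte-identical text.
#' @param n_extra number of additional outer-shell residues (default 12).
#' @param pocket_radius radius of the outer shell, Angstrom (default 9).
#' @param ligand_size ligand heavy-atom count (default 9).
#' @param het_code HET residue code of the ligand.
#' @param organism value of the SOURCE organism record.
#' @param chain chain identifier.
#' @param n_waters number of water molecules to scatter near the ligand.
#' @param assembly_copies if > 1, REMARK 350 operators (identity plus
#'   rotated copies) are written.
#' @param lig_pattern element pattern of the ligand (recycled to
#'   `ligand_size`); the default mixes C/N/O. An all-carbon pattern yields
#'   an apolar ligand and pocket, useful as a decoy in planted-binder
#'   screens.
#' @return PDB-format text (single string).
#' @export
make_toy_complex <- function(seed = 1L, n_extra = 12L, pocket_radius = 9,
                             ligand_size = 9L, het_code = "LIG",
                             organism = "Homo sapiens", chain = "A",
                             n_waters = 0L, assembly_copies = 1L,
                             lig_pattern = c("C", "N", "O", "C", "O",
                                             "C", "N", "C", "O")) {
  core <- as.matrix(expand.grid(c(0, 1.4), c(0, 1.5), c(0, 1.6)))
  core <- sweep(core, 2, colMeans(core))
  core <- rbind(core, core[8, ] + c(1, 1, 1) / sqrt(3) * 1.5)
  lig_radius <- max(sqrt(rowSums(core^2))) + 1.5 * max(0, ligand_size - 9)
  if (lig_radius + 3.6 + 2.0 > pocket_radius) {
    stop("ligand larger than pocket: increase pocket_radius")
  }
  stopifnot(length(lig_pattern) >= 1,
            all(lig_pattern %in% SUPPORTED_ELEMENTS))
  el_pattern <- lig_pattern

  with_seed(seed, {
    lig <- core
    if (ligand_size > 9L) {
      # flexible tail grown from the first core vertex, away from center
      dir0 <- core[1, ] / sqrt(sum(core[1, ]^2))
      for (k in seq_len(ligand_size - 9L)) {
        lig <- rbind(lig, core[1, ] + dir0 * 1.5 * k +
                       c(0, 0.25 * (k %% 2), 0))
      }
    } else if (ligand_size < 9L) {
      lig <- lig[seq_len(ligand_size), , drop = FALSE]
    }
    lig <- lig %*% t(random_rotations(1)[[1]])
    lig_el <- rep(el_pattern, length.out = nrow(lig))

    # complementary imprint: H-bond partners across polar atoms, apolar
    # carbons across carbons, with seeded direction jitter
    ctr <- colMeans(lig)
    gap <- ifelse(lig_el == "C", 3.6, 2.8)
    imp_el <- ifelse(lig_el == "C", "C", ifelse(lig_el == "N", "O", "N"))
    dirs <- lig - matrix(ctr, nrow(lig), 3, byrow = TRUE)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    dirs <- dirs + matrix(rnorm(length(dirs), sd = 0.25), nrow(dirs), 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    imp <- lig + dirs * gap
    imp_ca <- imp + dirs * 1.5
    imp_res <- ifelse(imp_el == "C",
                      sample(c("ALA", "VAL", "LEU"), nrow(lig), TRUE),
                      ifelse(imp_el == "O", "SER", "ASN"))
    imp_name <- ifelse(imp_el == "C", "CB",
                       ifelse(imp_el == "O", "OG", "ND2"))

    # outer shell for bulk
    shell_dirs <- matrix(NA_real_, n_extra, 3)
    got <- 0L
    while (got < n_extra) {
      v <- rnorm(3)
      v <- v / sqrt(sum(v^2))
      if (v[3] < cos(40 * pi / 180)) {
        got <- got + 1L
        shell_dirs[got, ] <- v
      }
    }
    shell_res <- sample(c("ALA", "SER", "VAL", "LEU", "THR"), n_extra, TRUE)
    shell_ca <- sweep(shell_dirs * pocket_radius, 2, ctr, "+")
    shell_cb <- sweep(shell_dirs * (pocket_radius - 1.3), 2, ctr, "+")

    wat <- NULL
    if (n_waters > 0) {
      wd <- matrix(rnorm(3 * n_waters), n_waters, 3)
      wd <- wd / sqrt(rowSums(wd^2))
      wat <- sweep(wd * 3.2, 2, ctr, "+")
    }

    lines <- c(
      "HEADER    SYNTHETIC COMPLEX",
      sprintf("TITLE     TOY POCKET SEED %d", seed),
      sprintf("SOURCE    2 ORGANISM_SCIENTIFIC: %s;", toupper(organism))
    )
    if (assembly_copies > 1L) {
      lines <- c(lines,
                 "REMARK 350 BIOMOLECULE: 1",
                 sprintf("REMARK 350 APPLY THE FOLLOWING TO CHAINS: %s", chain))
      for (k in seq_len(assembly_copies)) {
        ang <- 2 * pi * (k - 1) / assembly_copies
        R <- axis_rotation(c(0, 0, 1), ang)
        tr <- if (k == 1) c(0, 0, 0) else c(0, 0, 3 * pocket_radius * (k - 1))
        for (row in 1:3) {
          lines <- c(lines, sprintf(
            "REMARK 350   BIOMT%d %3d %9.6f %9.6f %9.6f %14.5f",
            row, k, R[row, 1], R[row, 2], R[row, 3], tr[row]))
        }
      }
    }
    serial <- 0L
    atom_line <- function(type, name, resid, resno, xyz, element,
                          het = FALSE) {
      serial <<- serial + 1L
      sprintf("%-6s%5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              type, serial, name, "", resid, chain, resno, "",
              xyz[1], xyz[2], xyz[3], 1.0, 0.0, element)
    }
    for (i in seq_len(nrow(imp))) {
      lines <- c(lines,
                 atom_line("ATOM", "CA", imp_res[i], i, imp_ca[i, ], "C"),
                 atom_line("ATOM", imp_name[i], imp_res[i], i, imp[i, ],
                           imp_el[i]))
    }
    for (i in seq_len(n_extra)) {
      lines <- c(lines,
                 atom_line("ATOM", "CA", shell_res[i], nrow(imp) + i,
                           shell_ca[i, ], "C"),
                 atom_line("ATOM", "CB", shell_res[i], nrow(imp) + i,
                           shell_cb[i, ], "C"))
    }
    for (i in seq_len(nrow(lig))) {
      lines <- c(lines,
                 atom_line("HETATM", paste0(lig_el[i], i), het_code,
                           500L, lig[i, ], lig_el[i]))
    }
    if (!is.null(wat)) {
      for (i in seq_len(nrow(wat))) {
        lines <- c(lines,
                   atom_line("HETATM", "O", "HOH", 600L + i, wat[i, ], "O"))
      }
    }
    paste(c(lines, "END"), collapse = "\n")
  })
}

#' The stored curcumin structure
#'
#' Reads the canonical curcumin structure shipped with the package: the
#' enol tautomer (the form favored at physiological pH), neutral, with a
#' fixed 3D conformation, explicit hydrogens and perceived aromaticity.
#' Two methoxylated phenol rings joined by the conjugated heptadienone
#' linker; 27 heavy atoms, 7 rotatable bonds under the fragmentation rule.
#'
#' @return an `invdock_mol`.
#' @export
make_curcumin <- function() {
  path <- system.file("extdata", "curcumin.sdf", package = "invdock")
  if (!nzchar(path)) stop("stored curcumin structure not found")
  parse_small_molecule(path, name = "curcumin")
}

#' Generate a labeled score table
#'
#' Draws `n` active scores from Normal(`active_mean`, `sd`) and `N - n`
#' inactive scores from Normal(`inactive_mean`, `sd`), merges, sorts and
#' labels them. The defaults mimic the shape of a proteome-wide inverse
#' screen: 21 actives among 13,553 entries, an inactive score distribution
#' centered at -27.47 with sd 13.13 (the fitted screen-wide distribution)
#' and actives centered at the selection threshold -53.21.
#'
#' @param seed RNG seed.
#' @param n number of actives.
#' @param N total entries.
#' @param active_mean,inactive_mean,sd normal parameters (arb. units).
#' @return an `invdock_ranking`.
#' @export
make_labeled_scores <- function(seed = 1L, n = 21L, N = 13553L,
                                active_mean = -53.21,
                                inactive_mean = -27.47, sd = 13.13) {
  stopifnot(N >= n, n >= 1, sd > 0)
  with_seed(seed, {
    sc_a <- rnorm(n, active_mean, sd)
    sc_i <- rnorm(N - n, inactive_mean, sd)
    labeled_ranking(
      id = sprintf("P%05d", seq_len(N)),
      score = c(sc_a, sc_i),
      active = c(rep(TRUE, n), rep(FALSE, N - n))
    )
  })
}
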