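# Small-molecule model: atoms, bonds, rotatable-bond perception and
# fragmentation into rigid units ("atoms to fragments").

SUPPORTED_ELEMENTS <- c("C", "N", "O", "S", "P", "H", "F", "Cl", "Br", "I")
HALOGENS <- c("F", "Cl", "Br", "I")

#' Construct a molecule object
#'
#' Low-level constructor; most users will call [parse_small_molecule()].
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix (n x 3), Angstrom.
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices),
#'   `order` (1, 2, 3; aromatic bonds carry their Kekule order) and logical
#'   `aromatic`. A `rotatable` column is added by
#'   [perceive_rotatable_bonds()].
#' @param name molecule identifier.
#' @param aromatic logical per-atom aromatic flags.
#' @param formal_charge integer per-atom formal charges.
#' @return an object of class `invdock_mol`.
#' @export
new_molecule <- function(elements, coords, bonds, name = "mol",
                         aromatic = NULL, formal_charge = NULL) {
  coords <- as.matrix(coords)
  n <- length(elements)
  stopifnot(nrow(coords) == n, ncol(coords) == 3)
  if (!all(is.finite(coords))) stop("molecule '", name, "': non-finite coordinates")
  bad <- setdiff(unique(elements), SUPPORTED_ELEMENTS)
  if (length(bad)) stop("unsupported element(s): ", paste(bad, collapse = ", "))
  bonds <- as.data.frame(bonds)
  if (nrow(bonds)) {
    if (any(bonds$i == bonds$j)) stop("self-bond in molecule '", name, "'")
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n)) {
      stop("bond index out of range in molecule '", name, "'")
    }
  }
  if (is.null(bonds$aromatic)) bonds$aromatic <- logical(nrow(bonds))
  structure(list(
    name = name,
    elements = elements,
    coords = coords,
    bonds = bonds,
    aromatic = aromatic %||% rep(FALSE, n),
    formal_charge = as.integer(formal_charge %||% rep(0L, n))
  ), class = "invdock_mol")
}

#' @export
print.invdock_mol <- function(x, ...) {
  cat("<invdock_mol>", x$name, "-", length(x$elements), "atoms (",
      count_heavy_atoms(x), "heavy ),", nrow(x$bonds), "bonds\n")
  invisible(x)
}

is_heavy <- function(m) m$elements != "H"

#' Count non-hydrogen atoms
#'
#' Heavy-atom counting backs the co-crystallized-ligand filter of the
#' site-database builder (groups with more than 7 heavy atoms are candidate
#' ligands).
#'
#' @param m an `invdock_mol`.
#' @return integer count of non-hydrogen atoms.
#' @export
count_heavy_atoms <- function(m) sum(is_heavy(m))

# igraph over heavy atoms only; vertex names are original atom indices.
heavy_graph <- function(m) {
  heavy <- which(is_heavy(m))
  b <- m$bonds[m$bonds$i %in% heavy & m$bonds$j %in% heavy, , drop = FALSE]
  igraph::graph_from_data_frame(
    data.frame(from = as.character(b$i), to = as.character(b$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(heavy))
  )
}

#' Parse a small molecule from SMILES or SDF
#'
#' SMILES strings are parsed through ChemmineR/OpenBabel; SDF (V2000) text,
#' a path to an `.sdf`/`.mol` file, or a `ChemmineR::SDFset` are read with
#' ChemmineR. Aromaticity is perceived from the ring systems. If the input
#' carries no 3D coordinates (SMILES, 2D SDF), deterministic 3D coordinates
#' are generated by a seeded distance-restraint embedding
#' ([embed_molecule_3d()]).
#'
#' @param source SMILES string, SDF text, file path, or `SDFset`.
#' @param name molecule name; defaults to the SDF title or "mol".
#' @param embed_seed seed for the deterministic 3D embedding of inputs
#'   without coordinates.
#' @return an `invdock_mol` with aromatic flags set.
#' @export
parse_small_molecule <- function(source, name = NULL, embed_seed = 1L) {
  lines <- NULL
  if (inherits(source, "SDFset")) {
    if (length(source) < 1) stop("empty SDF input")
    mol <- mol_from_sdf(source[[1]], name = name)
    if (all(abs(mol$coords[, 3]) < 1e-8)) {
      mol <- embed_molecule_3d(mol, seed = embed_seed)
    }
    return(mol)
  } else if (length(source) == 1 && !grepl("\n", source) &&
             file.exists(source)) {
    lines <- readLines(source)
  } else if (any(grepl("V2000", source))) {
    lines <- unlist(strsplit(source, "\n"))
  } else {
    if (length(source) != 1) stop("expected a single SMILES string")
    txt <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF",
                                                 paste0(source, "\n"))),
      error = function(e) {
        stop("SMILES parse failure for '", source, "': ", conditionMessage(e))
      }
    )
    lines <- unlist(strsplit(txt, "\n"))
    if (!any(grepl("V2000", lines))) {
      stop("SMILES parse failure for '", source, "': no structure returned")
    }
  }
  idx <- grep("^M  END", lines)
  if (length(idx)) lines <- lines[seq_len(idx[1])]  # first record only
  if (!any(grepl("V2000", lines))) stop("not a V2000 molblock")
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(c(lines, "$$$$"), tf)
  sdf <- suppressWarnings(ChemmineR::read.SDFset(tf))
  mol <- if (length(sdf) >= 1 && isTRUE(ChemmineR::validSDF(sdf)[1])) {
    mol_from_sdf(sdf[[1]], name = name)
  } else {
    # ChemmineR rejects bond-less molecules; read the molblock directly
    mol_from_v2000(lines, name = name)
  }
  if (nrow(mol$coords) > 1 && all(abs(mol$coords[, 3]) < 1e-8)) {
    mol <- embed_molecule_3d(mol, seed = embed_seed)
  }
  mol
}

# Minimal V2000 reader for the degenerate cases (0 or 1 bond) that the
# ChemmineR container cannot hold.
mol_from_v2000 <- function(lines, name = NULL) {
  counts <- lines[4]
  n <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(n) || n < 1) stop("empty or malformed molblock")
  atoms <- lines[5:(4 + n)]
  tok <- strsplit(trimws(atoms), "\\s+")
  coords <- t(vapply(tok, function(t) as.numeric(t[1:3]), numeric(3)))
  elements <- vapply(tok, `[[`, "", 4)
  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  if (!is.na(nb) && nb > 0) {
    bl <- lines[(5 + n):(4 + n + nb)]
    bonds <- data.frame(
      i = as.integer(substr(bl, 1, 3)),
      j = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  }
  charges <- integer(n)
  chg <- grep("^M  CHG", lines, value = TRUE)
  for (line in chg) {
    t2 <- as.integer(strsplit(trimws(sub("^M  CHG", "", line)), "\\s+")[[1]])
    for (p in seq_len(t2[1])) charges[t2[2 * p]] <- t2[2 * p + 1]
  }
  ttl <- trimws(lines[1])
  mol <- new_molecule(elements, coords, bonds,
                      name = name %||% (if (nzchar(ttl)) ttl else "mol"),
                      formal_charge = charges)
  perceive_aromaticity(mol)
}

# Build an invdock_mol from a single ChemmineR SDF object.
mol_from_sdf <- function(sdfobj, name = NULL) {
  ab <- ChemmineR::atomblock(sdfobj)
  bb <- ChemmineR::bondblock(sdfobj)
  if (is.null(dim(ab))) ab <- matrix(ab, nrow = 1,
                                     dimnames = list(names(ab)[1], NULL))
  if (!is.null(bb) && is.null(dim(bb))) bb <- matrix(bb, nrow = 1)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  n <- length(elements)
  bonds <- if (!is.null(bb) && nrow(bb)) {
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  } else {
    data.frame(i = integer(0), j = integer(0), order = integer(0))
  }
  charges <- sdf_formal_charges(sdfobj, n)
  mol <- new_molecule(elements, coords, bonds,
                      name = name %||% sdf_title(sdfobj),
                      formal_charge = charges)
  perceive_aromaticity(mol)
}

sdf_title <- function(sdfobj) {
  h <- ChemmineR::header(sdfobj)
  t <- trimws(h[["Molecule_Name"]] %||% h[[1]] %||% "mol")
  if (!nzchar(t)) "mol" else t
}

# Formal charges from the V2000 block: "M  CHG" properties override the
# old-style per-atom charge codes (3 = +1, 5 = -1, ...).
sdf_formal_charges <- function(sdfobj, n) {
  lines <- as(sdfobj, "character")
  charges <- integer(n)
  atom_lines <- lines[seq(5L, length.out = n)]
  code_map <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  for (k in seq_len(n)) {
    tok <- strsplit(trimws(atom_lines[k]), "\\s+")[[1]]
    if (length(tok) >= 6) {
      code <- tok[6]
      if (code %in% names(code_map)) charges[k] <- code_map[[code]]
    }
  }
  chg <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg)) {
    charges[] <- 0L
    for (line in chg) {
      tok <- as.integer(strsplit(trimws(sub("^M  CHG", "", line)), "\\s+")[[1]])
      cnt <- tok[1]
      for (p in seq_len(cnt)) {
        charges[tok[2 * p]] <- tok[2 * p + 1]
      }
    }
  }
  charges
}

# Flag atoms and bonds belonging to aromatic rings (ChemmineR ring
# perception with aromaticity test).
perceive_aromaticity <- function(mol) {
  n <- length(mol$elements)
  arom_atoms <- rep(FALSE, n)
  if (nrow(mol$bonds)) {
    sdfobj <- mol_to_sdf(mol)
    r <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdfobj, type = "all", arom = TRUE)),
      error = function(e) NULL
    )
    if (!is.null(r) && length(r$RINGS)) {
      for (k in seq_along(r$RINGS)) {
        if (isTRUE(r$AROMATIC[[k]])) {
          idx <- as.integer(sub("^[A-Za-z]+_", "", r$RINGS[[k]]))
          arom_atoms[idx] <- TRUE
        }
      }
    }
  }
  mol$aromatic <- arom_atoms
  mol$bonds$aromatic <- arom_atoms[mol$bonds$i] & arom_atoms[mol$bonds$j] &
    bond_in_ring(mol)
  mol
}

# TRUE for bonds that are part of at least one ring (non-bridges).
bond_in_ring <- function(mol) {
  nb <- nrow(mol$bonds)
  if (!nb) return(logical(0))
  g <- igraph::graph_from_data_frame(
    data.frame(from = mol$bonds$i, to = mol$bonds$j),
    directed = FALSE,
    vertices = data.frame(name = seq_along(mol$elements))
  )
  br <- igraph::bridges(g)
  in_ring <- rep(TRUE, nb)
  in_ring[as.integer(br)] <- FALSE
  in_ring
}

# Round-trip an invdock_mol into a ChemmineR SDF object.
mol_to_sdf <- function(mol) {
  n <- length(mol$elements)
  ab <- cbind(mol$coords, matrix(0, n, 13))
  rownames(ab) <- paste(mol$elements, seq_len(n), sep = "_")
  colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:16), "C17")
  bb <- as.matrix(cbind(mol$bonds$i, mol$bonds$j, mol$bonds$order,
                        0, 0, 0, 0))
  colnames(bb) <- paste0("C", 1:7)
  rownames(bb) <- as.character(seq_len(nrow(bb)))
  methods::new(methods::getClass("SDF", where = asNamespace("ChemmineR")),
               header = c(Molecule_Name = mol$name, Source = "invdock",
                          Comment = "", Counts_Line = sprintf(
                            "%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bb))),
               atomblock = ab, bondblock = bb, datablock = character(0))
}

#' Write molecules to an SDF (V2000) file
#'
#' @param mols a single `invdock_mol` or a list of them.
#' @param path output file.
#' @export
write_molecule_sdf <- function(mols, path) {
  if (inherits(mols, "invdock_mol")) mols <- list(mols)
  sdfl <- lapply(mols, mol_to_sdf)
  sdfs <- methods::new(
    methods::getClass("SDFset", where = asNamespace("ChemmineR")),
    SDF = sdfl, ID = make.unique(vapply(mols, `[[`, "", "name")))
  ChemmineR::write.SDF(sdfs, file = path)
  invisible(path)
}

#' Flag rotatable bonds
#'
#' A bond is rotatable iff it is a single (non-aromatic) bond, acyclic
#' (a bridge of the heavy-atom graph), non-terminal (both ends bonded to at
#' least two heavy atoms) and not an amide C-N bond. This is the
#' fragmentation contract of the docking engine: cutting exactly these
#' bonds yields the rigid fragments.
#'
#' @param m an `invdock_mol` with aromaticity perceived.
#' @return the molecule with a logical `rotatable` column on `$bonds`.
#' @export
perceive_rotatable_bonds <- function(m) {
  b <- m$bonds
  nb <- nrow(b)
  if (!nb) {
    m$bonds$rotatable <- logical(0)
    return(m)
  }
  heavy <- is_heavy(m)
  hdeg <- integer(length(m$elements))
  hb <- b[heavy[b$i] & heavy[b$j], , drop = FALSE]
  for (k in seq_len(nrow(hb))) {
    hdeg[hb$i[k]] <- hdeg[hb$i[k]] + 1L
    hdeg[hb$j[k]] <- hdeg[hb$j[k]] + 1L
  }
  in_ring <- bond_in_ring(m)
  rot <- b$order == 1 & !b$aromatic & !in_ring &
    heavy[b$i] & heavy[b$j] & hdeg[b$i] >= 2L & hdeg[b$j] >= 2L
  rot <- rot & !is_amide_bond(m)
  m$bonds$rotatable <- rot
  m
}

# Amide C-N: a single bond between N and a carbon that carries a double
# bond to oxygen.
is_amide_bond <- function(m) {
  b <- m$bonds
  carbonyl_c <- unique(c(
    b$i[b$order == 2 & m$elements[b$i] == "C" & m$elements[b$j] == "O"],
    b$j[b$order == 2 & m$elements[b$j] == "C" & m$elements[b$i] == "O"]
  ))
  (b$order == 1) & (
    (m$elements[b$i] == "N" & b$j %in% carbonyl_c) |
    (m$elements[b$j] == "N" & b$i %in% carbonyl_c)
  )
}

#' Cut rotatable bonds into rigid fragments
#'
#' Cutting every rotatable bond partitions the heavy atoms into rigid
#' fragments; link records keep the cut-bond atom pair and its reference
#' length so that fragment poses can later be reassembled
#' ("fragments to ligands").
#'
#' @param m an `invdock_mol` with rotatable bonds perceived
#'   (see [perceive_rotatable_bonds()]; called automatically if missing).
#' @return an object of class `invdock_fraggraph`: list with `molecule`,
#'   `fragments` (list of heavy-atom index vectors), and `links`
#'   (data.frame `frag_i`, `frag_j`, `atom_i`, `atom_j`, `ref_length`).
#' @export
fragment_ligand <- function(m) {
  if (is.null(m$bonds$rotatable)) m <- perceive_rotatable_bonds(m)
  g <- heavy_graph(m)
  if (igraph::vcount(g) == 0) stop("molecule has no heavy atoms")
  if (igraph::components(g)$no != 1) {
    stop("molecule '", m$name, "' is disconnected; cannot fragment")
  }
  cuts <- m$bonds[m$bonds$rotatable, , drop = FALSE]
  g_cut <- g
  if (nrow(cuts)) {
    eids <- igraph::get_edge_ids(
      g, rbind(as.character(cuts$i), as.character(cuts$j)))
    g_cut <- igraph::delete_edges(g, eids)
  }
  comp <- igraph::components(g_cut)
  atom_ids <- as.integer(igraph::V(g)$name)
  fragments <- lapply(seq_len(comp$no), function(k) {
    sort(atom_ids[comp$membership == k])
  })
  frag_of <- integer(max(atom_ids))
  for (k in seq_along(fragments)) frag_of[fragments[[k]]] <- k
  links <- data.frame(frag_i = integer(0), frag_j = integer(0),
                      atom_i = integer(0), atom_j = integer(0),
                      ref_length = numeric(0))
  for (k in seq_len(nrow(cuts))) {
    ai <- cuts$i[k]; aj <- cuts$j[k]
    links[k, ] <- list(frag_of[ai], frag_of[aj], ai, aj,
                       sqrt(sum((m$coords[ai, ] - m$coords[aj, ])^2)))
  }
  structure(list(molecule = m, fragments = fragments, links = links),
            class = "invdock_fraggraph")
}

#' @export
print.invdock_fraggraph <- function(x, ...) {
  cat("<invdock_fraggraph>", x$molecule$name, "-",
      length(x$fragments), "fragments,", nrow(x$links), "links\n")
  invisible(x)
}

# Hydrogens riding on each fragment (index vector per fragment).
fragment_hydrogens <- function(fg) {
  m <- fg$molecule
  h_idx <- which(m$elements == "H")
  frag_of <- integer(length(m$elements))
  for (k in seq_along(fg$fragments)) frag_of[fg$fragments[[k]]] <- k
  out <- vector("list", length(fg$fragments))
  for (h in h_idx) {
    nb <- c(m$bonds$j[m$bonds$i == h], m$bonds$i[m$bonds$j == h])
    nb <- nb[m$elements[nb] != "H"]
    if (length(nb)) {
      k <- frag_of[nb[1]]
      out[[k]] <- c(out[[k]], h)
    }
  }
  out
}
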