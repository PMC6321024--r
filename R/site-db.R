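# Binding-site database: extract co-crystallized ligands and their binding
# residues from PDB entries, cluster chains by sequence and sites by
# structural similarity, and reduce each site cluster to one representative
# whose docking search volume is a union of centroid spheres.

#' Parameters of the site-database builder
#'
#' @param min_heavy_atoms minimum heavy-atom count of a candidate ligand
#'   (default 8, i.e. strictly more than 7 heavy atoms).
#' @param ligand_contact_cutoff Angstrom; a candidate ligand must have at
#'   least one heavy atom strictly closer than this to the protein chain
#'   (default 3.0).
#' @param binding_residue_cutoff Angstrom; residues with any heavy atom
#'   strictly closer than this to any ligand heavy atom are binding
#'   residues (default 5.0).
#' @param seq_identity_cutoff fraction in (0, 1]; chains are clustered at
#'   this sequence identity (default 1.0 = exact identity).
#' @param site_z_cutoff similarity z-score at or above which two sites join
#'   the same cluster (default 2.0).
#' @param taxon_filter keep only entries whose source organism matches this
#'   (case-insensitive); `NULL` disables the filter. Default "Homo sapiens".
#' @param cofactor_codes HET codes treated as cofactors and excluded from
#'   candidate ligands, alongside water.
#' @return a list of class `invdock_sitedb_params`.
#' @export
site_db_params <- function(min_heavy_atoms = 8L,
                           ligand_contact_cutoff = 3.0,
                           binding_residue_cutoff = 5.0,
                           seq_identity_cutoff = 1.0,
                           site_z_cutoff = 2.0,
                           taxon_filter = "Homo sapiens",
                           cofactor_codes = c("HEM", "NAD", "NAP", "FAD",
                                              "FMN", "ADP", "ATP", "AMP",
                                              "GDP", "GTP", "COA", "PLP",
                                              "SAM", "SAH")) {
  stopifnot(min_heavy_atoms >= 1, ligand_contact_cutoff > 0,
            binding_residue_cutoff > 0,
            seq_identity_cutoff > 0, seq_identity_cutoff <= 1,
            site_z_cutoff > 0)
  structure(list(min_heavy_atoms = as.integer(min_heavy_atoms),
                 ligand_contact_cutoff = ligand_contact_cutoff,
                 binding_residue_cutoff = binding_residue_cutoff,
                 seq_identity_cutoff = seq_identity_cutoff,
                 site_z_cutoff = site_z_cutoff,
                 taxon_filter = taxon_filter,
                 cofactor_codes = cofactor_codes),
            class = "invdock_sitedb_params")
}

#' Load a protein structure from PDB text or file
#'
#' Parses ATOM/HETATM records (through bio3d), keeps the highest-occupancy
#' alternate location per atom, separates waters (HOH) from other HET
#' groups, reads biological-assembly transforms from REMARK 350 (identity
#' if absent) and the source organism from the SOURCE records.
#'
#' @param pdb path to a PDB file or PDB-format text (with newlines).
#' @param entry_id entry identifier; defaults to the file base name.
#' @param apply_assembly logical; apply REMARK 350 transforms, generating
#'   chain copies for non-identity operators (default TRUE).
#' @return an object of class `invdock_entry` with elements `entry_id`,
#'   `atom` (protein atoms, data.frame), `het` (list of HET groups),
#'   `waters` (water oxygen coordinates), `transforms`, `organism`.
#' @export
load_structure <- function(pdb, entry_id = NULL, apply_assembly = TRUE) {
  if (length(pdb) == 1 && !grepl("\n", pdb)) {
    if (!file.exists(pdb)) stop("PDB file not found: ", pdb)
    path <- pdb
    entry_id <- entry_id %||% sub("\\.(pdb|ent)$", "", basename(path))
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(paste(pdb, collapse = "\n"), path)
    entry_id <- entry_id %||% "entry"
  }
  raw <- readLines(path)
  if (!any(grepl("^ATOM ", raw))) stop("entry '", entry_id, "': no ATOM records")
  bad <- grep("^(ATOM|HETATM)", raw)
  bad <- bad[nchar(raw[bad]) >= 54 &
             is.na(suppressWarnings(as.numeric(substr(raw[bad], 31, 38))))]
  if (length(bad)) {
    stop("entry '", entry_id, "': malformed coordinates at line ", bad[1])
  }
  p <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- p$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at <- pick_altloc(at)

  organism <- "unknown"
  src <- grep("ORGANISM_SCIENTIFIC:", raw, value = TRUE)
  if (length(src)) {
    organism <- trimws(sub(";.*$", "", sub(".*ORGANISM_SCIENTIFIC:", "", src[1])))
  }

  transforms <- list(diag(4)[1:3, ])
  bm <- p$remark$biomat
  if (!is.null(bm) && length(bm$mat)) {
    mats <- unlist(bm$mat, recursive = FALSE)
    if (length(mats)) transforms <- unname(mats)
  }

  prot <- at[at$type == "ATOM", , drop = FALSE]
  hets <- at[at$type == "HETATM" & at$resid != "HOH", , drop = FALSE]
  wat <- at[at$type == "HETATM" & at$resid == "HOH", , drop = FALSE]

  if (apply_assembly && length(transforms) > 1) {
    prot <- apply_transforms(prot, transforms)
    hets <- apply_transforms(hets, transforms)
    wat <- apply_transforms(wat, transforms)
  }

  het_groups <- split(hets, interaction(hets$chain, hets$resno, hets$resid,
                                        drop = TRUE))
  het_groups <- lapply(het_groups, function(g) {
    structure(list(het_code = g$resid[1], chain = g$chain[1],
                   resno = g$resno[1], parent_entry = entry_id,
                   elements = normalize_element(g$elesy, g$elety),
                   coords = as.matrix(g[, c("x", "y", "z")])),
              class = "invdock_het")
  })
  ord <- order(vapply(het_groups, function(g) {
    sprintf("%s|%06d|%s", g$chain, g$resno, g$het_code)
  }, ""))
  het_groups <- unname(het_groups[ord])

  structure(list(entry_id = entry_id, atom = prot, het = het_groups,
                 waters = as.matrix(wat[, c("x", "y", "z")]),
                 transforms = transforms, organism = organism),
            class = "invdock_entry")
}

#' @export
print.invdock_entry <- function(x, ...) {
  cat("<invdock_entry>", x$entry_id, "-", length(entry_chain_ids(x)),
      "chain(s),", length(x$het), "het group(s),", nrow(x$waters),
      "water(s), organism:", x$organism, "\n")
  invisible(x)
}

# Keep, per atom position (chain/resno/insert/elety), the altloc row with
# the highest occupancy; ties broken by altloc letter.
pick_altloc <- function(at) {
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
  if (!anyDuplicated(key)) return(at)
  at$o[is.na(at$o)] <- 1
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
    idx[order(-at$o[idx], at$alt[idx])][1]
  }), use.names = FALSE)
  at[sort(keep), , drop = FALSE]
}

# Apply 3x4 rotation|translation operators; copy k > 1 renames chains by
# suffixing the operator index.
apply_transforms <- function(at, transforms) {
  if (!nrow(at)) return(at)
  out <- vector("list", length(transforms))
  for (k in seq_along(transforms)) {
    tr <- transforms[[k]]
    a <- at
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(tr[, 1:3]) +
      matrix(tr[, 4], nrow(a), 3, byrow = TRUE)
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    if (k > 1) a$chain <- paste0(a$chain, k)
    out[[k]] <- a
  }
  do.call(rbind, out)
}

normalize_element <- function(elesy, elety) {
  e <- ifelse(is.na(elesy) | elesy == "", NA, elesy)
  e <- ifelse(is.na(e), sub("[0-9'].*$", "", trimws(elety)), e)
  e <- sub("^([A-Za-z])([a-z]?).*$", "\\1\\2", e)
  paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, 2)))
}

#' @export
print.invdock_het <- function(x, ...) {
  cat("<invdock_het>", x$het_code, "on chain", x$chain, "resno", x$resno,
      "-", sum(x$elements != "H"), "heavy atoms\n")
  invisible(x)
}

entry_chain_ids <- function(entry) sort(unique(entry$atom$chain))

chain_atoms <- function(entry, chain_id) {
  entry$atom[entry$atom$chain == chain_id, , drop = FALSE]
}

#' One-letter sequence of a protein chain
#' @param entry an `invdock_entry`.
#' @param chain_id chain identifier.
#' @return one-letter amino-acid string ("X" for non-standard residues).
#' @export
chain_sequence <- function(entry, chain_id) {
  at <- chain_atoms(entry, chain_id)
  res <- at[!duplicated(paste(at$resno, at$insert)), , drop = FALSE]
  res <- res[order(res$resno, res$insert), , drop = FALSE]
  paste(bio3d::aa321(res$resid), collapse = "")
}

het_heavy_coords <- function(het) het$coords[het$elements != "H", , drop = FALSE]

#' Extract candidate co-crystallized ligands of a chain
#'
#' A HET group is a candidate ligand iff it has at least `min_heavy_atoms`
#' heavy atoms (default: strictly more than 7) and its minimum heavy-atom
#' distance to the chain's heavy atoms is strictly below
#' `ligand_contact_cutoff` (default 3 Angstrom). Waters are excluded
#' upstream; configured cofactor codes are excluded here.
#'
#' @param entry an `invdock_entry`.
#' @param chain_id chain to test contacts against.
#' @param p `site_db_params()`.
#' @return list of HET groups (possibly empty).
#' @export
extract_candidate_ligands <- function(entry, chain_id, p = site_db_params()) {
  at <- chain_atoms(entry, chain_id)
  prot <- as.matrix(at[at$elesy != "H" | is.na(at$elesy), c("x", "y", "z")])
  keep <- vapply(entry$het, function(h) {
    if (h$het_code %in% p$cofactor_codes) return(FALSE)
    hc <- het_heavy_coords(h)
    nrow(hc) >= p$min_heavy_atoms &&
      nrow(prot) > 0 &&
      min_dist(hc, prot) < p$ligand_contact_cutoff
  }, logical(1))
  entry$het[keep]
}

residue_key <- function(chain, resno, insert) {
  paste(chain, resno, insert, sep = ":")
}

#' Binding residues of a ligand
#'
#' Residues of the chain with at least one heavy atom strictly closer than
#' `binding_residue_cutoff` (default 5 Angstrom) to any ligand heavy atom.
#'
#' @inheritParams extract_candidate_ligands
#' @param lig a HET group as returned by [extract_candidate_ligands()].
#' @return character vector of residue keys "chain:resno:insert".
#' @export
binding_residues <- function(entry, chain_id, lig, p = site_db_params()) {
  at <- chain_atoms(entry, chain_id)
  at <- at[at$elesy != "H" | is.na(at$elesy), , drop = FALSE]
  if (!nrow(at)) return(character(0))
  d <- cross_dist(as.matrix(at[, c("x", "y", "z")]), het_heavy_coords(lig))
  near <- apply(d, 1, min) < p$binding_residue_cutoff
  keys <- residue_key(at$chain, at$resno, at$insert)
  sort(unique(keys[near]))
}

#' Assemble a binding site around one ligand
#'
#' @inheritParams binding_residues
#' @return an `invdock_site`: residues, their names, C-alpha coordinates,
#'   and the source ligand(s).
#' @export
make_binding_site <- function(entry, chain_id, lig, p = site_db_params()) {
  keys <- binding_residues(entry, chain_id, lig, p)
  if (!length(keys)) stop("ligand ", lig$het_code, " has no binding residues")
  at <- chain_atoms(entry, chain_id)
  akey <- residue_key(at$chain, at$resno, at$insert)
  ca <- at[at$elety == "CA" & akey %in% keys, , drop = FALSE]
  ca <- ca[order(ca$resno, ca$insert), , drop = FALSE]
  structure(list(
    site_id = paste(entry$entry_id, chain_id, lig$het_code, lig$resno,
                    sep = "_"),
    entry_id = entry$entry_id,
    chain = chain_id,
    residues = keys,
    res_names = ca$resid,
    ca_coords = as.matrix(ca[, c("x", "y", "z")]),
    ligands = list(lig),
    centroids = NULL
  ), class = "invdock_site")
}

#' @export
print.invdock_site <- function(x, ...) {
  cat("<invdock_site>", x$site_id, "-", length(x$residues), "residues,",
      length(x$ligands), "ligand(s),",
      if (is.null(x$centroids)) 0L else nrow(x$centroids), "centroid(s)\n")
  invisible(x)
}

#' Cluster protein chains by sequence identity
#'
#' At the default 100\% cutoff, chains share a cluster iff their sequences
#' are identical (single linkage over exact-identity pairs is then exact
#' grouping by sequence).
#'
#' @param seqs named character vector of one-letter sequences
#'   (names = chain identifiers).
#' @param p `site_db_params()`.
#' @return list of character vectors of chain identifiers.
#' @export
cluster_sequences <- function(seqs, p = site_db_params()) {
  stopifnot(all(nzchar(seqs)))
  if (p$seq_identity_cutoff < 1) {
    # identity fraction over the aligned-length-free exact positions
    n <- length(seqs)
    g <- igraph::make_empty_graph(n, directed = FALSE)
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a < b && seq_identity(seqs[a], seqs[b]) >= p$seq_identity_cutoff) {
        g <- igraph::add_edges(g, c(a, b))
      }
    }
    comp <- igraph::components(g)$membership
  } else {
    comp <- as.integer(factor(seqs, levels = unique(seqs)))
  }
  lapply(split(names(seqs) %||% seq_along(seqs), comp), as.character)
}

seq_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) return(0)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  mean(ca == cb)
}
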