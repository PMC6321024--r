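# Structural similarity of binding sites and the site-level clustering.
# The raw similarity is the size of the largest residue-label-compatible,
# distance-consistent correspondence between the two C-alpha sets,
# standardized against a permutation null into a z-score.

#' Structural-similarity z-score of two binding sites
#'
#' Builds the correspondence (product) graph: one node per residue pair
#' (i in `a`, j in `b`) with equal residue names; an edge joins two nodes
#' when the intra-site C-alpha distances agree within `tol`. The raw score
#' is the maximum clique size of that graph (the largest geometrically
#' consistent correspondence). The null distribution is obtained by
#' recomputing the raw score under `n_perm` seeded random permutations of
#' the residue labels of `b`; z = (raw - null mean) / null sd.
#'
#' @param a,b `invdock_site` objects with at least 3 residues.
#' @param tol distance-consistency tolerance, Angstrom (default 1.5).
#' @param n_perm number of label permutations for the null (default 100).
#' @param seed RNG seed for the permutations.
#' @return the z-score (can be `Inf` when the null is degenerate and the
#'   observed score exceeds it).
#' @export
site_similarity_z <- function(a, b, tol = 1.5, n_perm = 100L, seed = 1L) {
  if (length(a$residues) < 3 || length(b$residues) < 3) {
    stop("site similarity needs >= 3 residues per site")
  }
  raw <- site_raw_similarity(a$res_names, a$ca_coords,
                             b$res_names, b$ca_coords, tol)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    site_raw_similarity(a$res_names, a$ca_coords,
                        sample(b$res_names), b$ca_coords, tol)
  }, numeric(1)))
  mu <- mean(null); s <- stats::sd(null)
  if (!is.finite(s) || s < 1e-9) {
    return(if (raw > mu + 1e-9) Inf else 0)
  }
  (raw - mu) / s
}

site_raw_similarity <- function(lab_a, xyz_a, lab_b, xyz_b, tol) {
  pairs <- which(outer(lab_a, lab_b, "=="), arr.ind = TRUE)
  if (!nrow(pairs)) return(0L)
  da <- as.matrix(stats::dist(xyz_a))
  db <- as.matrix(stats::dist(xyz_b))
  np <- nrow(pairs)
  edges <- integer(0)
  for (u in seq_len(np - 1)) {
    i1 <- pairs[u, 1]; j1 <- pairs[u, 2]
    v <- (u + 1):np
    i2 <- pairs[v, 1]; j2 <- pairs[v, 2]
    ok <- i2 != i1 & j2 != j1 &
      abs(da[cbind(i1, i2)] - db[cbind(j1, j2)]) <= tol
    if (any(ok)) edges <- c(edges, rbind(u, v[ok]))
  }
  if (!length(edges)) return(1L)
  g <- igraph::make_graph(edges, n = np, directed = FALSE)
  igraph::clique_num(g)
}

#' Cluster binding sites by similarity z-score
#'
#' Single-linkage clustering: sites sharing a pair with z >= the cutoff are
#' connected; clusters are the connected components. The representative of
#' a cluster is the site with the most source ligands; ties broken by
#' lexicographic site id.
#'
#' @param sites list of `invdock_site` (normally within one sequence
#'   cluster).
#' @param p `site_db_params()`.
#' @param seed seed forwarded to [site_similarity_z()].
#' @return list of clusters: each a list with `members` (site ids),
#'   `representative` (an `invdock_site`).
#' @export
cluster_sites <- function(sites, p = site_db_params(), seed = 1L) {
  n <- length(sites)
  if (!n) return(list())
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (n > 1) {
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      z <- site_similarity_z(sites[[a]], sites[[b]], seed = seed)
      if (z >= p$site_z_cutoff) g <- igraph::add_edges(g, c(a, b))
    }
  }
  memb <- igraph::components(g)$membership
  lapply(split(seq_len(n), memb), function(idx) {
    nlig <- vapply(sites[idx], function(s) length(s$ligands), integer(1))
    ids <- vapply(sites[idx], function(s) s$site_id, "")
    rep_idx <- idx[order(-nlig, ids)][1]
    list(members = ids[order(ids)], representative = sites[[rep_idx]])
  })
}

#' Greedy centroid-sphere cover of a site's ligand atoms
#'
#' The docking search volume is the union of centroid spheres. Spheres are
#' grown greedily: take the first uncovered ligand heavy atom, group the
#' uncovered atoms within 3.5 Angstrom of it, center the sphere on their
#' mean (falling back to the seed atom if that grows the radius beyond
#' bounds) and pad the radius by 0.5 Angstrom, capped at 4.0. Every ligand
#' heavy atom ends up inside the union (asserted).
#'
#' @param site an `invdock_site` with source ligands.
#' @return the site with a `centroids` matrix (columns x, y, z, r).
#' @export
make_centroids <- function(site) {
  pts <- do.call(rbind, lapply(site$ligands, het_heavy_coords))
  if (is.null(pts) || !nrow(pts)) stop("site has no source-ligand atoms")
  uncovered <- rep(TRUE, nrow(pts))
  cents <- NULL
  while (any(uncovered)) {
    a0 <- pts[which(uncovered)[1], ]
    d0 <- sqrt(rowSums((pts - matrix(a0, nrow(pts), 3, byrow = TRUE))^2))
    members <- uncovered & d0 <= 3.5
    ctr <- colMeans(pts[members, , drop = FALSE])
    dm <- sqrt(rowSums((pts[members, , drop = FALSE] -
                        matrix(ctr, sum(members), 3, byrow = TRUE))^2))
    if (max(dm) > 3.5) {
      ctr <- a0
      dm <- d0[members]
    }
    r <- min(max(max(dm) + 0.5, 1.5), 4.0)
    dall <- sqrt(rowSums((pts - matrix(ctr, nrow(pts), 3, byrow = TRUE))^2))
    uncovered <- uncovered & dall > r
    cents <- rbind(cents, c(ctr, r))
  }
  colnames(cents) <- c("x", "y", "z", "r")
  stopifnot(all(apply(cross_dist(pts, cents[, 1:3, drop = FALSE]) <=
                      matrix(cents[, 4], nrow(pts), nrow(cents), byrow = TRUE),
                      1, any)))
  site$centroids <- cents
  site
}

#' Build the binding-site database (full pipeline)
#'
#' Composes the whole preparation: per entry and chain, extract candidate
#' ligands and their binding-residue sites; cluster chains by sequence;
#' cluster sites within each sequence cluster by similarity z-score; keep
#' one representative site per cluster with its centroid-sphere cover; and
#' filter entries by source organism. Failures of individual entries are
#' logged and skipped, never abort the batch.
#'
#' Ligands of merged (clustered) sites contribute to the representative's
#' centroids only when they lie on the representative's own entry and
#' chain; no structural superposition between chains is attempted.
#'
#' @param entries list of `invdock_entry`.
#' @param p `site_db_params()`.
#' @param seed seed forwarded to the similarity permutation null.
#' @return list of representative `invdock_site` objects, deterministically
#'   ordered by site id, with a "log" attribute of skipped-entry messages.
#' @export
build_site_database <- function(entries, p = site_db_params(), seed = 1L) {
  sites <- list()
  seqs <- character(0)
  log <- character(0)
  for (entry in entries) {
    res <- tryCatch({
      if (!is.null(p$taxon_filter) &&
          !identical(tolower(entry$organism), tolower(p$taxon_filter))) {
        NULL
      } else {
        es <- list()
        for (ch in entry_chain_ids(entry)) {
          sq <- chain_sequence(entry, ch)
          if (!nzchar(sq)) next
          seqs[paste(entry$entry_id, ch, sep = "_")] <- sq
          for (lig in extract_candidate_ligands(entry, ch, p)) {
            es <- c(es, list(make_binding_site(entry, ch, lig, p)))
          }
        }
        es
      }
    }, error = function(e) {
      log <<- c(log, paste0(entry$entry_id, ": ", conditionMessage(e)))
      list()
    })
    sites <- c(sites, res)
  }
  if (!length(sites)) {
    return(structure(list(), log = log))
  }
  seq_clusters <- cluster_sequences(seqs, p)
  site_chain <- vapply(sites, function(s) {
    paste(s$entry_id, s$chain, sep = "_")
  }, "")
  reps <- list()
  for (cl in seq_clusters) {
    cl_sites <- sites[site_chain %in% cl]
    if (!length(cl_sites)) next
    for (sc in cluster_sites(cl_sites, p, seed = seed)) {
      rep_site <- sc$representative
      # pool ligands of member sites that live on the representative chain
      for (s in cl_sites) {
        if (s$site_id != rep_site$site_id && s$site_id %in% sc$members &&
            s$entry_id == rep_site$entry_id && s$chain == rep_site$chain) {
          rep_site$ligands <- c(rep_site$ligands, s$ligands)
        }
      }
      rep_site <- make_centroids(rep_site)
      rep_site$cluster_members <- sc$members
      reps <- c(reps, list(rep_site))
    }
  }
  ids <- vapply(reps, function(s) s$site_id, "")
  reps <- reps[order(ids)]
  structure(reps, log = log)
}

#' Serialize a site database to TSV
#'
#' One row per site: site id, entry, chain, semicolon-joined residue keys,
#' semicolon-joined centroid spheres "x,y,z,r", and ligand count.
#'
#' @param sites list of `invdock_site` (with centroids).
#' @param path output TSV path.
#' @param ligand_sdf optional path; when given, the source ligands are
#'   written as a companion SDF (connectivity perceived by distance).
#' @export
write_site_db <- function(sites, path, ligand_sdf = NULL) {
  if (!is.null(ligand_sdf)) {
    mols <- unlist(lapply(sites, function(s) {
      lapply(s$ligands, het_to_molecule)
    }), recursive = FALSE)
    if (length(mols)) write_molecule_sdf(mols, ligand_sdf)
  }
  rows <- lapply(sites, function(s) {
    data.frame(site_id = s$site_id, entry = s$entry_id, chain = s$chain,
               residues = paste(s$residues, collapse = ";"),
               centroids = paste(apply(s$centroids, 1, function(r) {
                 paste(sprintf("%.3f", r), collapse = ",")
               }), collapse = ";"),
               n_ligands = length(s$ligands))
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a HET group to a molecule by distance-based bond perception
#'
#' PDB HETATM records carry no connectivity; bonds are inferred between
#' heavy atoms closer than 1.25 times the sum of their covalent radii.
#'
#' @param het an `invdock_het`.
#' @return an `invdock_mol` (single bonds, no aromatic flags).
#' @export
het_to_molecule <- function(het) {
  heavy <- het$elements != "H"
  el <- het$elements[heavy]
  xyz <- het$coords[heavy, , drop = FALSE]
  rad <- c(C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07, F = 0.57,
           Cl = 1.02, Br = 1.20, I = 1.39, H = 0.31)
  n <- length(el)
  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  if (n > 1) {
    d <- as.matrix(stats::dist(xyz))
    lim <- 1.25 * outer(rad[el], rad[el], "+")
    hit <- which(d < lim & upper.tri(d), arr.ind = TRUE)
    bonds <- data.frame(i = hit[, 1], j = hit[, 2],
                        order = rep(1L, nrow(hit)))
  }
  mol <- new_molecule(el, xyz, bonds,
                      name = paste0(het$het_code, "_", het$chain, het$resno))
  perceive_aromaticity(mol)
}
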