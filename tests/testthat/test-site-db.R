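# Structure loading, candidate-ligand extraction, binding residues,
# sequence/site clustering and the site-database pipeline.

# Hand-written minimal PDB with controllable ligand size and distance.
mini_pdb <- function(n_lig = 8, lig_dist = 2.5, waters = 1) {
  fmt <- function(type, serial, name, resid, chain, resno, x, y, z, el) {
    sprintf("%-6s%5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, name, "", resid, chain, resno, "", x, y, z, 1, 0, el)
  }
  lines <- c("HEADER    MINI",
             "SOURCE    2 ORGANISM_SCIENTIFIC: HOMO SAPIENS;")
  s <- 0
  for (r in 1:3) {
    s <- s + 1
    lines <- c(lines, fmt("ATOM", s, "CA", "ALA", "A", r, r * 3.8, 0, 0, "C"))
    s <- s + 1
    lines <- c(lines, fmt("ATOM", s, "CB", "ALA", "A", r, r * 3.8, 1.5, 0, "C"))
  }
  # ligand atoms in a line starting lig_dist away from residue-1 CA
  for (k in seq_len(n_lig)) {
    s <- s + 1
    lines <- c(lines, fmt("HETATM", s, paste0("C", k), "LIG", "A", 90,
                          3.8, -lig_dist - (k - 1) * 1.4, 0, "C"))
  }
  for (w in seq_len(waters)) {
    s <- s + 1
    lines <- c(lines, fmt("HETATM", s, "O", "HOH", "A", 200 + w,
                          50 + w, 50, 50, "O"))
  }
  paste(c(lines, "END"), collapse = "\n")
}

test_that("load_structure separates chains, het groups and waters", {
  e <- load_structure(mini_pdb(), entry_id = "mini")
  expect_s3_class(e, "invdock_entry")
  expect_equal(length(e$het), 1)          # waters not counted as het
  expect_equal(nrow(e$waters), 1)
  expect_equal(e$organism, "HOMO SAPIENS")
  expect_equal(e$het[[1]]$het_code, "LIG")

  expect_error(load_structure("REMARK  1 nothing\nEND\n"), "no ATOM")
  expect_error(load_structure(""))
  bad <- sub("3.800   0.000", "3.8xx   0.000", mini_pdb())
  expect_error(load_structure(bad), "line")
})

test_that("highest-occupancy altloc is kept", {
  pdb <- paste(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.400   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       1.600   0.000   0.000  0.60  0.00           C",
    "END"), collapse = "\n")
  e <- load_structure(pdb, entry_id = "alt")
  ca <- e$atom[e$atom$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 1.6)   # the B conformer has the higher occupancy
})

test_that("REMARK 350 operators produce assembly copies", {
  pdb <- make_toy_complex(seed = 3, assembly_copies = 2)
  e <- load_structure(pdb, entry_id = "asm")
  expect_equal(length(e$transforms), 2)
  expect_equal(length(entry_chain_ids(e)), 2)   # A and its copy
  e1 <- load_structure(make_toy_complex(seed = 3), entry_id = "one")
  expect_equal(length(e1$transforms), 1)        # identity when absent
  expect_equal(nrow(e$atom), 2 * nrow(e1$atom))
})

test_that("candidate-ligand filters respect the >7 heavy atom and <3 A rules", {
  p <- site_db_params()
  keep <- load_structure(mini_pdb(n_lig = 8, lig_dist = 2.5), entry_id = "a")
  expect_length(extract_candidate_ligands(keep, "A", p), 1)

  boundary <- load_structure(mini_pdb(n_lig = 7, lig_dist = 2.5), entry_id = "b")
  expect_length(extract_candidate_ligands(boundary, "A", p), 0)

  far <- load_structure(mini_pdb(n_lig = 9, lig_dist = 3.2), entry_id = "c")
  expect_length(extract_candidate_ligands(far, "A", p), 0)

  # cofactors excluded by code
  p2 <- site_db_params(cofactor_codes = "LIG")
  expect_length(extract_candidate_ligands(keep, "A", p2), 0)
})

test_that("binding residues equal a brute-force all-pairs scan", {
  p <- site_db_params()
  st <- toy_setup(seed = 5)
  keys <- binding_residues(st$entry, "A", st$lig, p)
  expect_gt(length(keys), 0)

  at <- st$entry$atom[st$entry$atom$chain == "A", ]
  lig_xyz <- st$lig$coords[st$lig$elements != "H", , drop = FALSE]
  oracle <- character(0)
  for (r in seq_len(nrow(at))) {
    for (l in seq_len(nrow(lig_xyz))) {
      d <- sqrt(sum((c(at$x[r], at$y[r], at$z[r]) - lig_xyz[l, ])^2))
      if (d < p$binding_residue_cutoff) {
        oracle <- c(oracle, paste(at$chain[r], at$resno[r], at$insert[r],
                                  sep = ":"))
      }
    }
  }
  expect_setequal(keys, unique(oracle))

  # strict inequality at the cutoff
  pdb <- mini_pdb(n_lig = 8, lig_dist = 2.5)
  e <- load_structure(pdb, entry_id = "strict")
  lig <- e$het[[1]]
  keys2 <- binding_residues(e, "A", lig, p)
  at2 <- e$atom
  dmin_by_res <- tapply(seq_len(nrow(at2)), at2$resno, function(idx) {
    min(cross_dist(as.matrix(at2[idx, c("x", "y", "z")]),
                   lig$coords))
  })
  for (r in names(dmin_by_res)) {
    key <- paste("A", r, "", sep = ":")
    if (dmin_by_res[[r]] < 5.0) expect_true(key %in% keys2)
    else expect_false(key %in% keys2)
  }
})

test_that("sequence clustering groups exactly identical sequences", {
  seqs <- c(a = "AAAA", b = "AAAA", c = "AAAS", d = "GGGG")
  cl <- cluster_sequences(seqs)
  expect_length(cl, 3)
  expect_equal(sort(unname(lengths(cl))), c(1, 1, 2))
  together <- vapply(cl, function(x) all(c("a", "b") %in% x), logical(1))
  expect_true(any(together))

  n_distinct <- cluster_sequences(c(x = "AA", y = "AS", z = "SS"))
  expect_length(n_distinct, 3)
})

# Synthetic site with seeded random geometry and labels (genuinely
# unrelated to any toy pocket).
random_site <- function(seed, n = 10, id = paste0("rnd", seed)) {
  invdock:::with_seed(seed, {
    structure(list(
      site_id = id, entry_id = id, chain = "A",
      residues = paste("A", seq_len(n), "", sep = ":"),
      res_names = sample(c("ALA", "SER", "VAL", "LEU", "THR"), n, TRUE),
      ca_coords = matrix(runif(3 * n, 0, 15), n, 3),
      ligands = list()
    ), class = "invdock_site")
  })
}

test_that("site similarity: self-similar sites score high, unrelated near zero", {
  s1 <- toy_setup(seed = 11)$site
  expect_gte(site_similarity_z(s1, s1), 2.0)
  r1 <- random_site(1)
  expect_gte(site_similarity_z(r1, r1), 2.0)

  # unrelated random fixtures: mean z near 0 over repeats
  zs <- vapply(1:6, function(k) {
    site_similarity_z(random_site(k), random_site(100 + k), seed = 1)
  }, numeric(1))
  expect_true(all(is.finite(zs)))
  expect_lt(abs(mean(zs)), 1.0)

  # symmetry within null-sampling tolerance
  z_ab <- site_similarity_z(random_site(3), random_site(103), seed = 1)
  z_ba <- site_similarity_z(random_site(103), random_site(3), seed = 1)
  expect_lt(abs(z_ab - z_ba), 1.5)

  small <- s1
  small$res_names <- small$res_names[1:2]
  small$ca_coords <- small$ca_coords[1:2, , drop = FALSE]
  small$residues <- small$residues[1:2]
  expect_error(site_similarity_z(small, s1), ">= 3 residues")
})

test_that("site clustering equals connected components of the z-threshold graph", {
  p <- site_db_params()
  dup <- toy_setup(seed = 11)$site
  sites <- list(dup, dup, random_site(5, n = 12, id = "s3"))
  sites[[1]]$site_id <- "s1"; sites[[2]]$site_id <- "s2"
  cl <- cluster_sites(sites, p, seed = 1)

  # brute-force components on the pairwise z graph
  n <- length(sites)
  adj <- matrix(FALSE, n, n)
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    adj[a, b] <- adj[b, a] <-
      site_similarity_z(sites[[a]], sites[[b]], seed = 1) >= p$site_z_cutoff
  }
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
  expect_equal(length(cl), length(unique(comp)))
  grp <- split(c("s1", "s2", "s3"), comp)
  sizes <- sort(unname(lengths(grp)))
  got <- sort(unname(lengths(lapply(cl, function(x) x$members))))
  expect_equal(got, sizes)
  # the duplicated site pair clusters together with a deterministic
  # representative (ties broken lexicographically)
  two <- Filter(function(x) length(x$members) >= 2, cl)
  expect_gte(length(two), 1)
  expect_equal(two[[1]]$representative$site_id, "s1")
})

test_that("centroid cover contains every ligand atom with radius <= 4", {
  for (sd in c(2, 9, 17)) {
    st <- toy_setup(seed = sd)
    cents <- st$site$centroids
    expect_true(all(cents[, "r"] <= 4.0))
    pts <- st$lig$coords[st$lig$elements != "H", , drop = FALSE]
    d <- cross_dist(pts, cents[, 1:3, drop = FALSE])
    inside <- d <= matrix(cents[, "r"], nrow(pts), nrow(cents), byrow = TRUE)
    expect_true(all(rowSums(inside) >= 1))
    expect_lte(nrow(cents), nrow(pts))
  }
  # single-atom ligand: one sphere containing it
  het1 <- structure(list(het_code = "ONE", chain = "A", resno = 1L,
                         parent_entry = "x", elements = "C",
                         coords = matrix(c(1, 2, 3), 1)),
                    class = "invdock_het")
  s <- structure(list(site_id = "one", entry_id = "x", chain = "A",
                      residues = "A:1:", res_names = "ALA",
                      ca_coords = matrix(0, 1, 3), ligands = list(het1)),
                 class = "invdock_site")
  s <- make_centroids(s)
  expect_equal(nrow(s$centroids), 1)
  expect_lte(sqrt(sum((s$centroids[1, 1:3] - c(1, 2, 3))^2)),
             s$centroids[1, "r"])
})

test_that("site database pipeline filters taxa and is deterministic", {
  pdbs <- c(make_toy_complex(seed = 1), make_toy_complex(seed = 2),
            make_toy_complex(seed = 3, organism = "Mus musculus"))
  entries <- lapply(1:3, function(k) {
    load_structure(pdbs[k], entry_id = paste0("toy", k))
  })
  db <- build_site_database(entries)
  expect_length(db, 2)                       # non-human entry excluded
  expect_false(any(grepl("toy3", vapply(db, `[[`, "", "site_id"))))

  # identical chains/sites collapse to one representative
  same <- lapply(1:2, function(k) {
    load_structure(make_toy_complex(seed = 7), entry_id = paste0("dup", k))
  })
  db_dup <- build_site_database(same)
  expect_length(db_dup, 1)

  # rerun gives a byte-identical database file
  f1 <- tempfile(); f2 <- tempfile()
  sdf1 <- tempfile(fileext = ".sdf")
  write_site_db(build_site_database(entries), f1, ligand_sdf = sdf1)
  write_site_db(build_site_database(entries), f2)
  expect_identical(readLines(f1), readLines(f2))
  # companion SDF holds one molecule per source ligand
  expect_length(ChemmineR::read.SDFset(sdf1), 2)
})

test_that("relaxing filters never removes accepted ligands (monotonicity)", {
  e <- load_structure(mini_pdb(n_lig = 8, lig_dist = 2.5), entry_id = "m")
  strict <- site_db_params()
  relaxed <- site_db_params(min_heavy_atoms = 5, ligand_contact_cutoff = 4.0)
  ids <- function(ligs) vapply(ligs, function(l) l$het_code, "")
  expect_true(all(ids(extract_candidate_ligands(e, "A", strict)) %in%
                  ids(extract_candidate_ligands(e, "A", relaxed))))
})
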