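# Pair potential derivation and scoring, grid generation, fragment pose
# sampling, clique linking and pose minimization.

test_that("pair potential: uniform shells give ~0, enriched contacts negative", {
  # training pairs spread like the radial reference: values near 0
  set.seed(42)
  nrep <- 4000
  r <- (runif(nrep))^(1 / 3) * 6          # density proportional to r^2
  dirs <- matrix(rnorm(3 * nrep), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  prot <- dirs * r
  cx <- list(protein_coords = prot, protein_elements = rep("C", nrep),
             ligand_coords = matrix(0, 1, 3), ligand_elements = "C")
  pot_u <- derive_pair_potential(list(cx))
  cc <- pot_u$values["C", "C", ]
  first_obs <- which(cc != 3)[1]
  expect_lt(max(abs(cc[first_obs:12])), 0.35)

  # hand-counted toy: 10 pairs, contacts concentrated at 3.0-3.5
  prot2 <- cbind(seq(3.1, 3.4, length.out = 10), 0, 0)
  cx2 <- list(protein_coords = prot2, protein_elements = rep("N", 10),
              ligand_coords = matrix(0, 1, 3), ligand_elements = "O")
  pot2 <- derive_pair_potential(list(cx2))
  bin7 <- pot2$values["O", "N", 7]        # 3.0-3.5 A bin
  shell <- diff(seq(0, 6, by = 0.5)^3); shell <- shell / sum(shell)
  expect_equal(bin7, -log((10 + 1) / (10 * shell[7] + 1)))
  expect_lt(bin7, 0)

  # symmetry under type-pair swap
  expect_equal(pot2$values["O", "N", ], pot2$values["N", "O", ])
  st <- toy_setup(seed = 2)
  v <- st$pot$values
  for (a in dimnames(v)[[1]]) for (b in dimnames(v)[[2]]) {
    expect_equal(v[a, b, ], v[b, a, ])
  }
  expect_error(derive_pair_potential(list()), "empty")
})

test_that("score_pose equals a brute-force double loop", {
  set.seed(7)
  lig <- matrix(runif(50 * 3, 0, 10), 50, 3)
  lel <- sample(c("C", "N", "O", "S"), 50, TRUE)
  prot <- list(coords = matrix(runif(30 * 3, 0, 10), 30, 3),
               elements = sample(c("C", "N", "O"), 30, TRUE))
  st <- toy_setup(seed = 2)
  pot <- st$pot
  got <- score_pose(pot, lig, lel, prot)
  oracle <- 0
  for (i in 1:50) for (j in 1:30) {
    d <- sqrt(sum((lig[i, ] - prot$coords[j, ])^2))
    if (d < pot$cutoff) {
      bin <- min(dim(pot$values)[3], floor(d / pot$bin_width) + 1)
      oracle <- oracle + pot$values[lel[i], prot$elements[j], bin]
    }
  }
  expect_equal(got, oracle)

  # all-zero potential scores 0; a single pair reads its bin value
  expect_equal(score_pose(zero_potential(), lig, lel, prot), 0)
  pot1 <- zero_potential()
  pot1$values["C", "C", 7] <- -1.0        # 3.0-3.5 A bin
  single <- score_pose(pot1, matrix(c(0, 0, 0), 1), "C",
                       list(coords = matrix(c(3.2, 0, 0), 1),
                            elements = "C"))
  expect_equal(single, -1.0)
})

test_that("score is linear in the potential and ranking is scale-invariant", {
  st <- toy_setup(seed = 3)
  lig <- st$lig$coords[st$lig$elements != "H", , drop = FALSE]
  lel <- st$lig$elements[st$lig$elements != "H"]
  s1 <- score_pose(st$pot, lig, lel, st$protein)
  pot2 <- st$pot
  pot2$values <- pot2$values * 2.5
  expect_equal(score_pose(pot2, lig, lel, st$protein), 2.5 * s1)
})

test_that("grid enumerates exactly the lattice points inside the centroid union", {
  site <- structure(list(site_id = "g", entry_id = "g", chain = "A",
                         residues = "A:1:",
                         centroids = matrix(c(0, 0, 0, 2), 1,
                                            dimnames = list(NULL,
                                              c("x", "y", "z", "r")))),
                    class = "invdock_site")
  g <- generate_grid(site, 1.0)
  # brute-force lattice scan over the bounding box
  cand <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  oracle <- cand[sqrt(rowSums(cand^2)) <= 2, , drop = FALSE]
  expect_equal(nrow(g), nrow(oracle))
  d <- sqrt(rowSums(g^2))
  expect_true(all(d <= 2))
  expect_gte(nrow(g), nrow(generate_grid(site, 2.0)))  # monotone in spacing
  expect_error(generate_grid(site, -1), "positive")

  st <- toy_setup(seed = 4)
  g2 <- generate_grid(st$site, 1.0)
  cents <- st$site$centroids
  dmat <- invdock:::cross_dist(g2, cents[, 1:3, drop = FALSE])
  inside <- dmat <= matrix(cents[, "r"], nrow(g2), nrow(cents), byrow = TRUE)
  expect_true(all(rowSums(inside) >= 1))
})

test_that("fragment pose lists are sorted, bounded and deterministic", {
  st <- toy_setup(seed = 5)
  mol <- het_to_molecule(st$lig)
  fg <- fragment_ligand(perceive_rotatable_bonds(mol))
  grid <- generate_grid(st$site, 1.0)
  params <- light_dock_params()
  pl1 <- dock_fragments(fg, grid, st$protein, st$pot, params, seed = 0)
  pl2 <- dock_fragments(fg, grid, st$protein, st$pot, params, seed = 0)
  for (f in seq_along(pl1)) {
    sc <- vapply(pl1[[f]], `[[`, 0, "score")
    expect_true(!is.unsorted(sc))
    expect_lte(length(pl1[[f]]), params$k_keep)
    # clash-free
    for (p in pl1[[f]]) {
      expect_gte(min(invdock:::cross_dist(p$coords, st$protein$coords)),
                 params$clash_cutoff)
    }
  }
  expect_identical(pl1, pl2)

  # single-atom fragment on a single grid point lands on that point
  one <- new_molecule("C", matrix(0, 1, 3),
                      data.frame(i = integer(0), j = integer(0),
                                 order = integer(0)), name = "atom")
  fg1 <- fragment_ligand(perceive_rotatable_bonds(one))
  g1 <- matrix(c(30, 0, 0), 1, dimnames = list(NULL, c("x", "y", "z")))
  pl <- dock_fragments(fg1, g1, st$protein, st$pot, params, seed = 0)
  expect_length(pl[[1]], 1)
  expect_equal(unname(pl[[1]][[1]]$coords), matrix(c(30, 0, 0), 1))
})

test_that("clique linking equals brute-force enumeration of compatible pose sets", {
  st <- toy_setup(seed = 6, ligand_size = 11, pocket_radius = 12)
  mol <- het_to_molecule(st$lig)
  fg <- fragment_ligand(perceive_rotatable_bonds(mol))
  expect_gte(length(fg$fragments), 2)
  grid <- generate_grid(st$site, 1.0)
  params <- dock_params(n_rot = 6, k_keep = 5, n_refine = 2, max_iter = 20)
  pl <- dock_fragments(fg, grid, st$protein, st$pot, params, seed = 0)
  cands <- link_fragments(fg, pl, st$protein, st$pot, params)

  # brute force: every pose combination, pairwise-compatibility filtered
  nf <- length(fg$fragments)
  combos <- expand.grid(lapply(pl, seq_along))
  ok <- apply(combos, 1, function(sel) {
    for (a in 1:(nf - 1)) for (b in (a + 1):nf) {
      if (!invdock:::poses_compatible(fg, pl[[a]][[sel[a]]],
                                      pl[[b]][[sel[b]]], params)) {
        return(FALSE)
      }
    }
    TRUE
  })
  expect_equal(length(cands), min(sum(ok), 50))
  if (length(cands)) {
    # every cut bond of the snapped pose sits at its reference length
    m <- fg$molecule
    for (k in seq_len(nrow(fg$links))) {
      ai <- match(fg$links$atom_i[k], cands[[1]]$atom_index)
      aj <- match(fg$links$atom_j[k], cands[[1]]$atom_index)
      d <- sqrt(sum((cands[[1]]$coords[ai, ] - cands[[1]]$coords[aj, ])^2))
      expect_lt(abs(d - fg$links$ref_length[k]), 0.5)
    }
  }
})

test_that("crafted compatibility graph yields exactly its unique full clique", {
  # two fragments, three poses each; only pose pair (2, 3) is compatible
  core <- matrix(c(0, 0, 0), 1, 3)
  m <- new_molecule(c("C", "C", "C", "C"),
                    rbind(c(0, 0, 0), c(1.5, 0, 0), c(3.0, 0, 0),
                          c(4.5, 0, 0)),
                    data.frame(i = 1:3, j = 2:4, order = 1), name = "chain4")
  m$bonds$rotatable <- c(FALSE, TRUE, FALSE)
  fg <- fragment_ligand(m)
  expect_length(fg$fragments, 2)
  ref <- fg$links$ref_length[1]
  far <- matrix(c(99, 99, 99), 1, 3)
  mk <- function(frag, coords, score) {
    list(frag = frag, coords = coords, score = score, grid_id = 1L,
         rot_id = 1L)
  }
  # fragment 1 atoms (1,2); fragment 2 atoms (3,4)
  a_good <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  b_good <- rbind(c(1.5 + ref, 0, 0), c(3.0 + ref, 0, 0))
  pose_lists <- list(
    list(mk(1, a_good + 50, 0), mk(1, a_good, 1), mk(1, a_good - 50, 2)),
    list(mk(2, far, 0), mk(2, far + 5, 1), mk(2, b_good, 2))
  )
  params <- dock_params()
  prot <- list(coords = matrix(c(0, 0, 50), 1), elements = "C",
               types = "C")
  cands <- link_fragments(fg, pose_lists, prot, zero_potential(), params)
  expect_length(cands, 1)
  expect_equal(cands[[1]]$frag_poses, c(`1` = 2L, `2` = 3L))
})

test_that("minimization is monotone and finds a single-well optimum", {
  st <- toy_setup(seed = 7)
  mol <- het_to_molecule(st$lig)
  fg <- fragment_ligand(perceive_rotatable_bonds(mol))
  heavy <- sort(unlist(fg$fragments))
  start <- st$lig$coords[st$lig$elements != "H", , drop = FALSE] +
    matrix(c(1, 0.5, -0.5), length(heavy), 3, byrow = TRUE)
  pose <- structure(list(coords = start, atom_index = heavy,
                         score = score_pose(st$pot, start,
                                            mol$elements[heavy], st$protein,
                                            interpolate = TRUE),
                         frag_poses = 1L),
                    class = "invdock_pose")
  out <- minimize_pose(pose, fg, st$protein, st$pot)
  expect_lte(out$score, pose$score)
  # re-minimizing a converged pose changes nothing appreciable
  again <- minimize_pose(out, fg, st$protein, st$pot)
  expect_lte(again$score, out$score)
  expect_lt(out$score - again$score, 0.5)

  # toy single-well potential: one ligand atom, one protein atom, C-C well
  # at the 2.5-3.0 A bin; interpolated optimum sits at the bin center 2.75
  pot <- zero_potential()
  pot$values["C", "C", 6] <- -5
  one <- new_molecule("C", matrix(c(4.5, 0, 0), 1),
                      data.frame(i = integer(0), j = integer(0),
                                 order = integer(0)), name = "probe")
  fg1 <- fragment_ligand(perceive_rotatable_bonds(one))
  prot1 <- list(coords = matrix(0, 1, 3), elements = "C", types = "C")
  pose1 <- structure(list(coords = matrix(c(4.5, 0, 0), 1), atom_index = 1L,
                          score = 0, frag_poses = 1L),
                     class = "invdock_pose")
  out1 <- minimize_pose(pose1, fg1, prot1, pot)
  expect_lt(abs(sqrt(sum(out1$coords^2)) - 2.75), 0.1)
})

test_that("dock_ligand is deterministic and scale-equivariant", {
  st <- toy_setup(seed = 8)
  mol <- het_to_molecule(st$lig)
  params <- light_dock_params()
  r1 <- dock_ligand(mol, st$site, st$protein, st$pot, params, seed = 0)
  r2 <- dock_ligand(mol, st$site, st$protein, st$pot, params, seed = 0)
  expect_equal(r1$best_score, r2$best_score)
  expect_gt(r1$n_poses, 0)
  sc <- vapply(r1$poses, `[[`, 0, "score")
  expect_true(!is.unsorted(sc))

  # scaling the potential scales scores, preserving the ranking
  pot2 <- st$pot
  pot2$values <- pot2$values * 3
  r3 <- dock_ligand(mol, st$site, st$protein, pot2, params, seed = 0)
  expect_equal(r3$best_score, 3 * r1$best_score, tolerance = 1e-8)

  # unreachable site produces the documented no-pose outcome
  far_site <- st$site
  far_site$centroids <- matrix(c(500, 500, 500, 1.5), 1,
                               dimnames = list(NULL, c("x", "y", "z", "r")))
  big <- het_to_molecule(st$lig)
  rn <- dock_ligand(big, far_site, list(
    coords = matrix(c(500, 500, 500), 1), elements = "C", types = "C"),
    st$pot, params, seed = 0)
  expect_equal(rn$n_poses, 0)
  expect_true(is.na(rn$best_score))
})
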