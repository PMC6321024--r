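# Geometric detection of the seven protein-ligand interaction types on
# crafted geometries with known answers.

# Minimal entry with specified residues/atoms placed by hand.
craft_entry <- function(rows) {
  fmt <- function(serial, name, resid, resno, x, y, z, el, het = FALSE) {
    sprintf("%-6s%5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            if (het) "HETATM" else "ATOM", serial, name, "", resid, "A",
            resno, "", x, y, z, 1, 0, el)
  }
  lines <- c("HEADER    CRAFTED",
             # anchor chain so the file parses as a protein entry
             fmt(9001, "CA", "GLY", 999, 99, 99, 99, "C"))
  for (k in seq_along(rows)) {
    r <- rows[[k]]
    lines <- c(lines, fmt(k, r$name, r$resid, r$resno, r$x, r$y, r$z, r$el,
                          isTRUE(r$het)))
  }
  load_structure(paste(c(lines, "END"), collapse = "\n"), entry_id = "craft")
}

simple_mol <- function(elements, coords, bonds = NULL, charges = NULL) {
  if (is.null(bonds)) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  }
  new_molecule(elements, coords, bonds, name = "probe",
               formal_charge = charges)
}

test_that("ideal hydrogen-bond geometry is detected with its angle", {
  e <- craft_entry(list(
    list(name = "O", resid = "ALA", resno = 1, x = 2.9, y = 0, z = 0,
         el = "O")
  ))
  # donor N at origin with H pointing straight at the acceptor
  m <- simple_mol(c("N", "H"), rbind(c(0, 0, 0), c(1.0, 0, 0)),
                  data.frame(i = 1, j = 2, order = 1))
  out <- profile_interactions(m, e)
  hb <- out[out$kind == "hydrogen_bond", ]
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.9)
  expect_equal(hb$angle, 180, tolerance = 1e-6)
  expect_equal(hb$residue, "A:1:")

  # beyond 3.5 A: nothing
  e_far <- craft_entry(list(
    list(name = "O", resid = "ALA", resno = 1, x = 3.8, y = 0, z = 0,
         el = "O")))
  expect_equal(nrow(profile_interactions(m, e_far)), 0)

  # bent geometry below the 120 degree window is rejected as donor
  m_bent <- simple_mol(c("N", "H"), rbind(c(0, 0, 0), c(-1.0, 0, 0)),
                       data.frame(i = 1, j = 2, order = 1))
  out_bent <- profile_interactions(m_bent, e_far)
  expect_equal(nrow(out_bent), 0)
})

test_that("parallel stacked rings are reported as pi-stacking", {
  ring <- function(z, r = 1.39) {
    ang <- seq(0, 2 * pi, length.out = 7)[1:6]
    cbind(r * cos(ang), r * sin(ang), z)
  }
  phe <- ring(0)
  names_phe <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  e <- craft_entry(lapply(1:6, function(k) {
    list(name = names_phe[k], resid = "PHE", resno = 5,
         x = phe[k, 1], y = phe[k, 2], z = phe[k, 3], el = "C")
  }))
  lig_ring <- ring(3.6)
  m <- parse_small_molecule("c1ccccc1", name = "benz")
  m$coords <- rbind(lig_ring, matrix(99, length(m$elements) - 6, 3))
  out <- profile_interactions(m, e)
  ps <- out[out$kind == "pi_stacking", ]
  expect_equal(nrow(ps), 1)
  expect_equal(ps$distance, 3.6, tolerance = 1e-6)
  expect_lte(ps$angle, 30)
})

test_that("salt bridges, pi-cation and halogen bonds fire inside their windows", {
  e <- craft_entry(list(
    list(name = "OD1", resid = "ASP", resno = 7, x = 3.0, y = 0.5, z = 0,
         el = "O"),
    list(name = "OD2", resid = "ASP", resno = 7, x = 3.0, y = -0.5, z = 0,
         el = "O"),
    list(name = "NZ", resid = "LYS", resno = 8, x = -3.5, y = 0, z = 0,
         el = "N")
  ))
  # ligand ammonium-like cation at origin
  m_pos <- simple_mol("N", matrix(0, 1, 3), charges = 1L)
  out <- profile_interactions(m_pos, e)
  expect_true("salt_bridge" %in% out$kind)
  expect_equal(out$residue[out$kind == "salt_bridge"], "A:7:")

  m_neg <- simple_mol("O", matrix(0, 1, 3), charges = -1L)
  out_n <- profile_interactions(m_neg, e)
  expect_true(any(out_n$kind == "salt_bridge" & out_n$residue == "A:8:"))

  # halogen bond: C-Cl ... O, linear, 3.2 A
  e_x <- craft_entry(list(
    list(name = "O", resid = "SER", resno = 2, x = 4.9, y = 0, z = 0,
         el = "O")))
  m_x <- simple_mol(c("C", "Cl"), rbind(c(0, 0, 0), c(1.7, 0, 0)),
                    data.frame(i = 1, j = 2, order = 1))
  out_x <- profile_interactions(m_x, e_x)
  expect_true("halogen_bond" %in% out_x$kind)
  expect_equal(out_x$distance[out_x$kind == "halogen_bond"], 3.2,
               tolerance = 1e-6)
})

test_that("water bridges connect ligand and protein through a water oxygen", {
  e <- craft_entry(list(
    list(name = "N", resid = "GLN", resno = 3, x = 5.6, y = 0, z = 0,
         el = "N"),
    list(name = "O", resid = "HOH", resno = 300, x = 2.8, y = 0, z = 0,
         el = "O", het = TRUE)
  ))
  m <- simple_mol("O", matrix(0, 1, 3))
  out <- profile_interactions(m, e)
  expect_true("water_bridge" %in% out$kind)
  expect_equal(out$residue[out$kind == "water_bridge"], "A:3:")
})

test_that("distant atoms yield an empty, well-formed report", {
  e <- craft_entry(list(
    list(name = "O", resid = "SER", resno = 1, x = 20, y = 20, z = 20,
         el = "O")))
  m <- simple_mol(c("C", "O"), rbind(c(0, 0, 0), c(1.4, 0, 0)),
                  data.frame(i = 1, j = 2, order = 1))
  out <- profile_interactions(m, e)
  expect_equal(nrow(out), 0)
  expect_named(out, c("kind", "residue", "ligand_atoms", "distance",
                      "angle"))
})

test_that("every record re-validates against its detection window", {
  st <- toy_setup(seed = 13)
  m <- het_to_molecule(st$lig)
  out <- profile_interactions(m, st$entry)
  cfg <- interaction_params()
  for (k in seq_len(nrow(out))) {
    rec <- out[k, ]
    lim <- switch(rec$kind,
                  hydrogen_bond = cfg$hbond_dist,
                  hydrophobic = cfg$hydrophobic_max,
                  pi_stacking = cfg$pistack_dist,
                  pi_cation = cfg$pication_dist,
                  salt_bridge = cfg$saltbridge_dist,
                  water_bridge = cfg$hbond_dist,
                  halogen_bond = cfg$halogen_dist)
    expect_lte(rec$distance, lim)
  }
  # deterministic ordering by residue then kind
  expect_false(is.unsorted(order(out$residue, out$kind)))

  # invariant to ligand atom order
  perm <- rev(seq_along(m$elements))
  m2 <- m
  m2$elements <- m$elements[perm]
  m2$coords <- m$coords[perm, , drop = FALSE]
  m2$formal_charge <- m$formal_charge[perm]
  inv <- order(perm)
  m2$bonds$i <- inv[m$bonds$i]; m2$bonds$j <- inv[m$bonds$j]
  m2$aromatic <- m$aromatic[perm]
  out2 <- profile_interactions(m2, st$entry)
  expect_equal(out2[, c("kind", "residue", "distance")],
               out[, c("kind", "residue", "distance")])
})
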