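# Hierarchical fragment docking: atomic grid inside the centroid union,
# fragment pose sampling, maximum-clique linking of fragment poses into
# whole-ligand candidates, and rigid-body + torsional minimization.

#' Docking engine parameters
#'
#' @param grid_spacing lattice spacing of the atomic grid, Angstrom.
#' @param n_rot number of seeded uniform rotations sampled per grid point.
#' @param k_keep fragment poses kept per fragment (best by score).
#' @param clash_cutoff minimum allowed fragment-to-protein heavy-atom
#'   distance, Angstrom.
#' @param overlap_cutoff minimum allowed heavy-atom distance between poses
#'   of different fragments (cut-bond atom pairs exempt), Angstrom.
#' @param link_tol allowed deviation of a cut-bond atom distance from its
#'   reference length when linking fragment poses, Angstrom.
#' @param n_refine number of best linked candidates passed to minimization.
#' @param max_iter minimization iteration cap.
#' @param min_tol minimization convergence tolerance on the score.
#' @return list of class `invdock_dock_params`.
#' @export
dock_params <- function(grid_spacing = 1.0, n_rot = 24L, k_keep = 20L,
                        clash_cutoff = 2.0, overlap_cutoff = 1.5,
                        link_tol = 1.0, n_refine = 20L, max_iter = 200L,
                        min_tol = 1e-4) {
  stopifnot(grid_spacing > 0, n_rot >= 1, k_keep >= 1)
  structure(list(grid_spacing = grid_spacing, n_rot = as.integer(n_rot),
                 k_keep = as.integer(k_keep), clash_cutoff = clash_cutoff,
                 overlap_cutoff = overlap_cutoff, link_tol = link_tol,
                 n_refine = as.integer(n_refine),
                 max_iter = as.integer(max_iter), min_tol = min_tol),
            class = "invdock_dock_params")
}

#' Atomic grid inside a site's centroid union
#'
#' Lattice points with the given spacing, anchored at integer multiples of
#' the spacing, retained iff inside at least one centroid sphere. Ordering
#' is lexicographic in (x, y, z), so the grid is deterministic.
#'
#' @param site an `invdock_site` with centroids (see [make_centroids()]).
#' @param spacing lattice spacing, Angstrom.
#' @return matrix of grid points (n x 3), with the site id as an attribute.
#' @export
generate_grid <- function(site, spacing = 1.0) {
  if (spacing <= 0) stop("grid spacing must be positive")
  cents <- site$centroids
  if (is.null(cents) || !nrow(cents)) stop("site has no centroids")
  lo <- floor((apply(cents[, 1:3, drop = FALSE] - cents[, 4], 2, min)) /
                spacing) * spacing
  hi <- ceiling((apply(cents[, 1:3, drop = FALSE] + cents[, 4], 2, max)) /
                  spacing) * spacing
  pts <- as.matrix(expand.grid(
    x = seq(lo[1], hi[1], by = spacing),
    y = seq(lo[2], hi[2], by = spacing),
    z = seq(lo[3], hi[3], by = spacing)
  ))
  # expand.grid varies the first factor fastest; reorder to lexicographic
  pts <- pts[order(pts[, 1], pts[, 2], pts[, 3]), , drop = FALSE]
  d <- cross_dist(pts, cents[, 1:3, drop = FALSE])
  inside <- apply(d <= matrix(cents[, 4], nrow(pts), nrow(cents),
                              byrow = TRUE), 1, any)
  g <- pts[inside, , drop = FALSE]
  attr(g, "spacing") <- spacing
  attr(g, "site_id") <- site$site_id
  g
}

#' Sample fragment poses over the grid
#'
#' Each rigid fragment is centered at every grid point under `n_rot`
#' seeded uniform rotations; poses clashing with the protein (any
#' heavy-atom pair closer than `clash_cutoff`) are dropped and the
#' `k_keep` best poses by pair-potential score are kept, sorted ascending.
#'
#' @param fg an `invdock_fraggraph`.
#' @param grid matrix from [generate_grid()].
#' @param protein list from [protein_for_docking()].
#' @param pot an `invdock_potential`.
#' @param params [dock_params()].
#' @param seed RNG seed for the rotation sample.
#' @return list (one element per fragment) of pose lists; each pose has
#'   `frag`, `coords`, `score`, `grid_id`, `rot_id`.
#' @export
dock_fragments <- function(fg, grid, protein, pot, params = dock_params(),
                           seed = 0L) {
  if (!nrow(grid)) stop("empty grid")
  m <- fg$molecule
  rots <- with_seed(seed, random_rotations(params$n_rot))
  pt_idx <- match(protein$types %||% pair_atom_type(protein$elements),
                  PAIR_TYPES)
  keep_p <- !is.na(pt_idx)
  pcoords <- protein$coords[keep_p, , drop = FALSE]
  pt_idx <- pt_idx[keep_p]
  ng <- nrow(grid)
  nb <- dim(pot$values)[3]

  lapply(seq_along(fg$fragments), function(fi) {
    atoms <- fg$fragments[[fi]]
    fcoords <- m$coords[atoms, , drop = FALSE]
    fcoords <- sweep(fcoords, 2, colMeans(fcoords))
    ft <- pair_atom_type(m$elements[atoms])
    ft_idx <- match(ft, PAIR_TYPES)
    k <- nrow(fcoords)
    poses <- list()
    for (ri in seq_along(rots)) {
      rc <- fcoords %*% t(rots[[ri]])
      # stacked coordinates: k atom rows per grid point
      stacked <- rc[rep(seq_len(k), ng), , drop = FALSE] +
        grid[rep(seq_len(ng), each = k), , drop = FALSE]
      d <- cross_dist(stacked, pcoords)
      pose_of_row <- rep(seq_len(ng), each = k)
      dmin <- tapply(apply(d, 1, min), pose_of_row, min)
      ok <- which(dmin >= params$clash_cutoff)
      if (!length(ok)) next
      # per-pose score from binned pair values
      hit <- which(d < pot$cutoff, arr.ind = TRUE)
      sc <- numeric(ng)
      if (nrow(hit)) {
        ti <- ft_idx[(hit[, 1] - 1L) %% k + 1L]
        tj <- pt_idx[hit[, 2]]
        typed <- !is.na(ti)
        v <- numeric(nrow(hit))
        v[typed] <- pair_values(pot, d[hit][typed], ti[typed], tj[typed],
                                interpolate = TRUE)
        agg <- rowsum(v, pose_of_row[hit[, 1]])
        sc[as.integer(rownames(agg))] <- agg[, 1]
      }
      for (gi in ok) {
        poses[[length(poses) + 1L]] <- list(
          frag = fi,
          coords = rc + matrix(grid[gi, ], k, 3, byrow = TRUE),
          score = sc[gi], grid_id = gi, rot_id = ri
        )
      }
    }
    if (!length(poses)) {
      warning("fragment ", fi, " has no clash-free poses in the grid")
      return(list())
    }
    o <- order(vapply(poses, `[[`, 0, "score"),
               vapply(poses, `[[`, 0L, "grid_id"),
               vapply(poses, `[[`, 0L, "rot_id"))
    poses <- poses[o]
    # drop geometric duplicates (e.g. all rotations of a 1-atom fragment)
    key <- vapply(poses, function(p) {
      paste(round(p$coords, 4), collapse = ",")
    }, "")
    poses <- poses[!duplicated(key)]
    poses[seq_len(min(params$k_keep, length(poses)))]
  })
}

# Compatibility of two fragment poses: no heavy-atom overlap (cut-bond
# atom pairs exempt) and every cut bond between the fragments within
# link_tol of its reference length.
poses_compatible <- function(fg, pa, pb, params) {
  m <- fg$molecule
  A <- fg$fragments[[pa$frag]]
  B <- fg$fragments[[pb$frag]]
  d <- cross_dist(pa$coords, pb$coords)
  links <- fg$links[(fg$links$frag_i == pa$frag & fg$links$frag_j == pb$frag) |
                    (fg$links$frag_i == pb$frag & fg$links$frag_j == pa$frag), ,
                    drop = FALSE]
  if (nrow(links)) {
    for (k in seq_len(nrow(links))) {
      ai <- links$atom_i[k]; aj <- links$atom_j[k]
      if (ai %in% A) { ia <- match(ai, A); ib <- match(aj, B) }
      else { ia <- match(aj, A); ib <- match(ai, B) }
      if (abs(d[ia, ib] - links$ref_length[k]) > params$link_tol) return(FALSE)
      d[ia, ib] <- Inf
    }
  }
  min(d) >= params$overlap_cutoff
}

#' Link fragment poses into whole-ligand candidates
#'
#' Builds the pose-compatibility graph (one node per fragment pose, edges
#' between geometrically compatible poses of distinct fragments) and finds
#' cliques covering all fragments: exact maximal-clique enumeration
#' (Bron-Kerbosch with pivoting, via igraph) for graphs of at most 64
#' nodes, a deterministic beam search over the fragment tree above that.
#' Each full clique is reassembled into a candidate pose: fragments are
#' snapped along the fragment tree so every cut bond takes exactly its
#' reference length, then rescored.
#'
#' @inheritParams dock_fragments
#' @param pose_lists output of [dock_fragments()].
#' @param max_candidates cap on returned candidates (best by score).
#' @return list of candidate poses of class `invdock_pose` (fields
#'   `coords` over all heavy atoms, `score`, `frag_poses`), sorted
#'   ascending by score; empty (with a message attribute) when no full
#'   cover exists.
#' @export
link_fragments <- function(fg, pose_lists, protein, pot,
                           params = dock_params(), max_candidates = 50L) {
  nf <- length(fg$fragments)
  if (length(pose_lists) != nf || any(!lengths(pose_lists))) {
    out <- list()
    attr(out, "message") <- "missing fragment poses; no full reconstruction"
    return(out)
  }
  nodes <- do.call(rbind, lapply(seq_len(nf), function(fi) {
    data.frame(frag = fi, pose = seq_along(pose_lists[[fi]]))
  }))
  nn <- nrow(nodes)
  combos <- if (nf == 1L) {
    lapply(seq_len(nn), function(i) i)
  } else if (nn <= 64L) {
    adj <- matrix(FALSE, nn, nn)
    for (u in seq_len(nn - 1)) for (v in (u + 1):nn) {
      if (nodes$frag[u] != nodes$frag[v]) {
        pa <- pose_lists[[nodes$frag[u]]][[nodes$pose[u]]]
        pb <- pose_lists[[nodes$frag[v]]][[nodes$pose[v]]]
        adj[u, v] <- adj[v, u] <- poses_compatible(fg, pa, pb, params)
      }
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    cl <- igraph::cliques(g, min = nf, max = nf)
    lapply(cl, as.integer)
  } else {
    beam_assemble(fg, pose_lists, nodes, params, beam = 50L)
  }
  if (!length(combos)) {
    out <- list()
    attr(out, "message") <- "no compatible full-cover pose combination"
    return(out)
  }
  cands <- lapply(combos, function(idx) {
    sel <- setNames(nodes$pose[idx], nodes$frag[idx])
    assemble_pose(fg, pose_lists, sel, protein, pot)
  })
  o <- order(vapply(cands, `[[`, 0, "score"))
  cands <- cands[o]
  cands[seq_len(min(max_candidates, length(cands)))]
}

# Deterministic beam search over the fragment tree for large graphs:
# fragments are added in breadth-first tree order; partial selections are
# extended by every compatible pose of the next fragment and the `beam`
# best by summed fragment score are kept.
beam_assemble <- function(fg, pose_lists, nodes, params, beam = 50L) {
  nf <- length(fg$fragments)
  tg <- igraph::graph_from_data_frame(
    fg$links[, c("frag_i", "frag_j")], directed = FALSE,
    vertices = data.frame(name = seq_len(nf)))
  ord <- as.integer(igraph::bfs(tg, root = 1)$order)
  partials <- lapply(seq_along(pose_lists[[ord[1]]]), function(p) {
    sel <- rep(NA_integer_, nf); sel[ord[1]] <- p
    list(sel = sel,
         score = pose_lists[[ord[1]]][[p]]$score)
  })
  for (fi in ord[-1]) {
    nxt <- list()
    for (pp in partials) {
      done <- which(!is.na(pp$sel))
      for (p in seq_along(pose_lists[[fi]])) {
        cand <- pose_lists[[fi]][[p]]
        ok <- all(vapply(done, function(fj) {
          poses_compatible(fg, pose_lists[[fj]][[pp$sel[fj]]], cand, params)
        }, logical(1)))
        if (ok) {
          sel <- pp$sel; sel[fi] <- p
          nxt[[length(nxt) + 1L]] <- list(sel = sel,
                                          score = pp$score + cand$score)
        }
      }
    }
    if (!length(nxt)) return(list())
    o <- order(vapply(nxt, `[[`, 0, "score"))
    partials <- nxt[o][seq_len(min(beam, length(nxt)))]
  }
  # convert fragment->pose selections to node-index sets
  lapply(partials, function(pp) {
    vapply(seq_len(nf), function(fi) {
      which(nodes$frag == fi & nodes$pose == pp$sel[fi])
    }, integer(1))
  })
}

# Merge selected fragment poses into full-ligand heavy-atom coordinates,
# snapping each cut bond to its reference length along the fragment tree
# (child subtree translated along the bond vector).
assemble_pose <- function(fg, pose_lists, sel, protein, pot) {
  m <- fg$molecule
  nf <- length(fg$fragments)
  heavy_idx <- sort(unlist(fg$fragments))
  coords <- matrix(NA_real_, length(m$elements), 3)
  for (fi in seq_len(nf)) {
    coords[fg$fragments[[fi]], ] <- pose_lists[[fi]][[sel[[as.character(fi)]]]]$coords
  }
  if (nf > 1) {
    tg <- igraph::graph_from_data_frame(
      fg$links[, c("frag_i", "frag_j")], directed = FALSE,
      vertices = data.frame(name = seq_len(nf)))
    parent <- rep(NA_integer_, nf)
    ord <- as.integer(igraph::bfs(tg, root = 1, father = TRUE)$father)
    bfs_order <- as.integer(igraph::bfs(tg, root = 1)$order)
    parent[seq_len(nf)] <- ord
    subtree <- function(fi) {
      # all fragments in the subtree rooted at fi (tree, so BFS suffices)
      todo <- fi; out <- integer(0)
      while (length(todo)) {
        x <- todo[1]; todo <- todo[-1]; out <- c(out, x)
        todo <- c(todo, setdiff(which(parent == x), out))
      }
      out
    }
    for (fi in bfs_order[-1]) {
      fp <- parent[fi]
      lk <- fg$links[(fg$links$frag_i == fp & fg$links$frag_j == fi) |
                     (fg$links$frag_i == fi & fg$links$frag_j == fp), ,
                     drop = FALSE][1, ]
      ai <- if (lk$atom_i %in% fg$fragments[[fp]]) lk$atom_i else lk$atom_j
      aj <- if (identical(ai, lk$atom_i)) lk$atom_j else lk$atom_i
      v <- coords[aj, ] - coords[ai, ]
      len <- sqrt(sum(v^2))
      if (len < 1e-9) next
      shift <- v / len * (lk$ref_length - len)
      sub_atoms <- unlist(fg$fragments[subtree(fi)])
      coords[sub_atoms, ] <- coords[sub_atoms, ] +
        matrix(shift, length(sub_atoms), 3, byrow = TRUE)
    }
  }
  lig_coords <- coords[heavy_idx, , drop = FALSE]
  sc <- score_pose(pot, lig_coords, m$elements[heavy_idx], protein,
                   interpolate = TRUE)
  structure(list(coords = lig_coords, atom_index = heavy_idx, score = sc,
                 frag_poses = unlist(sel)),
            class = "invdock_pose")
}

#' @export
print.invdock_pose <- function(x, ...) {
  cat("<invdock_pose>", nrow(x$coords), "heavy atoms, score",
      sprintf("%.3f", x$score), "\n")
  invisible(x)
}

# Rotate points about the line through p0 with direction axis.
rotate_about_line <- function(coords, p0, axis, angle) {
  R <- axis_rotation(axis, angle)
  shifted <- sweep(coords, 2, p0)
  sweep(shifted %*% t(R), 2, p0, "+")
}

#' Minimize a docked pose
#'
#' Coordinate descent over the rigid-body degrees of freedom (three
#' translations, three rotations about the ligand centroid) plus one
#' torsion per cut bond, with step halving. The score is monotonically
#' non-increasing; iteration stops at `max_iter` sweeps or when a full
#' sweep improves the score by less than `min_tol`.
#'
#' @param pose an `invdock_pose`.
#' @param fg the `invdock_fraggraph` the pose was built from.
#' @inheritParams dock_fragments
#' @return the refined `invdock_pose`.
#' @export
minimize_pose <- function(pose, fg, protein, pot, params = dock_params()) {
  m <- fg$molecule
  heavy_idx <- pose$atom_index
  elements <- m$elements[heavy_idx]
  coords <- pose$coords
  score <- score_pose(pot, coords, elements, protein, interpolate = TRUE)

  nf <- length(fg$fragments)
  torsions <- list()
  if (nrow(fg$links)) {
    tg <- igraph::graph_from_data_frame(
      fg$links[, c("frag_i", "frag_j")], directed = FALSE,
      vertices = data.frame(name = seq_len(nf)))
    parent <- as.integer(igraph::bfs(tg, root = 1, father = TRUE)$father)
    subtree_frags <- function(fi) {
      todo <- fi; out <- integer(0)
      while (length(todo)) {
        x <- todo[1]; todo <- todo[-1]; out <- c(out, x)
        todo <- c(todo, setdiff(which(parent == x), out))
      }
      out
    }
    for (k in seq_len(nrow(fg$links))) {
      lk <- fg$links[k, ]
      child <- if (!is.na(parent[lk$frag_j]) && parent[lk$frag_j] == lk$frag_i) {
        lk$frag_j
      } else lk$frag_i
      anchor <- if (child == lk$frag_j) lk$atom_i else lk$atom_j
      moved <- if (child == lk$frag_j) lk$atom_j else lk$atom_i
      rot_atoms <- match(unlist(fg$fragments[subtree_frags(child)]), heavy_idx)
      torsions[[k]] <- list(anchor = match(anchor, heavy_idx),
                            moved = match(moved, heavy_idx),
                            atoms = rot_atoms[!is.na(rot_atoms)])
    }
  }

  lt_idx <- match(pair_atom_type(elements), PAIR_TYPES)
  pt_idx <- match(protein$types %||% pair_atom_type(protein$elements),
                  PAIR_TYPES)
  keep_p <- !is.na(pt_idx)
  pcoords <- protein$coords[keep_p, , drop = FALSE]
  pt_idx <- pt_idx[keep_p]
  trial_score <- function(trial) {
    d <- cross_dist(trial, pcoords)
    if (min(d) < params$clash_cutoff) return(Inf)
    hit <- which(d < pot$cutoff, arr.ind = TRUE)
    if (!nrow(hit)) return(0)
    t1 <- lt_idx[hit[, 1]]
    ok <- !is.na(t1)
    if (!any(ok)) return(0)
    sum(pair_values(pot, d[hit][ok], t1[ok], pt_idx[hit[, 2]][ok],
                    interpolate = TRUE))
  }
  # per-dof step-halving line search: walk down a ladder of step sizes in
  # both directions and take the first improving move (largest step wins)
  line_search <- function(move, s0) {
    for (s in s0 / 2^(0:4)) for (sgn in c(-1, 1)) {
      trial <- move(sgn * s)
      sc <- trial_score(trial)
      if (sc < score - 1e-12) {
        score <<- sc
        coords <<- trial
        return(TRUE)
      }
    }
    FALSE
  }

  # axis and diagonal move directions (unit vectors); diagonals let the
  # descent cut across valleys that axis-aligned zigzagging stalls in
  dirs3 <- rbind(diag(3),
                 c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
                 c(1, 0, -1), c(0, 1, 1), c(0, 1, -1), c(1, 1, 1))
  dirs3 <- dirs3 / sqrt(rowSums(dirs3^2))

  sweep_once <- function(ndir, t_step, r_step) {
    for (di in seq_len(ndir)) {
      v <- dirs3[di, ]
      line_search(function(s) {
        sweep(coords, 2, s * v, "+")
      }, t_step)
    }
    ctr <- colMeans(coords)
    for (di in seq_len(ndir)) {
      ax <- dirs3[di, ]
      line_search(function(s) rotate_about_line(coords, ctr, ax, s), r_step)
    }
    for (tor in torsions) {
      axis <- coords[tor$moved, ] - coords[tor$anchor, ]
      if (sum(axis^2) < 1e-12) next
      line_search(function(s) {
        trial <- coords
        trial[tor$atoms, ] <- rotate_about_line(coords[tor$atoms, , drop = FALSE],
                                                coords[tor$anchor, ], axis, s)
        trial
      }, r_step)
    }
  }

  t_step <- 2.0; r_step <- 1.0
  for (iter in seq_len(params$max_iter)) {
    prev <- score
    sweep_once(3L, t_step, r_step)          # axis moves
    if (prev - score < params$min_tol) {
      sweep_once(nrow(dirs3), t_step, r_step)  # escape: diagonal moves
    }
    if (prev - score < params$min_tol) {
      if (t_step < 0.05) break
      t_step <- t_step / 2; r_step <- r_step / 2
    }
  }
  pose$coords <- coords
  pose$score <- score
  pose
}

#' Dock a ligand into a binding site
#'
#' Full hierarchical pipeline: perceive rotatable bonds and fragment the
#' ligand, generate the atomic grid inside the site's centroid union,
#' sample and score fragment poses, link them by clique search, snap cut
#' bonds, minimize the best candidates and return poses sorted ascending
#' by score. The first pose's score is the protein's docking score
#' (arbitrary units, lower = stronger predicted binding).
#'
#' @param mol an `invdock_mol` ligand.
#' @param site an `invdock_site` with centroids.
#' @param protein list from [protein_for_docking()].
#' @param pot an `invdock_potential`.
#' @param params [dock_params()].
#' @param seed RNG seed (rotation sampling).
#' @return object of class `invdock_dockres`: list with `poses`,
#'   `best_score` (NA when no pose was found), `n_poses`, `site_id`.
#' @export
dock_ligand <- function(mol, site, protein, pot, params = dock_params(),
                        seed = 0L) {
  if (is.null(mol$bonds$rotatable)) mol <- perceive_rotatable_bonds(mol)
  fg <- fragment_ligand(mol)
  grid <- generate_grid(site, params$grid_spacing)
  res <- structure(list(poses = list(), best_score = NA_real_, n_poses = 0L,
                        site_id = site$site_id, ligand = mol$name),
                   class = "invdock_dockres")
  if (!nrow(grid)) return(res)
  pose_lists <- withCallingHandlers(
    dock_fragments(fg, grid, protein, pot, params, seed = seed),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (any(!lengths(pose_lists))) return(res)
  cands <- link_fragments(fg, pose_lists, protein, pot, params)
  if (!length(cands)) return(res)
  refined <- lapply(cands[seq_len(min(params$n_refine, length(cands)))],
                    minimize_pose, fg = fg, protein = protein, pot = pot,
                    params = params)
  refined <- refined[order(vapply(refined, `[[`, 0, "score"))]
  res$poses <- refined
  res$best_score <- refined[[1]]$score
  res$n_poses <- length(refined)
  res
}

#' Apply a docked pose's coordinates back onto its molecule
#'
#' Returns the ligand molecule with heavy-atom coordinates replaced by
#' the pose coordinates (hydrogens, if any, are dropped); useful for
#' writing poses as SDF via [write_molecule_sdf()] or for interaction
#' profiling.
#'
#' @param pose an `invdock_pose`.
#' @param mol the `invdock_mol` the pose was docked from.
#' @return an `invdock_mol` holding the posed heavy atoms.
#' @export
pose_to_molecule <- function(pose, mol) {
  idx <- pose$atom_index
  b <- mol$bonds[mol$bonds$i %in% idx & mol$bonds$j %in% idx, , drop = FALSE]
  remap <- match(seq_along(mol$elements), idx)
  b$i <- remap[b$i]; b$j <- remap[b$j]
  out <- new_molecule(mol$elements[idx], pose$coords, b,
                      name = paste0(mol$name, "_pose"),
                      formal_charge = mol$formal_charge[idx])
  out$aromatic <- mol$aromatic[idx]
  out$bonds$aromatic <- mol$bonds$aromatic[mol$bonds$i %in% idx &
                                             mol$bonds$j %in% idx]
  out
}

#' @export
print.invdock_dockres <- function(x, ...) {
  cat("<invdock_dockres>", x$ligand, "in", x$site_id, "-", x$n_poses,
      "pose(s), best score",
      if (is.na(x$best_score)) "NA" else sprintf("%.3f", x$best_score), "\n")
  invisible(x)
}
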