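# Deterministic distance-restraint embedding for inputs that carry no 3D
# coordinates (SMILES, 2D SDF). Not a conformer search: one seeded,
# reproducible geometry good enough to define rigid fragment shapes.

IDEAL_BOND <- list(
  "C-C" = 1.53, "C=C" = 1.34, "C:C" = 1.39, "C-N" = 1.47, "C=N" = 1.30,
  "C:N" = 1.34, "C-O" = 1.43, "C=O" = 1.23, "C-S" = 1.81, "C-P" = 1.85,
  "N-O" = 1.40, "O-P" = 1.60, "O=P" = 1.48, "S=O" = 1.45,
  "C-F" = 1.35, "C-Cl" = 1.77, "C-Br" = 1.94, "C-I" = 2.14,
  "H-C" = 1.09, "H-N" = 1.01, "H-O" = 0.96, "H-S" = 1.34
)

ideal_bond_length <- function(e1, e2, order, aromatic) {
  pair <- sort(c(e1, e2))
  sep <- if (aromatic) ":" else if (order >= 2) "=" else "-"
  key <- paste0(pair[1], sep, pair[2])
  IDEAL_BOND[[key]] %||% IDEAL_BOND[[paste0(pair[1], "-", pair[2])]] %||% 1.5
}

#' Deterministic 3D embedding of a molecular graph
#'
#' Minimizes a distance-restraint stress function: bonded pairs at ideal
#' bond lengths, geminal (1-3) pairs at the distance implied by an
#' idealized bond angle (120 degrees at sp2/aromatic centers, 109.5
#' otherwise), and a soft lower bound of 2.5 Angstrom between all other
#' atom pairs. Started from the input coordinates plus a seeded jitter, so
#' the result is reproducible per seed.
#'
#' @param m an `invdock_mol`.
#' @param seed integer RNG seed for the starting jitter.
#' @param maxit BFGS iteration cap.
#' @return the molecule with embedded 3D coordinates.
#' @export
embed_molecule_3d <- function(m, seed = 1L, maxit = 500L) {
  n <- length(m$elements)
  if (n == 1L) {
    m$coords <- matrix(0, 1, 3)
    return(m)
  }
  b <- m$bonds
  sp2 <- m$aromatic | seq_len(n) %in% c(b$i[b$order >= 2], b$j[b$order >= 2])

  d0 <- numeric(nrow(b))
  for (k in seq_len(nrow(b))) {
    d0[k] <- ideal_bond_length(m$elements[b$i[k]], m$elements[b$j[k]],
                               b$order[k], b$aromatic[k])
  }
  restr_i <- b$i; restr_j <- b$j; restr_d <- d0

  # geminal pairs via the common neighbor; angle set by the center atom
  adj <- vector("list", n)
  blen <- matrix(NA_real_, n, n)
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
    blen[b$i[k], b$j[k]] <- blen[b$j[k], b$i[k]] <- d0[k]
  }
  seen <- new.env()
  for (c_ in seq_len(n)) {
    nb <- adj[[c_]]
    if (length(nb) < 2) next
    theta <- if (sp2[c_]) 120 else 109.5
    for (a in seq_along(nb)) for (bb_ in seq_along(nb)) {
      if (a >= bb_) next
      u <- nb[a]; v <- nb[bb_]
      key <- paste(min(u, v), max(u, v))
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      d13 <- sqrt(blen[c_, u]^2 + blen[c_, v]^2 -
                  2 * blen[c_, u] * blen[c_, v] * cos(theta * pi / 180))
      restr_i <- c(restr_i, u); restr_j <- c(restr_j, v)
      restr_d <- c(restr_d, d13)
    }
  }
  restrained <- paste(pmin(restr_i, restr_j), pmax(restr_i, restr_j))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pkey <- paste(pairs[, 1], pairs[, 2])
  free <- pairs[!(pkey %in% restrained), , drop = FALSE]
  # exclude hydrogens from the repulsive floor to keep X-H geometry loose
  hh <- m$elements[free[, 1]] == "H" | m$elements[free[, 2]] == "H"
  free <- free[!hh, , drop = FALSE]
  dmin <- 2.5

  stress <- function(x) {
    xyz <- matrix(x, ncol = 3)
    di <- xyz[restr_i, , drop = FALSE] - xyz[restr_j, , drop = FALSE]
    d <- sqrt(rowSums(di^2))
    s <- sum((d - restr_d)^2)
    if (nrow(free)) {
      df <- xyz[free[, 1], , drop = FALSE] - xyz[free[, 2], , drop = FALSE]
      dd <- sqrt(rowSums(df^2))
      viol <- pmax(0, dmin - dd)
      s <- s + 0.3 * sum(viol^2)
    }
    s
  }
  grad <- function(x) {
    xyz <- matrix(x, ncol = 3)
    g <- matrix(0, nrow(xyz), 3)
    di <- xyz[restr_i, , drop = FALSE] - xyz[restr_j, , drop = FALSE]
    d <- pmax(sqrt(rowSums(di^2)), 1e-9)
    coef <- 2 * (d - restr_d) / d
    for (ax in 1:3) {
      gi <- coef * di[, ax]
      g[, ax] <- g[, ax] +
        tapply(c(gi, -gi), c(restr_i, restr_j), sum)[as.character(seq_len(nrow(xyz)))] |>
        (\(v) ifelse(is.na(v), 0, v))()
    }
    if (nrow(free)) {
      df <- xyz[free[, 1], , drop = FALSE] - xyz[free[, 2], , drop = FALSE]
      dd <- pmax(sqrt(rowSums(df^2)), 1e-9)
      viol <- pmax(0, dmin - dd)
      coef <- 0.3 * 2 * (-viol) / dd
      for (ax in 1:3) {
        gi <- coef * df[, ax]
        add <- tapply(c(gi, -gi), c(free[, 1], free[, 2]), sum)
        idx <- as.integer(names(add))
        g[idx, ax] <- g[idx, ax] + add
      }
    }
    as.vector(g)
  }

  start <- with_seed(seed, {
    m$coords + matrix(rnorm(3 * n, sd = 0.35), n, 3)
  })
  fit <- stats::optim(as.vector(start), stress, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  m$coords <- matrix(fit$par, ncol = 3)
  m$coords <- sweep(m$coords, 2, colMeans(m$coords))
  m
}
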