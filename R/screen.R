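# End-to-end inverse screen: build the site database, dock the ligand into
# every site, prioritize targets by the score-distribution threshold, and
# optionally profile interactions and validate against labels.

#' Run an inverse screen
#'
#' Composes the whole protocol: load structures, build the binding-site
#' database, derive (or accept) a pair potential, dock the ligand into
#' every representative site, keep each protein's best score, fit the
#' normal score distribution, select targets below the central-interval
#' lower bound, and optionally profile interactions of the selected poses
#' and compute validation metrics when activity labels are supplied.
#' Per-site docking failures are logged and skipped.
#'
#' @param structures character vector of PDB file paths or PDB texts.
#' @param ligand an `invdock_mol`, SMILES string, or SDF path.
#' @param site_params [site_db_params()].
#' @param params [dock_params()].
#' @param potential an `invdock_potential`; by default one is derived from
#'   the co-crystallized ligands of the site database itself.
#' @param level coverage of the central interval (default 0.95).
#' @param labels optional data.frame `protein_id`, `active` for validation.
#' @param alpha RIE/BEDROC exponential weight (default 20).
#' @param seed master seed for all stochastic steps.
#' @param profile when TRUE, interactions of the best pose of every
#'   selected target are profiled and attached as `interactions`.
#' @param out_dir optional directory; when given, the screen table,
#'   threshold report and metrics are written as TSV/JSON.
#' @return list of class `invdock_screen`: `screen` (data.frame
#'   `protein_id`, `site_id`, `score`, `n_poses`), `report`
#'   (threshold report), `results` (per-site dock results), `metrics`
#'   (when labels given), `log`.
#' @export
run_inverse_screen <- function(structures, ligand,
                               site_params = site_db_params(),
                               params = dock_params(),
                               potential = NULL, level = 0.95,
                               labels = NULL, alpha = 20, seed = 0L,
                               profile = FALSE, out_dir = NULL) {
  mol <- if (inherits(ligand, "invdock_mol")) ligand else {
    if (length(ligand) == 1 && !grepl("\n", ligand) &&
        grepl("\\.(sdf|mol)$", ligand) && !file.exists(ligand)) {
      stop("ligand file not found: ", ligand)
    }
    parse_small_molecule(ligand)
  }
  ids <- names(structures)
  entries <- lapply(seq_along(structures), function(k) {
    id <- if (!is.null(ids) && nzchar(ids[k])) ids[k] else {
      if (!grepl("\n", structures[k])) NULL else sprintf("entry%02d", k)
    }
    load_structure(structures[k], entry_id = id)
  })
  db <- build_site_database(entries, site_params, seed = seed)
  log <- attr(db, "log") %||% character(0)
  if (!length(db)) stop("site database is empty; nothing to screen")

  entry_by_id <- setNames(entries, vapply(entries, `[[`, "", "entry_id"))
  if (is.null(potential)) {
    complexes <- list()
    for (s in db) {
      for (h in s$ligands) {
        complexes <- c(complexes, list(
          complex_from_entry(entry_by_id[[s$entry_id]], s$chain, h)))
      }
    }
    potential <- derive_pair_potential(complexes)
  }

  rows <- list()
  results <- list()
  for (s in db) {
    prot <- protein_for_docking(entry_by_id[[s$entry_id]], s$chain)
    res <- tryCatch(
      dock_ligand(mol, s, prot, potential, params, seed = seed),
      error = function(e) {
        log <<- c(log, paste0(s$site_id, ": ", conditionMessage(e)))
        NULL
      })
    if (is.null(res)) next
    results[[s$site_id]] <- res
    if (res$n_poses > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = paste(s$entry_id, s$chain, sep = "_"),
        site_id = s$site_id, score = res$best_score, n_poses = res$n_poses)
    } else {
      log <- c(log, paste0(s$site_id, ": no-pose outcome, excluded"))
    }
  }
  screen <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(protein_id = character(0), site_id = character(0),
               score = numeric(0), n_poses = integer(0))
  }
  # best score per protein
  if (nrow(screen)) {
    screen <- screen[order(screen$score, screen$protein_id), , drop = FALSE]
    screen <- screen[!duplicated(screen$protein_id), , drop = FALSE]
    screen <- screen[order(screen$protein_id), , drop = FALSE]
    rownames(screen) <- NULL
  }

  report <- if (nrow(screen) >= 2 && stats::sd(screen$score) > 0) {
    prioritize_targets(screen, level = level)
  } else NULL

  interactions <- NULL
  if (profile && !is.null(report) && nrow(report$selected)) {
    interactions <- lapply(seq_len(nrow(report$selected)), function(k) {
      sid <- report$selected$site_id[k]
      res <- results[[sid]]
      eid <- sub("_[^_]*$", "", report$selected$protein_id[k])
      profile_interactions(pose_to_molecule(res$poses[[1]], mol),
                           entry_by_id[[eid]])
    })
    names(interactions) <- report$selected$protein_id
  }

  metrics <- NULL
  if (!is.null(labels) && nrow(screen) > 1) {
    m <- merge(screen, labels, by = "protein_id")
    if (sum(m$active) >= 1 && sum(!m$active) >= 1) {
      metrics <- screen_metrics(
        labeled_ranking(m$protein_id, m$score, m$active), alpha = alpha)
    }
  }

  out <- structure(list(screen = screen, report = report, results = results,
                        interactions = interactions, metrics = metrics,
                        ligand = mol$name, seed = seed, log = log),
                   class = "invdock_screen")
  if (!is.null(out_dir)) write_screen(out, out_dir)
  out
}

#' @export
print.invdock_screen <- function(x, ...) {
  cat("<invdock_screen>", x$ligand, "vs", nrow(x$screen), "protein(s)\n")
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Write screen outputs to a directory
#'
#' Writes `screen.tsv` (per-protein best scores), `selected.tsv` (ranked
#' targets below the threshold) and `summary.json` (fit, interval and
#' metrics).
#'
#' @param x an `invdock_screen`.
#' @param out_dir output directory (created if missing).
#' @export
write_screen <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(x$screen, file.path(out_dir, "screen.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summary <- list(ligand = x$ligand, seed = x$seed,
                  n_proteins = nrow(x$screen))
  if (!is.null(x$report)) {
    write.table(x$report$selected, file.path(out_dir, "selected.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summary$fit <- list(mean = x$report$fit$mean, sd = x$report$fit$sd,
                        n = x$report$fit$n)
    summary$interval <- c(low = x$report$low, high = x$report$high)
    summary$n_selected <- nrow(x$report$selected)
  }
  if (!is.null(x$metrics)) {
    summary$metrics <- x$metrics[c("auc", "ef", "rie", "bedroc", "tg")]
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
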