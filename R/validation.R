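# Early-recognition validation of an inverse screen: ROC/AUC, enrichment,
# RIE, BEDROC, predictiveness curve and standardized total gain over a
# score-ranked list of proteins with active/inactive labels.

#' Build a labeled ranking
#'
#' Entries are sorted ascending by score (lower docking score = better,
#' ranked first); ties are broken by id, giving a deterministic total
#' order on which all metrics are computed.
#'
#' @param id identifiers.
#' @param score numeric scores (arb. units; lower is better).
#' @param active logical (or 0/1) activity labels.
#' @return data.frame of class `invdock_ranking` with attributes `N`, `n`
#'   (actives) and `Ra` (active fraction).
#' @export
labeled_ranking <- function(id, score, active) {
  stopifnot(length(id) == length(score), length(score) == length(active))
  active <- as.logical(active)
  if (!any(active)) stop("ranking needs at least one active")
  o <- order(score, as.character(id))
  r <- data.frame(id = as.character(id)[o], score = score[o],
                  active = active[o], rank = seq_along(o))
  class(r) <- c("invdock_ranking", "data.frame")
  attr(r, "N") <- nrow(r)
  attr(r, "n") <- sum(active)
  attr(r, "Ra") <- sum(active) / nrow(r)
  r
}

rank_check <- function(r) {
  N <- attr(r, "N"); n <- attr(r, "n")
  if (n < 1 || n >= N) stop("metrics need both classes present (0 < n < N)")
  invisible(list(N = N, n = n))
}

#' ROC curve and AUC of a labeled ranking
#'
#' Stepwise true-positive versus false-positive fraction over the ranking;
#' AUC by the trapezoid rule (with score ties handled by the deterministic
#' total order, this equals the normalized Mann-Whitney rank-sum
#' statistic).
#'
#' @param r an `invdock_ranking`.
#' @return list with `curve` (data.frame `fpf`, `tpf`) and `auc`.
#' @export
roc_auc <- function(r) {
  ck <- rank_check(r)
  tp <- cumsum(r$active)
  fp <- cumsum(!r$active)
  tpf <- c(0, tp / ck$n)
  fpf <- c(0, fp / (ck$N - ck$n))
  auc <- sum(diff(fpf) * (utils::head(tpf, -1) + utils::tail(tpf, -1)) / 2)
  list(curve = data.frame(fpf = fpf, tpf = tpf), auc = auc)
}

#' Enrichment factors and enrichment curve
#'
#' `EF(chi)` is the active rate in the top `ceiling(chi * N)` entries
#' divided by the overall active rate `n / N`; the curve tabulates the
#' true-positive fraction at every rank for plotting on a log fraction
#' axis.
#'
#' @param r an `invdock_ranking`.
#' @param fractions screen fractions in (0, 1] (default 0.01).
#' @return list with `ef` (named vector, one value per fraction) and
#'   `curve` (data.frame `fraction`, `tpf`).
#' @export
enrichment <- function(r, fractions = 0.01) {
  ck <- rank_check(r)
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]")
  }
  ef <- vapply(fractions, function(chi) {
    top <- ceiling(chi * ck$N)
    (sum(r$active[seq_len(top)]) / top) / (ck$n / ck$N)
  }, numeric(1))
  names(ef) <- sprintf("EF%g", fractions * 100)
  curve <- data.frame(fraction = r$rank / ck$N,
                      tpf = cumsum(r$active) / ck$n)
  list(ef = ef, curve = curve)
}

#' Robust initial enhancement (RIE)
#'
#' Exponentially weighted early-recognition score:
#' `RIE = sum_i exp(-alpha * rank_i / N) / (Ra * (1 - exp(-alpha)) /
#' (exp(alpha / N) - 1))` over active ranks; 1 for a random ranking,
#' larger when actives concentrate early.
#'
#' @param r an `invdock_ranking`.
#' @param alpha exponential weight (default 20).
#' @return numeric RIE.
#' @export
rie <- function(r, alpha = 20) {
  ck <- rank_check(r)
  stopifnot(alpha > 0)
  s <- sum(exp(-alpha * r$rank[r$active] / ck$N))
  denom <- (ck$n / ck$N) * (1 - exp(-alpha)) / (exp(alpha / ck$N) - 1)
  s / denom
}

#' Convert RIE to BEDROC
#'
#' Closed-form rescaling of RIE to the [0, 1]-bounded Boltzmann-enhanced
#' discrimination of ROC:
#' `BEDROC = RIE * Ra * sinh(alpha/2) / (cosh(alpha/2) -
#' cosh(alpha/2 - alpha * Ra)) + 1 / (1 - exp(alpha * (1 - Ra)))`.
#'
#' @param rie_value RIE value.
#' @param alpha exponential weight.
#' @param n number of actives.
#' @param N total entries.
#' @return numeric BEDROC in [0, 1].
#' @export
bedroc_from_rie <- function(rie_value, alpha, n, N) {
  Ra <- n / N
  rie_value * (Ra * sinh(alpha / 2)) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
}

#' Boltzmann-enhanced discrimination of ROC (BEDROC)
#'
#' Computed as the analytic conversion of [rie()]; bounded in [0, 1] and
#' approaching 1 for perfect early ranking at small active fractions.
#'
#' @inheritParams rie
#' @return numeric BEDROC.
#' @export
bedroc <- function(r, alpha = 20) {
  ck <- rank_check(r)
  bedroc_from_rie(rie(r, alpha), alpha, ck$n, ck$N)
}

#' Predictiveness curve and standardized total gain
#'
#' Fits a logistic regression of the activity label on the score (the
#' calibration model), orders the fitted activity probabilities by rank
#' fraction (the predictiveness curve) and summarizes them as the
#' standardized total gain
#' `TG = mean(|p_i - pbar|) / (2 * pbar * (1 - pbar))` with
#' `pbar = n / N`: 0 when scores carry no label information, 1 for
#' perfectly separated classes.
#'
#' @param r an `invdock_ranking`.
#' @return list with `curve` (data.frame `fraction`, `prob`), `tg`, and
#'   `separation` flag (TRUE when the fit hit perfect separation and the
#'   bounded-step fallback was used).
#' @export
predictiveness_total_gain <- function(r) {
  ck <- rank_check(r)
  if (length(unique(r$score)) < 2) stop("scores are all equal")
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(active ~ score, data = r, family = stats::binomial(),
               control = list(maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities|converge", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  p <- stats::fitted(fit)
  pbar <- ck$n / ck$N
  tg <- mean(abs(p - pbar)) / (2 * pbar * (1 - pbar))
  list(curve = data.frame(fraction = r$rank / ck$N, prob = as.numeric(p)),
       tg = tg, separation = separation)
}

#' All validation metrics of a labeled ranking
#'
#' @param r an `invdock_ranking`.
#' @param alpha exponential weight for RIE/BEDROC.
#' @param fractions enrichment-factor fractions.
#' @return list with `auc`, `ef`, `rie`, `bedroc`, `tg`, `n`, `N` and the
#'   underlying curves.
#' @export
screen_metrics <- function(r, alpha = 20, fractions = 0.01) {
  ck <- rank_check(r)
  roc <- roc_auc(r)
  enr <- enrichment(r, fractions)
  pc <- predictiveness_total_gain(r)
  rie_v <- rie(r, alpha)
  list(auc = roc$auc, ef = enr$ef, rie = rie_v,
       bedroc = bedroc_from_rie(rie_v, alpha, ck$n, ck$N),
       tg = pc$tg, n = ck$n, N = ck$N,
       roc_curve = roc$curve, enrichment_curve = enr$curve,
       predictiveness_curve = pc$curve)
}

#' Read a labeled score table from TSV
#'
#' Expects columns `id`, `score` and optionally `active` (0/1).
#'
#' @param path TSV file.
#' @return an `invdock_ranking` (when labels present) or plain data.frame.
#' @export
read_score_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "score") %in% names(df))) {
    stop("score table needs 'id' and 'score' columns: ", path)
  }
  if ("active" %in% names(df)) {
    labeled_ranking(df$id, df$score, df$active)
  } else {
    df
  }
}
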