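# Screen-wide score distribution, interval threshold and target selection.
# The screen's docking scores are treated as approximately normal (checked
# visually via the Q-Q points); proteins scoring below the central 95%
# probability interval of the fitted normal are selected as candidates.

#' Fit a normal distribution to docking scores
#'
#' Maximum-likelihood fit: mean and (by default) population standard
#' deviation. The unbiased (n-1) estimator is available via
#' `sd_method = "sample"`; at screen scale the difference is negligible.
#'
#' @param scores numeric vector of finite docking scores, n >= 2.
#' @param sd_method "ml" (population, maximum likelihood) or "sample".
#' @return list of class `invdock_normalfit` with `mean`, `sd`, `n`.
#' @export
fit_normal <- function(scores, sd_method = c("ml", "sample")) {
  sd_method <- match.arg(sd_method)
  scores <- as.numeric(scores)
  if (length(scores) < 2 || !all(is.finite(scores))) {
    stop("fit_normal needs >= 2 finite scores")
  }
  m <- mean(scores)
  s <- if (sd_method == "ml") {
    sqrt(mean((scores - m)^2))
  } else {
    stats::sd(scores)
  }
  if (s <= 0) stop("zero variance: all scores identical")
  structure(list(mean = m, sd = s, n = length(scores)),
            class = "invdock_normalfit")
}

#' @export
print.invdock_normalfit <- function(x, ...) {
  cat(sprintf("<invdock_normalfit> mean %.3f, sd %.3f (n = %d)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' Central probability interval of a fitted normal
#'
#' Returns `mean +/- z * sd` with `z = qnorm((1 + level) / 2)`; at the
#' default level 0.95 this is the interval containing the central 95% of
#' the fitted score distribution. Scores below the lower bound are the
#' screen's selection threshold.
#'
#' @param fit an `invdock_normalfit` (or list with `mean` and `sd`).
#' @param level coverage fraction in (0, 1), default 0.95.
#' @return named numeric vector `c(low, high)`.
#' @export
central_interval <- function(fit, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("level must be a single number in (0, 1)")
  }
  z <- stats::qnorm((1 + level) / 2)
  c(low = fit$mean - z * fit$sd, high = fit$mean + z * fit$sd)
}

#' Normal Q-Q points of a score sample
#'
#' Sample order statistics against standard-normal quantiles at plotting
#' positions (i - 0.5) / n; the visual normality check behind the
#' interval threshold.
#'
#' @param scores numeric vector, n >= 3.
#' @return data.frame with `theoretical` and `sample` columns.
#' @export
qq_points <- function(scores) {
  scores <- as.numeric(scores)
  n <- length(scores)
  if (n < 3) stop("qq_points needs >= 3 scores")
  data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
             sample = sort(scores))
}

#' Select and rank candidate targets below a score threshold
#'
#' Keeps rows with score strictly below `low` and ranks them ascending
#' (best first); ties broken by protein id. A score exactly equal to the
#' threshold is excluded.
#'
#' @param result data.frame with columns `protein_id` and `score`
#'   (optionally `site_id`), one best score per protein/site.
#' @param low lower interval bound (arb. units).
#' @param level coverage level recorded in the report.
#' @return list of class `invdock_threshold_report`: `level`, `low`,
#'   `selected` (ranked data.frame), `n_screened`.
#' @export
select_targets <- function(result, low, level = 0.95) {
  stopifnot(is.data.frame(result), all(c("protein_id", "score") %in%
                                         names(result)))
  if (!all(is.finite(result$score))) stop("non-finite scores in screen result")
  sel <- result[result$score < low, , drop = FALSE]
  sel <- sel[order(sel$score, sel$protein_id), , drop = FALSE]
  rownames(sel) <- NULL
  structure(list(level = level, low = low, selected = sel,
                 n_screened = nrow(result)),
            class = "invdock_threshold_report")
}

#' @export
print.invdock_threshold_report <- function(x, ...) {
  cat(sprintf("<invdock_threshold_report> %d of %d below %.2f (level %.2f)\n",
              nrow(x$selected), x$n_screened, x$low, x$level))
  if (nrow(x$selected)) {
    print(utils::head(x$selected, 5))
    if (nrow(x$selected) > 5) cat("...\n")
  }
  invisible(x)
}

#' Threshold report from a screen in one call
#'
#' Convenience composition: fit the normal, take the central interval at
#' `level`, select targets below its lower bound.
#'
#' @param result screen data.frame (see [select_targets()]).
#' @param level interval coverage, default 0.95.
#' @param sd_method forwarded to [fit_normal()].
#' @return an `invdock_threshold_report` with the fit attached as `fit`.
#' @export
prioritize_targets <- function(result, level = 0.95, sd_method = "ml") {
  fit <- fit_normal(result$score, sd_method = sd_method)
  ci <- central_interval(fit, level)
  rep <- select_targets(result, ci[["low"]], level)
  rep$fit <- fit
  rep$high <- ci[["high"]]
  rep
}
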