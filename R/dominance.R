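#' Empirical CDF of an outcome distribution
#'
#' Risk comparison of candidate harvest levels works directly on the
#' cumulative distribution functions of their sustainable-harvest-index
#' outcomes. `empirical_cdf` builds a right-continuous step function that
#' evaluates to `k/n` at the k-th order statistic, together with its sorted
#' support and cumulative probabilities; `write_cdf` exports it as a
#' two-column CSV (`value`, `cumulative_probability`) for external plotting.
#'
#' @param draws Numeric draws (>= 1, finite).
#' @param cdf An `empirical_cdf` object.
#' @param x Evaluation points.
#' @param path Output CSV path.
#' @return `empirical_cdf`: an object with fields `support`, `probs`, `n`;
#'   `eval_cdf`: probabilities at `x`.
#' @examples
#' f <- empirical_cdf(c(1, 2, 3))
#' eval_cdf(f, 2)  # 2/3
#' @export
empirical_cdf <- function(draws) {
  if (!length(draws) || any(!is.finite(draws)))
    stop("empirical_cdf needs at least one finite draw", call. = FALSE)
  support <- sort(unique(draws))
  probs <- cumsum(tabulate(match(sort(draws), support))) / length(draws)
  structure(list(support = support, probs = probs, n = length(draws)),
            class = "empirical_cdf")
}

#' @rdname empirical_cdf
#' @export
eval_cdf <- function(cdf, x) {
  stopifnot(inherits(cdf, "empirical_cdf"))
  idx <- findInterval(x, cdf$support)
  ifelse(idx == 0, 0, cdf$probs[pmax(idx, 1)])
}

#' @rdname empirical_cdf
#' @export
write_cdf <- function(cdf, path) {
  stopifnot(inherits(cdf, "empirical_cdf"))
  utils::write.csv(data.frame(value = cdf$support,
                              cumulative_probability = cdf$probs),
                   path, row.names = FALSE)
  invisible(path)
}

#' @export
print.empirical_cdf <- function(x, ...) {
  cat(sprintf("<empirical_cdf> %d draws, support [%g, %g]\n",
              x$n, min(x$support), max(x$support)))
  invisible(x)
}

as_draws <- function(x) {
  if (inherits(x, "empirical_cdf"))
    stop("dominance tests need the raw draws, not a cdf", call. = FALSE)
  if (is.list(x) && !is.null(x$draws)) x <- x$draws
  if (!is.numeric(x) || !length(x))
    stop("expected a non-empty numeric vector of draws", call. = FALSE)
  x
}

#' Stochastic dominance between two outcome distributions
#'
#' First-order dominance orders distributions for *any* decision-maker who
#' prefers the "better" direction; second-order dominance additionally
#' encodes risk aversion (avoiding large spread and adverse skew). Both are
#' evaluated exactly on the merged empirical support of the two samples. On
#' the smaller-is-better scale (the SHI scale), `A` first-order dominates
#' `B` when its CDF lies on or above `B`'s everywhere and strictly above
#' somewhere; `A` second-order dominates when the running (trapezoidal)
#' integral of its CDF does. First-order dominance implies second-order.
#' The better direction is an explicit argument because SHI is
#' smaller-is-better — the opposite of a yield framing — and a silent
#' direction error inverts conclusions.
#'
#' @param A,B Numeric draw vectors (or lists with a `draws` field).
#' @param better `"smaller"` (SHI scale, default) or `"larger"`.
#' @return `"A"`, `"B"`, or `"none"`.
#' @examples
#' first_order_dominates(c(1, 2, 3), c(2, 3, 4))      # "A"
#' second_order_dominates(c(2, 2), c(1, 3))           # "A": same centre, tighter
#' @export
first_order_dominates <- function(A, B, better = c("smaller", "larger")) {
  better <- match.arg(better)
  a <- as_draws(A); b <- as_draws(B)
  grid <- sort(unique(c(a, b)))
  FA <- eval_cdf(empirical_cdf(a), grid)
  FB <- eval_cdf(empirical_cdf(b), grid)
  if (better == "larger") { tmp <- FA; FA <- FB; FB <- tmp }
  dominance_verdict(FA, FB)
}

#' @rdname first_order_dominates
#' @export
second_order_dominates <- function(A, B, better = c("smaller", "larger")) {
  better <- match.arg(better)
  a <- as_draws(A); b <- as_draws(B)
  grid <- sort(unique(c(a, b)))
  FA <- eval_cdf(empirical_cdf(a), grid)
  FB <- eval_cdf(empirical_cdf(b), grid)
  if (better == "larger") { tmp <- FA; FA <- FB; FB <- tmp }
  dominance_verdict(cum_trapezoid(grid, FA), cum_trapezoid(grid, FB))
}

cum_trapezoid <- function(x, y) {
  if (length(x) == 1L) return(0)
  c(0, cumsum(diff(x) * (y[-length(y)] + y[-1]) / 2))
}

dominance_verdict <- function(GA, GB, tol = 1e-12) {
  a_ge <- all(GA >= GB - tol); b_ge <- all(GB >= GA - tol)
  a_gt <- any(GA > GB + tol);  b_gt <- any(GB > GA + tol)
  if (a_ge && a_gt) "A" else if (b_ge && b_gt) "B" else "none"
}

#' Rank candidate harvest levels by stochastic dominance
#'
#' Re-runs a single-species assessment once per candidate harvest
#' specification under common random numbers (identical seed and draw
#' order, with harvest sampled by inversion), so the SHI outcome
#' distributions differ only through the harvest itself. The observed
#' harvest from the scenario is always included as candidate `"observed"`.
#' Pairwise first- and second-order dominance matrices are returned, along
#' with the set of non-dominated candidates and a flag raised when a
#' candidate with lower expected harvest dominates the observed one — for a
#' risk-averse decision-maker, evidence that the observed harvest is
#' inconsistent with the stated management objective.
#'
#' @param config A single-species [assessment_config()].
#' @param candidates List of `dist_spec` harvest candidates (plain numbers
#'   are promoted to fixed specs); at least one in addition to the observed
#'   harvest, or two if `include_observed = FALSE`.
#' @param labels Optional candidate labels.
#' @param include_observed Include the scenario's own harvest spec (default
#'   `TRUE`).
#' @return A `dominance_report`: fields `labels`, `mean_harvest`, `shi`
#'   (list of draw vectors), `fsd` and `ssd` (character matrices with
#'   entries `"row"`, `"column"`, `"none"`), `preferred` (labels not
#'   second-order dominated by any other), and
#'   `observed_inconsistent_with_objective`.
#' @export
rank_harvest_candidates <- function(config, candidates, labels = NULL,
                                    include_observed = TRUE) {
  stopifnot(inherits(config, "assessment_config"))
  if (length(config$species) != 1L)
    stop("candidate ranking works on a single-species config", call. = FALSE)
  if (!is.list(candidates)) candidates <- as.list(candidates)
  candidates <- lapply(seq_along(candidates), function(i)
    dist_from_list(candidates[[i]], sprintf("candidates[%d]", i)))
  if (is.null(labels))
    labels <- vapply(candidates, function(d)
      sprintf("harvest~%g", dist_mean(d)), character(1))
  if (include_observed) {
    candidates <- c(list(config$species[[1]]$harvest), candidates)
    labels <- c("observed", labels)
  }
  if (length(candidates) < 2L)
    stop("need at least two candidate harvest levels to rank", call. = FALSE)
  if (anyDuplicated(labels)) stop("candidate labels must be unique", call. = FALSE)

  shi <- vector("list", length(candidates))
  names(shi) <- labels
  for (i in seq_along(candidates)) {
    cfg <- config
    cfg$species[[1]]$harvest <- candidates[[i]]
    shi[[i]] <- shi_draws(run_assessment(cfg))
  }
  k <- length(labels)
  fsd <- ssd <- matrix("none", k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    v1 <- first_order_dominates(shi[[i]], shi[[j]])
    v2 <- second_order_dominates(shi[[i]], shi[[j]])
    fsd[i, j] <- c(A = "row", B = "column", none = "none")[[v1]]
    fsd[j, i] <- c(A = "column", B = "row", none = "none")[[v1]]
    ssd[i, j] <- c(A = "row", B = "column", none = "none")[[v2]]
    ssd[j, i] <- c(A = "column", B = "row", none = "none")[[v2]]
  }
  dominated <- vapply(seq_len(k), function(i)
    any(ssd[, i] == "row" & seq_len(k) != i), TRUE)
  mean_h <- vapply(candidates, dist_mean, numeric(1))
  inconsistent <- FALSE
  if (include_observed) {
    obs <- which(labels == "observed")
    beats_obs <- which(ssd[, obs] == "row" | fsd[, obs] == "row")
    inconsistent <- any(mean_h[beats_obs] < mean_h[obs])
  }
  structure(list(labels = labels, mean_harvest = mean_h, shi = shi,
                 fsd = fsd, ssd = ssd, preferred = labels[!dominated],
                 observed_inconsistent_with_objective = inconsistent),
            class = "dominance_report")
}

#' @export
print.dominance_report <- function(x, ...) {
  cat(sprintf("<dominance_report> %d candidates\n", length(x$labels)))
  med <- vapply(x$shi, stats::median, numeric(1))
  for (i in seq_along(x$labels))
    cat(sprintf("  %-12s mean harvest %8.1f   median SHI %6.3f%s\n",
                x$labels[i], x$mean_harvest[i], med[i],
                if (x$labels[i] %in% x$preferred) "   (non-dominated)" else ""))
  if (isTRUE(x$observed_inconsistent_with_objective))
    cat("  NOTE: a lower harvest level dominates the observed harvest;\n",
        "  for a risk-averse decision-maker the observed harvest is\n",
        "  inconsistent with the stated management objective.\n", sep = "")
  invisible(x)
}
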