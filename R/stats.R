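# Two-group statistical workflow: Anderson-Darling normality dispatch,
# F-test variance selection, one-tailed t vs. Mann-Whitney, BH FDR
# adjustment at q = 0.1, and two-tier significance labels.

#' Normality-dispatched two-group comparison
#'
#' Dispatch: when both samples pass an Anderson-Darling normality test
#' (case-3 critical values, estimated mean and variance) at
#' `alpha_normality`, an F-test on the variances selects a pooled
#' (p >= 0.05) or unequal-variance (p < 0.05) one-tailed t-test; otherwise a
#' Mann-Whitney U test is used (exact when both n <= 8 with no ties,
#' tie-corrected normal approximation otherwise).  The Anderson-Darling test
#' needs at least 8 observations, so smaller samples take the rank branch.
#' The tail direction must be declared per contrast -- choosing it from the
#' data would double the type-I error.
#'
#' @param x,y numeric samples (n >= 3 each).
#' @param tail `"greater"` (x stochastically larger than y) or `"less"`.
#' @param alpha_normality Anderson-Darling level (default 0.05).
#' @param var_alpha F-test level for pooled vs. Welch (default 0.05).
#' @param force `"auto"` (dispatch as above), `"t"` or `"mann_whitney"` to
#'   force a branch.
#' @return An object of class `comparison_result`: `n_a`, `n_b`,
#'   `test_used` (one of `"t_pooled"`, `"t_welch"`, `"mann_whitney"`),
#'   `statistic`, `p_raw`, `tail`.
#' @export
compare_two_groups <- function(x, y, tail = c("greater", "less"),
                               alpha_normality = 0.05, var_alpha = 0.05,
                               force = c("auto", "t", "mann_whitney")) {
  tail <- match.arg(tail)
  force <- match.arg(force)
  min_n <- if (force == "mann_whitney") 2 else 3
  if (length(x) < min_n || length(y) < min_n)
    stop(sprintf("each sample needs at least %d observations", min_n),
         call. = FALSE)
  ad_p <- function(v) {
    if (length(v) < 8 || stats::sd(v) == 0) return(NA_real_)
    tryCatch(nortest::ad.test(v)$p.value, error = function(e) NA_real_)
  }
  use_t <- switch(force,
    t = TRUE,
    mann_whitney = FALSE,
    auto = {
      px <- ad_p(x); py <- ad_p(y)
      !is.na(px) && !is.na(py) && px >= alpha_normality && py >= alpha_normality
    })
  if (use_t) {
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      stop("both samples have zero variance; t-test undefined", call. = FALSE)
    pooled <- stats::var.test(x, y)$p.value >= var_alpha
    tt <- stats::t.test(x, y, alternative = tail, var.equal = pooled)
    res <- list(test_used = if (pooled) "t_pooled" else "t_welch",
                statistic = unname(tt$statistic), p_raw = tt$p.value)
  } else {
    exact <- length(x) <= 8 && length(y) <= 8 && !any(duplicated(c(x, y)))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = tail, exact = exact, correct = TRUE))
    res <- list(test_used = "mann_whitney",
                statistic = unname(wt$statistic), p_raw = wt$p.value)
  }
  structure(c(list(n_a = length(x), n_b = length(y), tail = tail), res),
            class = "comparison_result")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment of a family of p-values with pass flags at the FDR
#' threshold `q` (default 0.1): sorted ascending,
#' `p_adj(i) = min over j >= i of m * p(j) / j`, capped at 1; a contrast
#' passes when its adjusted p is at most `q`.
#'
#' @param p_values raw p-values, all in (0, 1].
#' @param q FDR threshold in (0, 1).
#' @return list with `p_adjusted` (same order as input) and `pass` flags.
#' @export
bh_adjust <- function(p_values, q = 0.1) {
  if (length(p_values) == 0) stop("empty p-value family", call. = FALSE)
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  check_number(q, "q", min = 0, max = 1, strict_min = TRUE, strict_max = TRUE)
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, pass = adj <= q)
}

#' Two-tier significance labels
#'
#' Black tier from the raw p-value at thresholds 0.05 / 0.005 / 0.001
#' (one/two/three symbols) and red tier from the FDR-adjusted p-value at
#' 0.1 / 0.05 / 0.01; all thresholds inclusive.
#'
#' @param p_raw,p_fdr raw and BH-adjusted p-values (vectorized).
#' @return data.frame with `tier_black` in `{ns, p<=0.05, p<=0.005,
#'   p<=0.001}` and `tier_red` in `{ns, q<=0.1, q<=0.05, q<=0.01}`.
#' @export
assign_tiers <- function(p_raw, p_fdr) {
  tier <- function(p, cuts, labels) {
    out <- rep("ns", length(p))
    for (i in seq_along(cuts)) out[p <= cuts[i]] <- labels[i]
    out
  }
  data.frame(
    tier_black = tier(p_raw, c(0.05, 0.005, 0.001),
                      c("p<=0.05", "p<=0.005", "p<=0.001")),
    tier_red = tier(p_fdr, c(0.1, 0.05, 0.01),
                    c("q<=0.1", "q<=0.05", "q<=0.01")))
}

#' Tidy table of group contrasts with FDR adjustment
#'
#' Runs [compare_two_groups()] for each requested contrast over a per-unit
#' value table, adjusts the raw p-values together as one BH family (the
#' family is typically one figure-panel analysis), and appends both
#' significance tiers.
#'
#' @param data data.frame with one row per unit.
#' @param value,group column names of the measured value and group label.
#' @param contrasts list of 2-vectors `c(group_a, group_b)`; default all
#'   pairs.
#' @param tail tail direction passed to every contrast (or a vector, one per
#'   contrast).
#' @param q FDR threshold.
#' @param family label recorded on every row.
#' @param ... further arguments to [compare_two_groups()].
#' @return data.frame, one row per contrast: groups, n's, test used,
#'   statistic, `p_raw`, `p_fdr`, `fdr_pass`, tiers.
#' @export
compare_groups <- function(data, value, group, contrasts = NULL,
                           tail = "greater", q = 0.1, family = "", ...) {
  groups <- unique(data[[group]])
  if (is.null(contrasts))
    contrasts <- utils::combn(as.character(groups), 2, simplify = FALSE)
  if (length(tail) == 1) tail <- rep(tail, length(contrasts))
  rows <- do.call(rbind, Map(function(ct, tl) {
    x <- data[[value]][data[[group]] == ct[1]]
    y <- data[[value]][data[[group]] == ct[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    r <- compare_two_groups(x, y, tail = tl, ...)
    data.frame(family = family, group_a = ct[1], group_b = ct[2],
               n_a = r$n_a, n_b = r$n_b, test_used = r$test_used,
               statistic = r$statistic, p_raw = r$p_raw)
  }, contrasts, tail))
  adj <- bh_adjust(rows$p_raw, q = q)
  rows$p_fdr <- adj$p_adjusted
  rows$fdr_pass <- adj$pass
  cbind(rows, assign_tiers(rows$p_raw, rows$p_fdr))
}
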