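#' Weekly COD-normalized production rates
#'
#' Splits a cumulative volume trace into 7-day windows aligned to the start
#' of the run, fits a production rate in each, and normalizes the slope by
#' the daily organic load `olr_gCOD_L_d * working_volume_L` so that periods
#' with different substrate loads are comparable (mL d^-1 gCOD_added^-1).
#'
#' @param volume a `volume_trace` from [to_volume()] or
#'   [run_pipeline()]`$volume`.
#' @param config the reactor's [reactor_config()] (supplies OLR and working
#'   volume).
#' @param reactor_id label for the output; defaults to the trace's.
#' @return data.frame with one row per week: `reactor_id`, `week_index`
#'   (1-based), `rate_mL_d`, `rate_mL_d_gCOD`, `r2`, `se_mL_d`, `n_points`.
#'   Weeks with fewer than 3 points are omitted with a warning.
#' @export
weekly_rates <- function(volume, config, reactor_id = NULL) {
  stopifnot(inherits(config, "reactor_config"))
  if (is.null(reactor_id)) {
    reactor_id <- attr(volume, "reactor_id")
    if (is.null(reactor_id)) reactor_id <- "R1"
  }
  daily_gCOD <- config$olr_gCOD_L_d * config$working_volume_mL / 1000
  n_weeks <- ceiling(max(volume$time_d) / 7)
  rows <- vector("list", n_weeks)
  for (w in seq_len(n_weeks)) {
    sel <- volume$time_d >= 7 * (w - 1) & volume$time_d < 7 * w
    if (sum(sel) < 3L) {
      warnf("week %d has %d point(s); omitted", w, sum(sel))
      next
    }
    r <- fit_rate(volume[sel, , drop = FALSE])
    rows[[w]] <- data.frame(
      reactor_id = reactor_id, week_index = w,
      rate_mL_d = r$slope_mL_d,
      rate_mL_d_gCOD = r$slope_mL_d / daily_gCOD,
      r2 = r$r2, se_mL_d = r$se_slope_mL_d, n_points = r$n_points,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis rank sum test (tie-corrected)
#'
#' Nonparametric k-sample comparison used to test whether replicated
#' reactors seeded from different inocula perform differently. Implemented
#' from the rank formula: with mid-ranks pooled over all `N` observations,
#' `H = 12 / (N (N + 1)) * sum n_i Rbar_i^2 - 3 (N + 1)`, divided by the
#' tie correction `1 - sum(t^3 - t) / (N^3 - N)`; the p-value comes from the
#' chi-square distribution with `k - 1` degrees of freedom. When every
#' observation is identical the statistic is 0 and p = 1 by convention.
#'
#' @param groups list of numeric vectors, each nonempty, at least 2 groups.
#' @return list of class `kw_test`: `H`, `df`, `p_value`.
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))  # H = 7.2
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stopf("`groups` must be a list of at least 2 numeric samples")
  }
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stopf("every group must be nonempty")
  x <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(x))) stopf("observations must be finite")
  N <- length(x)
  k <- length(groups)
  g <- rep.int(seq_len(k), sizes)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  H <- 12 / (N * (N + 1)) * sum(sizes * rbar^2) - 3 * (N + 1)
  tie_tab <- table(x)
  tie_term <- sum(tie_tab^3 - tie_tab)
  denom <- 1 - tie_term / (N^3 - N)
  if (denom <= 0) {
    # all observations identical
    H <- 0
    p <- 1
  } else {
    H <- H / denom
    p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  }
  structure(list(H = H, df = k - 1L, p_value = p), class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.4f, df = %d, p-value = %.4g\n",
              x$H, x$df, x$p_value))
  invisible(x)
}

#' Dunn's post-hoc test for multiple pairwise comparisons
#'
#' Rank-based pairwise z tests following a Kruskal-Wallis test, with the
#' usual tie correction in the variance:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N (N + 1) / 12 - T) (1/n_i + 1/n_j))`
#' where `T = sum(t^3 - t) / (12 (N - 1))`. Two-sided p-values; multiplicity
#' adjustment via [stats::p.adjust()].
#'
#' @param groups list of numeric vectors; names become group labels.
#' @param adjust_method `"holm"` (default), `"bonferroni"` or `"none"`.
#' @return data.frame of class `dunn_test` with one row per pair:
#'   `group_i`, `group_j`, `z`, `p_raw`, `p_adjusted`; the adjustment method
#'   is attached as attribute `adjust_method`.
#' @export
dunn_posthoc <- function(groups, adjust_method = c("holm", "bonferroni",
                                                   "none")) {
  adjust_method <- match.arg(adjust_method)
  if (!is.list(groups) || length(groups) < 2L) {
    stopf("`groups` must be a list of at least 2 numeric samples")
  }
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stopf("every group must be nonempty")
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("group", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  g <- rep.int(seq_along(groups), sizes)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  tie_tab <- table(x)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  pairs <- utils::combn(seq_along(groups), 2L)
  z <- p_raw <- numeric(ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1L, c]; j <- pairs[2L, c]
    se <- sqrt(s2 * (1 / sizes[i] + 1 / sizes[j]))
    z[c] <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    p_raw[c] <- 2 * stats::pnorm(-abs(z[c]))
  }
  out <- data.frame(
    group_i = labels[pairs[1L, ]], group_j = labels[pairs[2L, ]],
    z = z, p_raw = p_raw,
    p_adjusted = stats::p.adjust(p_raw, method = adjust_method),
    stringsAsFactors = FALSE
  )
  attr(out, "adjust_method") <- adjust_method
  class(out) <- c("dunn_test", "data.frame")
  out
}

#' Compare groups: Kruskal-Wallis with conditional Dunn post-hoc
#'
#' Runs the omnibus [kruskal_wallis()] test and, when it is significant at
#' `alpha` (or when `force_posthoc = TRUE`), Dunn's pairwise post-hoc test.
#' The adjustment method is always recorded in the output.
#'
#' @param groups named list of numeric vectors.
#' @param adjust_method passed to [dunn_posthoc()].
#' @param alpha significance level gating the post-hoc (default 0.05).
#' @param force_posthoc run the post-hoc regardless of the omnibus p-value.
#' @return list of class `group_comparison`: `H`, `df`, `p_value`,
#'   `pairwise` (NULL when the omnibus test is not significant and not
#'   forced), `adjust_method`.
#' @export
compare_groups <- function(groups, adjust_method = "holm", alpha = 0.05,
                           force_posthoc = FALSE) {
  kw <- kruskal_wallis(groups)
  pairwise <- NULL
  if (force_posthoc || kw$p_value < alpha) {
    pairwise <- dunn_posthoc(groups, adjust_method)
  }
  structure(
    list(H = kw$H, df = kw$df, p_value = kw$p_value, pairwise = pairwise,
         adjust_method = adjust_method),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.4f, df = %d, p = %.4g\n",
              x$H, x$df, x$p_value))
  if (is.null(x$pairwise)) {
    cat("No post-hoc comparisons (omnibus test not significant).\n")
  } else {
    cat(sprintf("Dunn post-hoc (%s adjustment):\n", x$adjust_method))
    print(as.data.frame(x$pairwise), row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Weekly group comparison across reactors
#'
#' For each week, groups the per-reactor normalized rates by their design
#' label (e.g. inoculum origin) and runs [compare_groups()], reproducing the
#' weekly boxplot-plus-test summary of a replicated inoculum experiment.
#'
#' @param rates data.frame as returned by [weekly_rates()] (stacked over
#'   reactors), needing columns `reactor_id`, `week_index`,
#'   `rate_mL_d_gCOD`.
#' @param design data.frame mapping `reactor_id` to `group`.
#' @param adjust_method,alpha,force_posthoc passed to [compare_groups()].
#' @return list with `summary` (data.frame: `week_index`, `H`, `df`,
#'   `p_value`, `n_significant_pairs`) and `pairwise` (data.frame of all
#'   post-hoc rows with a `week_index` column).
#' @export
compare_weekly <- function(rates, design, adjust_method = "holm",
                           alpha = 0.05, force_posthoc = FALSE) {
  if (!all(c("reactor_id", "week_index", "rate_mL_d_gCOD") %in% names(rates))) {
    stopf("`rates` needs columns reactor_id, week_index, rate_mL_d_gCOD")
  }
  if (!all(c("reactor_id", "group") %in% names(design))) {
    stopf("`design` needs columns reactor_id, group")
  }
  rates$group <- design$group[match(rates$reactor_id, design$reactor_id)]
  if (any(is.na(rates$group))) {
    stopf("reactor(s) missing from design: %s",
          paste(unique(rates$reactor_id[is.na(rates$group)]), collapse = ", "))
  }
  weeks <- sort(unique(rates$week_index))
  summ <- vector("list", length(weeks))
  pw <- vector("list", length(weeks))
  for (k in seq_along(weeks)) {
    wk <- rates[rates$week_index == weeks[k], , drop = FALSE]
    groups <- split(wk$rate_mL_d_gCOD, wk$group)
    cmp <- compare_groups(groups, adjust_method, alpha, force_posthoc)
    n_sig <- if (is.null(cmp$pairwise)) 0L else
      sum(cmp$pairwise$p_adjusted < alpha)
    summ[[k]] <- data.frame(week_index = weeks[k], H = cmp$H, df = cmp$df,
                            p_value = cmp$p_value,
                            n_significant_pairs = n_sig)
    if (!is.null(cmp$pairwise)) {
      pw[[k]] <- cbind(week_index = weeks[k], as.data.frame(cmp$pairwise))
    }
  }
  list(summary = do.call(rbind, summ),
       pairwise = if (any(!vapply(pw, is.null, TRUE))) {
         do.call(rbind, pw[!vapply(pw, is.null, TRUE)])
       } else NULL)
}
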