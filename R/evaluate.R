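#' Pair extracted RRs with segment-averaged reference RRs
#'
#' For every included segment, averages the reference samples whose
#' timestamps fall in the half-open window `[start, start + seg_len)`
#' (15 samples for a 30-s window at 0.5 Hz) and pairs that average with
#' the extracted RR. Segments whose reference window is entirely gaps
#' are dropped and counted.
#'
#' @param ref an `nrr_reference`.
#' @param results an `nrr_results` data frame.
#' @param seg_len_s segment length, seconds; defaults to the value in
#'   the results' parameters.
#' @return data frame with columns `start_s`, `ref_rr`, `est_rr`;
#'   attributes `n_total` (all segments), `n_included`, `n_dropped`
#'   (included segments without reference coverage).
#' @export
align_reference <- function(ref, results, seg_len_s = NULL) {
  p <- attr(results, "params")
  if (is.null(seg_len_s)) seg_len_s <- p$seg_len_s %||% 30
  tt <- ref_times(ref)
  inc <- results[results$included & !is.na(results$rr_bpm), , drop = FALSE]
  pairs <- lapply(seq_len(nrow(inc)), function(i) {
    s0 <- inc$start_s[i]
    sel <- tt >= s0 & tt < s0 + seg_len_s & !is.na(ref$rr)
    if (!any(sel)) return(NULL)
    data.frame(start_s = s0, ref_rr = mean(ref$rr[sel]),
               est_rr = inc$rr_bpm[i])
  })
  keep <- !vapply(pairs, is.null, TRUE)
  out <- if (any(keep)) do.call(rbind, pairs[keep])
  else data.frame(start_s = numeric(), ref_rr = numeric(), est_rr = numeric())
  attr(out, "n_total") <- nrow(results)
  attr(out, "n_included") <- nrow(inc)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Agreement metrics between reference and extracted RR
#'
#' Error is extracted minus reference. Reports the mean error (bias),
#' root-mean-square error, Bland-Altman limits of agreement
#' (1.96 times the sample standard deviation of the error), Pearson's
#' correlation with its two-sided t-test p-value (n - 2 degrees of
#' freedom), and the percentage of segments in which RR was computed.
#'
#' @param pairs output of [align_reference()].
#' @param n_total total segment count for the included percentage;
#'   defaults to the attribute carried by `pairs`.
#' @return an object of class `nrr_agreement`: list with `me`, `rmse`,
#'   `loa`, `pearson_r`, `pearson_p`, `included_pct`, `n_pairs`.
#' @export
agreement <- function(pairs, n_total = attr(pairs, "n_total")) {
  if (nrow(pairs) < 2) stop("need at least 2 pairs")
  err <- pairs$est_rr - pairs$ref_rr
  r <- p <- NA_real_
  if (nrow(pairs) >= 3 && var(pairs$ref_rr) > 0 && var(pairs$est_rr) > 0) {
    ct <- cor.test(pairs$ref_rr, pairs$est_rr, method = "pearson")
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  inc_pct <- if (is.null(n_total)) NA_real_
  else 100 * (attr(pairs, "n_included") %||% nrow(pairs)) / n_total
  structure(list(me = mean(err), rmse = sqrt(mean(err^2)),
                 loa = 1.96 * sd(err), pearson_r = r, pearson_p = p,
                 included_pct = inc_pct, n_pairs = nrow(pairs)),
            class = "nrr_agreement")
}

#' @export
print.nrr_agreement <- function(x, ...) {
  cat(sprintf(paste0("<agreement over %d pairs>\n",
                     "  ME   %7.2f BPM\n  RMSE %7.2f BPM\n  LoA  %7.2f BPM\n",
                     "  r    %7.3f (p = %.3g)\n  included %.1f%%\n"),
              x$n_pairs, x$me, x$rmse, x$loa, x$pearson_r, x$pearson_p,
              x$included_pct))
  invisible(x)
}

#' The 30% agreement boundary
#'
#' A pair lies outside the boundary when the absolute error is at least
#' `boundary_frac` times the mean of the paired reference and extracted
#' RRs.
#'
#' @param pairs output of [align_reference()].
#' @param boundary_frac boundary fraction (default 0.30).
#' @return list with `pct_outside`, `outside` (logical vector),
#'   `boundary_frac`.
#' @export
boundary30 <- function(pairs, boundary_frac = 0.30) {
  if (nrow(pairs) < 1) stop("need at least one pair")
  err <- abs(pairs$est_rr - pairs$ref_rr)
  lim <- boundary_frac * (pairs$ref_rr + pairs$est_rr) / 2
  outside <- err >= lim
  list(pct_outside = 100 * mean(outside), outside = outside,
       boundary_frac = boundary_frac)
}

#' Pairwise method comparison on per-segment absolute errors
#'
#' Aligns the methods' pairs on common segment start times and runs a
#' paired two-sided t-test on the per-segment absolute errors for every
#' method pair. A method compared with itself (all differences zero)
#' is reported as p = 1.
#'
#' @param pair_list named list of [align_reference()] outputs, one per
#'   method.
#' @param alpha significance level for the decision column.
#' @return data frame with one row per method pair: `method_a`,
#'   `method_b`, `mean_abs_a`, `mean_abs_b`, `p_value`, `significant`.
#' @export
compare_methods <- function(pair_list, alpha = 0.05) {
  stopifnot(length(pair_list) >= 2, !is.null(names(pair_list)))
  nm <- names(pair_list)
  combs <- utils::combn(nm, 2)
  rows <- lapply(seq_len(ncol(combs)), function(j) {
    a <- pair_list[[combs[1, j]]]
    b <- pair_list[[combs[2, j]]]
    common <- intersect(a$start_s, b$start_s)
    if (length(common) < 3) stop("methods share fewer than 3 segments")
    ea <- abs(a$est_rr - a$ref_rr)[match(common, a$start_s)]
    eb <- abs(b$est_rr - b$ref_rr)[match(common, b$start_s)]
    d <- ea - eb
    pv <- if (all(abs(d) < 1e-12)) 1 else t.test(ea, eb, paired = TRUE)$p.value
    data.frame(method_a = combs[1, j], method_b = combs[2, j],
               mean_abs_a = mean(ea), mean_abs_b = mean(eb),
               p_value = pv, significant = pv < alpha)
  })
  do.call(rbind, rows)
}

measurement_rmse <- function(dataset, p) {
  vapply(dataset, function(d) {
    res <- run_nrr(d$recording, p, channel = d$channel %||% NULL)
    pr <- align_reference(d$reference, res)
    if (nrow(pr) < 1) return(NA_real_)
    sqrt(mean((pr$est_rr - pr$ref_rr)^2))
  }, 0)
}

#' Sequential sensitivity analysis of the main NRR parameters
#'
#' Sweeps the three tunables in sequence: window length with
#' `(a_low, a_high) = (0.05, 0.95)`; then `a_low` at the winning window
#' with `a_high = 0.95`; then `a_high` at the winning pair. Each cell
#' reports mean and sd of per-measurement RMSE. A cell "ties" with the
#' numeric optimum when a paired t-test on per-measurement RMSEs is
#' non-significant at `alpha`; among ties, the lower `a_low` and the
#' higher `a_high` are preferred (both enlarge the adaptive RR band).
#'
#' @param dataset list of measurements, each a list with elements
#'   `recording` (`nrr_recording`), `reference` (`nrr_reference`) and
#'   optionally `channel`.
#' @param win_grid,alow_grid,ahigh_grid the three sweep axes.
#' @param base an [nrr_params()] object supplying all other settings.
#' @param alpha significance level for the tie test.
#' @return list with per-axis tables (`window`, `a_low`, `a_high`),
#'   each with columns value/mean_rmse/sd_rmse/p_vs_best, and the
#'   selected `optimum` (list: `seg_len_s`, `a_low`, `a_high`).
#' @export
sensitivity_grid <- function(dataset,
                             win_grid = seq(20, 60, by = 10),
                             alow_grid = seq(0.05, 0.20, by = 0.05),
                             ahigh_grid = seq(0.75, 0.95, by = 0.05),
                             base = nrr_params(), alpha = 0.05) {
  stopifnot(length(win_grid) >= 1, length(alow_grid) >= 1,
            length(ahigh_grid) >= 1)
  sweep_axis <- function(values, make_p) {
    per_meas <- lapply(values, function(v) measurement_rmse(dataset, make_p(v)))
    means <- vapply(per_meas, function(r) mean(r, na.rm = TRUE), 0)
    sds <- vapply(per_meas, function(r) sd(r[!is.na(r)]), 0)
    best <- which.min(means)
    pvs <- vapply(seq_along(values), function(i) {
      if (i == best) return(1)
      d <- per_meas[[i]] - per_meas[[best]]
      d <- d[!is.na(d)]
      if (length(d) < 2 || all(abs(d) < 1e-12)) return(1)
      t.test(d)$p.value
    }, 0)
    list(table = data.frame(value = values, mean_rmse = means,
                            sd_rmse = sds, p_vs_best = pvs),
         best = best, ties = which(pvs >= alpha))
  }

  sw <- sweep_axis(win_grid, function(v)
    modify_params(base, seg_len_s = v, a_low = 0.05, a_high = 0.95))
  win_opt <- win_grid[sw$best]

  sl <- sweep_axis(alow_grid, function(v)
    modify_params(base, seg_len_s = win_opt, a_low = v, a_high = 0.95))
  alow_opt <- min(alow_grid[sl$ties])     # lower a_low -> larger band

  sh <- sweep_axis(ahigh_grid, function(v)
    modify_params(base, seg_len_s = win_opt, a_low = alow_opt, a_high = v))
  ahigh_opt <- max(ahigh_grid[sh$ties])   # higher a_high -> larger band

  list(window = sw$table, a_low = sl$table, a_high = sh$table,
       optimum = list(seg_len_s = win_opt, a_low = alow_opt,
                      a_high = ahigh_opt))
}

modify_params <- function(p, ...) {
  do.call(nrr_params, modifyList(unclass(p), list(...)))
}

#' Bland-Altman plot of paired reference and extracted RRs
#'
#' Mean-vs-difference plot with the bias line, the limits of agreement,
#' and the 30% boundary curves.
#'
#' @param pairs output of [align_reference()].
#' @param boundary_frac boundary fraction drawn as guide curves.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted data frame.
#' @export
plot_bland_altman <- function(pairs, boundary_frac = 0.30, ...) {
  m <- (pairs$ref_rr + pairs$est_rr) / 2
  d <- pairs$est_rr - pairs$ref_rr
  loa <- 1.96 * sd(d)
  graphics::plot(m, d, xlab = "mean RR (BPM)",
                 ylab = "extracted - reference (BPM)", pch = 16,
                 col = grDevices::adjustcolor("black", 0.5), ...)
  graphics::abline(h = mean(d), col = "magenta", lwd = 2)
  graphics::abline(h = mean(d) + c(-loa, loa), col = "red", lty = 2)
  xs <- seq(min(m), max(m), length.out = 100)
  graphics::lines(xs, boundary_frac * xs, col = "cyan3")
  graphics::lines(xs, -boundary_frac * xs, col = "cyan3")
  invisible(data.frame(mean = m, diff = d))
}
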