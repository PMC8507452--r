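#' Resolution-table statistics and reporting
#'
#' Aggregates FWHM tables into the summary statistics used for dual-camera
#' triple-line resolution studies: means with sample SD, X-Y paired
#' differences with percent differences, and paired two-sided t-tests with
#' 95% confidence intervals.
#'
#' @name stats_report
NULL

#' Bundled example resolution table
#'
#' Gaussian-fit FWHM values (mm) of three In-111 line sources (A-C) in a
#' water-filled Jaszczak phantom, imaged with two clinical cameras and
#' reconstructed with the three OSEM variants; a worked-example input for the
#' statistics layer.
#'
#' @return data.frame with columns `camera`, `variant` (`AC`, `ACRR`, `MC`),
#'   `line` (`A`, `B`, `C`), `direction` (`x`, `y`) and `fwhm_mm`.
#' @export
example_resolution_table <- function() {
  variants <- c("AC", "ACRR", "MC")
  vals <- list(
    # camera 1: x by line A,B,C then y; camera 2 likewise
    AC   = list(c1x = c(11.8, 9.3, 6.8),  c1y = c(18.0, 12.1, 14.2),
                c2x = c(12.8, 7.4, 9.1),  c2y = c(18.6, 13.6, 13.0)),
    ACRR = list(c1x = c(9.9, 7.1, 5.7),   c1y = c(13.1, 9.0, 9.7),
                c2x = c(10.4, 6.2, 7.0),  c2y = c(13.8, 9.9, 9.3)),
    MC   = list(c1x = c(8.4, 6.4, 5.0),   c1y = c(11.1, 8.6, 8.9),
                c2x = c(8.7, 5.6, 6.5),   c2y = c(11.4, 9.1, 9.0))
  )
  rows <- list()
  for (v in variants) {
    for (cam in 1:2) {
      for (dirn in c("x", "y")) {
        fw <- vals[[v]][[paste0("c", cam, dirn)]]
        rows[[length(rows) + 1]] <- data.frame(
          camera = cam, variant = v, line = c("A", "B", "C"),
          direction = dirn, fwhm_mm = fw)
      }
    }
  }
  do.call(rbind, rows)
}

#' Mean and sample standard deviation
#'
#' @param values numeric, length >= 2.
#' @return named numeric: `mean`, `sd` (n-1 denominator).
#' @export
#' @examples
#' mean_sd(c(11.8, 9.3, 6.8)) # 9.3, 2.5 at 1 decimal
mean_sd <- function(values) {
  if (length(values) < 2) stop("need at least 2 values for a sample SD")
  c(mean = mean(values), sd = sd(values))
}

#' Paired t-test with confidence interval and percent difference
#'
#' Differences are `d = a - b`. Reports mean and sample SD of `d`, the
#' per-pair percent difference `mean(d_i / b_i) * 100` (convention-sensitive;
#' the denominator is the second argument), the t statistic with n-1 df, the
#' two-sided p value, and the `1 - alpha` confidence interval for the mean
#' difference. The t machinery is delegated to [stats::t.test()].
#'
#' @param a,b paired numeric vectors of equal length n >= 2.
#' @param alpha significance level (default 0.05 for a 95% CI).
#' @return object of class `paired_stats`: `mean_diff`, `sd_diff`,
#'   `percent`, `t_stat`, `df`, `p_two_sided`, `ci` (length 2).
#' @export
paired_t_ci <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  sd_d <- sd(d)
  if (sd_d == 0) {
    m <- mean(d)
    res <- list(mean_diff = m, sd_diff = 0,
                percent = mean(d / b) * 100,
                t_stat = if (m == 0) 0 else sign(m) * Inf,
                df = n - 1,
                p_two_sided = if (m == 0) 1 else 0,
                ci = c(m, m))
    return(structure(res, class = "paired_stats"))
  }
  tt <- stats::t.test(a, b, paired = TRUE, conf.level = 1 - alpha)
  structure(list(mean_diff = mean(d), sd_diff = sd_d,
                 percent = mean(d / b) * 100,
                 t_stat = unname(tt$statistic), df = unname(tt$parameter),
                 p_two_sided = tt$p.value,
                 ci = as.numeric(tt$conf.int)),
            class = "paired_stats")
}

#' @export
print.paired_stats <- function(x, ...) {
  cat(sprintf("paired diff %.1f +/- %.1f (%.0f%%), t(%d) = %.2f, p = %.3g, 95%% CI [%.1f, %.1f]\n",
              x$mean_diff, x$sd_diff, x$percent, x$df, x$t_stat,
              x$p_two_sided, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Summary report of a resolution table
#'
#' Builds three summaries from a long FWHM table:
#' \describe{
#'   \item{overall}{per-variant mean and SD over all cameras, lines and
#'     directions.}
#'   \item{by_camera}{per (camera/realization, variant, direction) mean and
#'     SD over lines, plus the per-line values.}
#'   \item{xy_paired}{per-variant paired statistics of the Y-X differences
#'     over (camera, line) pairs.}
#' }
#' All numbers are emitted unrounded; `rounded = TRUE` adds display columns
#' at 1 decimal (mm) and whole percent.
#'
#' @param tab data.frame with columns `variant`, `line`, `direction`,
#'   `fwhm_mm` and a realization column (`camera` or `realization`).
#' @param variant_pairs optional list of length-2 character vectors; for each
#'   pair `c(v1, v2)` a paired test of v1 - v2 over all matched rows is added
#'   under `variant_paired`.
#' @return list with data.frames `overall`, `by_camera`, `xy_paired` and
#'   optionally `variant_paired`.
#' @export
build_report <- function(tab, variant_pairs = NULL) {
  if (nrow(tab) == 0) {
    return(list(overall = data.frame(), by_camera = data.frame(),
                xy_paired = data.frame()))
  }
  realiz_col <- if ("camera" %in% names(tab)) "camera" else "realization"
  variants <- unique(tab$variant)
  overall <- do.call(rbind, lapply(variants, function(v) {
    ms <- mean_sd(tab$fwhm_mm[tab$variant == v])
    data.frame(variant = v, mean_mm = ms[["mean"]], sd_mm = ms[["sd"]],
               n = sum(tab$variant == v))
  }))
  by_camera <- do.call(rbind, lapply(split(
    tab, list(tab[[realiz_col]], tab$variant, tab$direction), drop = TRUE),
    function(g) {
      ms <- if (nrow(g) >= 2) mean_sd(g$fwhm_mm) else
        c(mean = mean(g$fwhm_mm), sd = NA_real_)
      data.frame(realization = g[[realiz_col]][1], variant = g$variant[1],
                 direction = g$direction[1], mean_mm = ms[["mean"]],
                 sd_mm = ms[["sd"]], n = nrow(g))
    }))
  rownames(by_camera) <- NULL
  xy <- do.call(rbind, lapply(variants, function(v) {
    g <- tab[tab$variant == v, ]
    wide <- merge(g[g$direction == "y", c(realiz_col, "line", "fwhm_mm")],
                  g[g$direction == "x", c(realiz_col, "line", "fwhm_mm")],
                  by = c(realiz_col, "line"), suffixes = c("_y", "_x"))
    if (nrow(wide) < 2 || any(is.na(wide$fwhm_mm_y))) {
      return(data.frame(variant = v, mean_diff_mm = NA, sd_diff_mm = NA,
                        percent = NA, p = NA, ci_lo = NA, ci_hi = NA,
                        n = nrow(wide)))
    }
    ps <- paired_t_ci(wide$fwhm_mm_y, wide$fwhm_mm_x)
    data.frame(variant = v, mean_diff_mm = ps$mean_diff,
               sd_diff_mm = ps$sd_diff, percent = ps$percent,
               p = ps$p_two_sided, ci_lo = ps$ci[1], ci_hi = ps$ci[2],
               n = nrow(wide))
  }))
  out <- list(overall = overall, by_camera = by_camera, xy_paired = xy)
  if (!is.null(variant_pairs)) {
    vp <- do.call(rbind, lapply(variant_pairs, function(pr) {
      key <- c(realiz_col, "line", "direction")
      w <- merge(tab[tab$variant == pr[1], c(key, "fwhm_mm")],
                 tab[tab$variant == pr[2], c(key, "fwhm_mm")],
                 by = key, suffixes = c("_1", "_2"))
      ps <- paired_t_ci(w$fwhm_mm_1, w$fwhm_mm_2)
      data.frame(variant_1 = pr[1], variant_2 = pr[2],
                 mean_diff_mm = ps$mean_diff, sd_diff_mm = ps$sd_diff,
                 p = ps$p_two_sided, ci_lo = ps$ci[1], ci_hi = ps$ci[2],
                 n = nrow(w))
    }))
    out$variant_paired <- vp
  }
  out
}
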