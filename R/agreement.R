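#' Long-format regional results table
#'
#' One row per (participant, region): the common currency of the
#' agreement machinery. A typical full study pools 20 participants x 7
#' regions = 140 data points per variant.
#'
#' @param id participant ids; `region` region names; `value` VT or SUV;
#'   `variant` a label such as "ppif-90".
#' @param region,value,variant see above.
#' @return data frame of class `roi_table`.
#' @export
roi_table <- function(id, region, value, variant) {
  df <- data.frame(id = as.character(id), region = as.character(region),
                   value = as.numeric(value),
                   variant = as.character(variant))
  if (anyDuplicated(df[, c("id", "region")])) {
    stop("duplicate (participant, region) cells", call. = FALSE)
  }
  if (any(!is.finite(df$value))) stop("non-finite values", call. = FALSE)
  structure(df, class = c("roi_table", "data.frame"))
}

#' Align two variants into paired vectors
#'
#' @param reference,test `roi_table`s covering the same
#'   (participant, region) cells.
#' @return data frame: id, region, x (reference), y (test).
#' @export
pool <- function(reference, test) {
  key_r <- paste(reference$id, reference$region, sep = "\r")
  key_t <- paste(test$id, test$region, sep = "\r")
  miss_t <- setdiff(key_r, key_t)
  miss_r <- setdiff(key_t, key_r)
  if (length(miss_t) || length(miss_r)) {
    stop("variants do not cover the same cells; missing: ",
         paste(gsub("\r", "/", c(miss_t, miss_r)), collapse = ", "),
         call. = FALSE)
  }
  m <- match(key_r, key_t)
  data.frame(id = reference$id, region = reference$region,
             x = reference$value, y = test$value[m])
}

#' Spearman rank correlation with a Fisher-z 95% confidence interval
#'
#' Average ranks on ties; CI via the Fisher z-transform with
#' SE = 1/sqrt(n - 3). A perfect correlation (|rho| = 1) has a
#' degenerate CI equal to rho; a constant vector has undefined rho,
#' reported as NA.
#'
#' @param x,y paired numeric vectors, n >= 4, no missing values.
#' @return list: `rho`, `ci_low`, `ci_high`, `n`.
#' @export
spearman_ci <- function(x, y) {
  n <- length(x)
  if (n < 4L || length(y) != n) stop("need paired vectors, n >= 4", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, ci_low = NA_real_, ci_high = NA_real_, n = n))
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1) {
    return(list(rho = rho, ci_low = rho, ci_high = rho, n = n))
  }
  z <- atanh(rho)
  se <- 1 / sqrt(n - 3)
  list(rho = rho, ci_low = tanh(z - 1.96 * se), ci_high = tanh(z + 1.96 * se),
       n = n)
}

#' Bland-Altman agreement analysis
#'
#' Differences are test minus reference; bias = mean difference; limits
#' of agreement = bias +/- 1.96 sd. Percent differences 100 (y - x)/x
#' are summarised as mean +/- sd; pairs with a zero reference are
#' excluded from the percent summary and counted in `n_pct_excluded`.
#'
#' @param x reference values; `y` test values (paired, n >= 2).
#' @param y see above.
#' @return list: `bias`, `loa_low`, `loa_high`, `sd_diff`,
#'   `mean_pct_diff`, `sd_pct_diff`, `n_pct_excluded`, `pairs` (data
#'   frame with `mean` and `diff` per pair, for plotting).
#' @export
bland_altman <- function(x, y) {
  n <- length(x)
  if (n < 2L || length(y) != n) stop("need paired vectors, n >= 2", call. = FALSE)
  d <- y - x
  bias <- mean(d)
  s <- stats::sd(d)
  ok <- x != 0
  pct <- 100 * d[ok] / x[ok]
  list(bias = bias,
       loa_low = bias - 1.96 * s,
       loa_high = bias + 1.96 * s,
       sd_diff = s,
       mean_pct_diff = if (any(ok)) mean(pct) else NA_real_,
       sd_pct_diff = if (sum(ok) > 1) stats::sd(pct) else NA_real_,
       n_pct_excluded = sum(!ok),
       pairs = data.frame(mean = (x + y) / 2, diff = d))
}

#' Between-subject coefficient of variation
#'
#' 100 x sample SD / mean across participants. Undefined (NA) for a
#' non-positive mean.
#'
#' @param values per-participant values within one region, n >= 2.
#' @return percent, or NA.
#' @export
bs_cv <- function(values) {
  if (length(values) < 2L) stop("need >= 2 participants", call. = FALSE)
  m <- mean(values)
  if (m <= 0) return(NA_real_)
  100 * stats::sd(values) / m
}

#' Per-region between-subject CV of a variant
#'
#' @param tab an `roi_table`.
#' @return data frame: region, bs_cv (percent).
#' @export
bs_cv_table <- function(tab) {
  regs <- unique(tab$region)
  data.frame(region = regs,
             bs_cv = vapply(regs, function(r) bs_cv(tab$value[tab$region == r]),
                            numeric(1)))
}

#' Full agreement report between two quantification variants
#'
#' Pooled Spearman correlation with CI, per-region correlations,
#' Bland-Altman bias and limits, per-region and pooled mean percent
#' differences (relative to the reference), and between-subject CV per
#' variant per region with the difference (test minus reference).
#'
#' @param reference,test aligned `roi_table`s.
#' @return object of class `agreement_report`: list with `pooled_rho`,
#'   `per_roi_rho`, `bland_altman`, `pct_diff` (per-region data frame),
#'   `mean_pct_diff`, `bs_cv` (per-region, both variants and delta),
#'   `variants` (labels), `n_pairs`.
#' @export
compare_variants <- function(reference, test) {
  p <- pool(reference, test)
  regs <- unique(p$region)
  per_roi <- do.call(rbind, lapply(regs, function(r) {
    s <- p[p$region == r, ]
    # per-region rho needs >= 4 participants; reported missing below that
    rho <- if (nrow(s) >= 4L) spearman_ci(s$x, s$y)$rho else NA_real_
    ba <- bland_altman(s$x, s$y)
    data.frame(region = r, rho = rho, mean_pct_diff = ba$mean_pct_diff)
  }))
  cv_r <- bs_cv_table(reference)
  cv_t <- bs_cv_table(test)
  cv <- data.frame(region = cv_r$region,
                   bs_cv_reference = cv_r$bs_cv,
                   bs_cv_test = cv_t$bs_cv[match(cv_r$region, cv_t$region)])
  cv$delta_bs_cv <- cv$bs_cv_test - cv$bs_cv_reference
  structure(list(pooled_rho = spearman_ci(p$x, p$y),
                 per_roi_rho = per_roi[, c("region", "rho")],
                 bland_altman = bland_altman(p$x, p$y),
                 pct_diff = per_roi[, c("region", "mean_pct_diff")],
                 mean_pct_diff = bland_altman(p$x, p$y)$mean_pct_diff,
                 bs_cv = cv,
                 variants = c(reference = reference$variant[1],
                              test = test$variant[1]),
                 n_pairs = nrow(p)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s vs %s (%d pairs)\n",
              x$variants["test"], x$variants["reference"], x$n_pairs))
  cat(sprintf("  pooled rho %.3f (95%% CI %.3f-%.3f)\n",
              x$pooled_rho$rho, x$pooled_rho$ci_low, x$pooled_rho$ci_high))
  cat(sprintf("  bias %.3f, LoA [%.3f, %.3f], mean %% diff %.2f%%\n",
              x$bland_altman$bias, x$bland_altman$loa_low,
              x$bland_altman$loa_high, x$mean_pct_diff))
  cat(sprintf("  mean delta BS-CV %.2f pp\n", mean(x$bs_cv$delta_bs_cv)))
  invisible(x)
}

#' Serialise an agreement report to JSON + CSV
#'
#' @param report an `agreement_report`.
#' @param json_path,csv_path output paths (either may be NULL to skip).
#' @export
write_agreement_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(variants = as.list(report$variants),
           n_pairs = report$n_pairs,
           pooled_rho = report$pooled_rho,
           bias = report$bland_altman$bias,
           loa = c(report$bland_altman$loa_low, report$bland_altman$loa_high),
           mean_pct_diff = report$mean_pct_diff,
           per_roi = report$per_roi_rho,
           bs_cv = report$bs_cv),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(csv_path)) {
    df <- merge(report$per_roi_rho, report$pct_diff, by = "region")
    df <- merge(df, report$bs_cv, by = "region")
    utils::write.csv(df[order(df$region), ], csv_path, row.names = FALSE)
  }
  invisible(report)
}
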