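# ---------------------------------------------------------------------------
# Reporting: per-dataset metric reports, pairwise model improvement
# tables (relative SSIM %, relative RMSE reduction %, absolute PSNR dB),
# positive-fraction summaries and paired t-tests.
# ---------------------------------------------------------------------------

#' Per-image and aggregate metric report
#'
#' @param preds,gts Lists of co-shaped matrices (reconstructions and
#'   ground truths).
#' @param dataset,model Labels carried into the report.
#' @param ssim_par An [ssim_params()] object.
#' @return A `pa_metric_report`: per-image data frame plus aggregate
#'   means.
#' @export
metric_report <- function(preds, gts, dataset = "", model = "",
                          ssim_par = ssim_params()) {
  stopifnot(length(preds) == length(gts), length(preds) >= 1L)
  per <- data.frame(
    item = seq_along(preds),
    ssim = vapply(seq_along(preds), function(i)
      ssim(preds[[i]], gts[[i]], ssim_par), numeric(1)),
    rmse = vapply(seq_along(preds), function(i)
      rmse(preds[[i]], gts[[i]]), numeric(1)),
    psnr = vapply(seq_along(preds), function(i)
      psnr(preds[[i]], gts[[i]]), numeric(1)))
  structure(list(per_image = per,
                 aggregate = c(ssim = mean(per$ssim),
                               rmse = mean(per$rmse),
                               psnr = mean(per$psnr)),
                 dataset = dataset, model = model),
            class = "pa_metric_report")
}

#' @export
print.pa_metric_report <- function(x, ...) {
  cat(sprintf("<pa_metric_report> %s%s n=%d  SSIM %.4f  RMSE %.4f  PSNR %.2f dB\n",
              x$dataset, if (nzchar(x$model)) paste0(" [", x$model, "]")
              else "", nrow(x$per_image), x$aggregate["ssim"],
              x$aggregate["rmse"], x$aggregate["psnr"]))
  invisible(x)
}

#' Pairwise improvement row: model A relative to model B
#'
#' SSIM: relative change `100*(SSIM_a - SSIM_b)/SSIM_b` (%); RMSE:
#' relative reduction `100*(RMSE_b - RMSE_a)/RMSE_b` (%); PSNR: absolute
#' difference in dB. Positive values favour model A throughout.
#'
#' @param report_a,report_b `pa_metric_report`s on the same dataset.
#' @return One-row data frame with `dataset`, `ssim_pct`, `rmse_pct`,
#'   `psnr_db`.
#' @export
improvement_row <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "pa_metric_report"),
            inherits(report_b, "pa_metric_report"))
  if (!identical(report_a$dataset, report_b$dataset))
    stop("reports must describe the same dataset", call. = FALSE)
  a <- report_a$aggregate; b <- report_b$aggregate
  if (b["ssim"] == 0 || b["rmse"] == 0)
    stop("zero reference SSIM/RMSE: relative improvement undefined",
         call. = FALSE)
  data.frame(dataset = report_a$dataset,
             ssim_pct = 100 * (a["ssim"] - b["ssim"]) / b["ssim"],
             rmse_pct = 100 * (b["rmse"] - a["rmse"]) / b["rmse"],
             psnr_db = a["psnr"] - b["psnr"], row.names = NULL)
}

improvement_columns <- c("ssim_pct", "rmse_pct", "psnr_db")

#' Column means of an improvement table
#'
#' Arithmetic means of the improvement columns, reported at 2 decimals
#' (the "Average Improvement" row of a comparison panel).
#'
#' @param table Data frame with columns `ssim_pct`, `rmse_pct`,
#'   `psnr_db`.
#' @export
aggregate_mean <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L,
            all(improvement_columns %in% names(table)))
  round(colMeans(table[improvement_columns]), 2)
}

#' Truncated percentage of positive entries in a column
#'
#' `floor(100 * count(value > 0) / n)` -- the "outperformed in X% of
#' cases" summary.
#'
#' @param table Data frame.
#' @param column Column name.
#' @export
fraction_positive <- function(table, column = "ssim_pct") {
  v <- table[[column]]
  if (is.null(v) || length(v) == 0L)
    stop("empty or missing column", call. = FALSE)
  as.integer(floor(100 * sum(v > 0) / length(v)))
}

#' Paired two-sided t-test on matched score vectors
#'
#' @param scores_a,scores_b Equal-length numeric vectors (n >= 2) of
#'   paired scores.
#' @return A `pa_ttest`: `t`, `p`, `n`, `df`, `two_sided`.
#' @export
paired_ttest <- function(scores_a, scores_b) {
  stopifnot(is.numeric(scores_a), is.numeric(scores_b))
  if (length(scores_a) != length(scores_b) || length(scores_a) < 2L)
    stop("need two equal-length score vectors with n >= 2", call. = FALSE)
  d <- scores_a - scores_b
  if (stats::sd(d) == 0)
    stop("degenerate paired t-test: zero-variance differences",
         call. = FALSE)
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  structure(list(t = unname(tt$statistic), p = tt$p.value,
                 n = length(d), df = unname(tt$parameter),
                 two_sided = TRUE),
            class = "pa_ttest")
}

#' @export
print.pa_ttest <- function(x, ...) {
  cat(sprintf("Paired t-test: t = %.4f, p = %.4f (n = %d, df = %d)\n",
              x$t, x$p, x$n, x$df))
  invisible(x)
}

#' Bundled published improvement table
#'
#' Per-dataset improvement percentages for the three pairwise model
#' comparisons (generalized network vs generalized U-net, specific vs
#' specific, generalized vs specific U-net) shipped with the package; the
#' raw material for panel averages and positive-fraction summaries.
#'
#' @return Data frame with `comparison`, `dataset`, `ssim_pct`,
#'   `rmse_pct`, `psnr_db`.
#' @export
published_improvements <- function() {
  utils::read.csv(system.file("extdata", "improvement_table.csv",
                              package = "paomninet"),
                  comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a report to disk (CSV + JSON + markdown)
#'
#' @param tables Named list of improvement-table data frames.
#' @param ttests Named list of `pa_ttest` objects (may be empty).
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(tables, ttests = list(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stopifnot(is.list(tables))
  all_tab <- if (length(tables))
    do.call(rbind, lapply(names(tables), function(nm)
      cbind(data.frame(comparison = nm), tables[[nm]])))
  else data.frame(comparison = character(0), dataset = character(0),
                  ssim_pct = numeric(0), rmse_pct = numeric(0),
                  psnr_db = numeric(0))
  csv <- file.path(out_dir, "improvements.csv")
  utils::write.csv(all_tab, csv, row.names = FALSE)
  js <- file.path(out_dir, "report.json")
  payload <- list(
    tables = lapply(tables, function(t)
      list(rows = t, average = as.list(aggregate_mean(t)))),
    ttests = lapply(ttests, function(tt)
      list(t = tt$t, p = tt$p, n = tt$n, df = tt$df)))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows", pretty = TRUE), js)
  md <- file.path(out_dir, "summary.md")
  lines <- c("# Model comparison report", "")
  for (nm in names(tables)) {
    av <- aggregate_mean(tables[[nm]])
    lines <- c(lines, sprintf("## %s", nm),
               sprintf("Average improvement: SSIM %+.2f%%, RMSE %+.2f%%, PSNR %+.2f dB",
                       av["ssim_pct"], av["rmse_pct"], av["psnr_db"]), "")
  }
  for (nm in names(ttests))
    lines <- c(lines, sprintf("- %s: t = %.4f, p = %.4f", nm,
                              ttests[[nm]]$t, ttests[[nm]]$p))
  writeLines(lines, md)
  invisible(c(csv, js, md))
}
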