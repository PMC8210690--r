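## Repeatability and workflow-comparison statistics: per-dataset mean / SD /
## relative SD (CV), their aggregation across datasets, and the two-sample
## Kolmogorov-Smirnov comparison of the two workflows' result vectors.

#' Summarize repeated snGFR measurements of one dataset
#'
#' Sample statistics of a replicate set: mean, sample SD (n-1 denominator),
#' and relative SD (coefficient of variation) `100 * sd / mean` in percent.
#'
#' @param values numeric vector of >= 2 repeated measurements (nl/min).
#' @return named vector `c(mean, sd, relative_sd_percent)`;
#'   `relative_sd_percent` is `NA` when the mean is zero.
#' @export
summarize_dataset <- function(values) {
  if (length(values) < 2L || !all(is.finite(values)))
    stop("need >= 2 finite replicate values", call. = FALSE)
  m <- mean(values)
  s <- sd(values)
  c(mean = m, sd = s,
    relative_sd_percent = if (m == 0) NA_real_ else 100 * s / m)
}

#' Aggregate per-dataset CVs into the workflow's mean CV
#'
#' The repeatability figure of merit: the unweighted mean of the
#' per-dataset relative SDs (CVs, percent).
#'
#' @param relative_sds numeric vector of per-dataset relative SDs (percent),
#'   or a long-format replicate `data.frame` (see [read_repeat_table()])
#'   from which they are computed.
#' @param workflow when a `data.frame` is given, which workflow to
#'   aggregate.
#' @return mean CV in percent.
#' @export
aggregate_cv <- function(relative_sds, workflow = NULL) {
  if (is.data.frame(relative_sds)) {
    sub <- repeat_table_summary(relative_sds, workflow)
    relative_sds <- sub$relative_sd_percent
  }
  if (length(relative_sds) < 1L)
    stop("need at least one dataset", call. = FALSE)
  mean(relative_sds)
}

#' Workflow-level snGFR summary
#'
#' Mean and sample SD over the per-dataset mean snGFRs: the "mean +/- SD"
#' figure reported per workflow.
#'
#' @param means numeric vector of per-dataset mean snGFRs (nl/min), or a
#'   long-format replicate `data.frame`.
#' @param workflow when a `data.frame` is given, which workflow to
#'   summarize.
#' @return named vector `c(mean, sd)`.
#' @export
workflow_summary <- function(means, workflow = NULL) {
  if (is.data.frame(means)) {
    sub <- repeat_table_summary(means, workflow)
    means <- sub$mean
  }
  if (length(means) < 2L)
    stop("need at least two datasets", call. = FALSE)
  c(mean = mean(means), sd = sd(means))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|` with the p-value from [stats::ks.test()]
#' (exact small-sample computation when `n * m < 10^4` and the data are
#' tie-free, asymptotic otherwise; the method used is reported).
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return list with `statistic` (D), `p_value`, and `method`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples need >= 2 values", call. = FALSE)
  kt <- suppressWarnings(ks.test(x, y))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       method = if (length(x) * length(y) < 1e4 &&
                    !anyDuplicated(c(x, y))) "exact" else "asymptotic")
}

## -- replicate tables ------------------------------------------------------

#' Read / summarize a long-format replicate table
#'
#' The replicate CSV has columns `dataset_id, workflow, replicate,
#' sngfr_nl_min` — one row per repeated analysis of one dataset with one
#' workflow. `repeat_table_summary()` reduces it to one row per dataset
#' (mean, SD, relative SD), optionally restricted to one workflow.
#'
#' @param path CSV path.
#' @return `read_repeat_table()`: the long `data.frame`;
#'   `repeat_table_summary()`: a per-dataset summary `data.frame`.
#' @export
read_repeat_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("dataset_id", "workflow", "replicate", "sngfr_nl_min")
  if (!all(need %in% names(df)))
    stop("replicate table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_repeat_table
#' @param table a long-format replicate `data.frame`.
#' @param workflow optional workflow name to filter on.
#' @export
repeat_table_summary <- function(table, workflow = NULL) {
  if (!is.null(workflow)) table <- table[table$workflow == workflow, ]
  if (!nrow(table)) stop("no rows for the requested workflow", call. = FALSE)
  ids <- unique(table$dataset_id)
  rows <- lapply(ids, function(id) {
    s <- summarize_dataset(table$sngfr_nl_min[table$dataset_id == id])
    data.frame(dataset_id = id, mean = s[["mean"]], sd = s[["sd"]],
               relative_sd_percent = s[["relative_sd_percent"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Published repeatability summary of the two workflows
#'
#' The per-dataset repeatability summary (15 glomeruli from five healthy
#' mice, each analysed five times with each workflow by the same
#' researcher): per dataset and workflow, the mean snGFR, sample SD, and
#' relative SD in percent. Bundled with the package as
#' `extdata/repeatability_summary.csv`.
#'
#' @return `data.frame` with columns `dataset_id, workflow, mean, sd,
#'   relative_sd_percent`.
#' @export
published_repeatability <- function() {
  path <- system.file("extdata", "repeatability_summary.csv",
                      package = "sngfr", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
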