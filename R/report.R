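# Cohort evaluation: per-image metric records and aggregate tables with
# enhancement percentages and paired significance versus a baseline.

metricDirections <- c(mae = "lower-better", psnr = "higher-better",
                      nqm = "higher-better", mssim = "higher-better")

computeOneMetric <- function(metric, ref, test, peak, mssimLevels) {
  switch(metric,
         mae = imageMAE(ref, test),
         psnr = imagePSNR(ref, test, peak = peak),
         nqm = imageNQM(ref, test),
         mssim = imageMSSIM(ref, test, peak = peak, levels = mssimLevels),
         stop(sprintf("unknown metric '%s'", metric)))
}

#' Evaluate methods against reference images
#'
#' Computes the requested full-reference metrics for every (image,
#' method) pair.
#'
#' @param refs list of reference images (ground truth).
#' @param methods named list; each element is a list of images aligned
#'   with \code{refs} (e.g. \code{list(bicubic = ..., ddpm = ...)}).
#' @param ids image identifiers (default \code{img-01} style).
#' @param metrics subset of \code{c("mae", "psnr", "nqm", "mssim")}.
#' @param peak metric dynamic range (default 255).
#' @param mssimLevels MS-SSIM pyramid depth (reduce for small images).
#' @return data.frame: id, method, one column per metric.
#' @export
evaluatePairs <- function(refs, methods,
                          ids = sprintf("img-%02d", seq_along(refs)),
                          metrics = c("mae", "psnr", "nqm", "mssim"),
                          peak = 255, mssimLevels = 5L) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  stopifnot(is.list(methods), length(names(methods)) == length(methods))
  rows <- list()
  for (mname in names(methods)) {
    imgs <- methods[[mname]]
    stopifnot(length(imgs) == length(refs))
    for (i in seq_along(refs)) {
      vals <- vapply(metrics, computeOneMetric, numeric(1),
                     ref = refs[[i]], test = imgs[[i]], peak = peak,
                     mssimLevels = mssimLevels)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(id = ids[i], method = mname,
                         stringsAsFactors = FALSE),
              as.data.frame(as.list(vals)))
    }
  }
  do.call(rbind, rows)
}

#' Aggregate a per-image metric table
#'
#' Builds the cohort summary: mean and SD per (method, metric),
#' enhancement percentage relative to a named baseline method, and a
#' paired two-sided Wilcoxon signed-rank p-value versus the baseline.
#' Enhancement supports two conventions: \code{"aggregate"} compares the
#' cohort means, \code{"per-image"} averages the per-image percentages
#' (the two differ slightly; both are reported in the field).
#'
#' @param perImage data.frame from \code{\link{evaluatePairs}}.
#' @param baseline method name the enhancement and p-values refer to,
#'   or \code{NULL} for plain summaries.
#' @param enhancementMode \code{"aggregate"} or \code{"per-image"}.
#' @return A \code{\linkS4class{MetricReport}}.
#' @export
summarizeMetrics <- function(perImage, baseline = NULL,
                             enhancementMode = c("aggregate", "per-image")) {
  enhancementMode <- match.arg(enhancementMode)
  metrics <- setdiff(names(perImage), c("id", "method"))
  methodNames <- unique(perImage$method)
  if (!is.null(baseline) && !baseline %in% methodNames)
    stop(sprintf("baseline '%s' not among methods", baseline))
  rows <- list()
  for (mname in methodNames) {
    sub <- perImage[perImage$method == mname, , drop = FALSE]
    sub <- sub[order(sub$id), , drop = FALSE]
    for (met in metrics) {
      v <- sub[[met]]
      row <- data.frame(method = mname, metric = met,
                        mean = mean(v), sd = stats::sd(v),
                        enhancementPct = NA_real_, pValue = NA_real_,
                        stringsAsFactors = FALSE)
      if (!is.null(baseline) && mname != baseline) {
        bsub <- perImage[perImage$method == baseline, , drop = FALSE]
        bsub <- bsub[order(bsub$id), , drop = FALSE]
        b <- bsub[[met]]
        dir <- metricDirections[[met]]
        row$enhancementPct <- if (enhancementMode == "aggregate")
          enhancementPct(mean(b), mean(v), dir)
        else mean(enhancementPct(b, v, dir))
        row$pValue <- pairedCompare(v, b)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  new("MetricReport", perImage = perImage,
      aggregate = do.call(rbind, rows),
      baseline = if (is.null(baseline)) "" else baseline)
}

#' @rdname MetricReport-class
#' @param x a \code{MetricReport}.
#' @export
perImageMetrics <- function(x) { stopifnot(is(x, "MetricReport")); x@perImage }

#' @rdname MetricReport-class
#' @export
aggregateMetrics <- function(x) { stopifnot(is(x, "MetricReport")); x@aggregate }

#' Write a metric report as CSV
#'
#' Two blocks: the per-image records (\code{id, method, metric, value})
#' followed by the aggregate table.
#'
#' @param report a \code{\linkS4class{MetricReport}}.
#' @param path output file.
#' @export
writeMetricReport <- function(report, path) {
  per <- report@perImage
  metrics <- setdiff(names(per), c("id", "method"))
  long <- do.call(rbind, lapply(metrics, function(met)
    data.frame(id = per$id, method = per$method, metric = met,
               value = per[[met]], stringsAsFactors = FALSE)))
  utils::write.csv(long, path, row.names = FALSE)
  aggPath <- sub("\\.csv$", "_aggregate.csv", path)
  if (identical(aggPath, path)) aggPath <- paste0(path, ".aggregate")
  utils::write.csv(report@aggregate, aggPath, row.names = FALSE)
  invisible(c(path, aggPath))
}
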