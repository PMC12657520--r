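#' Unpaired two-tailed Student t test
#'
#' Pooled-variance (equal-variance) two-sample t test, the group comparison
#' used throughout the screen; a Welch option is provided.
#'
#' @param a,b numeric samples (each of length >= 2)
#' @param welch use the Welch (unequal-variance) form instead
#' @return list with \code{t}, \code{df} and two-tailed \code{p}.
#' @examples
#' studentTTest(1:5, 3:7)  # t = -2, df = 8
#' @export
studentTTest <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values")
  if (!welch) {
    pooled <- ((length(a) - 1) * stats::var(a) +
               (length(b) - 1) * stats::var(b)) /
              (length(a) + length(b) - 2)
    if (pooled <= 0) stop("zero pooled variance")
  } else if (stats::var(a) + stats::var(b) <= 0) {
    stop("zero variance")
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Tukey box-and-whisker summary
#'
#' Quartiles use the linear-interpolation convention (R \code{quantile}
#' type 7, the single percentile convention of the package).  Whiskers
#' extend to the smallest and largest data values within 1.5 times the IQR
#' of the quartiles; values outside those fences are listed as outliers.
#'
#' @param values numeric vector; with fewer than 4 values the whiskers are
#'   \code{NA} and \code{flagged} is TRUE.
#' @return list with \code{q1}, \code{median}, \code{q3}, \code{iqr},
#'   \code{whisker_low}, \code{whisker_high}, \code{outliers},
#'   \code{flagged}.
#' @examples
#' boxSummary(c(1, 2, 3, 4, 100))  # whisker_high 4, outlier 100
#' @export
boxSummary <- function(values) {
  stopifnot(length(values) >= 1L, all(is.finite(values)))
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3L] - q[1L]
  lowFence <- q[1L] - 1.5 * iqr
  highFence <- q[3L] + 1.5 * iqr
  inside <- values >= lowFence & values <= highFence
  out <- list(q1 = q[1L], median = q[2L], q3 = q[3L], iqr = iqr,
              whisker_low = NA_real_, whisker_high = NA_real_,
              outliers = sort(values[!inside]), flagged = length(values) < 4L)
  if (!out$flagged) {
    out$whisker_low <- min(values[inside])
    out$whisker_high <- max(values[inside])
  }
  out
}

#' Significance star category
#'
#' \code{***} for p < 0.001, \code{**} for p < 0.01, \code{*} for p < 0.05
#' (all strict), \code{ns} otherwise.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return character vector of categories.
#' @export
starCategory <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p must lie in [0, 1]")
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "ns")))
}

#' Build the screening report
#'
#' Compares every condition to the reference condition (default the loaded,
#' untreated group) for each metric: group mean, box summary, pooled
#' Student t statistic, two-tailed p, significance stars, and the direction
#' of the change.  Mirroring the screen's published statistics there is no
#' multiple-testing correction across conditions, but a Benjamini-Hochberg
#' adjusted column (\code{p_bh}) is printed alongside for transparency.
#' Conditions with fewer than 2 replicates are excluded from testing (with
#' a message).
#'
#' @param table long-format data.frame with columns \code{condition},
#'   \code{replicate}, \code{metric}, \code{value}
#' @param reference reference condition label
#' @param welch use Welch instead of pooled t tests
#' @return data.frame, one row per condition x metric, with columns
#'   \code{metric}, \code{condition}, \code{n}, \code{mean}, \code{q1},
#'   \code{median}, \code{q3}, \code{whisker_low}, \code{whisker_high},
#'   \code{n_outliers}, \code{t}, \code{df}, \code{p}, \code{p_bh},
#'   \code{stars}, \code{direction}.
#' @export
buildScreenReport <- function(table, reference, welch = FALSE) {
  need <- c("condition", "replicate", "metric", "value")
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  if (!reference %in% table$condition)
    stop("reference condition '", reference, "' not present")
  rows <- list()
  for (metric in unique(table$metric)) {
    sub <- table[table$metric == metric, , drop = FALSE]
    ref <- sub$value[sub$condition == reference]
    for (cond in unique(sub$condition)) {
      vals <- sub$value[sub$condition == cond]
      if (length(vals) < 2L) {
        message("buildScreenReport: condition '", cond, "' has n < 2 for ",
                metric, "; excluded from testing")
        next
      }
      bx <- boxSummary(vals)
      if (cond == reference) {
        tt <- list(t = 0, df = 2 * length(ref) - 2, p = 1)
      } else {
        tt <- tryCatch(studentTTest(vals, ref, welch = welch),
                       error = function(e) list(t = NA_real_, df = NA_real_,
                                                p = NA_real_))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, condition = cond, n = length(vals),
        mean = mean(vals), q1 = bx$q1, median = bx$median, q3 = bx$q3,
        whisker_low = bx$whisker_low, whisker_high = bx$whisker_high,
        n_outliers = length(bx$outliers),
        t = tt$t, df = tt$df, p = tt$p,
        direction = sign(mean(vals) - mean(ref)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable condition")
  nonref <- out$condition != reference & !is.na(out$p)
  out$p_bh <- NA_real_
  out$p_bh[nonref] <- stats::p.adjust(out$p[nonref], method = "BH")
  out$stars <- ifelse(is.na(out$p), NA_character_, starCategory(pmin(out$p, 1)))
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  attr(out, "multiple_testing") <-
    "uncorrected per-condition t tests (BH column p_bh added for transparency)"
  out
}
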