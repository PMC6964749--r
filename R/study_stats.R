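# Paired-cohort statistics: normality-based test selection, paired
# comparisons, replicate averaging, inter-delivery variation, and
# complexity-GPR correlation, mirroring a standard plan-QA study layout.

#' A paired sample of two plan arms
#'
#' @param labels Plan identifiers.
#' @param a,b Metric values of arms A and B, same length and order.
#' @return Object of class `paired_sample`.
#' @export
paired_sample <- function(labels, a, b) {
  if (length(a) != length(b) || length(a) != length(labels))
    stop("arms and labels must have equal length")
  if (length(a) < 3) stop("paired sample needs n >= 3")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("paired sample values must be finite")
  structure(list(labels = labels, a = as.numeric(a), b = as.numeric(b)),
            class = "paired_sample")
}

#' Choose the paired test from the distribution of differences
#'
#' Shapiro-Wilk on the paired differences at `alpha`: a paired t-test when
#' normality is not rejected, a two-sided Wilcoxon signed-rank test
#' otherwise. Constant differences are degenerate and flagged.
#'
#' @param differences Numeric vector of paired differences.
#' @param alpha Normality significance level (default 0.05).
#' @return `"t_test"`, `"wilcoxon"`, or `"degenerate"` when the differences
#'   have zero variance.
#' @export
choose_paired_test <- function(differences, alpha = 0.05) {
  if (stats::sd(differences) == 0) return("degenerate")
  p <- stats::shapiro.test(differences)$p.value
  if (p >= alpha) "t_test" else "wilcoxon"
}

#' Two-sided paired comparison of two arms
#'
#' Runs the requested paired test on arm differences. The Wilcoxon
#' signed-rank test drops zero differences (the original treatment of
#' ties to zero) and uses the exact null distribution when `n <= 25` with
#' no tied absolute differences, falling back to the normal approximation
#' with continuity correction otherwise.
#'
#' @param sample A [paired_sample()].
#' @param test `"t_test"`, `"wilcoxon"`, or `"auto"` (choose via
#'   [choose_paired_test()]).
#' @param alpha Significance level used by `"auto"` and for the
#'   `significant` flag.
#' @return List with `test`, `statistic`, `p`, `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`, `significant`.
#' @export
paired_compare <- function(sample, test = c("auto", "t_test", "wilcoxon"),
                           alpha = 0.05) {
  test <- match.arg(test)
  d <- sample$b - sample$a
  if (stats::sd(d) == 0) {
    # zero-variance differences break both tests' machinery: identical
    # arms are a non-effect (p = 1); a constant nonzero shift still has
    # well-defined signs, so fall through to the Wilcoxon sign path
    if (all(d == 0))
      return(list(test = "degenerate", statistic = NA_real_, p = 1,
                  mean_a = mean(sample$a), sd_a = stats::sd(sample$a),
                  mean_b = mean(sample$b), sd_b = stats::sd(sample$b),
                  significant = FALSE))
    test <- "wilcoxon"
  } else if (test == "auto") {
    test <- choose_paired_test(d, alpha)
  }
  if (test == "t_test") {
    ht <- stats::t.test(sample$b, sample$a, paired = TRUE)
    stat <- unname(ht$statistic); p <- ht$p.value
  } else {
    dz <- d[d != 0]
    if (!length(dz)) {
      stat <- NA_real_; p <- 1
    } else {
      exact <- length(dz) <= 25 && !any(duplicated(abs(dz)))
      ht <- suppressWarnings(stats::wilcox.test(dz, exact = exact,
                                                correct = TRUE))
      stat <- unname(ht$statistic); p <- ht$p.value
    }
  }
  list(test = test, statistic = stat, p = p,
       mean_a = mean(sample$a), sd_a = stats::sd(sample$a),
       mean_b = mean(sample$b), sd_b = stats::sd(sample$b),
       significant = p < alpha)
}

#' Average gamma passing rates over replicate deliveries
#'
#' @param gprs Numeric vector of per-delivery passing rates for one plan.
#' @return List with `mean` and `sd` (`NA` with a flag for a single
#'   replicate).
#' @export
average_replicates <- function(gprs) {
  if (!length(gprs)) stop("no replicates")
  list(mean = mean(gprs),
       sd = if (length(gprs) > 1) stats::sd(gprs) else NA_real_,
       sd_undefined = length(gprs) < 2)
}

#' Compare inter-delivery variation between arms
#'
#' Paired comparison (test chosen from the differences) of the per-plan
#' replicate standard deviations of the two arms.
#'
#' @param sd_a,sd_b Per-plan replicate SDs of arms A and B.
#' @param alpha Significance level.
#' @return As [paired_compare()].
#' @export
interdelivery_variation_compare <- function(sd_a, sd_b, alpha = 0.05) {
  s <- paired_sample(seq_along(sd_a), sd_a, sd_b)
  paired_compare(s, "auto", alpha)
}

#' Pearson correlation between a complexity metric and passing rates
#'
#' @param metric Numeric vector (e.g. MU or MCS per plan).
#' @param gpr Numeric vector of passing rates, same order.
#' @return List with `r`, `p`, `n`; `r = NA` flagged `undefined` when
#'   either vector is constant.
#' @export
correlate <- function(metric, gpr) {
  if (length(metric) != length(gpr)) stop("vectors differ in length")
  if (stats::sd(metric) == 0 || stats::sd(gpr) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(metric),
                undefined = TRUE))
  ct <- stats::cor.test(metric, gpr, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(metric),
       undefined = FALSE)
}

## ---- cohort-level report ----

#' Per-plan QA table for a synthetic cohort
#'
#' Computes the four complexity metrics for every plan and, when gamma
#' presets are given, the replicate-averaged gamma passing rate (and
#' replicate SD) of measured-vs-computed planes at each preset.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param presets Named list of [gamma_criteria()] (default
#'   [tg218_presets()]); `NULL` skips gamma analysis.
#' @return Data frame, one row per (patient, arm).
#' @export
cohort_qa_table <- function(cohort, presets = tg218_presets()) {
  rows <- list()
  for (p in cohort$patients) {
    for (arm in names(p$plans)) {
      cr <- complexity_report(p$plans[[arm]])
      row <- data.frame(patient_id = p$patient_id, arm = arm,
                        modulation = p$modulation[[arm]],
                        mu = cr$mu, mu_per_gy = cr$mu_per_gy, mcs = cr$mcs,
                        em = cr$em, lm = cr$lm, stringsAsFactors = FALSE)
      if (!is.null(presets)) {
        for (nm in names(presets)) {
          gprs <- vapply(p$measured[[arm]], function(meas)
            compute_gamma_map(meas, p$planes[[arm]],
                              presets[[nm]])$passing_rate, numeric(1))
          avg <- average_replicates(gprs)
          key <- gsub("[^0-9a-z]+", "_", tolower(nm))
          row[[paste0("gpr_", key)]] <- avg$mean
          row[[paste0("gpr_sd_", key)]] <- avg$sd
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Build the cohort comparison report
#'
#' For every metric column, compares the two arms with a paired test chosen
#' from the differences, and correlates each complexity metric with each
#' passing-rate column over all plans (both arms pooled by default).
#'
#' @param qa_table Result of [cohort_qa_table()].
#' @param arm_a,arm_b Arm labels (defaults `"reference"`, `"kbp"`).
#' @param alpha Significance level (default 0.05).
#' @param correlation_arms `"pooled"` (default) or one arm label.
#' @return Object of class `cohort_report`: `comparisons` (data frame:
#'   metric, means, SDs, test, p, significant), `correlations` (data
#'   frame: metric, gpr column, r, p), `alpha`.
#' @export
build_report <- function(qa_table, arm_a = "reference", arm_b = "kbp",
                         alpha = 0.05, correlation_arms = "pooled") {
  ta <- qa_table[qa_table$arm == arm_a, ]
  tb <- qa_table[qa_table$arm == arm_b, ]
  ta <- ta[order(ta$patient_id), ]; tb <- tb[order(tb$patient_id), ]
  if (!identical(ta$patient_id, tb$patient_id))
    stop("arms do not cover the same patients")
  metric_cols <- setdiff(names(qa_table)[vapply(qa_table, is.numeric, logical(1))],
                         "modulation")
  metric_cols <- metric_cols[!grepl("^gpr_sd_", metric_cols)]
  comparisons <- do.call(rbind, lapply(metric_cols, function(mc) {
    pc <- paired_compare(paired_sample(ta$patient_id, ta[[mc]], tb[[mc]]),
                         "auto", alpha)
    data.frame(metric = mc, mean_a = pc$mean_a, sd_a = pc$sd_a,
               mean_b = pc$mean_b, sd_b = pc$sd_b, test = pc$test,
               p = pc$p, significant = pc$significant,
               stringsAsFactors = FALSE)
  }))
  cx <- c("mu", "mcs", "em", "lm")
  gpr_cols <- grep("^gpr_", metric_cols, value = TRUE)
  pool <- if (identical(correlation_arms, "pooled")) qa_table
          else qa_table[qa_table$arm == correlation_arms, ]
  correlations <- NULL
  if (length(gpr_cols))
    correlations <- do.call(rbind, lapply(cx, function(m)
      do.call(rbind, lapply(gpr_cols, function(g) {
        ct <- correlate(pool[[m]], pool[[g]])
        data.frame(metric = m, gpr = g, r = ct$r, p = ct$p,
                   stringsAsFactors = FALSE)
      }))))
  structure(list(comparisons = comparisons, correlations = correlations,
                 alpha = alpha),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report> paired comparisons (B vs A):\n")
  df <- x$comparisons
  df$flag <- ifelse(df$significant, "*", "")
  print(df[, c("metric", "mean_a", "sd_a", "mean_b", "sd_b", "test", "p", "flag")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a cohort report to CSV (comparisons) and JSON (everything)
#'
#' @param report A `cohort_report`.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return Invisibly, the report.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$comparisons, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(comparisons = report$comparisons,
                              correlations = report$correlations,
                              alpha = report$alpha),
                         json_path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  invisible(report)
}
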