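# Group comparison (Wilcoxon rank-sum) and ROC / Youden cutoff analysis.

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum comparison of two independent
#' samples, with mid-ranks for ties. The exact null distribution (full
#' enumeration) is used when the pooled sample size is at most
#' `exact_max_n` and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y numeric samples (both non-empty, pooled size >= 2).
#' @param exact_max_n largest pooled size for the exact test (default 12).
#' @return List: `U` (Mann-Whitney statistic for `x`), `p` (two-sided),
#'   `exact` (logical).
#' @export
wilcoxon_ranksum <- function(x, y, exact_max_n = 12) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(x) + length(y) < 2) stop("need at least 2 observations")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= exact_max_n) && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' ROC curve analysis with the Youden-index cutoff
#'
#' Computes the area under the ROC curve via the Mann-Whitney identity
#' (ties count one half) for discriminating the positive class, and scans
#' every candidate cutoff (midpoints between sorted unique scores plus
#' the two infinities) in both directions (`>=` and `<=` predicting
#' positive) for the maximal Youden index J = sensitivity + specificity -
#' 1. Ties in J are broken toward the higher-sensitivity operating point.
#'
#' @param scores numeric per-case scores.
#' @param labels vector of class labels.
#' @param positive the label treated as positive (default `"non-OR"`,
#'   the convention of reporting sensitivity for predicting
#'   non-response).
#' @return An `roc_result` list: `auc`, `cutoff`, `direction` (`">="` or
#'   `"<="`), `sensitivity`, `specificity`, `youden_j`.
#' @export
roc_youden <- function(scores, labels, positive = "non-OR") {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  np <- sum(pos); nn <- sum(!pos)
  # AUC via rank statistic: P(score_pos > score_neg) + 0.5 P(equal)
  r <- rank(scores)
  auc_ge <- (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
  su <- sort(unique(scores))
  cuts <- c(-Inf, if (length(su) > 1) (head(su, -1) + tail(su, -1)) / 2, Inf)
  best <- NULL
  for (dir in c(">=", "<=")) {
    for (ct in cuts) {
      pred <- if (dir == ">=") scores >= ct else scores <= ct
      sens <- sum(pred & pos) / np
      spec <- sum(!pred & !pos) / nn
      j <- sens + spec - 1
      if (is.null(best) || j > best$youden_j + 1e-12 ||
          (abs(j - best$youden_j) <= 1e-12 && sens > best$sensitivity + 1e-12)) {
        best <- list(cutoff = ct, direction = dir, sensitivity = sens,
                     specificity = spec, youden_j = j)
      }
    }
  }
  structure(c(list(auc = auc_ge), best), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f; cutoff %s %.4g -> sens %.2f, spec %.2f (J %.2f)\n",
              x$auc, x$direction, x$cutoff, x$sensitivity, x$specificity,
              x$youden_j))
  invisible(x)
}

feature_names <- function() c("ifp_mean_kpa", "ifp_sd_kpa", "ifp_skew",
                              "ifp_kurt", "ifv_mean_mps", "ifv_sd_mps",
                              "ifv_skew", "ifv_kurt")

#' Compare feature distributions between response groups
#'
#' For each of the eight histogram features at each timepoint set (pre,
#' post, delta), runs the two-sided Wilcoxon rank-sum test between OR and
#' non-OR lesions and, for rows significant at `alpha`, an ROC/Youden
#' cutoff analysis with non-OR as the positive class. Optionally applies
#' Benjamini-Hochberg correction across the 24 rows.
#'
#' @param cohort data.frame with columns `lesion_id`, `group` (values
#'   `"OR"`/`"non-OR"`), and `<set>_<feature>` columns for sets `pre`,
#'   `post`, `delta` and the eight feature names (see the feature-table
#'   writers).
#' @param alpha significance level for flagging (default 0.05).
#' @param adjust if `TRUE`, Benjamini-Hochberg-adjust the p-values and
#'   flag on the adjusted values.
#' @return data.frame with one row per feature x set: group means, `p`,
#'   `significant`, and ROC columns (`auc`, `cutoff`, `direction`,
#'   `sensitivity`, `specificity`; `NA` for non-significant rows).
#' @export
group_comparison <- function(cohort, alpha = 0.05, adjust = FALSE) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  sets <- c("pre", "post", "delta")
  needed <- as.vector(outer(sets, feature_names(), paste, sep = "_"))
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols))
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "))
  g_or <- cohort$group == "OR"
  g_non <- cohort$group == "non-OR"
  if (!any(g_or) || !any(g_non)) stop("both response groups required")
  rows <- list()
  for (set in sets) for (feat in feature_names()) {
    col <- paste(set, feat, sep = "_")
    v <- cohort[[col]]
    ok <- is.finite(v)
    x <- v[ok & g_non]; y <- v[ok & g_or]
    wt <- wilcoxon_ranksum(x, y)
    rows[[col]] <- data.frame(set = set, feature = feat,
                              mean_non_or = mean(x), mean_or = mean(y),
                              p = wt$p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$p_adj <- stats::p.adjust(res$p, "BH")
  res$significant <- (if (adjust) res$p_adj else res$p) < alpha
  res$auc <- res$cutoff <- res$sensitivity <- res$specificity <- NA_real_
  res$direction <- NA_character_
  for (i in which(res$significant)) {
    col <- paste(res$set[i], res$feature[i], sep = "_")
    v <- cohort[[col]]
    ok <- is.finite(v)
    rc <- roc_youden(v[ok], cohort$group[ok], positive = "non-OR")
    res$auc[i] <- rc$auc; res$cutoff[i] <- rc$cutoff
    res$direction[i] <- rc$direction
    res$sensitivity[i] <- rc$sensitivity; res$specificity[i] <- rc$specificity
  }
  res
}
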