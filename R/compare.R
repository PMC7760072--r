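#' Compare two model versions with t-tests per quantity and marker
#'
#' For each robustness quantity (PM, WP, PM/TI, %WP) and each marker, tests
#' whether the two track-model versions differ across videos. The test is
#' paired by `video_id` by default — the same videos are scored under both
#' versions; an unpaired two-sample option is exposed. Zero variance of the
#' paired differences (or of both groups) is reported as a degenerate case
#' rather than a spurious p-value, except for the all-identical case which
#' is reported as t = 0, p = 1.
#'
#' @param v_a,v_b data.frames from [per_video_metrics()] for the two
#'   versions (same video_id set).
#' @param quantities Metric columns to compare.
#' @param paired Use a paired test (default `TRUE`).
#' @param alpha Significance level for the `significant` flag (default 0.05,
#'   no multiple-testing correction).
#' @return data.frame `quantity, marker, n, t, df, p_value, significant,
#'   degenerate`.
#' @export
compare_versions <- function(v_a, v_b,
                             quantities = c("PM", "WP", "pm_ti", "pct_wp"),
                             paired = TRUE, alpha = 0.05) {
  out <- list()
  for (m in sort(unique(v_a$marker))) {
    a <- v_a[v_a$marker == m, ]
    b <- v_b[v_b$marker == m, ]
    unmatched <- c(setdiff(a$video_id, b$video_id), setdiff(b$video_id, a$video_id))
    if (length(unmatched)) {
      stop_st("unmatched videos between versions: %s",
              paste(unique(unmatched), collapse = ", "))
    }
    b <- b[match(a$video_id, b$video_id), ]
    for (q in quantities) {
      xa <- a[[q]]; xb <- b[[q]]
      ok <- !is.na(xa) & !is.na(xb)
      xa <- xa[ok]; xb <- xb[ok]
      n <- length(xa)
      res <- version_t_test(xa, xb, paired)
      out[[length(out) + 1]] <- data.frame(
        quantity = q, marker = m, n = n, t = res$t, df = res$df,
        p_value = res$p, significant = !is.na(res$p) && res$p < alpha,
        degenerate = res$degenerate, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

version_t_test <- function(xa, xb, paired) {
  if (length(xa) < 2) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  if (paired) {
    d <- xa - xb
    if (stats::sd(d) == 0) {
      if (all(d == 0)) {
        # identical versions: no evidence of a difference
        return(list(t = 0, df = length(d) - 1, p = 1, degenerate = FALSE))
      }
      # constant non-zero shift: the t statistic is unbounded
      return(list(t = NA_real_, df = length(d) - 1, p = NA_real_, degenerate = TRUE))
    }
    tt <- stats::t.test(xa, xb, paired = TRUE)
  } else {
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      if (mean(xa) == mean(xb)) {
        return(list(t = 0, df = 2 * length(xa) - 2, p = 1, degenerate = FALSE))
      }
      return(list(t = NA_real_, df = NA_real_, p = NA_real_, degenerate = TRUE))
    }
    tt <- stats::t.test(xa, xb, var.equal = TRUE)
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' One-way ANOVA comparing prediction quality across markers
#'
#' Compares sensitivity, error rate or accuracy between the three markers
#' with a one-way analysis of variance over per-video values.
#'
#' @param values Numeric vector of per-video metric values.
#' @param marker Factor/character vector of marker names, same length.
#' @param alpha Significance level for the `significant` flag.
#' @return List with `F`, `df_between`, `df_within`, `p_value`,
#'   `significant`, and the underlying `table` (the stats::anova table).
#' @export
compare_markers_anova <- function(values, marker, alpha = 0.05) {
  ok <- !is.na(values)
  values <- values[ok]; marker <- factor(as.character(marker)[ok])
  counts <- table(marker)
  if (length(counts) < 2 || any(counts < 2)) {
    stop_st("need >= 2 groups with >= 2 defined values each (got: %s)",
            paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  }
  fit <- stats::aov(values ~ marker)
  tab <- stats::anova(fit)
  f <- tab$`F value`[1]
  if (is.na(f) && tab$`Sum Sq`[1] == 0) f <- 0  # identical groups: no effect
  p <- if (tab$`Sum Sq`[1] == 0) 1 else tab$`Pr(>F)`[1]
  list(F = f, df_between = tab$Df[1], df_within = tab$Df[2],
       p_value = p, significant = !is.na(p) && p < alpha, table = tab)
}
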