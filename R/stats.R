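# ROI quantification and two-group statistics: left/right hippocampal
# means, bilateral averaging, a normality screen, and an independent
# two-sample t-test.

#' ROI mean and SD of a parametric map
#'
#' Arithmetic mean over the valid voxels of the ROI only; invalid voxels
#' never contribute. An ROI with no valid voxels is an error, not a
#' silent zero.
#'
#' @param map A [parametric_map()].
#' @param labels Integer label image (vector or matrix matching the map).
#' @param roi Label code(s) selecting the ROI.
#' @return List with `mean`, `sd`, `n`.
#' @export
roi_mean <- function(map, labels, roi) {
  stopifnot(inherits(map, "parametric_map"))
  lab <- as.vector(labels)
  if (length(lab) != length(map$values))
    stop("label image does not match map size")
  sel <- lab %in% roi & map$valid
  if (!any(sel))
    stop("ROI ", paste(roi, collapse = "/"),
         " contains no valid voxels")
  v <- map$values[sel]
  list(mean = mean(v), sd = sd(v), n = length(v))
}

#' Two-group comparison of per-animal values
#'
#' Reproduces the study's statistical recipe: a per-group
#' Kolmogorov-Smirnov normality screen (Lilliefors variant, since the
#' population mean and SD are estimated from the sample) followed by a
#' two-sided independent two-sample t-test, equal-variance by default
#' with a Welch switch. Significance is reported against alpha = 0.05.
#'
#' @param values Numeric vector of per-animal values.
#' @param groups Factor/character of group membership (two levels).
#' @param var_equal Pooled-variance t-test (default) or Welch.
#' @param alpha Significance threshold reported alongside the p-value.
#' @return List of class `group_comparison`: `statistic`, `df`,
#'   `p_value`, `normality_p` (per group), `group_stats` data frame,
#'   `method`, `significant`.
#' @export
compare_groups <- function(values, groups, var_equal = TRUE, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) != 2)
    stop("exactly two groups are required, got ", nlevels(groups))
  split_v <- split(values, groups)
  ns <- vapply(split_v, length, integer(1))
  if (any(ns < 2)) stop("each group needs at least 2 values")
  if (all(vapply(split_v, function(v) var(v) == 0, logical(1))))
    stop("zero variance in both groups: t-test undefined")
  norm_p <- vapply(split_v, function(v) {
    if (length(v) < 5 || sd(v) == 0) return(NA_real_)
    nortest::lillie.test(v)$p.value
  }, numeric(1))
  tt <- t.test(split_v[[1]], split_v[[2]], var.equal = var_equal)
  gs <- data.frame(group = levels(groups), n = as.integer(ns),
                   mean = vapply(split_v, mean, numeric(1)),
                   sd = vapply(split_v, sd, numeric(1)),
                   row.names = NULL)
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 normality_p = norm_p,
                 group_stats = gs,
                 method = if (var_equal) "independent t-test (pooled variance)"
                          else "Welch t-test",
                 alpha = alpha,
                 significant = tt$p.value < alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$method, "\n", sep = "")
  print(x$group_stats, row.names = FALSE)
  cat(sprintf("t = %.4f, df = %.4g, p = %.4g (%ssignificant at %.2g)\n",
              x$statistic, x$df, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  cat("normality p (Lilliefors): ",
      paste(sprintf("%s = %.3g", names(x$normality_p), x$normality_p),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
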