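# Statistical helpers mirroring the analyses used with phantom/ROI data:
# linear concentration correlations, Wilcoxon rank-sum group comparison, and
# ROI summaries.

#' Correlate a per-tube statistic with concentration
#'
#' Ordinary least-squares regression of a derived parameter (e.g. amide MTR*)
#' on concentration (% w/v), returning the coefficient of determination,
#' the two-sided p-value of the slope t-test, and the slope.
#'
#' @param values Per-tube statistic.
#' @param conc Per-tube concentration, % w/v.
#' @return List with `r_squared`, `p_value`, `slope`, `intercept`, `n`.
#' @export
correlate_with_concentration <- function(values, conc) {
  if (length(values) != length(conc)) stop("lengths differ")
  if (length(values) < 3) stop("at least 3 tubes are required")
  if (stats::var(conc) == 0) stop("concentration has zero variance")
  fit <- stats::lm(values ~ conc)
  sm <- summary(fit)
  list(r_squared = sm$r.squared,
       p_value = sm$coefficients["conc", "Pr(>|t|)"],
       slope = unname(stats::coef(fit)["conc"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       n = length(values))
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test: the exact distribution
#' for small samples without ties, the normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param a,b Numeric samples (each `n >= 2`).
#' @return Two-sided p-value.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  suppressWarnings(stats::wilcox.test(a, b, exact = NULL, correct = TRUE))$p.value
}

#' Per-ROI mean and standard deviation
#'
#' @param map Numeric matrix/array of parameter values.
#' @param roi_masks Either an integer label image (0 = background) or a named
#'   list of logical masks, each matching `dim(map)`.
#' @return Data frame with one row per ROI: `roi`, `mean`, `sd`, `n`.
#' @export
roi_summary <- function(map, roi_masks) {
  if (is.list(roi_masks)) {
    rois <- roi_masks
    if (is.null(names(rois))) names(rois) <- paste0("roi", seq_along(rois))
  } else {
    if (!all(dim(roi_masks) == dim(map))) stop("map and mask grids differ")
    labs <- sort(unique(roi_masks[roi_masks != 0]))
    rois <- stats::setNames(lapply(labs, function(l) roi_masks == l),
                            as.character(labs))
  }
  out <- do.call(rbind, lapply(names(rois), function(nm) {
    m <- rois[[nm]]
    if (!all(dim(m) == dim(map))) stop("map and mask grids differ")
    v <- map[m]
    if (!length(v)) stop("ROI '", nm, "' is empty")
    data.frame(roi = nm, mean = mean(v), sd = stats::sd(v), n = length(v))
  }))
  rownames(out) <- NULL
  out
}
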