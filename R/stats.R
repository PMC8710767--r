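#' Group summary statistics
#'
#' Sample size, mean and unbiased variance of one group's values — the
#' sufficient statistics for Welch's t and Cohen's d.
#' @param x numeric vector (length >= 2, finite).
#' @return list(n, mean, var).
#' @export
groupSummary <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need n >= 2 per group")
  list(n = length(x), mean = mean(x), var = var(x))
}

asSummary <- function(x) if (is.list(x)) x else groupSummary(x)

#' Welch's t-test from group summaries
#'
#' Unequal-variance two-sample t statistic with Welch-Satterthwaite degrees
#' of freedom and a two-sided p-value:
#' \deqn{t = (\bar X_1 - \bar X_2) / \sqrt{s_1^2/n_1 + s_2^2/n_2}}
#'
#' @param a,b group summaries (\code{\link{groupSummary}}) or raw vectors.
#' @return list(t, df, p).
#' @export
welchT <- function(a, b) {
  a <- asSummary(a); b <- asSummary(b)
  se2 <- a$var / a$n + b$var / b$n
  if (se2 == 0) stop("undefined statistic: both group variances are zero")
  t <- (a$mean - b$mean) / sqrt(se2)
  df <- se2^2 / ((a$var / a$n)^2 / (a$n - 1) + (b$var / b$n)^2 / (b$n - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Cohen's d from group summaries
#'
#' Standardised mean difference using the pooled standard deviation
#' \eqn{\sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}}.
#'
#' @param a,b group summaries or raw vectors.
#' @return scalar d.
#' @export
cohensD <- function(a, b) {
  a <- asSummary(a); b <- asSummary(b)
  if (a$n + b$n <= 2) stop("need n1 + n2 > 2")
  sp2 <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / (a$n + b$n - 2)
  if (sp2 == 0) stop("zero pooled standard deviation")
  (a$mean - b$mean) / sqrt(sp2)
}

#' Intraclass correlation coefficient
#'
#' \code{method = "fisher"} evaluates the classical two-measurement formula
#' \deqn{r = \frac{1}{N s^2} \sum_n (x_{n,1} - \tilde x)(x_{n,2} - \tilde x)}
#' with the pooled mean \eqn{\tilde x} and pooled variance \eqn{s^2} over
#' both columns. \code{method = "icc21"} computes ICC(2,1): the two-way
#' random-effects, absolute-agreement, single-measure coefficient from the
#' ANOVA decomposition, supporting k >= 2 raters.
#'
#' @param x numeric matrix, participants x raters (k = 2 for "fisher").
#' @param method \code{"icc21"} (default) or \code{"fisher"}.
#' @return scalar coefficient in [-1, 1].
#' @export
icc <- function(x, method = c("icc21", "fisher")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  N <- nrow(x); k <- ncol(x)
  if (N < 2) stop("need at least 2 participants")
  if (method == "fisher") {
    if (k != 2) stop("the fisher formula is defined for exactly 2 measurements")
    xt <- mean(x)
    s2 <- (sum((x[, 1] - xt)^2) + sum((x[, 2] - xt)^2)) / (2 * N)
    if (s2 == 0) stop("zero total variance")
    sum((x[, 1] - xt) * (x[, 2] - xt)) / (N * s2)
  } else {
    grand <- mean(x)
    rowm <- rowMeans(x); colm <- colMeans(x)
    MSR <- k * sum((rowm - grand)^2) / (N - 1)
    MSC <- N * sum((colm - grand)^2) / (k - 1)
    SSE <- sum((sweep(sweep(x, 1, rowm), 2, colm) + grand)^2)
    MSE <- SSE / ((N - 1) * (k - 1))
    den <- MSR + (k - 1) * MSE + (k / N) * (MSC - MSE)
    if (den == 0) stop("zero total variance")
    (MSR - MSE) / den
  }
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors (>= 3 finite pairs, nonzero variances).
#' @return scalar r in [-1, 1].
#' @export
pearsonR <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 pairs")
  if (var(x) == 0 || var(y) == 0) stop("zero variance")
  cor(x, y)
}

#' Per-ROI aggregation of a voxelwise map
#'
#' ROI-level brain-age summaries: mean in-ROI predicted value, ROI-level
#' brain-PAD (mean in-ROI predicted age minus chronological age) and the ROI
#' tissue volume (in-mask voxel count times voxel volume in mm^3).
#'
#' @param map 3D array (NA outside mask).
#' @param atlas an \code{\link{RoiAtlas-class}} aligned with the map.
#' @param age_years the participant's chronological age (NA allowed for
#'   prediction-only aggregation).
#' @param voxel_size voxel edge length in mm.
#' @return data.frame(label, name, n_voxels, volume_mm3, mean_value,
#'   brain_pad).
#' @export
roiAggregate <- function(map, atlas, age_years = NA_real_, voxel_size = 1.5) {
  lab <- atlasLabels(atlas)
  stopifnot(identical(dim(lab), dim(map)))
  tab <- atlasNames(atlas)
  res <- lapply(seq_len(nrow(tab)), function(i) {
    sel <- lab == tab$label[i] & !is.na(map)
    if (!any(sel)) stop("ROI ", tab$name[i], " lies fully outside the mask")
    mv <- mean(map[sel])
    data.frame(label = tab$label[i], name = tab$name[i],
               n_voxels = sum(sel), volume_mm3 = sum(sel) * voxel_size^3,
               mean_value = mv, brain_pad = mv - age_years)
  })
  do.call(rbind, res)
}

#' Bonferroni adjustment for m comparisons
#' @param p raw p-values.
#' @param m number of comparisons (defaults to \code{length(p)}).
#' @return adjusted p-values \code{pmin(1, p * m)}.
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, p * m)

#' All pairwise group comparisons
#'
#' Welch's t, Welch df, two-sided p, Bonferroni-adjusted p and Cohen's d for
#' every pair of groups, at a given analysis scope (global: one value per
#' participant; voxel: pooled voxelwise values; roi: per-ROI values).
#'
#' @param values named list of numeric vectors, one per group (>= 2 groups,
#'   each n >= 2).
#' @param scope label recorded in the output ("global", "voxel" or "roi").
#' @param n_comparisons Bonferroni m; defaults to the number of pairwise
#'   tests performed.
#' @return tidy data.frame(scope, group_a, group_b, n_a, n_b, t, df, p,
#'   p_adj, d).
#' @export
compareGroups <- function(values, scope = "global", n_comparisons = NULL) {
  stopifnot(is.list(values), length(values) >= 2, !is.null(names(values)))
  ns <- vapply(values, function(v) sum(is.finite(v)), 0L)
  if (any(ns < 2)) stop("every group needs n >= 2")
  pairs <- utils::combn(names(values), 2)
  if (is.null(n_comparisons)) n_comparisons <- ncol(pairs)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    ga <- pairs[1, i]; gb <- pairs[2, i]
    sa <- groupSummary(values[[ga]]); sb <- groupSummary(values[[gb]])
    wt <- welchT(sa, sb)
    data.frame(scope = scope, group_a = ga, group_b = gb,
               n_a = sa$n, n_b = sb$n, t = wt$t, df = wt$df, p = wt$p,
               p_adj = bonferroni(wt$p, n_comparisons),
               d = cohensD(sa, sb))
  })
  do.call(rbind, res)
}

#' Age-matched subset of a cohort
#'
#' Retains participants strictly older than \code{min_age} (used to match
#' healthy controls to older clinical groups).
#' @param records cohort data.frame with \code{age_years}.
#' @param min_age age threshold in years.
#' @return filtered records; a warning (not an error) if empty.
#' @export
ageMatchedSubset <- function(records, min_age) {
  out <- records[records$age_years > min_age, , drop = FALSE]
  if (nrow(out) == 0)
    warning("no participants older than ", min_age, " years")
  out
}
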