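# Negative-binomial Wald differential expression: one engine applied
# identically to mRNA, lncRNA and miRNA count matrices.

#' Median-of-ratios size factors
#'
#' Computes per-sample normalization factors by the median-of-ratios
#' method: each sample's factor is the median, over features with nonzero
#' counts in every sample, of the ratio between the sample's count and the
#' feature's geometric mean. Factors are scale-equivariant: doubling one
#' sample's counts doubles its factor relative to every other sample's
#' (the feature-wise geometric means absorb a common rescaling, as in the
#' standard median-of-ratios formulation). When no feature is nonzero in all
#' samples the method falls back to total-count ratios with a warning.
#'
#' @param counts wide count tibble (`feature_id` + sample columns) or a
#'   numeric matrix.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors_median_ratio <- function(counts) {
  m <- as_count_matrix(counts)
  allpos <- rowSums(m > 0) == ncol(m)
  if (!any(allpos)) {
    warn("no feature has nonzero counts in all samples; falling back to total-count size factors")
    tot <- colSums(m)
    return(tot / exp(mean(log(tot))))
  }
  mm <- m[allpos, , drop = FALSE]
  geo <- exp(rowMeans(log(mm)))
  apply(mm / geo, 2, median)
}

#' Method-of-moments negative-binomial dispersion
#'
#' Estimates the per-feature NB dispersion `alpha` (Var = mu + alpha mu^2)
#' from normalized counts as `max(0, (s^2 - mu) / mu^2)`, floored at 1e-8;
#' no shrinkage is applied. When `groups` is supplied the variance is the
#' pooled within-group residual variance, so condition effects do not
#' inflate the estimate; otherwise the plain sample variance is used.
#' All-zero features are flagged untestable (`NA` dispersion).
#'
#' @param counts wide count tibble or matrix.
#' @param size_factors per-sample factors from
#'   [size_factors_median_ratio()] (default: all 1).
#' @param groups optional per-sample group labels (same order as the
#'   sample columns).
#' @return tibble (`feature_id`, `dispersion`, `testable`).
#' @export
estimate_dispersion_mom <- function(counts, size_factors = NULL,
                                    groups = NULL) {
  m <- as_count_matrix(counts)
  if (is.null(size_factors)) size_factors <- rep(1, ncol(m))
  y <- sweep(m, 2, size_factors, "/")
  mu <- rowMeans(y)
  if (is.null(groups)) {
    s2 <- apply(y, 1, var)
  } else {
    groups <- as.character(groups)
    ss <- 0
    df <- 0
    for (g in unique(groups)) {
      yg <- y[, groups == g, drop = FALSE]
      if (ncol(yg) < 2) next
      ss <- ss + rowSums((yg - rowMeans(yg))^2)
      df <- df + ncol(yg) - 1
    }
    if (df == 0) abort("need at least one group with >= 2 samples")
    s2 <- ss / df
  }
  disp <- pmax((s2 - mu) / mu^2, 1e-8)
  testable <- mu > 0
  disp[!testable] <- NA_real_
  tibble(feature_id = rownames(m), dispersion = unname(disp),
         testable = unname(testable))
}

#' Negative-binomial Wald test, treatment versus control
#'
#' For each feature computes the log2 fold change between mean normalized
#' counts (with a pseudo-count of 0.5 for stability at small n), a
#' delta-method standard error derived from the NB variance
#' `mu + alpha mu^2`, the Wald statistic and its two-sided normal p-value.
#' Benjamini-Hochberg adjusted p-values are reported for reference but
#' calls (via [call_de()]) use the raw p-value, following the convention
#' of filtering at `p <= 0.05` and `|log2FC| >= 0.5`.
#'
#' @param counts wide count tibble or matrix.
#' @param size_factors per-sample size factors (default: median-of-ratios
#'   computed from `counts`).
#' @param dispersions per-feature NB dispersion: a single number, a numeric
#'   vector, or the tibble from [estimate_dispersion_mom()].
#' @param groups per-sample group labels, same order as sample columns.
#' @param contrast length-2 character vector `c(treatment, control)`; the
#'   fold change is treatment over control.
#' @param pseudo_count added to group means before the log-ratio.
#' @param p_max,lfc_min thresholds forwarded to [call_de()].
#' @return a `cerna_de` tibble: `feature_id`, `base_mean`, `log2fc`, `se`,
#'   `wald_z`, `p_value`, `padj`, `call` (`up`/`down`/`ns`), `testable`.
#'   Untestable features get `p_value = 1` and `call = "ns"`.
#' @export
#' @examples
#' cm <- tibble::tibble(feature_id = c("g1", "g2"),
#'                      c1 = c(10L, 100L), c2 = c(12L, 90L),
#'                      t1 = c(30L, 95L), t2 = c(28L, 105L))
#' wald_test(cm, dispersions = 0.1,
#'           groups = c("control", "control", "treatment", "treatment"),
#'           contrast = c("treatment", "control"))
wald_test <- function(counts, size_factors = NULL, dispersions = NULL,
                      groups, contrast, pseudo_count = 0.5,
                      p_max = 0.05, lfc_min = 0.5) {
  m <- as_count_matrix(counts)
  groups <- as.character(groups)
  if (length(groups) != ncol(m))
    abort("`groups` must label every sample column")
  trt <- groups == contrast[1]
  ctl <- groups == contrast[2]
  if (sum(trt) < 2 || sum(ctl) < 2)
    abort("both contrast groups need >= 2 samples")
  if (is.null(size_factors)) size_factors <- size_factors_median_ratio(m)
  if (is.null(dispersions))
    dispersions <- estimate_dispersion_mom(m, size_factors, groups)
  if (is.data.frame(dispersions)) {
    alpha <- dispersions$dispersion[match(rownames(m),
                                          dispersions$feature_id)]
  } else {
    alpha <- rep_len(dispersions, nrow(m))
  }

  y <- sweep(m, 2, size_factors, "/")
  m_t <- rowMeans(y[, trt, drop = FALSE])
  m_c <- rowMeans(y[, ctl, drop = FALSE])
  base_mean <- rowMeans(y[, trt | ctl, drop = FALSE])
  lfc <- log2((m_t + pseudo_count) / (m_c + pseudo_count))

  # Var(K_i / s_i) = mu_g / s_i + alpha mu_g^2 for sample i in group g
  grp_var <- function(mg, idx) {
    n <- sum(idx)
    (mg * sum(1 / size_factors[idx]) + n * alpha * mg^2) / n^2
  }
  v_t <- grp_var(m_t, trt)
  v_c <- grp_var(m_c, ctl)
  se <- sqrt(v_t / ((m_t + pseudo_count) * log(2))^2 +
             v_c / ((m_c + pseudo_count) * log(2))^2)

  testable <- unname(!is.na(alpha) & (m_t + m_c) > 0 & se > 0)
  z <- ifelse(testable, unname(lfc / se), NA_real_)
  p <- ifelse(testable, 2 * pnorm(-abs(z)), 1)
  res <- tibble(feature_id = rownames(m), base_mean = unname(base_mean),
                log2fc = ifelse(testable, unname(lfc), 0),
                se = unname(se), wald_z = z, p_value = p,
                padj = p.adjust(p, method = "BH"),
                testable = testable)
  res <- call_de(res, p_max = p_max, lfc_min = lfc_min)
  structure(res, class = c("cerna_de", class(res)),
            contrast = contrast)
}

#' Call differential expression from Wald results
#'
#' Partitions features into `up`, `down` and `ns` with inclusive
#' boundaries: `p_value <= p_max` together with `log2fc >= lfc_min` is
#' `up`, with `log2fc <= -lfc_min` is `down`, anything else `ns` (so a
#' feature at exactly `p = 0.05` and `log2fc = 0.5` is called `up` under
#' the defaults).
#'
#' @param results tibble with `log2fc` and `p_value` columns.
#' @param p_max raw p-value cutoff (inclusive).
#' @param lfc_min absolute log2-fold-change cutoff (inclusive).
#' @return `results` with a recomputed `call` column.
#' @export
call_de <- function(results, p_max = 0.05, lfc_min = 0.5) {
  results |>
    mutate(call = dplyr::case_when(
      .data$p_value <= p_max & .data$log2fc >= lfc_min ~ "up",
      .data$p_value <= p_max & .data$log2fc <= -lfc_min ~ "down",
      .default = "ns"))
}

#' Up- and down-regulated feature id sets
#'
#' @param results a called DE table (see [call_de()]).
#' @return list with character vectors `up` and `down`.
#' @export
de_sets <- function(results) {
  list(up = results$feature_id[results$call == "up"],
       down = results$feature_id[results$call == "down"])
}

#' @export
tidy.cerna_de <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
glance.cerna_de <- function(x, ...) {
  tibble(n_features = nrow(x),
         n_testable = sum(x$testable),
         n_up = sum(x$call == "up"),
         n_down = sum(x$call == "down"),
         contrast = paste(attr(x, "contrast"), collapse = " vs "))
}

#' @export
autoplot.cerna_de <- function(object, p_max = 0.05, lfc_min = 0.5, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$p_value, 1e-300)),
                                   colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-lfc_min, lfc_min),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(p_max), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(up = "#d73027",
                                            down = "#4575b4",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}
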