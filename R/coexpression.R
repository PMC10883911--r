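# Pearson co-expression with exact t-based p-values.

#' Pearson correlation with an exact t-based p-value
#'
#' Computes the sample Pearson coefficient between two expression profiles
#' and its two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom; `r = +/-1` gives `p = 0` exactly. An edge
#' passes when `|r| >= r_min` and `p <= p_max`, both inclusive. Zero
#' variance in either profile leaves `r` undefined and the edge untestable
#' (never passing).
#'
#' @param x,y numeric vectors of equal length `n >= 3` with finite values.
#' @param r_min,p_max pass thresholds (inclusive).
#' @return one-row tibble (`r`, `n`, `p_value`, `passes`, `testable`).
#' @export
#' @examples
#' pearson_with_p(1:6, c(2, 4, 5, 9, 10, 12))
pearson_with_p <- function(x, y, r_min = 0.94, p_max = 0.05) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3) abort("need at least 3 paired samples")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    abort("expression profiles must be finite")
  if (var(x) == 0 || var(y) == 0) {
    return(tibble(r = NA_real_, n = n, p_value = NA_real_,
                  passes = FALSE, testable = FALSE))
  }
  r <- cor(x, y)
  r <- max(-1, min(1, r))
  # exact linear dependence up to floating-point noise: r = +/-1, p = 0
  if (abs(r) > 1 - 1e-12) r <- sign(r)
  p <- if (abs(r) >= 1) 0
  else 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
  tibble(r = r, n = n, p_value = p,
         passes = abs(r) >= r_min & p <= p_max, testable = TRUE)
}

#' Correlate candidate pairs between two expression matrices
#'
#' Transforms counts to `log2(count / size_factor + 1)` (the standard
#' variance-stabilizing transform before correlating count data; disable
#' with `log2_transform = FALSE` to correlate the raw values) and computes
#' one [pearson_with_p()] edge per requested pair, across all shared
#' samples.
#'
#' @param mat_a,mat_b wide count tibbles or matrices with identical,
#'   identically ordered sample columns.
#' @param pairs tibble (`id_a`, `id_b`) of candidate pairs, or `NULL` for
#'   all-vs-all.
#' @param size_factors_a,size_factors_b per-sample normalization factors
#'   (default 1).
#' @param log2_transform transform counts before correlating.
#' @param r_min,p_max pass thresholds (inclusive).
#' @return tibble (`id_a`, `id_b`, `r`, `n`, `p_value`, `passes`), ordered
#'   by (`id_a`, `id_b`).
#' @export
correlate_pairs <- function(mat_a, mat_b, pairs = NULL,
                            size_factors_a = NULL, size_factors_b = NULL,
                            log2_transform = TRUE, r_min = 0.94,
                            p_max = 0.05) {
  a <- as_count_matrix(mat_a)
  b <- as_count_matrix(mat_b)
  if (ncol(a) != ncol(b) || !all(colnames(a) == colnames(b))) {
    offending <- union(setdiff(colnames(a), colnames(b)),
                       setdiff(colnames(b), colnames(a)))
    abort(paste0("sample columns differ between matrices: ",
                 paste(offending, collapse = ", ")))
  }
  if (is.null(size_factors_a)) size_factors_a <- rep(1, ncol(a))
  if (is.null(size_factors_b)) size_factors_b <- rep(1, ncol(b))
  ya <- sweep(a, 2, size_factors_a, "/")
  yb <- sweep(b, 2, size_factors_b, "/")
  if (log2_transform) {
    ya <- log2(ya + 1)
    yb <- log2(yb + 1)
  }
  if (is.null(pairs)) {
    pairs <- tidyr::expand_grid(id_a = rownames(a), id_b = rownames(b))
  }
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) {
    return(tibble(id_a = character(), id_b = character(), r = double(),
                  n = integer(), p_value = double(), passes = logical()))
  }
  edges <- purrr::map2_dfr(pairs$id_a, pairs$id_b, function(ia, ib) {
    if (!ia %in% rownames(a) || !ib %in% rownames(b)) {
      return(tibble(id_a = ia, id_b = ib, r = NA_real_,
                    n = ncol(a), p_value = NA_real_, passes = FALSE))
    }
    e <- pearson_with_p(ya[ia, ], yb[ib, ], r_min = r_min, p_max = p_max)
    tibble(id_a = ia, id_b = ib, r = e$r, n = e$n, p_value = e$p_value,
           passes = e$passes)
  })
  arrange(edges, .data$id_a, .data$id_b)
}
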