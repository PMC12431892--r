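#' Mann-Whitney U test
#'
#' Two-sample rank test for independent samples. Reports the U statistic of
#' the first sample (and the min-U convention alongside), with an exact
#' p-value when the combined sample size is at most 20 and there are no
#' ties, and the normal approximation with continuity and tie correction
#' otherwise. A pooled sample with no variation gives p = 1.
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`.
#' @return A one-row tibble with `U` (first-sample convention), `U_min`,
#'   `p`, `n1`, `n2`, `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
mann_whitney <- function(x, y, alternative = "two.sided") {
  if (!length(x) || !length(y)) rlang::abort("both samples must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    return(tibble::tibble(U = n1 * n2 / 2, U_min = n1 * n2 / 2, p = 1,
                          n1 = n1, n2 = n2, method = "degenerate"))
  }
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- (n1 + n2) <= 20L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = use_exact,
                       correct = TRUE)
  )
  U <- unname(wt$statistic)
  tibble::tibble(U = U, U_min = min(U, n1 * n2 - U), p = wt$p.value,
                 n1 = n1, n2 = n2,
                 method = if (use_exact) "exact" else "normal_approx")
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)` for a family of `m` tests.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param m Family size (defaults to `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) rlang::abort("p-values must lie in [0, 1]")
  if (m < length(p)) rlang::abort("`m` must be at least the number of tests")
  pmin(1, m * p)
}

#' Spearman trend across ordered groups
#'
#' Rank correlation between a per-participant marker and an ordinal coding
#' of the group labels (default UWS = 0 < MCS = 1 < EMCS = 2 < HC = 3),
#' testing for a monotone gradient of the marker across the ordered states.
#'
#' @param values Numeric marker values, one per participant.
#' @param groups Group labels, parallel to `values`.
#' @param order Character vector giving the ordinal group order, lowest
#'   first.
#' @return A one-row tibble with `rs`, `p`, `n`, and the coding used.
#' @export
spearman_trend <- function(values, groups,
                           order = c("UWS", "MCS", "EMCS", "HC")) {
  groups <- as.character(groups)
  present <- order[order %in% groups]
  if (length(unique(groups)) < 2L) {
    rlang::abort("need at least 2 distinct groups for a trend")
  }
  if (!all(groups %in% order)) {
    rlang::abort("`groups` contains labels missing from `order`")
  }
  codes <- match(groups, order) - 1
  ct <- suppressWarnings(
    stats::cor.test(values, codes, method = "spearman")
  )
  tibble::tibble(rs = unname(ct$estimate), p = ct$p.value,
                 n = length(values), coding = paste(present, collapse = "<"))
}

#' Pairwise nonparametric group comparison of markers
#'
#' For every requested marker column, runs a two-sided Mann-Whitney U test
#' for every pair of groups and Bonferroni-corrects within the marker's
#' family of pairwise tests (m = number of pairs). Optionally adds the
#' Spearman ordinal trend per marker.
#'
#' @param markers A tibble with one row per participant, a `group` column,
#'   and marker columns.
#' @param marker_cols Character vector of marker column names (defaults to
#'   `coverage_entropy`, `gev_total`, `mmd`, `mdv`, `ep` where present).
#' @param group_col Name of the group column (default `"group"`).
#' @param order Ordinal group order for the trend test; `NULL` skips trends.
#' @param alpha Significance level recorded in the output (default 0.05).
#' @return A list of tibbles: `pairwise` (marker, group pair, U, p_raw,
#'   p_bonferroni, significance at `alpha`) and `trend` (marker, rs, p).
#' @export
compare_groups <- function(markers, marker_cols = NULL, group_col = "group",
                           order = c("UWS", "MCS", "EMCS", "HC"),
                           alpha = 0.05) {
  if (is.null(marker_cols)) {
    marker_cols <- intersect(c("coverage_entropy", "gev_total", "mmd",
                               "mdv", "ep"), names(markers))
  }
  gr <- as.character(markers[[group_col]])
  glev <- if (!is.null(order) && all(unique(gr) %in% order)) {
    order[order %in% gr]
  } else sort(unique(gr))
  pairs <- utils::combn(glev, 2L, simplify = FALSE)
  m <- length(pairs)
  pairwise <- purrr::map_dfr(marker_cols, function(col) {
    purrr::map_dfr(pairs, function(pr) {
      x <- markers[[col]][gr == pr[1L]]
      y <- markers[[col]][gr == pr[2L]]
      res <- mann_whitney(x, y)
      tibble::tibble(marker = col, group1 = pr[1L], group2 = pr[2L],
                     U = res$U, p_raw = res$p, n1 = res$n1, n2 = res$n2)
    })
  })
  pairwise <- pairwise |>
    dplyr::group_by(.data$marker) |>
    dplyr::mutate(p_bonferroni = bonferroni_adjust(.data$p_raw, m),
                  significant = .data$p_bonferroni < alpha) |>
    dplyr::ungroup()
  trend <- NULL
  if (!is.null(order) && all(unique(gr) %in% order)) {
    trend <- purrr::map_dfr(marker_cols, function(col) {
      dplyr::bind_cols(tibble::tibble(marker = col),
                       spearman_trend(markers[[col]], gr, order = order))
    })
  }
  list(pairwise = pairwise, trend = trend)
}
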