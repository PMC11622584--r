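#' Per-site regression statistics for the three-filter selection
#'
#' For every CpG site, computes (i) the Pearson correlation `r_site`
#' between its observed methylation column and the multifactor model's
#' fitted column, and (ii) per-factor ordinary-least-squares t-test
#' p-values from the same design matrix, Benjamini-Hochberg adjusted per
#' factor across all sites. Zero-variance sites get an undefined (`NA`)
#' `r_site` and therefore fail the correlation filter.
#'
#' @param fit a `multifactor_fit` from [mf_fit()].
#' @return A tibble of class `site_scores`, one row per (site, factor):
#'   `site_id`, `factor`, `coefficient`, `p_value`, `q_value`, `r_site`,
#'   `eligible` (FALSE for nuisance constant / batch columns, which never
#'   enter the selection filters).
#' @export
score_sites <- function(fit) {
  stopifnot(inherits(fit, "multifactor_fit"))
  M <- fit$M_obs; X <- fit$X
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop_data("per-site OLS inference needs n_samples > n_factors")
  if (matrix_rank(X, fit$pinv_tolerance) < p) {
    warn("design matrix is rank deficient; per-factor p-values are unreliable")
  }

  # Observed-vs-fitted correlation per site, vectorised.
  Mc <- scale(M, scale = FALSE)
  Pc <- scale(fit$M_pred, scale = FALSE)
  num <- colSums(Mc * Pc)
  den <- sqrt(colSums(Mc^2) * colSums(Pc^2))
  r_site <- ifelse(den > 0, num / den, NA_real_)

  # Per-site OLS t-tests with the shared design: se(beta_kj)^2 =
  # sigma2_j * (X'X)^{-1}_{kk}, sigma2_j = RSS_j / (n - p).
  XtX_inv <- tryCatch(solve(crossprod(X)),
                      error = function(e) pinv(crossprod(X)))
  res <- M - fit$M_pred
  df <- n - p
  sigma2 <- colSums(res^2) / df
  se <- sqrt(outer(diag(XtX_inv), sigma2))
  tstat <- fit$beta / se
  pval <- 2 * stats::pt(-abs(tstat), df = df)

  eligible <- !(colnames(X) %in% c("constant", "batch"))
  if (!is.null(fit$factor_matrix)) {
    eligible <- !(colnames(X) %in% fit$factor_matrix$nuisance)
  }

  out <- purrr::map_dfr(seq_len(p), function(k) {
    tibble(
      site_id = colnames(M),
      factor = colnames(X)[k],
      coefficient = unname(fit$beta[k, ]),
      p_value = unname(pval[k, ]),
      q_value = unname(stats::p.adjust(pval[k, ], method = "BH")),
      r_site = unname(r_site),
      eligible = eligible[k]
    )
  })
  structure(out, class = c("site_scores", class(out)))
}

#' Select factor-associated CpG sites with the three-filter procedure
#'
#' Applies three filters to the per-site scores: (1) high correlation,
#' `|r_site| >= r_min`; (2) statistical significance, BH-adjusted p-value
#' `<= q_max` for the factor; (3) highest coefficient, the site's largest
#' absolute coefficient among eligible (non-nuisance) factors belongs to
#' this factor. Survivors are ranked by adjusted p-value (ties broken by
#' absolute coefficient, then site id), truncated to `cap`, and split by
#' coefficient sign: negative coefficients mark methylation loss with
#' increasing factor values, positive coefficients methylation gain.
#'
#' @param scores a `site_scores` tibble from [score_sites()].
#' @param factor factor name (must be eligible, i.e. not constant/batch).
#' @param r_min correlation filter threshold (default 0.5).
#' @param q_max adjusted-p filter threshold (default 0.05).
#' @param cap maximum number of sites retained (default 200).
#' @return A `selection_result`: list with the `sites` tibble (ranked,
#'   with `sign`), the factor name, `n_pre_cap` (sites passing all filters
#'   before truncation) and the thresholds used.
#' @export
select_sites <- function(scores, factor, r_min = 0.5, q_max = 0.05,
                         cap = 200) {
  stopifnot(inherits(scores, "site_scores"))
  eligible_factors <- unique(scores$factor[scores$eligible])
  if (!factor %in% eligible_factors) {
    stop_config(paste0(
      "'", factor, "' is not an eligible factor; choose one of: ",
      paste(eligible_factors, collapse = ", ")
    ))
  }

  # Filter 3 support: per site, which eligible factor has the largest
  # absolute coefficient (ties resolved by factor order — deterministic,
  # and a site is assigned to exactly one factor).
  assign_tbl <- scores %>%
    dplyr::filter(.data$eligible) %>%
    dplyr::group_by(.data$site_id) %>%
    dplyr::summarise(
      assigned = .data$factor[which.max(abs(.data$coefficient))],
      .groups = "drop"
    )

  fac <- factor
  cand <- scores %>%
    dplyr::filter(.data$factor == fac) %>%
    dplyr::inner_join(assign_tbl, by = "site_id") %>%
    dplyr::filter(
      !is.na(.data$r_site), abs(.data$r_site) >= r_min,   # filter 1
      .data$q_value <= q_max,                             # filter 2
      .data$assigned == fac                               # filter 3
    ) %>%
    dplyr::arrange(.data$q_value, dplyr::desc(abs(.data$coefficient)),
                   .data$site_id)

  n_pre_cap <- nrow(cand)
  sel <- utils::head(cand, cap) %>%
    dplyr::mutate(
      sign = ifelse(.data$coefficient < 0, "neg", "pos"),
      zero_coefficient = .data$coefficient == 0
    ) %>%
    dplyr::select("site_id", "coefficient", "p_value", "q_value", "r_site",
                  "sign", "zero_coefficient")
  if (any(sel$zero_coefficient)) {
    warn(sprintf("%d selected site(s) have an exactly zero coefficient; grouped as positive",
                 sum(sel$zero_coefficient)))
  }

  structure(
    list(factor = fac, sites = sel, n_pre_cap = n_pre_cap,
         n_selected = nrow(sel),
         thresholds = list(r_min = r_min, q_max = q_max, cap = cap)),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> factor '%s': %d site(s) selected (%d passed filters pre-cap); %d negative, %d positive\n",
    x$factor, x$n_selected, x$n_pre_cap,
    sum(x$sites$sign == "neg"), sum(x$sites$sign == "pos")
  ))
  invisible(x)
}

#' @rdname select_sites
#' @param x a `selection_result`.
#' @param ... unused.
#' @export
tidy.selection_result <- function(x, ...) {
  dplyr::mutate(x$sites, factor = x$factor, .before = 1)
}

#' @rdname select_sites
#' @export
glance.selection_result <- function(x, ...) {
  tibble(factor = x$factor, n_selected = x$n_selected,
         n_pre_cap = x$n_pre_cap,
         n_negative = sum(x$sites$sign == "neg"),
         n_positive = sum(x$sites$sign == "pos"),
         r_min = x$thresholds$r_min, q_max = x$thresholds$q_max,
         cap = x$thresholds$cap)
}

#' Volcano-style plot of per-site scores for one factor
#' @param object a `site_scores` tibble.
#' @param factor factor to display (default: first eligible).
#' @param ... unused.
#' @export
plot_site_scores <- function(object, factor = NULL, ...) {
  stopifnot(inherits(object, "site_scores"))
  if (is.null(factor)) factor <- object$factor[object$eligible][1]
  fac <- factor
  df <- dplyr::filter(object, .data$factor == fac)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coefficient,
                                   y = -log10(.data$q_value))) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(title = fac, x = "coefficient (per scaled factor unit)",
                  y = expression(-log[10] ~ "BH-adjusted p")) +
    ggplot2::theme_minimal()
}
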