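#' Moore-Penrose pseudoinverse via singular value decomposition
#'
#' Singular values at or below `tol` are treated as zero. The default
#' tolerance is the conventional `max(dim(A)) * eps * max(singular value)`.
#'
#' @param A numeric matrix.
#' @param tol singular-value cutoff; `NULL` for the default.
#' @return The pseudoinverse, a `ncol(A)` x `nrow(A)` matrix.
#' @export
pinv <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

matrix_rank <- function(A, tol = NULL) {
  d <- svd(A, nu = 0, nv = 0)$d
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(d, 0)
  sum(d > tol)
}

as_values <- function(m) if (inherits(m, "methylation_matrix")) m$values else m
as_design <- function(x) if (inherits(x, "factor_matrix")) x$X else x

#' Fit the pseudoinverse multifactor model
#'
#' Models the observed methylation matrix as a linear combination of
#' phenotypic factors, `M_obs = X beta`, and solves for the least-squares
#' coefficient matrix with the Moore-Penrose pseudoinverse:
#' `beta = pinv(X) M_obs`. The fitted methylation matrix is
#' `M_pred = X beta` and the reverse prediction of the factors from
#' methylation is `X_pred = M_obs pinv(beta)`. When `X` has full column
#' rank, `beta` equals the per-site ordinary-least-squares solution; when
#' it does not, the minimum-norm solution is returned.
#'
#' @param m observed methylation, a [methylation_matrix()] or bare
#'   samples-by-sites matrix with no missing values.
#' @param x design, a `factor_matrix` from [build_factor_matrix()] or a
#'   bare samples-by-factors matrix.
#' @param tol pseudoinverse singular-value cutoff (`NULL` = default).
#' @return A `multifactor_fit` with elements `beta`, `M_pred`, `X_pred`,
#'   `M_obs`, `X`, `pinv_tolerance` and the originating `factor_matrix`
#'   (if one was supplied).
#' @export
mf_fit <- function(m, x, tol = NULL) {
  M <- as_values(m)
  X <- as_design(x)
  if (anyNA(M)) stop_data("methylation matrix has missing values; impute first")
  if (!identical(rownames(M), rownames(X))) {
    if (!setequal(rownames(M), rownames(X))) {
      stop_data("methylation and factor matrices cover different samples")
    }
    X <- X[rownames(M), , drop = FALSE]
  }
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop_data(sprintf("need more samples (%d) than factors (%d)", n, p))
  if (matrix_rank(X, tol) < 2) stop_data("degenerate design: rank(X) < 2")

  Xd <- pinv(X, tol)
  beta <- Xd %*% M
  rownames(beta) <- colnames(X)
  M_pred <- X %*% beta
  X_pred <- M %*% pinv(beta, tol)
  colnames(X_pred) <- colnames(X)

  structure(
    list(beta = beta, M_pred = M_pred, X_pred = X_pred,
         M_obs = M, X = X, pinv_tolerance = tol,
         factor_matrix = if (inherits(x, "factor_matrix")) x else NULL),
    class = "multifactor_fit"
  )
}

#' @export
print.multifactor_fit <- function(x, ...) {
  cat(sprintf("<multifactor_fit> %d samples, %d factors, %d sites\n",
              nrow(x$X), ncol(x$X), ncol(x$beta)))
  invisible(x)
}

#' @rdname mf_fit
#' @param ... unused.
#' @return For `tidy()`: a long tibble (site_id, factor, coefficient).
#' @export
tidy.multifactor_fit <- function(x, ...) {
  tibble(
    site_id = rep(colnames(x$beta), each = nrow(x$beta)),
    factor = rep(rownames(x$beta), times = ncol(x$beta)),
    coefficient = as.vector(x$beta)
  )
}

#' @rdname mf_fit
#' @export
glance.multifactor_fit <- function(x, ...) {
  res <- x$M_obs - x$M_pred
  tss <- sum(scale(x$M_obs, scale = FALSE)^2)
  tibble(
    n_samples = nrow(x$X), n_factors = ncol(x$X), n_sites = ncol(x$beta),
    rank = matrix_rank(x$X, x$pinv_tolerance),
    rss = sum(res^2),
    r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  )
}

# Per-factor prediction statistics shared by LOOCV and full-fit evaluation.
# Predictions and observations arrive on the [0,1] model scale; MAE is
# reported on original units via the factor_matrix scaling when available.
factor_prediction_stats <- function(X_obs, X_pred, fm, factors) {
  purrr::map_dfr(factors, function(f) {
    obs <- X_obs[, f]
    pred <- X_pred[, f]
    st <- pearson_stats(obs, pred)
    if (!is.null(fm)) {
      obs_u <- unscale_factor(fm, f, obs)
      pred_u <- unscale_factor(fm, f, pred)
    } else {
      obs_u <- obs; pred_u <- pred
    }
    tibble(factor = f, r = st$r, p_value = st$p,
           mae = mean(abs(pred_u - obs_u)), n = st$n)
  })
}

prediction_table <- function(X_obs, X_pred, fm, factors) {
  purrr::map_dfr(factors, function(f) {
    obs <- X_obs[, f]; pred <- X_pred[, f]
    tibble(
      sample_id = rownames(X_obs), factor = f,
      observed = if (is.null(fm)) obs else unscale_factor(fm, f, obs),
      predicted = if (is.null(fm)) pred else unscale_factor(fm, f, pred),
      observed_scaled = obs, predicted_scaled = pred
    )
  })
}

#' Leave-one-out cross-validation of the multifactor model
#'
#' For each sample i the model is refitted on the remaining n - 1 samples
#' and the held-out factor row is predicted as `M_obs[i, ] pinv(beta_-i)`.
#' Per factor (nuisance constant and batch columns excluded), the Pearson
#' correlation between predicted and observed values, its two-sided p-value
#' (t distribution, n - 2 df) and the mean absolute error on original,
#' unscaled units are reported.
#'
#' @inheritParams mf_fit
#' @return A `multifactor_loocv` with `stats` (per-factor tibble) and
#'   `predictions` (per sample x factor, original and scaled units).
#' @export
loocv <- function(m, x, tol = NULL) {
  M <- as_values(m)
  X <- as_design(x)
  if (!identical(rownames(M), rownames(X))) X <- X[rownames(M), , drop = FALSE]
  fm <- if (inherits(x, "factor_matrix")) x else NULL
  n <- nrow(X); p <- ncol(X)
  if (n < p + 3) stop_data(sprintf("LOOCV needs at least %d samples for %d factors", p + 3, p))

  X_pred <- matrix(NA_real_, n, p, dimnames = list(rownames(X), colnames(X)))
  for (i in seq_len(n)) {
    beta_i <- pinv(X[-i, , drop = FALSE], tol) %*% M[-i, , drop = FALSE]
    X_pred[i, ] <- M[i, , drop = FALSE] %*% pinv(beta_i, tol)
  }
  factors <- if (is.null(fm)) colnames(X) else report_factors(fm)
  factors <- setdiff(factors, "constant")
  structure(
    list(stats = factor_prediction_stats(X, X_pred, fm, factors),
         predictions = prediction_table(X, X_pred, fm, factors),
         X_pred = X_pred),
    class = "multifactor_loocv"
  )
}

#' @export
print.multifactor_loocv <- function(x, ...) {
  cat("<multifactor_loocv>\n")
  print(x$stats)
  invisible(x)
}

#' @rdname loocv
#' @param ... unused.
#' @export
tidy.multifactor_loocv <- function(x, ...) x$stats

#' @rdname loocv
#' @export
glance.multifactor_loocv <- function(x, ...) {
  tibble(n_factors = nrow(x$stats), median_r = stats::median(x$stats$r),
         min_p = min(x$stats$p_value))
}

#' @rdname loocv
#' @param object a `multifactor_loocv`.
#' @export
autoplot.multifactor_loocv <- function(object, ...) {
  lab <- object$stats %>%
    dplyr::mutate(label = sprintf("r = %.2f, MAE = %.3g", .data$r, .data$mae))
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$label),
                       x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                       inherit.aes = FALSE, size = 3) +
    ggplot2::facet_wrap(~factor, scales = "free") +
    ggplot2::labs(x = "observed", y = "LOOCV prediction") +
    ggplot2::theme_minimal()
}

#' In-sample evaluation of a fitted multifactor model
#'
#' Correlates the reverse predictions `X_pred = M_obs pinv(beta)` of a
#' full fit with the observed factor values — the in-sample (optimistic)
#' counterpart of [loocv()]. Nuisance columns are excluded.
#'
#' @param fit a `multifactor_fit`.
#' @return per-factor tibble (factor, r, p_value, mae, n).
#' @export
evaluate_fullfit <- function(fit) {
  stopifnot(inherits(fit, "multifactor_fit"))
  fm <- fit$factor_matrix
  factors <- if (is.null(fm)) colnames(fit$X) else report_factors(fm)
  factors <- setdiff(factors, "constant")
  factors <- factors[apply(fit$X[, factors, drop = FALSE], 2, stats::sd) > 0]
  factor_prediction_stats(fit$X, fit$X_pred, fm, factors)
}
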