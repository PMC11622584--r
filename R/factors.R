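#' Build the multifactor phenotype matrix
#'
#' Assembles the design matrix `X` of the multifactor model: a constant
#' column of ones, an optional 0/1 batch indicator, and the requested
#' phenotype / cell-composition factors min-max scaled into `[0, 1]` (the
#' scaling makes coefficients comparable across factors; the (min, max)
#' pair is stored for inverse transformation of predictions).
#'
#' To avoid multicollinearity, correlated factors are pruned iteratively:
#' while any pair of non-constant, non-batch factors has `|Pearson r|`
#' above `prune_threshold`, the factor involved in a violating pair with
#' the largest mean absolute correlation to the other factors is dropped.
#' Pinned factors (by default `age`) are never dropped.
#'
#' @param phenotypes tibble with `sample_id` plus phenotype columns (e.g.
#'   `age`, `batch`).
#' @param composition optional `cell_composition` tibble from
#'   [deconvolve_all()]; its cell-type columns become candidate factors.
#' @param factors character vector of factor names to include (columns of
#'   `phenotypes` or `composition`). Defaults to `age` plus all cell types.
#' @param prune_threshold pairwise `|r|` above which pruning kicks in
#'   (default 0.7).
#' @param pinned factors protected from pruning (default `"age"`).
#' @param batch_col name of the batch column in `phenotypes` (two levels,
#'   encoded 0/1), or `NULL` for no batch term.
#' @return A `factor_matrix`: list with the design matrix `X` (samples x
#'   factors), the `scaling` tibble (factor, min, max), the `pruned` report
#'   tibble, and bookkeeping of pinned / nuisance columns.
#' @export
build_factor_matrix <- function(phenotypes, composition = NULL,
                                factors = NULL, prune_threshold = 0.7,
                                pinned = "age", batch_col = "batch") {
  stopifnot("sample_id" %in% names(phenotypes))
  tbl <- as_tibble(phenotypes)
  if (!is.null(composition)) {
    comp <- as_tibble(composition)
    comp <- comp[, setdiff(names(comp), c("residual", "n_shared"))]
    if (!setequal(tbl$sample_id, comp$sample_id)) {
      stop_data("phenotype table and composition table cover different samples")
    }
    tbl <- dplyr::inner_join(tbl, comp, by = "sample_id")
  }
  tbl <- tbl[order(tbl$sample_id), ]
  if (anyDuplicated(tbl$sample_id)) stop_data("duplicate sample ids")

  if (is.null(factors)) {
    factors <- intersect(
      c("age", if (!is.null(composition)) cell_types(composition)),
      names(tbl)
    )
  }
  if (length(factors) == 0) stop_config("no factors requested")
  missing_cols <- setdiff(factors, names(tbl))
  if (length(missing_cols) > 0) {
    stop_config(paste0("unknown factor(s): ", paste(missing_cols, collapse = ", ")))
  }

  # Min-max scale each factor to [0, 1], keeping the transform.
  scaling <- purrr::map_dfr(factors, function(f) {
    v <- tbl[[f]]
    if (!is.numeric(v)) stop_config(paste0("factor '", f, "' is not numeric"))
    if (anyNA(v)) stop_data(paste0("factor '", f, "' has missing values"))
    rng <- range(v)
    if (diff(rng) == 0) {
      stop_config(paste0("factor '", f, "' is constant across samples"))
    }
    tibble(factor = f, min = rng[1], max = rng[2])
  })
  scaled <- vapply(seq_along(factors), function(i) {
    (tbl[[factors[i]]] - scaling$min[i]) / (scaling$max[i] - scaling$min[i])
  }, numeric(nrow(tbl)))
  colnames(scaled) <- factors
  rownames(scaled) <- tbl$sample_id

  # Iterative correlation pruning, pinned factors protected.
  pinned <- intersect(pinned, factors)
  kept <- factors
  pruned <- tibble(factor = character(), partner = character(), r = numeric(),
                   mean_abs_r = numeric())
  repeat {
    if (length(kept) < 2) break
    cm <- stats::cor(scaled[, kept, drop = FALSE])
    diag(cm) <- 0
    viol <- which(abs(cm) > prune_threshold, arr.ind = TRUE)
    if (nrow(viol) == 0) break
    involved <- unique(kept[viol[, 1]])
    droppable <- setdiff(involved, pinned)
    if (length(droppable) == 0) {
      warn(paste0("pinned factors remain correlated above the threshold: ",
                  paste(involved, collapse = ", ")))
      break
    }
    mean_abs <- rowMeans(abs(cm))[droppable]
    victim <- droppable[order(-mean_abs, droppable)][1]
    partners <- kept[viol[viol[, 1] == match(victim, kept), 2]]
    worst <- partners[which.max(abs(cm[victim, partners]))]
    pruned <- dplyr::bind_rows(pruned, tibble(
      factor = victim, partner = worst, r = cm[victim, worst],
      mean_abs_r = unname(mean_abs[victim])
    ))
    kept <- setdiff(kept, victim)
  }

  X <- cbind(constant = rep(1, nrow(tbl)), scaled[, kept, drop = FALSE])
  nuisance <- "constant"
  if (!is.null(batch_col)) {
    if (!batch_col %in% names(tbl)) {
      stop_config(paste0("batch column '", batch_col, "' not found"))
    }
    b <- as.factor(tbl[[batch_col]])
    if (nlevels(b) != 2) {
      stop_config("batch must have exactly two levels for the 0/1 encoding")
    }
    X <- cbind(X, batch = as.numeric(b) - 1)
    nuisance <- c(nuisance, "batch")
  }
  rownames(X) <- tbl$sample_id

  structure(
    list(X = X,
         scaling = dplyr::filter(scaling, .data$factor %in% kept),
         pruned = pruned, pinned = pinned, nuisance = nuisance),
    class = "factor_matrix"
  )
}

#' @export
print.factor_matrix <- function(x, ...) {
  cat(sprintf("<factor_matrix> %d samples x %d columns: %s\n",
              nrow(x$X), ncol(x$X), paste(colnames(x$X), collapse = ", ")))
  if (nrow(x$pruned) > 0) {
    cat("pruned for collinearity:",
        paste(sprintf("%s (r=%.2f with %s)", x$pruned$factor, x$pruned$r,
                      x$pruned$partner), collapse = "; "), "\n")
  }
  invisible(x)
}

#' @rdname build_factor_matrix
#' @param x a `factor_matrix`.
#' @param ... unused.
#' @return For `tidy()`: one row per retained factor column with its
#'   scaling bounds and role.
#' @export
tidy.factor_matrix <- function(x, ...) {
  tibble(factor = colnames(x$X)) %>%
    dplyr::left_join(x$scaling, by = "factor") %>%
    dplyr::mutate(
      role = dplyr::case_when(
        .data$factor %in% x$nuisance ~ "nuisance",
        .data$factor %in% x$pinned ~ "pinned",
        TRUE ~ "factor"
      )
    )
}

# Report (non-nuisance) factor names of a factor_matrix.
report_factors <- function(x) setdiff(colnames(x$X), x$nuisance)

# Map scaled predictions back to original units via the stored (min, max).
unscale_factor <- function(x, factor, values) {
  row <- dplyr::filter(x$scaling, .data$factor == !!factor)
  if (nrow(row) == 0) return(values)  # unscaled column (e.g. batch)
  row$min + values * (row$max - row$min)
}
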