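#' Build a reference methylome from replicate WGBS profiles
#'
#' Each cell type's reference profile is the unweighted mean of its
#' replicate profiles, restricted to panel sites observed in every
#' replicate of every type so the deconvolution design is complete.
#'
#' @param replicate_profiles named list (cell type -> list of profiles);
#'   each profile is a named numeric vector (site id -> methylation
#'   fraction) or a tibble with `site_id` and `level` columns.
#' @param panel optional site panel (character ids or `chrom`/`pos` tibble);
#'   `NULL` keeps all shared sites.
#' @param min_sites minimum number of common sites required (default 50);
#'   below this the reference is too sparse to deconvolve against.
#' @return A `reference_methylome`: sites-by-cell-types matrix wrapped with
#'   its site table.
#' @export
build_reference <- function(replicate_profiles, panel = NULL, min_sites = 50) {
  if (length(replicate_profiles) < 2) {
    stop_config("need at least two cell types to build a reference")
  }
  as_vec <- function(p) {
    if (is.data.frame(p)) stats::setNames(p$level, p$site_id) else p
  }
  profs <- lapply(replicate_profiles, function(reps) lapply(reps, as_vec))
  common <- Reduce(intersect, lapply(unlist(profs, recursive = FALSE), names))
  if (!is.null(panel)) {
    panel_ids <- if (is.character(panel)) panel else site_id(panel$chrom, panel$pos)
    common <- intersect(common, panel_ids)
  }
  if (length(common) < min_sites) {
    stop_data(sprintf(
      "only %d site(s) shared across all replicates and the panel (need >= %d)",
      length(common), min_sites
    ))
  }
  sites <- parse_site_id(common)
  sites <- sites[site_order(sites$chrom, sites$pos), ]
  values <- vapply(profs, function(reps) {
    rowMeans(vapply(reps, function(v) v[sites$site_id], numeric(nrow(sites))))
  }, numeric(nrow(sites)))
  rownames(values) <- sites$site_id
  reference_methylome(values)
}

#' @rdname build_reference
#' @param values sites-by-cell-types matrix of methylation fractions with
#'   `"chrom:pos"` row names and cell-type column names.
#' @export
reference_methylome <- function(values) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (min(values) < -1e-9 || max(values) > 1 + 1e-9) {
    stop_data("reference methylation values outside [0, 1]")
  }
  for (i in seq_len(ncol(values) - 1)) {
    for (j in (i + 1):ncol(values)) {
      if (isTRUE(all.equal(values[, i], values[, j], check.attributes = FALSE))) {
        stop_data(sprintf("reference columns '%s' and '%s' are identical",
                          colnames(values)[i], colnames(values)[j]))
      }
    }
  }
  structure(list(values = values, sites = parse_site_id(rownames(values))),
            class = "reference_methylome")
}

#' @export
print.reference_methylome <- function(x, ...) {
  cat(sprintf("<reference_methylome> %d sites x %d cell types: %s\n",
              nrow(x$values), ncol(x$values),
              paste(colnames(x$values), collapse = ", ")))
  invisible(x)
}

#' Deconvolve one sample against a reference methylome
#'
#' Solves the non-negative least-squares problem
#' \eqn{\min_{w \ge 0} \lVert R w - m \rVert_2} over the sites shared
#' between the sample (non-missing) and the reference, where `R` is the
#' reference matrix and `m` the sample's methylation vector. With
#' `normalize = TRUE` the weights are rescaled to sum to one, giving
#' DNA-proportion estimates (not cell counts: haploid sperm contribute half
#' the DNA per cell of diploid types).
#'
#' @param sample_levels named numeric vector (site id -> level; `NA`s
#'   dropped).
#' @param reference a `reference_methylome`.
#' @param normalize rescale the weights to sum to one (default `TRUE`).
#' @param min_shared minimum shared sites required (default 50).
#' @return list with `fractions` (normalized if requested), `raw_weights`,
#'   `residual` (the Euclidean residual norm) and `n_shared`.
#' @export
deconvolve_sample <- function(sample_levels, reference, normalize = TRUE,
                              min_shared = 50) {
  stopifnot(inherits(reference, "reference_methylome"))
  sample_levels <- sample_levels[!is.na(sample_levels)]
  shared <- intersect(names(sample_levels), rownames(reference$values))
  if (length(shared) < min_shared) {
    stop_data(sprintf("only %d site(s) shared with the reference (need >= %d)",
                      length(shared), min_shared))
  }
  R <- reference$values[shared, , drop = FALSE]
  m <- as.numeric(sample_levels[shared])
  sol <- pracma::lsqnonneg(R, m)
  w <- stats::setNames(sol$x, colnames(R))
  residual <- sqrt(max(sol$resid.norm, 0))
  fractions <- w
  if (normalize) {
    if (sum(w) <= 0) {
      stop_data("degenerate deconvolution fit: all cell-type weights are zero")
    }
    fractions <- w / sum(w)
  }
  list(fractions = fractions, raw_weights = w, residual = residual,
       n_shared = length(shared))
}

#' Deconvolve every sample of a methylation matrix
#'
#' Row-wise application of [deconvolve_sample()]. The result is a tibble of
#' class `cell_composition` with one row per sample, one column per cell
#' type (summing to one per sample when `normalize = TRUE`) and the
#' per-sample residual norm; raw NNLS weights are kept in the
#' `"raw_weights"` attribute.
#'
#' @inheritParams deconvolve_sample
#' @param m a [methylation_matrix()].
#' @return A `cell_composition` tibble.
#' @export
deconvolve_all <- function(m, reference, normalize = TRUE, min_shared = 50) {
  stopifnot(inherits(m, "methylation_matrix"))
  samples <- rownames(m$values)
  fits <- purrr::map(samples, function(s) {
    tryCatch(
      deconvolve_sample(m$values[s, ], reference, normalize = normalize,
                        min_shared = min_shared),
      error = function(e) {
        abort(paste0("sample '", s, "': ", conditionMessage(e)),
              class = class(e)[1])
      }
    )
  })
  frac <- do.call(rbind, purrr::map(fits, "fractions"))
  raw <- do.call(rbind, purrr::map(fits, "raw_weights"))
  rownames(raw) <- samples
  out <- dplyr::bind_cols(
    tibble(sample_id = samples),
    as_tibble(frac),
    tibble(residual = purrr::map_dbl(fits, "residual"),
           n_shared = purrr::map_int(fits, "n_shared"))
  )
  structure(out, class = c("cell_composition", class(out)),
            raw_weights = raw,
            cell_types = colnames(reference$values))
}

#' Cell types of a composition table
#' @param composition a `cell_composition` tibble.
#' @return character vector of cell-type column names.
#' @export
cell_types <- function(composition) attr(composition, "cell_types")

#' Stacked-bar plot of per-sample cell-type composition
#' @param object a `cell_composition` tibble from [deconvolve_all()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cell_composition <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              cols = dplyr::all_of(cell_types(object)),
                              names_to = "cell_type", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                                     fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "estimated DNA fraction", fill = "cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
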