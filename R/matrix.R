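#' Construct a methylation matrix object
#'
#' Light container for a samples-by-sites matrix of methylation fractions
#' with optional per-entry read coverage. Values are fractions in `[0, 1]`
#' (or `NA` where coverage was insufficient); row names are sample ids and
#' column names are `"chrom:pos"` site ids.
#'
#' @param values numeric matrix, samples x sites, with dimnames.
#' @param coverage optional integer matrix of the same shape.
#' @return An object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(values, coverage = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop_data("duplicate sample or site labels in methylation matrix")
  }
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop_data("methylation values outside [0, 1]")
  }
  if (!is.null(coverage)) {
    stopifnot(identical(dim(coverage), dim(values)))
    dimnames(coverage) <- dimnames(values)
  }
  structure(
    list(values = values, coverage = coverage,
         sites = parse_site_id(colnames(values))),
    class = "methylation_matrix"
  )
}

#' @export
dim.methylation_matrix <- function(x) dim(x$values)

#' @export
print.methylation_matrix <- function(x, ...) {
  d <- dim(x$values)
  n_missing <- sum(is.na(x$values))
  cat(sprintf("<methylation_matrix> %d samples x %d CpG sites (%d missing entries)\n",
              d[1], d[2], n_missing))
  invisible(x)
}

#' @rdname methylation_matrix
#' @param x a `methylation_matrix`.
#' @param ... unused.
#' @return For `as_tibble()`: a long tibble with one row per (sample, site).
#' @export
as_tibble.methylation_matrix <- function(x, ...) {
  out <- tibble(
    sample_id = rep(rownames(x$values), times = ncol(x$values)),
    site_id = rep(colnames(x$values), each = nrow(x$values)),
    level = as.vector(x$values)
  )
  if (!is.null(x$coverage)) out$coverage <- as.vector(x$coverage)
  out
}

#' Assemble a coverage-filtered methylation matrix from per-sample calls
#'
#' Builds the samples-by-sites matrix of methylation fractions from CGmap
#' records (as returned by [read_cgmap()]). An entry is kept when its total
#' read count reaches `min_coverage`, otherwise it is recorded as missing
#' (to be imputed later, see [knn_impute()]); recording low-coverage calls
#' as zero would bias the matrix toward hypomethylation. Sites outside the
#' capture panel are dropped, as are sites missing in every sample. Rows are
#' sorted by sample id and columns by (chromosome, position) so downstream
#' fits are deterministic.
#'
#' @param records_by_sample named list (sample id -> CGmap record tibble).
#' @param min_coverage minimum total read count for a call to be retained
#'   (default 40, the usual floor for targeted bisulfite panels).
#' @param panel optional site panel: a tibble with `chrom`/`pos`, a character
#'   vector of `"chrom:pos"` ids, or `NULL` for the union of observed sites.
#' @return A [methylation_matrix()] with `NA` at sub-threshold entries.
#' @export
aggregate_matrix <- function(records_by_sample, min_coverage = 40,
                             panel = NULL) {
  if (!is.list(records_by_sample) || length(records_by_sample) == 0 ||
      is.null(names(records_by_sample)) ||
      any(!nzchar(names(records_by_sample)))) {
    stop_config("records_by_sample must be a non-empty named list")
  }
  if (min_coverage < 1) stop_config("min_coverage must be >= 1")

  samples <- sort(names(records_by_sample))
  observed <- unique(unlist(lapply(records_by_sample,
                                   function(r) r$site_id), use.names = FALSE))
  if (is.null(panel)) {
    panel_ids <- observed
  } else if (is.character(panel)) {
    panel_ids <- unique(panel)
  } else {
    stopifnot(all(c("chrom", "pos") %in% names(panel)))
    panel_ids <- unique(site_id(panel$chrom, panel$pos))
  }
  keep_ids <- intersect(panel_ids, observed)
  if (length(keep_ids) == 0) {
    stop_data("no overlap between the site panel and the observed sites")
  }
  sites <- parse_site_id(keep_ids)
  sites <- sites[site_order(sites$chrom, sites$pos), ]

  values <- matrix(NA_real_, nrow = length(samples), ncol = nrow(sites),
                   dimnames = list(samples, sites$site_id))
  coverage <- matrix(0L, nrow = length(samples), ncol = nrow(sites),
                     dimnames = list(samples, sites$site_id))
  for (s in samples) {
    rec <- records_by_sample[[s]]
    rec <- rec[rec$site_id %in% sites$site_id, ]
    if (nrow(rec) == 0) next
    coverage[s, rec$site_id] <- rec$total_reads
    ok <- rec$total_reads >= min_coverage
    values[s, rec$site_id[ok]] <- rec$meth_reads[ok] / rec$total_reads[ok]
  }

  keep_col <- colSums(!is.na(values)) > 0
  if (!any(keep_col)) {
    stop_data("every panel site falls below the coverage threshold in all samples")
  }
  methylation_matrix(values[, keep_col, drop = FALSE],
                     coverage[, keep_col, drop = FALSE])
}

#' Impute missing methylation values by k nearest neighbours
#'
#' Fills each missing entry from the `k` most similar samples: distances
#' between samples are Euclidean over their mutually non-missing sites, and
#' a missing value at site j is the mean of the k nearest samples that have
#' an observed value at j (fewer are used if fewer are available). Observed
#' entries are never modified.
#'
#' @param m a [methylation_matrix()] (or bare samples-by-sites matrix).
#' @param k number of neighbours (default 5); must be below the sample count.
#' @return The matrix with no missing values, same class as the input.
#' @export
knn_impute <- function(m, k = 5) {
  is_obj <- inherits(m, "methylation_matrix")
  values <- if (is_obj) m$values else m
  n <- nrow(values)
  if (k < 1) stop_config("k must be >= 1")
  if (k >= n) stop_config(sprintf("k (%d) must be smaller than the number of samples (%d)", k, n))
  miss <- which(is.na(values), arr.ind = TRUE)
  if (nrow(miss) == 0) return(m)
  if (any(colSums(!is.na(values)) == 0)) {
    stop_data("cannot impute: some site has no observed value in any sample")
  }

  # Pairwise sample distances over mutually observed sites.
  dist_mat <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- !is.na(values[i, ]) & !is.na(values[j, ])
      if (any(shared)) {
        d <- sqrt(sum((values[i, shared] - values[j, shared])^2))
        dist_mat[i, j] <- d
        dist_mat[j, i] <- d
      }
    }
  }

  filled <- values
  for (idx in seq_len(nrow(miss))) {
    i <- miss[idx, 1]; j <- miss[idx, 2]
    donors <- which(!is.na(values[, j]))
    ord <- donors[order(dist_mat[i, donors], donors)]
    use <- ord[seq_len(min(k, length(ord)))]
    filled[i, j] <- mean(values[use, j])
  }
  filled <- clamp01(filled)
  if (is_obj) methylation_matrix(filled, m$coverage) else filled
}

#' Write / read a methylation or reference matrix as TSV
#'
#' Sites as rows (first column `site_id`, formatted `"chrom:pos"`), samples
#' or cell types as columns; missing values written as `NA`.
#'
#' @param m a [methylation_matrix()] or a sites-in-columns numeric matrix.
#' @param path output path.
#' @return `path` invisibly; for the reader, a [methylation_matrix()].
#' @export
write_methylation_matrix <- function(m, path) {
  values <- if (inherits(m, "methylation_matrix")) m$values else m
  df <- tibble(site_id = colnames(values))
  df <- dplyr::bind_cols(df, as_tibble(t(values)))
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

#' @rdname write_methylation_matrix
#' @export
read_methylation_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  values <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(values) <- df$site_id
  methylation_matrix(values)
}

#' Export CpG sites as a BED file
#'
#' Writes 0-based half-open intervals of length two covering each CpG
#' dinucleotide, with the coefficient sign (`"pos"`/`"neg"`) in the fourth
#' column, sorted lexicographically by chromosome then start.
#'
#' @param sites character vector of `"chrom:pos"` ids or a tibble with
#'   `chrom`/`pos` columns.
#' @param signs per-site labels (recycled if length 1).
#' @param path output path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' write_sites_bed("chr1:100", "neg", f)
#' readLines(f)  # "chr1\t99\t101\tneg"
#' @export
write_sites_bed <- function(sites, signs, path) {
  if (is.character(sites)) sites <- parse_site_id(sites)
  if (nrow(sites) == 0) stop_data("no sites to export")
  signs <- rep_len(signs, nrow(sites))
  ord <- order(sites$chrom, sites$pos, method = "radix")
  lines <- sprintf("%s\t%d\t%d\t%s",
                   sites$chrom[ord], sites$pos[ord] - 1L, sites$pos[ord] + 1L,
                   signs[ord])
  writeLines(lines, path)
  invisible(path)
}
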