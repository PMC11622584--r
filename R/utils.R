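#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Condition helpers: every user-facing failure carries a class so callers
# (and the pipeline driver) can distinguish bad files from bad configuration.
stop_parse <- function(msg, ...) abort(msg, class = "semenmeth_parse_error", ...)
stop_data <- function(msg, ...) abort(msg, class = "semenmeth_data_error", ...)
stop_config <- function(msg, ...) abort(msg, class = "semenmeth_config_error", ...)

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Split a "chrom:pos" site id into its components
#' @param id character vector of site ids
#' @return tibble with columns `chrom`, `pos`, `site_id`
#' @keywords internal
parse_site_id <- function(id) {
  chrom <- sub(":[0-9]+$", "", id)
  pos <- as.integer(sub("^.*:", "", id))
  if (anyNA(pos)) stop_data("malformed site id(s); expected 'chrom:pos'")
  tibble(site_id = id, chrom = chrom, pos = pos)
}

site_id <- function(chrom, pos) paste0(chrom, ":", pos)

# Natural chromosome order: chr2 before chr10, numbered before named (X, Y, M).
chrom_order_key <- function(chrom) {
  stripped <- sub("^chr", "", chrom, ignore.case = TRUE)
  num <- suppressWarnings(as.integer(stripped))
  num[is.na(num)] <- 1000L
  order(num, stripped, method = "radix")
}

# Order of (chrom, pos) pairs under natural chromosome ordering.
site_order <- function(chrom, pos) {
  stripped <- sub("^chr", "", chrom, ignore.case = TRUE)
  num <- suppressWarnings(as.integer(stripped))
  num[is.na(num)] <- 1000L
  order(num, stripped, pos, method = "radix")
}

# Pearson r and its two-sided t-test p-value on n - 2 df. Returns NA r (and
# p) when either vector has zero variance rather than silently reporting 0.
pearson_stats <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}
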