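#' Read a CGmap methylation-call file
#'
#' Parses the tab-delimited CGmap format emitted by bisulfite callers
#' (BSBolt / BS-Seeker2 dialect): chrom, nucleotide (C/G), 1-based position,
#' context (CG/CHG/CHH), dinucleotide sub-context, methylation ratio,
#' methylated read count, total read count. The 7-column variant without the
#' sub-context column is also accepted.
#'
#' Calls on the G strand are folded onto the C-strand coordinate of the CpG
#' dinucleotide (position minus one) and read counts are summed per CpG, so
#' one record per symmetric CpG site is returned. The methylation level is
#' always recomputed from the counts; the ratio column is only checked for
#' consistency (a warning is raised if any line disagrees by more than
#' `ratio_tolerance`).
#'
#' @param path path to a CGmap file (plain text, optionally absent header).
#' @param context_filter methylation context to retain (default `"CG"`).
#' @param merge_strands fold G-strand calls onto the C strand and sum counts
#'   per CpG dinucleotide (default `TRUE`).
#' @param ratio_tolerance maximum tolerated difference between the file's
#'   ratio column and `meth_reads / total_reads` before a warning.
#' @return A tibble with one row per retained site: `chrom`, `pos`,
#'   `site_id`, `meth_reads`, `total_reads`, `level`.
#' @examples
#' f <- tempfile(fileext = ".cgmap")
#' writeLines("chr1\tC\t100\tCG\tCG\t0.8\t8\t10", f)
#' read_cgmap(f)
#' @export
read_cgmap <- function(path, context_filter = "CG", merge_strands = TRUE,
                       ratio_tolerance = 1e-3) {
  if (!file.exists(path)) stop_data(paste0("CGmap file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop_data(paste0("empty CGmap file: ", path))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 8L & nf != 7L)
  if (length(bad) > 0) {
    stop_parse(sprintf(
      "malformed CGmap line %d in %s: expected 7 or 8 tab-separated columns, found %d",
      bad[1], path, nf[bad[1]]
    ))
  }
  # 7-column dialect lacks the dinucleotide sub-context column.
  get_col <- function(i8, i7) {
    vapply(seq_along(fields), function(j) {
      f <- fields[[j]]
      if (length(f) == 8L) f[i8] else f[i7]
    }, character(1))
  }
  chrom <- get_col(1L, 1L)
  nuc <- get_col(2L, 2L)
  pos_chr <- get_col(3L, 3L)
  context <- get_col(4L, 4L)
  ratio_chr <- get_col(6L, 5L)
  meth_chr <- get_col(7L, 6L)
  total_chr <- get_col(8L, 7L)

  check_int <- function(x, what) {
    v <- suppressWarnings(as.integer(x))
    num <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) | is.na(num) | num != v)
    if (length(bad) > 0) {
      stop_parse(sprintf("malformed CGmap line %d in %s: non-integer %s '%s'",
                         bad[1], path, what, x[bad[1]]))
    }
    v
  }
  pos <- check_int(pos_chr, "position")
  meth <- check_int(meth_chr, "methylated read count")
  total <- check_int(total_chr, "total read count")
  ratio <- suppressWarnings(as.numeric(ratio_chr))

  if (any(pos < 1L)) {
    stop_parse(sprintf("malformed CGmap line %d in %s: position < 1",
                       which(pos < 1L)[1], path))
  }
  over <- which(meth > total)
  if (length(over) > 0) {
    stop_data(sprintf(
      "CGmap line %d in %s: methylated reads (%d) exceed total reads (%d)",
      over[1], path, meth[over[1]], total[over[1]]
    ))
  }
  if (any(total < 1L)) {
    stop_data(sprintf("CGmap line %d in %s: total reads < 1",
                      which(total < 1L)[1], path))
  }

  keep <- context == context_filter
  chrom <- chrom[keep]; nuc <- nuc[keep]; pos <- pos[keep]
  meth <- meth[keep]; total <- total[keep]; ratio <- ratio[keep]
  if (length(pos) == 0) {
    return(tibble(chrom = character(), pos = integer(), site_id = character(),
                  meth_reads = integer(), total_reads = integer(),
                  level = numeric()))
  }

  level <- meth / total
  off <- is.finite(ratio) & abs(ratio - level) > ratio_tolerance
  if (any(off)) {
    warn(sprintf(
      "%d CGmap line(s) in %s have a ratio column inconsistent with the read counts; levels recomputed from counts",
      sum(off), path
    ))
  }

  rec <- tibble(chrom = chrom, pos = pos, nuc = nuc,
                meth_reads = meth, total_reads = total)
  if (merge_strands) {
    # Symmetric CpG methylation: a G-strand call at pos belongs to the CpG
    # whose cytosine sits at pos - 1 on the forward strand.
    rec$pos <- ifelse(rec$nuc == "G", rec$pos - 1L, rec$pos)
    rec <- rec %>%
      dplyr::group_by(.data$chrom, .data$pos) %>%
      dplyr::summarise(meth_reads = sum(.data$meth_reads),
                       total_reads = sum(.data$total_reads),
                       .groups = "drop")
  } else {
    rec$nuc <- NULL
    rec <- dplyr::distinct(rec)
  }
  rec <- rec[site_order(rec$chrom, rec$pos), ]
  rec %>%
    dplyr::mutate(site_id = site_id(.data$chrom, .data$pos),
                  level = .data$meth_reads / .data$total_reads) %>%
    dplyr::select("chrom", "pos", "site_id", "meth_reads", "total_reads",
                  "level")
}

#' Write per-site methylation calls as a CGmap file
#'
#' Emits one forward-strand (`C`) line per CpG site in the 8-column CGmap
#' layout consumed by [read_cgmap()].
#'
#' @param records tibble with `chrom`, `pos`, `meth_reads`, `total_reads`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cgmap <- function(records, path) {
  stopifnot(all(c("chrom", "pos", "meth_reads", "total_reads") %in%
                  names(records)))
  ord <- site_order(records$chrom, records$pos)
  records <- records[ord, ]
  lines <- sprintf("%s\tC\t%d\tCG\tCG\t%.6g\t%d\t%d",
                   records$chrom, records$pos,
                   records$meth_reads / records$total_reads,
                   records$meth_reads, records$total_reads)
  writeLines(lines, path)
  invisible(path)
}
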