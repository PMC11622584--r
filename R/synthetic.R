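#' Configuration for the synthetic methylome cohort generator
#'
#' Bundles every knob of the generator: cohort size, panel size, cell
#' types and their reference distinctness, the composition sampler, the
#' age and batch effects planted into the methylomes, and the read-noise
#' model. Defaults emulate a semen-like targeted bisulfite study: 40
#' samples, ages 27-62 years, two collection batches, mean read coverage
#' 74 with a retention floor of 40, sperm-dominant DNA mixtures over four
#' reference cell types with mean pairwise methylation distinctness 0.3,
#' and 200 predominantly demethylating age-associated sites spanning 0.1
#' methylation across the age range.
#'
#' @param profile `"semen"` (sperm-dominant mixtures) or `"buccal"`
#'   (epithelial-dominant mixtures).
#' @param n_samples cohort size.
#' @param n_sites CpG panel size.
#' @param cell_types reference cell-type names; `NULL` for the profile
#'   default.
#' @param delta required mean absolute methylation difference between any
#'   two reference cell-type columns.
#' @param age_range closed interval of ages (years) sampled uniformly.
#' @param n_age_sites number of sites with a planted linear age effect.
#' @param age_slope methylation change per scaled age unit at planted
#'   sites (magnitude used; negative default = demethylation with age).
#' @param frac_age_positive fraction of planted age sites given a
#'   positive (gaining) slope instead.
#' @param n_batch_sites,batch_shift sites and additive shift of the
#'   planted two-batch technical effect.
#' @param mean_coverage Poisson mean read depth per site.
#' @param coverage_floor minimum depth for a call to enter the matrix.
#' @param noise `"binomial"` (read sampling), `"gaussian"` (additive
#'   jitter of sd `jitter_sd`, then quantised to read counts) or
#'   `"none"`.
#' @param jitter_sd sd of the Gaussian jitter (used when
#'   `noise = "gaussian"`).
#' @param n_azoospermic number of samples generated with zero weight on
#'   the dominant cell type (semen profile: azoospermia-like).
#' @param seed integer seed; fully determines the generator's output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(profile = c("semen", "buccal"),
                              n_samples = 40, n_sites = 2000,
                              cell_types = NULL, delta = 0.3,
                              age_range = c(27, 62),
                              n_age_sites = 200, age_slope = -0.1,
                              frac_age_positive = 0.25,
                              n_batch_sites = 100, batch_shift = 0.05,
                              mean_coverage = 74, coverage_floor = 40,
                              noise = c("binomial", "gaussian", "none"),
                              jitter_sd = 0.03,
                              n_azoospermic = NULL, seed = 1) {
  profile <- match.arg(profile)
  noise <- match.arg(noise)
  if (is.null(cell_types)) {
    cell_types <- switch(profile,
      semen = c("sperm", "prostate_epithelium", "T_lymphocyte", "granulocyte"),
      buccal = c("epithelial", "T_lymphocyte", "granulocyte", "monocyte")
    )
  }
  if (length(cell_types) < 2) stop_config("need at least two cell types")
  if (delta <= 0) stop_config("delta must be positive")
  if (is.null(n_azoospermic)) n_azoospermic <- if (profile == "semen") 1L else 0L
  if (length(age_range) != 2 || diff(age_range) <= 0) {
    stop_config("age_range must be an increasing pair of ages")
  }
  if (mean_coverage < 1 || coverage_floor < 1) {
    stop_config("coverage parameters must be >= 1")
  }
  if (seed < 0 || seed >= 2^31 - 2) stop_config("seed must be in [0, 2^31 - 3]")

  # Reference feasibility: each cell type needs a discriminating block of
  # sites flipped by ~0.85 against all others; a pair's mean |difference|
  # gains ~1.7 * block / n_sites, and neutral sites reserved for planted
  # effects must also fit.
  n_disc <- ceiling(delta * n_sites / 1.6)
  if (length(cell_types) * n_disc + n_age_sites + n_batch_sites > n_sites) {
    stop_config(paste0(
      "delta = ", delta, " is too large for ", n_sites, " sites and ",
      length(cell_types), " cell types (plus planted-effect sites)"
    ))
  }

  structure(
    list(profile = profile, n_samples = as.integer(n_samples),
         n_sites = as.integer(n_sites), cell_types = cell_types,
         delta = delta, n_disc = as.integer(n_disc),
         age_range = as.numeric(age_range),
         n_age_sites = as.integer(n_age_sites), age_slope = age_slope,
         frac_age_positive = frac_age_positive,
         n_batch_sites = as.integer(n_batch_sites),
         batch_shift = batch_shift,
         mean_coverage = mean_coverage,
         coverage_floor = as.integer(coverage_floor),
         noise = noise, jitter_sd = jitter_sd,
         n_azoospermic = as.integer(n_azoospermic),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Synthetic panel coordinates: four chromosome blocks, positions spaced 50 bp,
# emitted already in (chrom, pos) order.
synthetic_panel <- function(n_sites) {
  per <- ceiling(n_sites / 4)
  chrom <- rep(paste0("chr", 1:4), each = per)[seq_len(n_sites)]
  pos <- unlist(lapply(table(factor(chrom, unique(chrom))),
                       function(k) seq(101L, by = 50L, length.out = k)),
                use.names = FALSE)
  tibble(chrom = chrom, pos = as.integer(pos),
         site_id = site_id(chrom, pos))
}

#' Simulate a reference methylome
#'
#' Draws a shared bimodal background profile (CpGs mostly near 0 or 1, as
#' in real methylomes), then gives every cell type a disjoint block of
#' discriminating sites where it is highly methylated and all other types
#' are not, sized so each pair of columns differs by at least `delta` on
#' average. A further block of mid-methylation "neutral" sites, identical
#' across cell types, is reserved for the cohort generator's planted age
#' and batch effects (kept in the `"neutral_sites"` attribute).
#'
#' @param config a [simulation_config()].
#' @return A `reference_methylome` (sites x cell types), deterministic in
#'   `config$seed`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    n <- config$n_sites
    K <- length(config$cell_types)
    panel <- synthetic_panel(n)
    hi <- stats::rbinom(n, 1, 0.5) == 1
    base <- ifelse(hi, stats::rbeta(n, 8, 2), stats::rbeta(n, 2, 8))
    values <- vapply(seq_len(K), function(k) {
      clamp01(base + stats::rnorm(n, 0, 0.02))
    }, numeric(n))
    colnames(values) <- config$cell_types
    rownames(values) <- panel$site_id

    idx <- sample.int(n)
    used <- 0L
    for (k in seq_len(K)) {
      block <- idx[(used + 1):(used + config$n_disc)]
      values[block, ] <- stats::rbeta(length(block) * K, 2, 40)
      values[block, k] <- stats::rbeta(length(block), 40, 2)
      used <- used + config$n_disc
    }
    n_neutral <- config$n_age_sites + config$n_batch_sites
    neutral <- integer(0)
    if (n_neutral > 0) {
      neutral <- idx[(used + 1):(used + n_neutral)]
      mid <- stats::rbeta(n_neutral, 15, 15)
      for (k in seq_len(K)) {
        values[neutral, k] <- clamp01(mid + stats::rnorm(n_neutral, 0, 0.01))
      }
    }

    ref <- reference_methylome(values)
    for (i in seq_len(K - 1)) {
      for (j in (i + 1):K) {
        if (mean(abs(values[, i] - values[, j])) < config$delta) {
          stop_config(sprintf(
            "constructed reference does not reach delta = %.3g between '%s' and '%s'",
            config$delta, config$cell_types[i], config$cell_types[j]
          ))
        }
      }
    }
    attr(ref, "neutral_sites") <- panel$site_id[neutral]
    attr(ref, "discriminating_sites") <- panel$site_id[idx[seq_len(used)]]
    ref
  })
}

# Composition sampler (stick-breaking). Semen profile: the epithelial
# fraction is carved out first from a narrow Beta (prostate shedding varies
# independently of sperm output), then sperm takes a wide Beta share of the
# remainder, and the immune residue is split by a tight Dirichlet. This
# reproduces the correlation regime of real semen mixtures — immune
# fractions tightly inverse to sperm abundance (so the collinearity pruning
# step is exercised) while the epithelial fraction is only moderately
# coupled. Buccal profile: an epithelial-dominant share, immune residue
# split tightly.
simulate_compositions <- function(config) {
  n <- config$n_samples
  types <- config$cell_types
  K <- length(types)
  azoo <- if (config$n_azoospermic > 0) {
    seq(n - config$n_azoospermic + 1, n)
  } else integer(0)
  W <- matrix(0, n, K, dimnames = list(NULL, types))
  if (config$profile == "semen" && K >= 3) {
    epi <- stats::rbeta(n, 3, 15)
    u <- stats::rbeta(n, 2.5, 1)      # sperm share of the non-epithelial DNA
    u[azoo] <- 0
    W[, 1] <- (1 - epi) * u
    W[, 2] <- epi
    resid <- (1 - epi) * (1 - u)
    split_types <- 3:K
  } else {
    dominant <- stats::rbeta(n, 8, 2)
    dominant[azoo] <- 0
    W[, 1] <- dominant
    resid <- 1 - dominant
    split_types <- 2:K
  }
  g <- matrix(stats::rgamma(n * length(split_types), shape = 50), n)
  g <- g / rowSums(g)
  W[, split_types] <- resid * g
  W
}

#' Simulate a synthetic bisulfite cohort
#'
#' Generates per-sample methylomes as DNA mixtures of the reference cell
#' types, injects a linear age effect at the reserved age sites (slope per
#' scaled age unit, predominantly negative) and an additive batch shift at
#' the reserved batch sites, then samples reads: per-entry coverage is
#' Poisson(`mean_coverage`) and methylated reads are Binomial(coverage,
#' mean level) under the default noise model. Entries below the coverage
#' floor are recorded as missing. The full ground truth (compositions,
#' ages, batches, planted sites with slopes and signs) is returned
#' alongside.
#'
#' @param config a [simulation_config()].
#' @param reference optionally a pre-built `reference_methylome` from
#'   [simulate_reference()]; `NULL` simulates one from `config`.
#' @return A `synthetic_cohort` list: `matrix` (a [methylation_matrix()]
#'   with sub-floor entries missing), `meth_reads` / `coverage` count
#'   matrices, `reference`, `truth` (compositions, phenotypes, planted
#'   sites) and `config`.
#' @export
simulate_cohort <- function(config, reference = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(reference)) reference <- simulate_reference(config)
  neutral <- attr(reference, "neutral_sites")
  if (length(neutral) < config$n_age_sites + config$n_batch_sites) {
    stop_config("reference does not reserve enough neutral sites for the planted effects")
  }

  withr::with_seed(config$seed + 1L, {
    n <- config$n_samples
    sites <- rownames(reference$values)
    n_sites <- length(sites)
    sample_ids <- sprintf("S%03d", seq_len(n))

    W <- simulate_compositions(config)
    rownames(W) <- sample_ids
    ages <- round(stats::runif(n, config$age_range[1], config$age_range[2]), 1)
    batch <- sample(rep(c("A", "B"), length.out = n))

    mean_meth <- W %*% t(reference$values)  # n x sites, DNA-weighted mixture

    age_sites <- neutral[seq_len(config$n_age_sites)]
    batch_sites <- neutral[config$n_age_sites + seq_len(config$n_batch_sites)]
    n_pos <- round(config$frac_age_positive * config$n_age_sites)
    slopes <- rep(-abs(config$age_slope), config$n_age_sites)
    if (n_pos > 0) slopes[seq_len(n_pos)] <- abs(config$age_slope)
    scaled_age <- (ages - config$age_range[1]) / diff(config$age_range)
    mean_meth[, age_sites] <- mean_meth[, age_sites] +
      outer(scaled_age, slopes)
    mean_meth[, batch_sites] <- mean_meth[, batch_sites] +
      outer(as.numeric(batch == "B"), rep(config$batch_shift,
                                          config$n_batch_sites))
    mean_meth <- clamp01(mean_meth)

    coverage <- matrix(stats::rpois(n * n_sites, config$mean_coverage),
                       n, n_sites, dimnames = list(sample_ids, sites))
    coverage[coverage < 1L] <- 1L
    level_target <- switch(config$noise,
      binomial = mean_meth,  # noise enters through the binomial draw
      gaussian = clamp01(mean_meth + stats::rnorm(n * n_sites, 0,
                                                  config$jitter_sd)),
      none = mean_meth
    )
    meth <- if (config$noise == "binomial") {
      matrix(stats::rbinom(n * n_sites, coverage, level_target), n, n_sites,
             dimnames = dimnames(coverage))
    } else {
      round(level_target * coverage)
    }
    values <- meth / coverage
    values[coverage < config$coverage_floor] <- NA_real_

    truth <- list(
      composition = dplyr::bind_cols(tibble(sample_id = sample_ids),
                                     as_tibble(W)),
      phenotypes = tibble(sample_id = sample_ids, age = ages, batch = batch,
                          tissue = config$profile,
                          azoospermic = W[, 1] == 0),
      planted = tibble(
        site_id = c(age_sites, batch_sites),
        factor = rep(c("age", "batch"),
                     c(length(age_sites), length(batch_sites))),
        slope = c(slopes, rep(config$batch_shift, length(batch_sites)))
      ) %>%
        dplyr::mutate(sign = ifelse(.data$slope < 0, "neg", "pos"))
    )

    structure(
      list(matrix = methylation_matrix(values, coverage),
           meth_reads = meth, coverage = coverage,
           reference = reference, truth = truth, config = config),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> profile '%s': %d samples x %d sites (seed %d)\n",
    x$config$profile, x$config$n_samples, x$config$n_sites, x$config$seed
  ))
  invisible(x)
}

#' Export a synthetic cohort as on-disk fixtures
#'
#' Writes the formats the analysis pipeline consumes — one CGmap file per
#' sample (every site with at least one read; the coverage floor is applied
#' at matrix aggregation), the phenotype table, the reference methylome
#' matrix, the panel BED — plus the ground-truth tables and a YAML manifest
#' recording the full configuration and seed.
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_fixtures <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "cgmap"), recursive = TRUE, showWarnings = FALSE)
  sites <- parse_site_id(colnames(cohort$coverage))

  for (s in rownames(cohort$coverage)) {
    cov <- cohort$coverage[s, ]
    keep <- cov >= 1L
    rec <- tibble(chrom = sites$chrom[keep], pos = sites$pos[keep],
                  meth_reads = as.integer(cohort$meth_reads[s, keep]),
                  total_reads = as.integer(cov[keep]))
    write_cgmap(rec, file.path(dir, "cgmap", paste0(s, ".cgmap")))
  }

  readr::write_tsv(cohort$truth$phenotypes, file.path(dir, "phenotypes.tsv"))
  ref_df <- dplyr::bind_cols(tibble(site_id = rownames(cohort$reference$values)),
                             as_tibble(cohort$reference$values))
  readr::write_tsv(ref_df, file.path(dir, "reference.tsv"))
  readr::write_tsv(cohort$truth$composition,
                   file.path(dir, "truth_composition.tsv"))
  readr::write_tsv(cohort$truth$planted, file.path(dir, "truth_sites.tsv"))
  write_sites_bed(sites, "panel", file.path(dir, "panel.bed"))
  write_methylation_matrix(cohort$matrix, file.path(dir, "matrix.tsv"))

  cfg <- unclass(cohort$config)
  yaml::write_yaml(cfg, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a reference methylome matrix written by [export_fixtures()]
#' @param path TSV with a `site_id` column and one column per cell type.
#' @return A `reference_methylome`.
#' @export
read_reference_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$site_id
  reference_methylome(values)
}
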