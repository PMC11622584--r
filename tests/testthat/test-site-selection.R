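fake_scores <- function(df) {
  structure(tibble::as_tibble(df),
            class = c("site_scores", class(tibble::tibble())))
}

# A small planted scenario: two real factors, known argmax assignments.
two_factor_scores <- function() {
  fake_scores(tibble::tibble(
    site_id = rep(sprintf("chr1:%d", 1:6 * 10), each = 2),
    factor = rep(c("age", "sperm"), 6),
    coefficient = c(-0.4, 0.1,   # s1: age wins, negative
                    0.3, -0.1,   # s2: age wins, positive
                    0.1, 0.5,    # s3: sperm wins
                    -0.2, 0.1,   # s4: age wins but r_site below cut
                    0.25, 0.1,   # s5: age wins but q above cut
                    0, -0.3),    # s6: sperm wins
    p_value = rep(0.001, 12),
    q_value = c(0.01, 0.01, 0.02, 0.02, 0.01, 0.01,
                0.001, 0.001, 0.2, 0.01, 0.01, 0.01),
    r_site = rep(c(0.9, 0.8, 0.7, 0.49, 0.6, -0.55), each = 2),
    eligible = TRUE
  ))
}

test_that("the three filters are enforced, including the |r| >= 0.5 boundary", {
  sel <- select_sites(two_factor_scores(), "age")
  expect_setequal(sel$sites$site_id, c("chr1:10", "chr1:20"))
  # chr1:40 fails filter 1 at r = 0.49 despite q = 0.001
  expect_false("chr1:40" %in% sel$sites$site_id)
  # chr1:50 fails filter 2 (q = 0.2)
  expect_false("chr1:50" %in% sel$sites$site_id)
  # chr1:30 fails filter 3 (sperm coefficient larger)
  expect_false("chr1:30" %in% sel$sites$site_id)
  expect_equal(sel$sites$sign[sel$sites$site_id == "chr1:10"], "neg")
  expect_equal(sel$sites$sign[sel$sites$site_id == "chr1:20"], "pos")
})

test_that("a site is assigned to at most one factor (argmax exclusivity)", {
  sc <- two_factor_scores()
  sel_age <- select_sites(sc, "age", r_min = 0, q_max = 1)
  sel_sperm <- select_sites(sc, "sperm", r_min = 0, q_max = 1)
  expect_length(intersect(sel_age$sites$site_id, sel_sperm$sites$site_id), 0)
  expect_setequal(c(sel_age$sites$site_id, sel_sperm$sites$site_id),
                  unique(sc$site_id))
})

test_that("filter application order does not change the selected set", {
  sc <- two_factor_scores()
  sel <- select_sites(sc, "age")
  assigned <- tapply(seq_len(nrow(sc)), sc$site_id, function(i) {
    sc$factor[i][which.max(abs(sc$coefficient[i]))]
  })
  f1 <- function(ids) ids[abs(sc$r_site[match(ids, sc$site_id)]) >= 0.5]
  f2 <- function(ids) {
    q <- sc$q_value[sc$factor == "age"][match(ids, sc$site_id[sc$factor == "age"])]
    ids[q <= 0.05]
  }
  f3 <- function(ids) ids[assigned[ids] == "age"]
  orders <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  filters <- list(f1, f2, f3)
  for (ord in orders) {
    ids <- unique(sc$site_id)
    for (k in ord) ids <- filters[[k]](ids)
    expect_setequal(ids, sel$sites$site_id)
  }
})

test_that("tightening thresholds never adds sites", {
  sc <- two_factor_scores()
  base <- select_sites(sc, "age", r_min = 0.3, q_max = 0.1)$sites$site_id
  tighter_r <- select_sites(sc, "age", r_min = 0.6, q_max = 0.1)$sites$site_id
  tighter_q <- select_sites(sc, "age", r_min = 0.3, q_max = 0.01)$sites$site_id
  expect_true(all(tighter_r %in% base))
  expect_true(all(tighter_q %in% base))
})

test_that("unknown or nuisance factors are rejected", {
  sc <- two_factor_scores()
  expect_error(select_sites(sc, "bmi"), class = "semenmeth_config_error")
  sc2 <- sc
  sc2$eligible[sc2$factor == "sperm"] <- FALSE
  expect_error(select_sites(sc2, "sperm"), class = "semenmeth_config_error")
})

test_that("BH adjustment matches the analytic step-up case", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(stats::p.adjust(p, method = "BH"), rep(0.04, 4))
  expect_equal(bh_bruteforce(p), rep(0.04, 4))
})

test_that("per-site scores: a noiseless planted site has r_site 1 and a tiny p-value", {
  withr::with_seed(30, {
    n <- 40
    X <- cbind(constant = 1, age = runif(n), other = runif(n))
    rownames(X) <- sprintf("S%03d", 1:n)
    M <- matrix(runif(n * 50, 0.3, 0.7), n, 50)
    M[, 1] <- 0.5 - 0.3 * X[, "age"]           # pure age site
    dimnames(M) <- list(rownames(X), paste0("chr1:", 1:50 * 10))
    fit <- mf_fit(M, X)
    sc <- score_sites(fit)
    s1 <- dplyr::filter(sc, site_id == "chr1:10", factor == "age")
    expect_equal(s1$r_site, 1, tolerance = 1e-8)
    expect_lt(s1$p_value, 1e-6)
    expect_lt(abs(s1$coefficient - (-0.3)), 1e-8)
    # adjusted never below raw
    expect_true(all(sc$q_value >= sc$p_value - 1e-15))
    # per-site OLS p-values agree with lm() on a spot-checked site
    lm_fit <- summary(stats::lm(M[, 7] ~ X[, "age"] + X[, "other"]))
    s7 <- dplyr::filter(sc, site_id == "chr1:70", factor == "age")
    expect_equal(s7$p_value, lm_fit$coefficients["X[, \"age\"]", 4],
                 tolerance = 1e-10)
  })
})

test_that("pure-noise matrices yield no BH-significant sites in most seeds", {
  hits <- vapply(1:10, function(s) {
    withr::with_seed(300 + s, {
      n <- 40
      X <- cbind(constant = 1, age = runif(n), comp = runif(n))
      rownames(X) <- sprintf("S%03d", 1:n)
      M <- matrix(rbeta(n * 500, 2, 2), n, 500,
                  dimnames = list(rownames(X), paste0("chr1:", 1:500 * 10)))
      sc <- score_sites(mf_fit(M, X))
      sum(sc$q_value[sc$factor == "age"] <= 0.05)
    })
  }, numeric(1))
  expect_gte(sum(hits == 0), 9)
})

test_that("planted age sites are recovered with correct signs and the cap binds", {
  cfg <- simulation_config(n_samples = 60, n_sites = 1500, n_age_sites = 50,
                           age_slope = -0.15, frac_age_positive = 0.4,
                           n_batch_sites = 40, noise = "gaussian",
                           jitter_sd = 0.03, n_azoospermic = 0, seed = 33)
  co <- simulate_cohort(cfg)
  m <- knn_impute(co$matrix, 5)
  comp <- deconvolve_all(m, co$reference)
  fm <- build_factor_matrix(co$truth$phenotypes[, c("sample_id", "age", "batch")],
                            comp, pinned = c("age", "sperm"))
  fit <- mf_fit(m, fm)
  sel <- select_sites(score_sites(fit), "age")

  planted <- dplyr::filter(co$truth$planted, factor == "age")
  hits <- dplyr::inner_join(sel$sites, planted, by = "site_id")
  expect_gte(nrow(hits) / nrow(planted), 0.9)     # sensitivity
  expect_gte(nrow(hits) / nrow(sel$sites), 0.9)   # precision
  expect_equal(hits$sign.x, hits$sign.y)          # signs match the truth
  expect_equal(sum(planted$sign == "neg") > sum(planted$sign == "pos"), TRUE)

  # cap binds when more pass the filters than the cap allows
  sel_capped <- select_sites(score_sites(fit), "age", cap = 10)
  expect_equal(sel_capped$n_selected, 10)
  expect_gte(sel_capped$n_pre_cap, nrow(hits))
  expect_true(all(sel_capped$sites$site_id %in% sel$sites$site_id[1:20]))
})
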