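random_design <- function(n, p, seed) {
  withr::with_seed(seed, {
    X <- cbind(1, matrix(runif(n * (p - 1)), n, p - 1))
    colnames(X) <- c("constant", paste0("f", seq_len(p - 1)))
    rownames(X) <- sprintf("S%03d", seq_len(n))
    X
  })
}

test_that("pseudoinverse of an orthonormal design is its transpose", {
  withr::with_seed(1, {
    Q <- qr.Q(qr(matrix(rnorm(30 * 3), 30, 3)))
    rownames(Q) <- sprintf("S%03d", 1:30)
    colnames(Q) <- paste0("f", 1:3)
    M <- matrix(runif(30 * 10), 30, 10,
                dimnames = list(rownames(Q), paste0("chr1:", 1:10 * 100)))
    fit <- mf_fit(M, Q)
    expect_equal(unname(fit$beta), unname(t(Q) %*% M), tolerance = 1e-12)
  })
})

test_that("pseudoinverse fit matches per-site normal-equation OLS on full-rank designs", {
  X <- random_design(50, 5, seed = 2)
  withr::with_seed(3, {
    M <- matrix(runif(50 * 500), 50, 500,
                dimnames = list(rownames(X), paste0("chr1:", 1:500 * 10)))
  })
  fit <- mf_fit(M, X)
  beta_ols <- ols_per_site(X, M)
  expect_lt(max(abs(fit$beta - beta_ols)), 1e-8)
  expect_equal(fit$M_pred, X %*% fit$beta)
})

test_that("noiseless data with full-row-rank coefficients gives exact reverse prediction", {
  withr::with_seed(4, {
    X <- random_design(30, 4, seed = 7)
    beta_true <- matrix(rnorm(4 * 60), 4, 60)
    M <- X %*% beta_true
    M <- (M - min(M)) / diff(range(M))  # keep within [0,1]
    colnames(M) <- paste0("chr1:", 1:60 * 10)
    fit <- mf_fit(M, X)
    expect_equal(unname(fit$X_pred), unname(X), tolerance = 1e-8)
  })
})

test_that("the fitted coefficients are least-squares optimal", {
  X <- random_design(25, 4, seed = 8)
  withr::with_seed(9, {
    M <- matrix(runif(25 * 40), 25, 40,
                dimnames = list(rownames(X), paste0("chr1:", 1:40 * 10)))
    fit <- mf_fit(M, X)
    obj <- norm(X %*% fit$beta - M, "F")
    for (i in 1:100) {
      B <- fit$beta + matrix(rnorm(length(fit$beta), 0, 0.05), nrow(fit$beta))
      expect_lte(obj, norm(X %*% B - M, "F") + 1e-12)
    }
  })
})

test_that("a rank-deficient design returns the minimum-norm solution", {
  withr::with_seed(10, {
    base <- random_design(20, 3, seed = 11)
    X <- cbind(base, dup = base[, 3])  # duplicated column -> rank 3
    M <- matrix(runif(20 * 30), 20, 30,
                dimnames = list(rownames(X), paste0("chr1:", 1:30 * 10)))
    fit <- mf_fit(M, X)
    # null space of X contains (0, 0, 1, -1); adding it must raise the norm
    null_vec <- c(0, 0, 1, -1)
    expect_lt(max(abs(X %*% null_vec)), 1e-10)
    for (a in c(-0.5, 0.1, 1)) {
      alt <- fit$beta + a * null_vec %*% t(rep(1, 30))
      expect_lte(norm(fit$beta, "F"), norm(alt, "F") + 1e-12)
      expect_equal(X %*% alt, fit$M_pred, tolerance = 1e-8)
    }
  })
})

test_that("degenerate inputs raise typed errors", {
  X <- random_design(10, 3, seed = 12)
  M <- matrix(runif(30), 10, 3,
              dimnames = list(rownames(X), paste0("chr1:", 1:3 * 10)))
  M_na <- M; M_na[1, 1] <- NA
  expect_error(mf_fit(M_na, X), class = "semenmeth_data_error")
  expect_error(mf_fit(M[1:2, ], X[1:2, ]), class = "semenmeth_data_error")
  X1 <- matrix(1, 10, 1, dimnames = list(rownames(X), "constant"))
  expect_error(mf_fit(M, X1), class = "semenmeth_data_error")
})

test_that("correlated factors are pruned, duplicates first, with pinned factors kept", {
  withr::with_seed(13, {
    ph <- tibble::tibble(
      sample_id = sprintf("S%02d", 1:30),
      age = runif(30, 27, 62),
      batch = rep(c("A", "B"), 15),
      f1 = runif(30)
    )
    ph$f2 <- ph$f1  # perfect duplicate
    fm <- build_factor_matrix(ph, factors = c("age", "f1", "f2"),
                              prune_threshold = 0.95)
    expect_equal(nrow(fm$pruned), 1)
    expect_true(fm$pruned$factor %in% c("f1", "f2"))
    expect_equal(sum(c("f1", "f2") %in% colnames(fm$X)), 1)
    expect_true(all(c("constant", "age", "batch") %in% colnames(fm$X)))
    expect_equal(unname(fm$X[, "constant"]), rep(1, 30))
    expect_setequal(unique(fm$X[, "batch"]), c(0, 1))
    # scaling bookkeeping
    expect_equal(range(fm$X[, "age"]), c(0, 1))
    expect_equal(fm$scaling$min[fm$scaling$factor == "age"], min(ph$age))
  })
})

test_that("constant factors and sample mismatches are rejected", {
  ph <- tibble::tibble(sample_id = sprintf("S%02d", 1:10),
                       age = rep(40, 10), batch = rep(c("A", "B"), 5))
  expect_error(build_factor_matrix(ph, factors = "age"),
               class = "semenmeth_config_error")
  expect_error(build_factor_matrix(ph, factors = "bmi"),
               class = "semenmeth_config_error")
})

test_that("semen-like compositions prune immune factors but keep pinned sperm and age", {
  cfg <- simulation_config(seed = 17)
  co <- simulate_cohort(cfg)
  comp <- co$truth$composition
  comp_cc <- structure(comp, cell_types = setdiff(names(comp), "sample_id"))
  fm <- build_factor_matrix(co$truth$phenotypes[, c("sample_id", "age", "batch")],
                            comp_cc, pinned = c("age", "sperm"))
  expect_setequal(colnames(fm$X),
                  c("constant", "age", "sperm", "prostate_epithelium", "batch"))
  expect_setequal(fm$pruned$factor, c("T_lymphocyte", "granulocyte"))
})

test_that("LOOCV recovers planted factors nearly perfectly in the noiseless limit", {
  cfg <- simulation_config(n_samples = 30, n_sites = 800, n_age_sites = 120,
                           n_batch_sites = 30, noise = "none",
                           n_azoospermic = 0, seed = 19)
  co <- simulate_cohort(cfg)
  m <- knn_impute(co$matrix, 5)
  comp <- deconvolve_all(m, co$reference)
  fm <- build_factor_matrix(co$truth$phenotypes[, c("sample_id", "age", "batch")],
                            comp, pinned = c("age", "sperm"))
  cv <- loocv(m, fm)
  expect_true(all(cv$stats$r > 0.99))
  expect_true(all(cv$stats$p_value < 1e-10))
  # MAE reported on original units: age errors are in years
  age_mae <- cv$stats$mae[cv$stats$factor == "age"]
  expect_lt(age_mae, 2)

  full <- evaluate_fullfit(mf_fit(m, fm))
  expect_true(all(full$r >= cv$stats$r - 1e-6))  # in-sample optimism
  expect_false("constant" %in% full$factor)
  expect_false("batch" %in% full$factor)
})

test_that("the LOOCV prediction for a sample ignores the ordering of the others", {
  withr::with_seed(20, {
    X <- random_design(15, 3, seed = 21)
    M <- matrix(runif(15 * 50), 15, 50,
                dimnames = list(rownames(X), paste0("chr1:", 1:50 * 10)))
    cv <- loocv(M, X)
    perm <- c(1, sample(2:15))
    cv_perm <- loocv(M[perm, ], X[perm, ])
    expect_equal(cv$X_pred["S001", ], cv_perm$X_pred["S001", ],
                 tolerance = 1e-10)
  })
})

test_that("zero-variance factors are reported as undefined, not zero", {
  X <- random_design(12, 3, seed = 22)
  withr::with_seed(23, {
    M <- matrix(runif(12 * 20), 12, 20,
                dimnames = list(rownames(X), paste0("chr1:", 1:20 * 10)))
  })
  X[, "f2"] <- X[, "f2"] * 0 + 0.5  # constant, non-pinned plain matrix input
  expect_error(mf_fit(M, X), NA)
  cv <- loocv(M, X)
  expect_true(is.na(cv$stats$r[cv$stats$factor == "f2"]))
})
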