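test_that("fixed-effect pooling matches the closed form and its invariants", {
  one <- meta_fixed(tibble::tibble(beta = 0.3, se = 0.1))
  expect_equal(one$beta, 0.3)
  expect_equal(one$se, 0.1)

  two <- meta_fixed(tibble::tibble(beta = c(0.1, 0.3), se = c(0.1, 0.1)))
  expect_equal(two$beta, 0.2)
  expect_equal(two$se, sqrt(0.005), tolerance = 1e-12)
  expect_equal(two$se, 0.0707, tolerance = 1e-3)
  expect_equal(two$Q, 2, tolerance = 1e-12)
  expect_equal(two$I2, 50, tolerance = 1e-10)
  expect_true(is.na(two$I2_ci_low))   # reported unavailable at k = 2

  same <- meta_fixed(tibble::tibble(beta = c(0.2, 0.2, 0.2), se = 0.05))
  expect_equal(same$beta, 0.2)
  expect_equal(same$I2, 0)

  expect_error(meta_fixed(tibble::tibble(beta = 0.1, se = 0)), "> 0")
})

test_that("pooled variance, study order and the I2 interval behave as required", {
  for (s in 1:20) {
    set.seed(s)
    k <- sample(2:8, 1)
    est <- tibble::tibble(beta = stats::rnorm(k, 0.1, 0.2),
                          se = stats::runif(k, 0.05, 0.3))
    m <- meta_fixed(est)
    expect_equal(m$se^2, 1 / sum(1 / est$se^2), tolerance = 1e-12)
    expect_lte(m$se, min(est$se))
    perm <- meta_fixed(est[sample(k), ])
    expect_equal(perm$beta, m$beta, tolerance = 1e-12)
    expect_equal(perm$Q, m$Q, tolerance = 1e-10)
    if (k >= 3) {
      expect_gte(m$I2, m$I2_ci_low - 1e-9)
      expect_lte(m$I2, m$I2_ci_high + 1e-9)
    }
  }
})

test_that("pooling agrees with metafor's fixed-effect fit", {
  skip_if_not_installed("metafor")
  for (s in 1:10) {
    set.seed(100 + s)
    k <- sample(2:6, 1)
    est <- tibble::tibble(beta = stats::rnorm(k, 0, 0.3),
                          se = stats::runif(k, 0.05, 0.3))
    m <- meta_fixed(est)
    rma <- metafor::rma(yi = est$beta, sei = est$se, method = "FE")
    expect_equal(m$beta, as.numeric(rma$beta), tolerance = 1e-8)
    expect_equal(m$se, rma$se, tolerance = 1e-8)
    expect_equal(m$Q, rma$QE, tolerance = 1e-8)
    expect_equal(m$I2, max(0, (rma$QE - (k - 1)) / rma$QE) * 100,
                 tolerance = 1e-8)
  }
})

test_that("per-SNP meta pools on a common effect allele", {
  a <- make_ds(c("rs1", "rs2"), c("A", "C"), c("G", "T"),
               beta = c(0.10, -0.05), se = c(0.02, 0.02),
               eaf = c(0.2, 0.4), type = "binary", n = 1000,
               ncase = 200, ncontrol = 800)
  expect_identical(meta_per_snp(list(a)), a)

  # Second study reports swapped alleles; flip correction makes the pooled
  # effect equal the common underlying value.
  b <- make_ds(c("rs1", "rs2"), c("G", "C"), c("A", "T"),
               beta = c(-0.10, -0.05), se = c(0.02, 0.02),
               eaf = c(0.8, 0.4), type = "binary", n = 1000,
               ncase = 200, ncontrol = 800)
  m <- meta_per_snp(list(a, b))
  expect_equal(m$beta[m$rsid == "rs1"], 0.10, tolerance = 1e-12)
  expect_equal(m$se[m$rsid == "rs1"], 0.02 / sqrt(2), tolerance = 1e-12)
  expect_equal(m$n[m$rsid == "rs1"], 2000)

  # Three studies against the closed-form inverse-variance oracle.
  set.seed(42)
  mk <- function(betas, ses) {
    make_ds(c("rs1", "rs2", "rs3"), "A", "G", beta = betas, se = ses,
            eaf = 0.3, type = "binary", n = 1000, ncase = 300, ncontrol = 700)
  }
  ds <- list(mk(stats::rnorm(3), stats::runif(3, .01, .05)),
             mk(stats::rnorm(3), stats::runif(3, .01, .05)),
             mk(stats::rnorm(3), stats::runif(3, .01, .05)))
  m3 <- meta_per_snp(ds)
  for (r in c("rs1", "rs2", "rs3")) {
    betas <- vapply(ds, function(d) d$beta[d$rsid == r], numeric(1))
    ses <- vapply(ds, function(d) d$se[d$rsid == r], numeric(1))
    expect_equal(m3$beta[m3$rsid == r], sum(betas / ses^2) / sum(1 / ses^2),
                 tolerance = 1e-12)
    expect_equal(m3$se[m3$rsid == r], sqrt(1 / sum(1 / ses^2)),
                 tolerance = 1e-12)
  }
})

test_that("BH q-values follow the step-up definition with a family size", {
  expect_equal(bh_fdr(0.03)$qvalue, 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$qvalue, rep(0.04, 4))

  # The design's family of 20: p = 0.002 -> q = 0.04, flagged.
  headline <- bh_fdr(0.002, m = 20)
  expect_equal(headline$qvalue, 0.04)
  expect_true(headline$discovery)

  expect_error(bh_fdr(c(0.1, 0)), "0, 1")
  expect_error(bh_fdr(c(0.1, 0.2), m = 1), "family size")

  for (s in 1:200) {
    set.seed(s)
    n <- sample(1:25, 1)
    p <- stats::runif(n)
    m <- n + sample(0:10, 1)
    q <- bh_fdr(p, m = m)$qvalue
    expect_equal(q, oracle_bh(p, m), tolerance = 1e-12)
    if (m == n) {
      expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    }
    expect_true(all(q[order(p)] == cummax(q[order(p)]) |
                      diff(c(0, q[order(p)])) >= -1e-15))
  }
})

test_that("BH at 5% rarely discovers anything under a global null", {
  set.seed(99)
  any_disc <- vapply(1:400, function(b) {
    any(bh_fdr(stats::runif(20), m = 20)$discovery)
  }, logical(1))
  expect_lte(mean(any_disc), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})
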