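one_inst <- function(gamma, Gamma, se_Gamma, se_gamma = 0.01) {
  tibble::tibble(rsid = "rs1", gamma = gamma, se_gamma = se_gamma,
                 Gamma = Gamma, se_Gamma = se_Gamma, excluded = FALSE)
}

test_that("the Wald ratio and its delta-method standard error are exact", {
  r <- mr_wald_ratio(one_inst(0.1, 0.012, 0.01))
  expect_equal(r$beta, 0.12)
  expect_equal(r$se, 0.1)
  expect_equal(mr_wald_ratio(one_inst(0.1, 0, 0.01))$beta, 0)
  expect_error(mr_wald_ratio(one_inst(0, 0.01, 0.01)), "gamma is zero")
  # Second-order correction adds the exposure-noise term.
  r2 <- mr_wald_ratio(one_inst(0.1, 0.012, 0.01, se_gamma = 0.02),
                      second_order = TRUE)
  expect_equal(r2$se, sqrt(0.01^2 / 0.01 + 0.012^2 * 0.02^2 / 1e-4),
               tolerance = 1e-12)
})

worked_insts <- tibble::tibble(
  rsid = c("rs1", "rs2", "rs3"),
  gamma = c(0.1, 0.2, 0.15), se_gamma = 0.01,
  Gamma = c(0.012, 0.020, 0.018), se_Gamma = 0.01, excluded = FALSE)

test_that("IVW reproduces the weighted-regression-through-origin oracle", {
  r <- mr_ivw(worked_insts, mode = "multiplicative_random")
  o <- oracle_wls_origin(worked_insts$gamma, worked_insts$Gamma,
                         1 / worked_insts$se_Gamma^2)
  expect_equal(r$beta, o$beta, tolerance = 1e-12)
  expect_equal(r$beta, 0.1090, tolerance = 1e-3)
  expect_equal(r$Q, oracle_q(worked_insts$gamma, worked_insts$Gamma,
                             worked_insts$se_Gamma, o$beta),
               tolerance = 1e-12)
  expect_equal(r$Q, 0.0717, tolerance = 1e-3)
  expect_equal(r$Q_df, 2)
  expect_equal(r$se, o$se_unit * sqrt(r$Q / 2), tolerance = 1e-12)
  expect_equal(mr_ivw(worked_insts, mode = "fixed")$se, o$se_unit,
               tolerance = 1e-12)
})

test_that("IVW reduces to the Wald ratio for one instrument and is exact under homogeneity", {
  single <- worked_insts[1, ]
  expect_equal(mr_ivw(single)$beta, mr_wald_ratio(single)$beta)
  hom <- tibble::tibble(rsid = c("a", "b", "c"), gamma = c(0.1, 0.2, 0.4),
                        se_gamma = 0.01, Gamma = c(0.05, 0.10, 0.20),
                        se_Gamma = 0.01, excluded = FALSE)
  r <- mr_ivw(hom)
  expect_equal(r$beta, 0.5)
  expect_equal(r$Q, 0, tolerance = 1e-20)
})

test_that("fixed-effect IVW equals the inverse-variance mean of Wald ratios", {
  for (s in 1:25) {
    x <- rand_insts(sample(3:10, 1), seed = s)
    w <- x$gamma^2 / x$se_Gamma^2
    theta <- x$Gamma / x$gamma
    expect_equal(mr_ivw(x, mode = "fixed")$beta, sum(w * theta) / sum(w),
                 tolerance = 1e-12)
  }
})

test_that("MR-Egger matches the weighted-regression oracle and its identities", {
  x <- worked_insts
  r <- mr_egger(x)
  o <- oracle_wls_intercept(x$gamma, x$Gamma, 1 / x$se_Gamma^2)
  expect_equal(r$beta, o$slope, tolerance = 1e-12)
  expect_equal(r$intercept, o$intercept, tolerance = 1e-12)
  scale <- max(1, o$sigma)
  expect_equal(r$se, sqrt(o$cov_unit[2, 2]) * scale, tolerance = 1e-12)
  expect_equal(r$intercept_se, sqrt(o$cov_unit[1, 1]) * scale,
               tolerance = 1e-12)

  # Points on a line through the origin: zero intercept, slope = ratio.
  line <- tibble::tibble(rsid = c("a", "b", "c"), gamma = c(0.1, 0.2, 0.3),
                         se_gamma = 0.01, Gamma = c(0.02, 0.04, 0.06),
                         se_Gamma = 0.01, excluded = FALSE)
  rl <- mr_egger(line)
  expect_equal(rl$intercept, 0, tolerance = 1e-12)
  expect_equal(rl$beta, 0.2, tolerance = 1e-12)

  # Adding a constant to every Gamma shifts the intercept, not the slope.
  shifted <- dplyr::mutate(x, Gamma = Gamma + 0.03)
  rs <- mr_egger(shifted)
  expect_equal(rs$beta, r$beta, tolerance = 1e-10)
  expect_equal(rs$intercept, r$intercept + 0.03, tolerance = 1e-10)

  expect_error(mr_egger(worked_insts[1:2, ]), "at least 3")
})

test_that("the weighted median interpolates the cumulative-percentile definition", {
  mk <- function(theta, w) {
    tibble::tibble(rsid = letters[seq_along(theta)], gamma = 1,
                   se_gamma = 1e-6, Gamma = theta, se_Gamma = 1 / sqrt(w),
                   excluded = FALSE)
  }
  expect_equal(mr_weighted_median(mk(c(0.10, 0.12, 0.30), c(1, 1, 1)),
                                  n_boot = 5)$beta, 0.12)
  expect_equal(mr_weighted_median(mk(c(0.10, 0.12, 0.30), c(0.2, 0.2, 0.6)),
                                  n_boot = 5)$beta, 0.21)
  for (s in 1:25) {
    x <- rand_insts(sample(3:12, 1), seed = 300 + s)
    r <- wald_ratios_for_test(x)
    expect_equal(mr_weighted_median(x, n_boot = 2)$beta,
                 oracle_weighted_median(r$theta, r$w), tolerance = 1e-10)
  }
  # Degenerate: identical ratios, vanishing noise, bootstrap se -> 0.
  deg <- tibble::tibble(rsid = c("a", "b", "c"), gamma = c(0.1, 0.2, 0.3),
                        se_gamma = 1e-9, Gamma = c(0.02, 0.04, 0.06),
                        se_Gamma = 1e-9, excluded = FALSE)
  rd <- mr_weighted_median(deg, n_boot = 200, seed = 4)
  expect_equal(rd$beta, 0.2)
  expect_lt(rd$se, 1e-6)
})

test_that("the weighted mode maximises the weighted kernel density", {
  deg <- tibble::tibble(rsid = c("a", "b", "c"), gamma = c(0.1, 0.2, 0.3),
                        se_gamma = 1e-9, Gamma = c(0.02, 0.04, 0.06),
                        se_Gamma = 1e-9, excluded = FALSE)
  expect_equal(mr_weighted_mode(deg, n_boot = 5)$beta, 0.2)

  majority <- tibble::tibble(rsid = letters[1:4], gamma = 1, se_gamma = 1e-6,
                             Gamma = c(0.1, 0.1, 0.1, 0.9),
                             se_Gamma = c(0.11, 0.1, 0.09, 0.1),
                             excluded = FALSE)
  expect_lt(abs(mr_weighted_mode(majority, n_boot = 5)$beta - 0.1), 0.05)

  two_cluster <- tibble::tibble(rsid = letters[1:5], gamma = 1,
                                se_gamma = 1e-6,
                                Gamma = c(0.08, 0.10, 0.12, 0.85, 0.90),
                                se_Gamma = c(0.1, 0.1, 0.1, 0.12, 0.12),
                                excluded = FALSE)
  for (phi in c(1, 0.5, 0.25)) {
    est <- mr_weighted_mode(two_cluster, bandwidth_phi = phi, n_boot = 2)$beta
    r <- wald_ratios_for_test(two_cluster)
    expect_equal(est, oracle_weighted_mode(r$theta, r$w, phi),
                 tolerance = 0.02)
    expect_lt(abs(est - 0.10), 0.06)   # stays on the dense cluster
  }
  expect_error(mr_weighted_mode(two_cluster[1:2, ]), "at least 3")
})

test_that("single-SNP and leave-one-out analyses agree with re-running the estimators", {
  two <- worked_insts[1:2, ]
  ss2 <- mr_single_snp(two)
  expect_equal(ss2$leave_one_out$beta[1], mr_wald_ratio(two[2, ])$beta)
  expect_equal(ss2$leave_one_out$beta[2], mr_wald_ratio(two[1, ])$beta)

  hom <- tibble::tibble(rsid = letters[1:4], gamma = c(0.1, 0.2, 0.3, 0.4),
                        se_gamma = 0.01, Gamma = c(0.05, 0.10, 0.15, 0.20),
                        se_Gamma = 0.01, excluded = FALSE)
  expect_equal(unique(round(mr_single_snp(hom)$leave_one_out$beta, 12)), 0.5)

  x <- rand_insts(4, seed = 9)
  ss <- mr_single_snp(x)
  for (i in 1:4) {
    expect_equal(ss$single_snp$beta[i], mr_wald_ratio(x[i, ])$beta)
    expect_equal(ss$leave_one_out$beta[i], mr_ivw(x[-i, ])$beta,
                 tolerance = 1e-12)
  }
})

test_that("estimates are sign- and scale-equivariant", {
  for (s in 1:10) {
    x <- rand_insts(6, seed = 40 + s)
    fits <- function(d) {
      c(ivw = mr_ivw(d)$beta, egger = mr_egger(d)$beta,
        wm = mr_weighted_median(d, n_boot = 2)$beta,
        mode = mr_weighted_mode(d, n_boot = 2)$beta)
    }
    base <- fits(x)
    both_neg <- dplyr::mutate(x, gamma = -gamma, Gamma = -Gamma)
    expect_equal(fits(both_neg), base, tolerance = 1e-9)
    out_neg <- dplyr::mutate(x, Gamma = -Gamma)
    expect_equal(fits(out_neg), -base, tolerance = 1e-9)
    scaled <- dplyr::mutate(x, Gamma = 3 * Gamma, se_Gamma = 3 * se_Gamma)
    expect_equal(fits(scaled), 3 * base, tolerance = 1e-9)
    expect_equal(mr_ivw(scaled)$se, 3 * mr_ivw(x)$se, tolerance = 1e-12)
  }
})

test_that("excluded instruments are dropped before estimation", {
  x <- rand_insts(5, seed = 77)
  x$excluded[4:5] <- TRUE
  expect_equal(mr_ivw(x)$nsnp, 3)
  expect_equal(mr_ivw(x)$beta, mr_ivw(x[1:3, ])$beta)
  x$excluded <- TRUE
  expect_error(mr_ivw(x), "no usable")
})
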