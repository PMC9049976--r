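test_that("significance selection is strict at the threshold", {
  ds <- make_ds(c("rs1", "rs2", "rs3"), "A", "G", beta = c(0.6, 0.5, 0.5),
                se = 0.09, eaf = 0.3)
  ds$pvalue <- c(1e-9, 5e-8, 1e-7)
  expect_equal(select_significant(ds)$rsid, "rs1")
  expect_equal(nrow(select_significant(ds, 1.0)), 3)
})

test_that("selection matches a direct filter on a generated fixture", {
  set.seed(11)
  k <- 100
  ds <- make_ds(sprintf("rs%03d", 1:k), "A", "G",
                beta = stats::rnorm(k, 0, 0.05), se = 0.01, eaf = 0.3)
  sel <- select_significant(ds, 5e-8)
  expect_equal(sort(sel$rsid), sort(ds$rsid[ds$pvalue < 5e-8]))
  expect_gt(nrow(sel), 0)
})

ld_from_long <- function(ids, pairs) {
  m <- diag(1, length(ids))
  dimnames(m) <- list(ids, ids)
  for (p in pairs) {
    m[p[[1]], p[[2]]] <- m[p[[2]], p[[1]]] <- p[[3]]
  }
  m
}

test_that("greedy clumping follows the p-value order and r2 rule", {
  ds <- make_ds(c("rsA", "rsB", "rsC"), "A", "G", beta = c(0.65, 0.6, 0.55),
                se = 0.1, eaf = 0.3)
  ds$pvalue <- c(1e-10, 1e-9, 1e-8)
  expect_equal(clump(ds[1, ], NULL)$rsid, "rsA")

  ld <- ld_from_long(ds$rsid, list(list("rsA", "rsB", 0.5)))
  expect_equal(clump(ds[1:2, ], ld)$rsid, "rsA")

  ld2 <- ld_from_long(ds$rsid, list(list("rsA", "rsB", 0.2),
                                    list("rsB", "rsC", 0.2),
                                    list("rsA", "rsC", 0.0)))
  expect_equal(sort(clump(ds, ld2)$rsid), c("rsA", "rsC"))
})

test_that("clumping is invariant to input row order and yields independent sets", {
  set.seed(5)
  k <- 12
  ds <- make_ds(sprintf("rs%02d", 1:k), "A", "G",
                beta = stats::runif(k, 0.3, 0.9), se = 0.05, eaf = 0.3)
  ids <- ds$rsid
  m <- diag(1, k); dimnames(m) <- list(ids, ids)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    m[i, j] <- m[j, i] <- sample(c(0, 0, 0.002, 0.3), 1)
  }
  base <- clump(ds, m, 0.001)
  for (s in 1:5) {
    shuffled <- ds[sample(k), ]
    expect_equal(sort(clump(shuffled, m, 0.001)$rsid), sort(base$rsid))
  }
  sel <- base$rsid
  off_diag <- m[sel, sel][upper.tri(diag(length(sel)))]
  expect_true(all(off_diag < 0.001))
})

test_that("unknown LD pairs are treated as independent with a warning", {
  ds <- make_ds(c("rsA", "rsZ"), "A", "G", beta = c(0.65, 0.6), se = 0.1,
                eaf = 0.3)
  ld <- ld_from_long("rsA", list())
  expect_warning(res <- clump(ds, ld), "absent")
  expect_equal(nrow(res), 2)
})

test_that("proxy lookup takes the best candidate above a strict bound", {
  ou <- make_ds(c("p1", "p2", "p3"), "A", "G", beta = c(0.1, 0.1, 0.1),
                se = 0.05, eaf = 0.3)
  ld <- ld_from_long(c("m1", "p1", "p2", "p3"),
                     list(list("m1", "p1", 0.9)))
  expect_equal(substitute_proxies("m1", ou, ld)$proxy_rsid, "p1")

  ld_eq <- ld_from_long(c("m1", "p1"), list(list("m1", "p1", 0.8)))
  expect_equal(nrow(substitute_proxies("m1", ou, ld_eq)), 0)

  ld2 <- ld_from_long(c("m1", "p1", "p2"),
                      list(list("m1", "p1", 0.85), list("m1", "p2", 0.95)))
  expect_equal(substitute_proxies("m1", ou, ld2)$proxy_rsid, "p2")

  # r2 tie broken by smaller outcome p-value.
  ou2 <- ou
  ou2$pvalue <- c(0.5, 0.01, 0.5)
  ld3 <- ld_from_long(c("m1", "p1", "p2"),
                      list(list("m1", "p1", 0.9), list("m1", "p2", 0.9)))
  expect_equal(substitute_proxies("m1", ou2, ld3)$proxy_rsid, "p2")
})

test_that("instrument strength follows the summary-statistic formula", {
  null_snp <- make_ds("rs1", "A", "G", beta = 0, se = 1, eaf = 0.5, n = 100)
  s0 <- instrument_strength(null_snp)
  expect_equal(s0$r2, 0)
  expect_equal(s0$f_stat, 0)

  snp <- make_ds("rs1", "A", "G", beta = 1, se = 1, eaf = 0.5, n = 100)
  s <- instrument_strength(snp)
  expect_equal(s$r2, 0.5 / 50.5, tolerance = 1e-10)
  expect_equal(s$f_stat, s$r2 * 98 / (1 - s$r2), tolerance = 1e-10)
  expect_equal(s$f_stat, 0.98, tolerance = 1e-3)
  expect_true(s$weak)

  # F strictly increasing in |beta|/se at fixed MAF and n.
  betas <- seq(0.1, 2, by = 0.1)
  fs <- vapply(betas, function(b) {
    instrument_strength(make_ds("rs1", "A", "G", b, 1, 0.5, 1000))$f_stat
  }, numeric(1))
  expect_true(all(diff(fs) > 0))
  expect_true(all(instrument_strength(
    make_ds("rs1", "A", "G", 0.3, 0.02, 0.25, 5000))$r2 < 1))

  expect_error(instrument_strength(make_ds("rs1", "A", "G", 1, 1, NA, 100)),
               "eaf")
})

test_that("summed per-SNP r2 recovers the generative variance explained", {
  cfg <- sim_config(n_snps = 24, r2_total = 0.0441, outcome_ncase = 5000,
                    outcome_ncontrol = 20000, seed = 1)
  totals <- vapply(1:100, function(b) {
    sim <- simulate_two_sample(cfg, seed = 500 + b)
    attr(instrument_strength(sim$exposure), "r2_total")
  }, numeric(1))
  # Small upward inflation (k/N) from estimating with noisy betas is
  # expected; 5% relative agreement covers it plus Monte-Carlo error.
  expect_lt(abs(mean(totals) - 0.0441) / 0.0441, 0.05)
})

test_that("the LD reference round-trips through the long text format", {
  sim <- simulate_two_sample(
    sim_config(n_snps = 4, r2_total = 0.01, outcome_ncase = 5000,
               outcome_ncontrol = 20000, seed = 2,
               ld_blocks = list(n_blocks = 2, block_size = 3, r2 = 0.9)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld(sim$ld, path)
  back <- read_ld(path)
  ids <- rownames(sim$ld)
  expect_equal(back[ids, ids], sim$ld)
})
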