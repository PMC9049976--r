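# Independent brute-force oracles used to cross-check the estimators.

# Weighted least squares through the origin by the normal equations.
oracle_wls_origin <- function(g, G, w) {
  beta <- sum(w * g * G) / sum(w * g^2)
  list(beta = beta, se_unit = sqrt(1 / sum(w * g^2)))
}

# Weighted least squares with intercept by the normal equations.
oracle_wls_intercept <- function(g, G, w) {
  X <- cbind(1, g)
  XtWX <- t(X) %*% (w * X)
  coefs <- solve(XtWX, t(X) %*% (w * G))
  resid <- G - X %*% coefs
  sigma2 <- sum(w * resid^2) / (length(g) - 2)
  list(intercept = coefs[1], slope = coefs[2],
       cov_unit = solve(XtWX), sigma = sqrt(sigma2))
}

# Cochran's Q by direct summation.
oracle_q <- function(g, G, se, beta) sum((G - beta * g)^2 / se^2)

# Weighted median by the cumulative-percentile definition, via approx().
oracle_weighted_median <- function(theta, w) {
  ord <- order(theta)
  th <- theta[ord]
  wn <- w[ord] / sum(w)
  p <- cumsum(wn) - wn / 2
  stats::approx(p, th, xout = 0.5, rule = 2, ties = "ordered")$y
}

# Weighted-mode argmax on a fine explicit grid of the weighted gaussian KDE.
oracle_weighted_mode <- function(theta, w, phi = 1, n_grid = 20001) {
  s <- 0.9 * min(stats::sd(theta), stats::mad(theta)) / length(theta)^(1 / 5)
  h <- max(1e-8, s * phi)
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = n_grid)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm(x, theta, h)),
                 numeric(1))
  grid[which.max(dens)]
}

# BH step-up q-values by the definitional double loop.
oracle_bh <- function(p, m = length(p)) {
  n <- length(p)
  ord <- order(p)
  sp <- p[ord]
  q_sorted <- vapply(seq_len(n), function(i) {
    min(1, min(m * sp[i:n] / (i:n)))
  }, numeric(1))
  q <- numeric(n)
  q[ord] <- q_sorted
  q
}

# Random harmonised-format instrument fixtures.
rand_insts <- function(k, seed, gamma_min = 0.03, gamma_max = 0.12) {
  set.seed(seed)
  tibble::tibble(
    rsid = sprintf("rs%03d", seq_len(k)),
    gamma = stats::runif(k, gamma_min, gamma_max) *
      sample(c(-1, 1), k, replace = TRUE),
    se_gamma = stats::runif(k, 0.005, 0.02),
    Gamma = stats::rnorm(k, 0, 0.05),
    se_Gamma = stats::runif(k, 0.005, 0.02),
    eaf_exposure = stats::runif(k, 0.1, 0.9),
    eaf_outcome = stats::runif(k, 0.1, 0.9),
    palindromic = FALSE, flipped = FALSE,
    excluded = FALSE, exclusion_reason = "none")
}

# A minimal well-formed summary dataset from a compact spec.
make_ds <- function(rsid, ea, oa, beta, se, eaf = NA, n = 10000,
                    type = "continuous", name = "trait", ncase = NA,
                    ncontrol = NA) {
  summary_dataset(
    tibble::tibble(rsid = rsid, effect_allele = ea, other_allele = oa,
                   beta = beta, se = se,
                   pvalue = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300),
                   eaf = eaf, n = n, ncase = ncase, ncontrol = ncontrol),
    trait_name = name, trait_type = type)
}

# Random exposure/outcome dataset pair whose outcome rows are reported
# under a random allele representation (same / swapped / strand-complement
# / swapped complement), for harmonisation property tests.
rand_harmonise_pair <- function(k, seed) {
  set.seed(seed)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                c("A", "T"), c("C", "G"))
  idx <- sample(length(pairs), k, replace = TRUE)
  ea <- vapply(idx, function(i) pairs[[i]][1], character(1))
  oa <- vapply(idx, function(i) pairs[[i]][2], character(1))
  eaf <- stats::runif(k, 0.05, 0.95)
  exposure <- make_ds(sprintf("rs%03d", seq_len(k)), ea, oa,
                      beta = stats::rnorm(k, 0, 0.1),
                      se = stats::runif(k, 0.01, 0.03), eaf = eaf)
  op <- sample(c("same", "swap", "comp", "swapcomp"), k, replace = TRUE)
  pal <- ea == comp[oa]
  op[pal] <- sample(c("same", "swap"), sum(pal), replace = TRUE)
  out_eaf <- pmin(pmax(eaf + stats::rnorm(k, 0, 0.02), 0.01), 0.99)
  o_ea <- ea; o_oa <- oa; o_beta <- stats::rnorm(k, 0, 0.1); o_eaf <- out_eaf
  swap <- op %in% c("swap", "swapcomp")
  o_ea[swap] <- oa[swap]; o_oa[swap] <- ea[swap]
  o_beta[swap] <- -o_beta[swap]; o_eaf[swap] <- 1 - o_eaf[swap]
  cc <- op %in% c("comp", "swapcomp")
  o_ea[cc] <- comp[o_ea[cc]]; o_oa[cc] <- comp[o_oa[cc]]
  outcome <- make_ds(exposure$rsid, o_ea, o_oa, beta = o_beta,
                     se = stats::runif(k, 0.01, 0.03), eaf = o_eaf)
  list(exposure = exposure, outcome = outcome)
}

# The globally allele-flipped representation of a dataset (swap the allele
# labels, negate beta, complement eaf): harmonisation must not care.
flip_dataset <- function(ds) {
  x <- tibble::as_tibble(ds)
  tmp <- x$effect_allele
  x$effect_allele <- x$other_allele
  x$other_allele <- tmp
  x$beta <- -x$beta
  x$eaf <- 1 - x$eaf
  summary_dataset(x, trait_name = attr(ds, "trait_name"),
                  trait_type = attr(ds, "trait_type"))
}

# Delta-method ratios and weights matching the estimators' convention.
wald_ratios_for_test <- function(x) {
  list(theta = x$Gamma / x$gamma, w = x$gamma^2 / x$se_Gamma^2)
}
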