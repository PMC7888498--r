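test_that("chain configuration arithmetic and validation", {
  expect_equal(n_stored(ltm_chain(1000, 0, 1)), 1000L)
  expect_equal(n_stored(ltm_chain(1000, 200, 10)), 80L)
  expect_error(ltm_chain(1000, 1000, 10), "burn_in")
  expect_error(ltm_chain(1000, 100, 7), "divisible")
  expect_error(ltm_chain(1000, 100, 0), "thin")
})

test_that("one-sided truncated normal draws respect sign and half-normal mean", {
  set.seed(1)
  pos <- vapply(1:20000, function(i) stayltm:::rtnorm_one(0, 1, TRUE), 0)
  expect_true(all(pos > 0))
  # E[half-normal] = sqrt(2/pi)
  expect_equal(mean(pos), sqrt(2 / pi), tolerance = 0.02)
  neg <- vapply(1:2000, function(i) stayltm:::rtnorm_one(0.5, 2, FALSE), 0)
  expect_true(all(neg <= 0))
  # far-tail bound: mean 8 sd below the threshold still returns valid draws
  tail_draws <- vapply(1:2000, function(i) stayltm:::rtnorm_one(-8, 1, TRUE), 0)
  expect_true(all(tail_draws > 0 & is.finite(tail_draws)))
})

test_that("inverse-Wishart sampler matches closed-form moments", {
  set.seed(2)
  # univariate: IW(S, nu) is scaled-inverse-chi-square with mean S/(nu-2)
  S <- 12.3; nu <- 30
  draws <- vapply(1:4000, function(i) stayltm:::riwish_cpp(nu, matrix(S))[1, 1], 0)
  expect_equal(mean(draws), S / (nu - 2), tolerance = 0.02)
  # trivariate mean: S/(nu - p - 1)
  S3 <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  m <- Reduce(`+`, lapply(1:3000, function(i) stayltm:::riwish_cpp(12, S3))) / 3000
  expect_equal(m, S3 / (12 - 3 - 1), tolerance = 0.1)
})

test_that("pinned residual draw matches the conditional decomposition of the IW", {
  set.seed(3)
  S <- matrix(c(5, 1.2, 0.8,
                1.2, 4, 0.6,
                0.8, 0.6, 2), 3)
  nu <- 25; b <- 3L
  n <- 4000
  pin <- lapply(1:n, function(i) stayltm:::riwish_pinned_cpp(nu, S, b))
  expect_true(all(vapply(pin, function(R) R[b, b] == 1, TRUE)))
  expect_true(all(vapply(pin, function(R) min(eigen(R)$values) > 0, TRUE)))
  # under independence of the pinned scalar from (B, W22.1), the implied
  # conditional block and regression vector have the same law as in
  # unconstrained IW draws
  free <- lapply(1:n, function(i) stayltm:::riwish_cpp(nu, S))
  w221_pin <- vapply(pin, function(R) R[1, 1] - R[1, b]^2, 0)
  w221_free <- vapply(free, function(W) W[1, 1] - W[1, b]^2 / W[b, b], 0)
  b_pin <- vapply(pin, function(R) R[1, b], 0)
  b_free <- vapply(free, function(W) W[1, b] / W[b, b], 0)
  expect_gt(suppressWarnings(ks.test(w221_pin, w221_free))$p.value, 0.001)
  expect_gt(suppressWarnings(ks.test(b_pin, b_free))$p.value, 0.001)
})

test_that("degenerate single-trait model reproduces the conjugate posterior", {
  set.seed(4)
  n <- 40
  y <- rnorm(n, 5, 2)
  d <- data.frame(sow = as.character(1:n), y = y)
  fit <- ltm_fit(d, NULL, traits = "y", binary = NULL, cg = NULL,
                 covariate = NULL, chain = ltm_chain(6000, 1000, 5, seed = 9),
                 priors = ltm_priors(flat = TRUE))
  s2 <- fit$store$R[1, 1, ]
  # sigma2 | y ~ Scaled-Inv-Chi2(n-1, s^2) under the flat convention
  expect_equal(mean(s2), (n - 1) * var(y) / (n - 3), tolerance = 0.1)
  expect_equal(fit$beta_cg[1, 1], mean(y), tolerance = 3 * sd(y) / sqrt(n))
})

test_that("intercept-only binary model recovers the success probability", {
  set.seed(5)
  n <- 2000
  p_true <- 0.75
  yb <- rbinom(n, 1, p_true)
  d <- data.frame(sow = as.character(1:n), s = yb)
  fit <- ltm_fit(d, NULL, traits = character(0), binary = "s", cg = NULL,
                 covariate = NULL, chain = ltm_chain(3000, 500, 5, seed = 6),
                 priors = ltm_priors(flat = TRUE))
  expect_equal(pnorm(fit$beta_cg[1, 1]), mean(yb), tolerance = 0.03)
  # liability residual variance is pinned at exactly 1 in every stored draw
  expect_true(all(fit$store$R[1, 1, ] == 1))
})

test_that("residual correlation with the liability is recovered in a two-trait toy", {
  set.seed(6)
  n <- 4000
  rho <- 0.5
  S <- matrix(c(2, rho * sqrt(2), rho * sqrt(2), 1), 2)
  e <- matrix(rnorm(2 * n), n) %*% chol(S)
  d <- data.frame(sow = as.character(1:n), y = 3 + e[, 1],
                  s = as.integer(0.4 + e[, 2] > 0))
  fit <- ltm_fit(d, NULL, traits = "y", binary = "s", cg = NULL,
                 covariate = NULL, chain = ltm_chain(4000, 1000, 3, seed = 2))
  r12 <- fit$store$R[1, 2, ] / sqrt(fit$store$R[1, 1, ])
  expect_equal(mean(r12), rho, tolerance = 0.1)
  expect_true(all(fit$store$R[2, 2, ] == 1))
})

test_that("augmented missing continuous cells leave estimation consistent", {
  set.seed(7)
  n <- 3000
  S <- matrix(c(1, 0.8, 0.8, 1), 2)
  e <- matrix(rnorm(2 * n), n) %*% chol(S)
  y1 <- 2 + e[, 1]; y2 <- -1 + e[, 2]
  y2[sample(n, n / 2)] <- NA  # half the records missing trait 2 at random
  d <- data.frame(sow = as.character(1:n), y1 = y1, y2 = y2)
  fit <- ltm_fit(d, NULL, traits = c("y1", "y2"), binary = NULL, cg = NULL,
                 covariate = NULL, chain = ltm_chain(4000, 1000, 3, seed = 3))
  Rm <- apply(fit$store$R, c(1, 2), mean)
  expect_equal(Rm[1, 2] / sqrt(Rm[1, 1] * Rm[2, 2]), 0.8, tolerance = 0.05)
  expect_equal(Rm[2, 2], 1, tolerance = 0.1)
})

test_that("fits are reproducible under the chain seed", {
  set.seed(8)
  herd <- simulate_herd(small_sim_config(seed = 8))
  tab <- herd_analysis_table(herd)
  rp <- ped_renumber(herd$pedigree)
  f1 <- ltm_fit(tab, rp, chain = ltm_chain(400, 100, 10, seed = 11))
  f2 <- ltm_fit(tab, rp, chain = ltm_chain(400, 100, 10, seed = 11))
  expect_identical(f1$store$G, f2$store$G)
  expect_identical(f1$store$R, f2$store$R)
  expect_equal(length(f1$store), 30L)
})

test_that("every stored covariance draw is positive definite with pinned liability variance", {
  set.seed(9)
  herd <- simulate_herd(small_sim_config(seed = 9))
  tab <- herd_analysis_table(herd)
  fit <- ltm_fit(tab, ped_renumber(herd$pedigree),
                 chain = ltm_chain(600, 100, 10, seed = 1))
  for (k in seq_len(length(fit$store))) {
    expect_no_error(chol(fit$store$G[, , k]))
    expect_no_error(chol(fit$store$R[, , k]))
    expect_identical(fit$store$R[4, 4, k], 1)
  }
})

test_that("records must map onto the pedigree and binary values are validated", {
  herd <- simulate_herd(small_sim_config(seed = 10))
  tab <- herd_analysis_table(herd)
  tab$sow[1] <- "GHOST"
  expect_error(
    ltm_fit(tab, ped_renumber(herd$pedigree),
            chain = ltm_chain(100, 0, 1, seed = 1)),
    "GHOST")
  d <- data.frame(sow = "a", s = 2)
  expect_error(ltm_fit(d, NULL, traits = character(0), binary = "s",
                       cg = NULL, covariate = NULL), "0, 1 or NA")
})
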