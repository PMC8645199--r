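test_that("the variable-rates likelihood matches closed forms and plain BM", {
  X <- matrix(0, 2, 1, dimnames = list(c("A", "B"), NULL))
  expect_equal(vr_log_likelihood(X, tree2(), 0, 1), -log(2 * pi),
               tolerance = 1e-12)

  tr <- simulate_tree(10, 10, seed = 41)
  traits <- cbind(bm_simulate(tr, rate = 0.5, seed = 1))
  empty <- data.frame(edge = integer(0), scope = character(0),
                      scalar = numeric(0))
  expect_equal(vr_log_likelihood(traits, tr, 0, 0.5, empty),
               vr_log_likelihood(traits, tr, 0, 0.5, NULL))
  expect_error(vr_log_likelihood(traits, tr, 0, -1), "> 0")
})

test_that("the pruning likelihood equals a dense MVN oracle with planted scalars", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    tr <- simulate_tree(n, 10)
    K <- sample(1:3, 1)
    shifts <- data.frame(edge = sample(nrow(tr$edge), 2),
                         scope = sample(c("branch", "clade"), 2, replace = TRUE),
                         scalar = runif(2, 0.1, 8))
    X <- matrix(rnorm(n * K), n, K, dimnames = list(tr$tip.label, NULL))
    al <- runif(K, -1, 1)
    s2 <- runif(K, 0.05, 3)
    ll <- vr_log_likelihood(X, tr, al, s2, shifts)
    scaled <- tr
    scaled$edge.length <- tr$edge.length * relative_rates_from_shifts(tr, shifts)
    C <- ape::vcv(scaled)[tr$tip.label, tr$tip.label]
    oracle <- sum(vapply(seq_len(K), function(k) {
      ch <- chol(s2[k] * C)
      d <- X[, k] - al[k]
      -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
                sum(backsolve(ch, d, transpose = TRUE)^2))
    }, numeric(1)))
    expect_lt(abs(ll - oracle), 1e-8)
  }
})

test_that("config validation catches inconsistent settings", {
  expect_error(rate_model_config(alpha_prior = c(1, -1)), "alpha")
  expect_error(rate_model_config(sigma2_prior = c(-1, 1)), "sigma2")
  expect_error(rate_model_config(n_iterations = 1000, burnin = 2000), "burnin")
  expect_error(rate_model_config(n_iterations = 1000, burnin = 100, thin = 7),
               "divide")
  expect_error(
    run_mcmc(matrix(0, 2, 1, dimnames = list(c("A", "B"), NULL)), tree2(),
             rate_model_config(n_iterations = 1000, burnin = 100, thin = 100,
                               move_weights = c(-1, 1, 1, 1, 1))),
    "move weights")
})

test_that("the chain is byte-reproducible given config and seed", {
  tr <- simulate_tree(12, 10, seed = 43)
  X <- cbind(bm_simulate(tr, rate = 5e-5, seed = 2))
  cfg <- rate_model_config(n_iterations = 5e4, burnin = 5e3, thin = 50,
                           seed = 77)
  a <- run_mcmc(X, tr, cfg)
  b <- run_mcmc(X, tr, cfg)
  expect_identical(a$samples, b$samples)
  expect_identical(a$rel_rates, b$rel_rates)
  expect_identical(a$shifts, b$shifts)
})

test_that("a prior-only chain recovers the Poisson shift-count prior", {
  tr <- simulate_tree(20, 10, seed = 44)
  X <- matrix(rnorm(20, sd = 0.01), 20, 1, dimnames = list(tr$tip.label, NULL))
  cfg <- rate_model_config(prior_only = TRUE, n_iterations = 1e6,
                           burnin = 1e5, thin = 100, seed = 99)
  post <- run_mcmc(X, tr, cfg)
  k <- post$samples$n_shifts
  # thin further to reduce autocorrelation before the GOF test
  k <- k[seq(1, length(k), by = 5)]
  kmax <- 5
  obs <- table(factor(pmin(k, kmax), levels = 0:kmax))
  pr <- dpois(0:kmax, 1)
  pr[kmax + 1] <- 1 - sum(pr[1:kmax])
  gof <- suppressWarnings(chisq.test(obs, p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("plain BM data yields near-unit posterior rates on most branches", {
  tr <- simulate_tree(50, 10, seed = 45)
  X <- bm_simulate(tr, rate = 5e-5, root_state = 0.2, n = 3, seed = 3)
  cfg <- rate_model_config(sigma2_prior = c(0, 1e-3),
                           n_iterations = 5e5, burnin = 5e4, thin = 100,
                           seed = 7)
  post <- run_mcmc(X, tr, cfg)
  br <- summarize_rates(post)
  expect_gte(mean(br$rate >= 0.5 & br$rate <= 2), 0.9)
})

test_that("posterior intervals for alpha and sigma2 cover the truth", {
  # 20 seeded replicates on a 100-tip tree; truth should sit inside the
  # central 90% interval in at least 16
  tr <- simulate_tree(100, 10, seed = 46)
  alpha_true <- 0.2
  s2_true <- 5e-5
  # all replicate datasets from one seeded stream (columns of one draw)
  datasets <- bm_simulate(tr, rate = s2_true, root_state = alpha_true,
                          n = 20, seed = 100)
  hits_a <- hits_s <- 0
  for (s in 1:20) {
    X <- datasets[, s, drop = FALSE]
    cfg <- rate_model_config(sigma2_prior = c(0, 1e-3),
                             n_iterations = 3e5, burnin = 5e4, thin = 250,
                             seed = 200 + s)
    post <- run_mcmc(X, tr, cfg)
    qa <- quantile(post$samples$alpha_trait1, c(0.05, 0.95))
    qs <- quantile(post$samples$sigma2_trait1, c(0.05, 0.95))
    if (alpha_true >= qa[1] && alpha_true <= qa[2]) hits_a <- hits_a + 1
    if (s2_true >= qs[1] && s2_true <= qs[2]) hits_s <- hits_s + 1
  }
  expect_gte(hits_a, 16)
  expect_gte(hits_s, 16)
})

test_that("ess matches iid and AR(1) expectations and guards input", {
  set.seed(48)
  x <- rnorm(10000)
  e <- ess(x)
  expect_gt(e, 8500); expect_lt(e, 11500)

  # AR(1), rho = 0.5: asymptotic ess/N = (1 - rho) / (1 + rho) = 1/3
  n <- 50000
  ar <- numeric(n)
  for (i in 2:n) ar[i] <- 0.5 * ar[i - 1] + rnorm(1)
  ratio <- ess(ar) / n
  expect_gt(ratio, 0.28); expect_lt(ratio, 0.39)

  expect_error(ess(rnorm(5)), "too short")
  expect_error(ess(rep(1, 100)), "constant")
})

test_that("ess agrees broadly with coda's estimator", {
  set.seed(49)
  n <- 20000
  ar <- numeric(n)
  for (i in 2:n) ar[i] <- 0.7 * ar[i - 1] + rnorm(1)
  mine <- ess(ar)
  ref <- unname(coda::effectiveSize(ar))
  expect_lt(abs(mine - ref) / ref, 0.25)
})

test_that("split_posterior counts optima and drops mixed iterations", {
  nb <- 4
  rel <- matrix(1, 100, nb, dimnames = list(NULL, paste0("b", 1:nb)))
  s2 <- cbind(c(rep(1e-5, 30), rep(5e-4, 60), rep(1e-5, 10)),
              c(rep(1e-5, 30), rep(5e-4, 60), rep(5e-4, 10)))
  post <- fake_posterior(rel, s2, traits = c("PC1", "PC2"))
  sp <- split_posterior(post, thresholds = c(1e-4, 1e-4))
  expect_equal(unname(sp$pp), c(0.3, 0.6))
  expect_equal(sp$n_dropped, 10)
  expect_error(split_posterior(post, thresholds = 1e-4), "per trait")
})

test_that("summarize_rates averages relative and absolute rates", {
  rel <- rbind(c(2, 1), c(4, 1))
  colnames(rel) <- c("b1", "b2")
  post <- fake_posterior(rel, cbind(c(1e-4, 2e-4)))
  br <- summarize_rates(post)
  expect_equal(br$rate, c(3, 1))

  # two sub-chains constructed so (sigma2 x relative rate) coincides:
  # low sigma2 with high scalars vs high sigma2 with low scalars
  low <- fake_posterior(matrix(c(8, 4), 1, 2, dimnames = list(NULL, c("b1", "b2"))),
                        cbind(1e-4))
  high <- fake_posterior(matrix(c(2.05, 1), 1, 2, dimnames = list(NULL, c("b1", "b2"))),
                         cbind(4e-4))
  abs_low <- summarize_rates(low, absolute = TRUE)$rate
  abs_high <- summarize_rates(high, absolute = TRUE)$rate
  expect_true(all(abs(abs_low - abs_high) / abs_low < 0.05))

  empty <- fake_posterior(rel[0, , drop = FALSE], cbind(numeric(0)))
  expect_error(summarize_rates(empty), "empty")
})
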