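test_that("contrasts match closed-form and hand-worked values", {
  p2 <- pic_contrasts(tree2(), c(A = 3, B = 1))
  expect_equal(unname(p2$contrasts), (3 - 1) / sqrt(2), tolerance = 1e-12)

  # 3-tip hand recursion: contrast at (A,B) node = (1-3)/sqrt(2); node value
  # 2 on an adjusted branch of 1 + 0.5, so the root contrast is (2-2)/sqrt(2.5)
  p3 <- pic_contrasts(tree3(), c(A = 1, B = 3, C = 2))
  expect_equal(sort(unname(p3$contrasts)), sort(c(-2 / sqrt(2), 0)),
               tolerance = 1e-12)

  expect_error(pic_contrasts(tree3(), c(A = 1, B = 3)), "missing trait.*C")
  poly <- read_newick("(A:1,B:1,C:1);", require_ultrametric = FALSE)
  expect_error(pic_contrasts(poly, c(A = 1, B = 2, C = 3)), "polytom")
})

test_that("contrasts are invariant to tip input order and match ape", {
  tr <- simulate_tree(24, 10, seed = 31)
  x <- bm_simulate(tr, seed = 1)
  base <- pic_contrasts(tr, x)
  shuffled <- x[sample(names(x))]
  expect_identical(base$contrasts, pic_contrasts(tr, shuffled)$contrasts)
  expect_equal(sort(abs(unname(base$contrasts))),
               sort(abs(unname(ape::pic(x[tr$tip.label], tr)))),
               tolerance = 1e-12)
})

test_that("contrast standardization yields unit variance under unit-rate BM", {
  tr <- simulate_tree(16, 10, seed = 32)
  traits <- bm_simulate(tr, rate = 1, n = 10000, seed = 2)
  eng <- evodecouple:::pic_engine(tr, traits)
  pooled_var <- mean(eng$contrasts^2)
  expect_gt(pooled_var, 0.97)
  expect_lt(pooled_var, 1.03)
})

test_that("through-origin PIC correlation has the stated df and behavior", {
  tr <- simulate_tree(234, 10, seed = 33)
  x <- pic_contrasts(tr, bm_simulate(tr, seed = 3))
  expect_length(x$contrasts, 233)
  y <- x
  y$contrasts <- 2 * x$contrasts
  res <- pic_correlation(x, y)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$df, 232L)
  # plain numeric vectors are accepted too
  plain <- pic_correlation(unname(x$contrasts), unname(y$contrasts))
  expect_equal(plain$r, 1, tolerance = 1e-12)
  zero <- x
  zero$contrasts <- 0 * x$contrasts
  expect_error(pic_correlation(x, zero), "zero-variance")
})

test_that("PIC correlations of independent BM traits center on zero", {
  tr <- simulate_tree(64, 10, seed = 34)
  nd <- null_correlations(tr, n_pairs = 1000, seed = 4)
  expect_gt(mean(nd$r_values), -0.02)
  expect_lt(mean(nd$r_values), 0.02)
  expect_true(all(abs(nd$r_values) <= 1))
})

test_that("bm_simulate has the analytic moments sigma^2 * C", {
  x <- bm_simulate(tree2(), rate = 1, n = 20000, seed = 5)
  expect_gt(var(x["A", ]), 0.97); expect_lt(var(x["A", ]), 1.03)
  cv <- cov(x["A", ], x["B", ])
  expect_gt(cv, -0.02); expect_lt(cv, 0.02)

  y <- bm_simulate(tree3(), rate = 1, n = 20000, seed = 6)
  cv3 <- cov(y["A", ], y["B", ])  # shared path length 1
  expect_gt(cv3, 0.95); expect_lt(cv3, 1.05)

  z <- bm_simulate(tree3(), rate = 1e-18, root_state = 0.4, seed = 7)
  expect_equal(unname(z), rep(0.4, 3), tolerance = 1e-6)
  expect_error(bm_simulate(tree2(), rate = 0), "> 0")
})

test_that("the PIC null distribution is tree-free", {
  t_a <- simulate_tree(64, 10, seed = 35)
  t_b <- simulate_tree(64, 3, seed = 36)
  nd_a <- null_correlations(t_a, 1000, seed = 8)
  nd_b <- null_correlations(t_b, 1000, seed = 9)
  expect_gt(suppressWarnings(ks.test(nd_a$r_values, nd_b$r_values))$p.value,
            0.01)
  # and matches iid normal vectors of the same length (63 contrasts)
  set.seed(10)
  iid <- replicate(1000, {
    a <- rnorm(63); b <- rnorm(63)
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  })
  expect_gt(suppressWarnings(ks.test(nd_a$r_values, iid))$p.value, 0.01)
  expect_error(null_correlations(t_a, 0), ">= 1")
})

test_that("phylo_pls is exact in degenerate and star cases", {
  tr <- simulate_tree(15, 10, seed = 37)
  X <- matrix(rnorm(45), 15, 3, dimnames = list(tr$tip.label, NULL))
  same <- phylo_pls(X, X, tr, n_permutations = 99, seed = 1)
  expect_equal(same$r_pls, 1, tolerance = 1e-10)

  star <- ape::stree(12, "star")
  star$edge.length <- rep(2, 12)
  star$tip.label <- paste0("s", 1:12)
  B1 <- matrix(rnorm(36), 12, 3, dimnames = list(star$tip.label, NULL))
  B2 <- matrix(rnorm(24), 12, 2, dimnames = list(star$tip.label, NULL))
  pp <- phylo_pls(B1, B2, star, n_permutations = 99, seed = 2)
  Z1 <- scale(B1, scale = FALSE); Z2 <- scale(B2, scale = FALSE)
  s <- svd(crossprod(Z1, Z2) / 11)
  ordinary <- abs(cor(Z1 %*% s$u[, 1], Z2 %*% s$v[, 1]))
  expect_lt(abs(pp$r_pls - ordinary), 1e-9)
})

test_that("phylo_pls r is invariant to orthogonal rotation of a block", {
  tr <- simulate_tree(20, 10, seed = 38)
  set.seed(11)
  B1 <- matrix(rnorm(60), 20, 3, dimnames = list(tr$tip.label, NULL))
  B2 <- matrix(rnorm(60), 20, 3, dimnames = list(tr$tip.label, NULL))
  base <- phylo_pls(B1, B2, tr, n_permutations = 99, seed = 3)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  rot <- phylo_pls(B1, B2 %*% Q, tr, n_permutations = 99, seed = 3)
  expect_equal(base$r_pls, rot$r_pls, tolerance = 1e-9)
})

test_that("the correlation grid labels pairs and flags null exceedance", {
  tr <- simulate_tree(40, 10, seed = 39)
  scn <- scenario("coupled", n_tips = 40, rho = 0.95, seed = 12)
  sim <- simulate_jaw_traits(tr, scn)
  nd <- null_correlations(tr, 300, seed = 13)
  grid <- pic_correlation_grid(tr, sim$block_a, sim$block_b, nd)
  expect_equal(nrow(grid), 9)
  expect_true(all(c("trait_a", "trait_b", "r", "p", "df", "outside_null")
                  %in% names(grid)))
  # strongly coupled matched axes should exceed the null band
  diag_rows <- grid[grid$trait_a == "A1" & grid$trait_b == "B1", ]
  expect_true(diag_rows$outside_null)
})
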