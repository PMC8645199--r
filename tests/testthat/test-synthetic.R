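test_that("simulated trees meet size, age, and determinism contracts", {
  t2 <- simulate_tree(2, root_age = 7, seed = 61)
  expect_equal(unname(t2$edge.length), c(7, 7))

  big <- simulate_tree(234, root_age = 10, seed = 62)
  expect_equal(nrow(big$edge), 466)
  expect_equal(max(node_ages(big)), 10, tolerance = 1e-9)
  expect_true(ape::is.ultrametric(big, tol = 1e-8))

  expect_identical(write_newick(simulate_tree(50, 10, seed = 63)),
                   write_newick(simulate_tree(50, 10, seed = 63)))
  expect_error(simulate_tree(1), ">= 2")
})

test_that("perfect coupling with equal rates duplicates the blocks exactly", {
  tr <- simulate_tree(30, 10, seed = 64)
  scn <- scenario("coupled", n_tips = 30, rho = 1,
                  rate_a = rep(1e-4, 3), rate_b = rep(1e-4, 3), seed = 65)
  sim <- simulate_jaw_traits(tr, scn)
  expect_equal(unname(sim$block_a), unname(sim$block_b), tolerance = 1e-12)
  expect_error(scenario("coupled", rho = 1.2), "<= 1")
})

test_that("generated cross-block coupling is recovered by PIC correlations", {
  tr <- simulate_tree(100, 10, seed = 66)
  mean_r <- function(rho, reps, seed0) {
    r <- numeric(reps)
    for (i in seq_len(reps)) {
      scn <- scenario("coupled", n_tips = 100, rho = rho, seed = seed0 + i)
      sim <- simulate_jaw_traits(tr, scn)
      r[i] <- pic_correlation(
        pic_contrasts(tr, sim$block_a[, 1]),
        pic_contrasts(tr, sim$block_b[, 1]))$r
    }
    mean(r)
  }
  expect_lt(abs(mean_r(0, 200, 1000)), 0.05)
  r05 <- mean_r(0.5, 200, 2000)
  expect_gt(r05, 0.43); expect_lt(r05, 0.57)
})

test_that("late-decoupled simulation splits coupling at the change age", {
  tr <- simulate_tree(120, 10, seed = 67)
  # strong old coupling, none young: tip-level PIC correlation should be
  # intermediate, but old-epoch contrasts alone should correlate strongly
  scn <- scenario("late_decoupled", n_tips = 120, rho_old = 0.95,
                  rho_young = 0, change_age = 2, seed = 68)
  reps <- 50
  r_all <- numeric(reps)
  for (i in seq_len(reps)) {
    scn$seed <- 68 + i
    sim <- simulate_jaw_traits(tr, scn)
    r_all[i] <- pic_correlation(pic_contrasts(tr, sim$block_a[, 1]),
                                pic_contrasts(tr, sim$block_b[, 1]))$r
  }
  expect_gt(mean(r_all), 0.05)  # residual signal from the old epoch
  expect_lt(mean(r_all), 0.9)   # but far from full coupling
})

test_that("planted clade shifts raise trait variance inside the clade", {
  tr <- simulate_tree(50, 10, seed = 69)
  cl <- evodecouple:::clade_edge_sets(tr)
  sizes <- vapply(cl, length, 1L)
  pick <- which(sizes >= 15 & sizes <= 25)[1]
  clade_tips <- tr$tip.label[intersect(tr$edge[cl[[pick]], 2], 1:50)]
  scn <- scenario("shifted_clade", n_tips = 50,
                  shifts = list(list(tips = clade_tips, scalar = 25)),
                  seed = 70)
  sim <- simulate_jaw_traits(tr, scn)
  expect_setequal(sim$planted_edges, setdiff(cl[[pick]], pick))
  # same seed without the shift: clade tips must be far more variable with it
  plain <- simulate_jaw_traits(tr, scenario("decoupled", n_tips = 50, seed = 70))
  v_shift <- var(sim$block_a[clade_tips, 1])
  v_plain <- var(plain$block_a[clade_tips, 1])
  expect_gt(v_shift / v_plain, 3)
})

test_that("trait-to-landmark mapping is exact at zero scores and rank-1", {
  tpl <- default_premaxilla_template()
  basis <- make_deformation_basis(tpl, 3)
  expect_lt(max(abs(crossprod(basis) - diag(3))), 1e-12)

  zero <- matrix(0, 5, 3, dimnames = list(paste0("sp", 1:5), NULL))
  lms <- traits_to_landmarks(zero, tpl, basis, n_specimens = 2,
                             noise_sd = 0, seed = 71)
  for (i in seq_len(dim(lms$coords)[3])) {
    expect_lt(procrustes_distance(lms$coords[, , i], tpl), 1e-9)
  }

  # species differing along one basis vector: species-mean PCA is rank-1
  scores <- cbind(seq(-0.05, 0.05, length.out = 12), 0, 0)
  rownames(scores) <- sprintf("sp%02d", 1:12)
  lms1 <- traits_to_landmarks(scores, tpl, basis, n_specimens = 3,
                              noise_sd = 0, seed = 72)
  p <- shape_pca(species_mean_shapes(gpa(lms1)))
  expect_gt(p$percent_variance[1], 99)

  bad <- basis
  bad[, 2] <- bad[, 1]
  expect_error(traits_to_landmarks(zero, tpl, bad, seed = 1), "orthonormal")
})

test_that("within-species shape variance grows with the noise level", {
  tpl <- default_premaxilla_template()
  basis <- make_deformation_basis(tpl, 3)
  scores <- matrix(0, 3, 3, dimnames = list(paste0("sp", 1:3), NULL))
  spread <- vapply(c(0.001, 0.01, 0.1), function(sd0) {
    lms <- traits_to_landmarks(scores, tpl, basis, n_specimens = 8,
                               noise_sd = sd0, seed = 73)
    fit <- gpa(lms)
    mean(vapply(seq_len(dim(fit$coords)[3]), function(i) {
      procrustes_distance(fit$coords[, , i], fit$consensus)^2
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})

test_that("generators are byte-reproducible under a fixed seed", {
  scn <- scenario("coupled", n_tips = 12, n_specimens = c(2, 2), seed = 74)
  a <- simulate_dataset(scn)
  b <- simulate_dataset(scn)
  expect_identical(write_newick(a$tree), write_newick(b$tree))
  expect_identical(a$traits$block_a, b$traits$block_a)
  expect_identical(a$oral$coords, b$oral$coords)
  expect_identical(a$lpj_half$coords, b$lpj_half$coords)
})

test_that("coupled and decoupled scenarios separate through Approaches 1-2", {
  # 20 seeded replicates each at desk scale (60 tips): the coupled regime
  # must show a significant partial Mantel association and a PC1-PC1 PIC
  # correlation above the null band in >= 18; the decoupled regime must
  # stay inside the null band in >= 17
  run_once <- function(name, rho, seed) {
    scn <- scenario(name, n_tips = 60, rho = rho, n_specimens = c(4, 3),
                    seed = seed)
    sim <- simulate_dataset(scn)
    oral_means <- species_mean_shapes(gpa(sim$oral))
    full <- lapply(seq_len(dim(sim$lpj_half$coords)[3]), function(i) {
      mirror_landmarks(sim$lpj_half$coords[, , i], sim$lpj_midline_ids,
                       sim$lpj_paired_ids)
    })
    lpj_full <- landmark_set(full, sim$lpj_half$specimens$specimen_id,
                             sim$lpj_half$specimens$species_id, "lpj_full")
    lpj_means <- species_mean_shapes(gpa(lpj_full))
    ord <- sim$tree$tip.label
    mant <- partial_mantel(pairwise_shape_distances(oral_means, scale = FALSE)[ord, ord],
                           pairwise_shape_distances(lpj_means, scale = FALSE)[ord, ord],
                           patristic_distances(sim$tree)[ord, ord],
                           n_permutations = 199, seed = seed + 1)
    pc_o <- shape_pca(oral_means)$scores[, 1]
    pc_l <- shape_pca(lpj_means)$scores[, 1]
    nd <- null_correlations(sim$tree, 500, seed = seed + 2)
    r <- pic_correlation(pic_contrasts(sim$tree, pc_o),
                         pic_contrasts(sim$tree, pc_l))$r
    list(mantel_p = mant$p, r = r, lo = nd$ci95[1], hi = nd$ci95[2])
  }
  coupled_hits <- decoupled_hits <- 0
  for (s in 1:20) {
    co <- run_once("coupled", 0.9, 3000 + s)
    if (co$mantel_p <= 0.05 && (co$r < co$lo || co$r > co$hi)) {
      coupled_hits <- coupled_hits + 1
    }
    de <- run_once("decoupled", 0, 4000 + s)
    if (de$r >= de$lo && de$r <= de$hi) decoupled_hits <- decoupled_hits + 1
  }
  expect_gte(coupled_hits, 18)
  expect_gte(decoupled_hits, 17)
})
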