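# shared fixture builders (all programmatic; no files)

# the two smallest worked trees
tree2 <- function() read_newick("(A:1,B:1);")
tree3 <- function() read_newick("((A:1,B:1):1,C:2);")

# random labeled distance matrix (Euclidean, generic)
random_dist <- function(n, seed = NULL, labels = sprintf("s%02d", seq_len(n))) {
  if (!is.null(seed)) set.seed(seed)
  m <- as.matrix(stats::dist(matrix(stats::rnorm(n * 3), n)))
  dimnames(m) <- list(labels, labels)
  m
}

# brute-force patristic distances by walking root-to-tip paths
patristic_bruteforce <- function(tree) {
  n <- ape::Ntip(tree)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  path_to_root <- function(tip) {
    edges <- integer(0)
    node <- tip
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      edges <- c(edges, e)
      node <- tree$edge[e, 1]
    }
    edges
  }
  paths <- lapply(seq_len(n), path_to_root)
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- intersect(paths[[i]], paths[[j]])
      sym <- c(setdiff(paths[[i]], shared), setdiff(paths[[j]], shared))
      d[i, j] <- d[j, i] <- sum(tree$edge.length[sym])
    }
  }
  d
}

# minimum Procrustes deviation over a dense rotation grid (2-D only)
grid_procrustes_min <- function(a, b, scale = TRUE, step = 0.001) {
  ctr <- function(m) sweep(m, 2, colMeans(m))
  a <- ctr(a); b <- ctr(b)
  if (scale) {
    a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  }
  thetas <- seq(0, 2 * pi, by = step)
  min(vapply(thetas, function(th) {
    R <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
    sqrt(sum((a - b %*% R)^2))
  }, numeric(1)))
}

# hand-rolled partial correlation used as an independent oracle
oracle_partial_cor <- function(x, y, z) {
  r12 <- cor(x, y); r13 <- cor(x, z); r23 <- cor(y, z)
  (r12 - r13 * r23) / sqrt((1 - r13^2) * (1 - r23^2))
}

# a minimal fake posterior for summary-level tests
fake_posterior <- function(rel_rates, sigma2, traits = "PC1") {
  n <- nrow(rel_rates)
  sm <- data.frame(iteration = seq_len(n),
                   logL = rep(0, n), n_shifts = rep(0, n))
  for (tn in traits) sm[[paste0("alpha_", tn)]] <- rep(0, n)
  s2 <- as.matrix(sigma2)
  for (i in seq_along(traits)) sm[[paste0("sigma2_", traits[i])]] <- s2[, i]
  structure(list(samples = sm, rel_rates = rel_rates,
                 shifts = rep("", nrow(rel_rates)),
                 traits = traits,
                 acceptance = NULL, config = NULL, tree = NULL),
            class = "vr_posterior")
}
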