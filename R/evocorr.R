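# --- internal: canonical bifurcating traversal ------------------------------
#
# For every internal node we need (a) a deterministic ordering of its two
# children so contrast signs do not depend on tip input order, and (b) a
# deterministic ordering of the contrasts themselves. Children are ordered
# by the lexicographically smallest descendant tip label; contrasts are
# ordered by (smallest descendant tip label, clade size), which is unique
# because two clades share their smallest tip only when nested.
pic_engine <- function(tree, X) {
  n_tip <- ape::Ntip(tree)
  n_node <- tree$Nnode
  if (!is.matrix(X)) X <- matrix(X, ncol = 1, dimnames = list(names(X), NULL))
  if (is.null(rownames(X))) stop("trait values must be named by tip label")
  missing <- setdiff(tree$tip.label, rownames(X))
  if (length(missing)) {
    stop("missing trait value for tip(s): ", paste(missing, collapse = ", "))
  }
  X <- X[tree$tip.label, , drop = FALSE]
  child_edges <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  if (any(lengths(child_edges) != 2)) {
    stop("tree contains polytomies; contrasts require a bifurcating tree")
  }
  po <- ape::reorder.phylo(tree, "postorder")
  # children-first node order: a node's LAST edge in the postorder edge list
  # comes after every edge in its subtree, so sorting internal nodes by last
  # appearance guarantees both children are resolved before their parent
  last_idx <- tapply(seq_len(nrow(po$edge)), po$edge[, 1], max)
  node_order <- as.integer(names(sort(last_idx)))
  vals <- matrix(NA_real_, n_tip + n_node, ncol(X))
  vals[seq_len(n_tip), ] <- X
  v_extra <- numeric(n_tip + n_node)
  min_tip <- character(n_tip + n_node)
  min_tip[seq_len(n_tip)] <- tree$tip.label
  clade_n <- integer(n_tip + n_node)
  clade_n[seq_len(n_tip)] <- 1L
  contrasts <- matrix(NA_real_, n_node, ncol(X))
  key_label <- character(n_node)
  key_size <- integer(n_node)
  var_c <- numeric(n_node)
  for (i in seq_along(node_order)) {
    nd <- node_order[i]
    es <- child_edges[[as.character(nd)]]
    ch <- tree$edge[es, 2]
    ord <- order(min_tip[ch])
    es <- es[ord]; ch <- ch[ord]
    v <- tree$edge.length[es] + v_extra[ch]
    contrasts[i, ] <- (vals[ch[1], ] - vals[ch[2], ]) / sqrt(sum(v))
    var_c[i] <- sum(v)
    vals[nd, ] <- (vals[ch[1], ] / v[1] + vals[ch[2], ] / v[2]) / (1 / v[1] + 1 / v[2])
    v_extra[nd] <- v[1] * v[2] / sum(v)
    min_tip[nd] <- min_tip[ch[1]]
    clade_n[nd] <- clade_n[ch[1]] + clade_n[ch[2]]
    key_label[i] <- min_tip[nd]
    key_size[i] <- clade_n[nd]
  }
  root <- node_order[length(node_order)]
  ord <- order(key_label, key_size)
  list(contrasts = contrasts[ord, , drop = FALSE],
       contrast_var = var_c[ord],
       node_key = paste0(key_label, "+", key_size)[ord],
       root_value = vals[root, ],
       root_var = v_extra[root])
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's pruning recursion: at each internal node with child
#' values x_i, x_j on (variance-adjusted) branch lengths v_i, v_j, the
#' standardized contrast is (x_i - x_j) / sqrt(v_i + v_j); the node is
#' assigned the weighted mean value and its parent branch is lengthened by
#' v_i v_j / (v_i + v_j). Contrast signs are fixed by always subtracting
#' the child whose clade contains the lexicographically larger smallest
#' tip label, so results do not depend on tip input order. Under Brownian
#' motion with rate sigma^2 the contrasts are iid N(0, sigma^2).
#'
#' @param tree A bifurcating `phylo` object.
#' @param trait Named numeric vector (names = tip labels), one value per tip.
#' @return Object of class `"pic_set"`: `contrasts` (named numeric vector
#'   of length n_tips - 1, deterministic order), `contrast_var` (the
#'   variance sums v_i + v_j), `n_tips`.
#' @export
pic_contrasts <- function(tree, trait) {
  validate_phylogeny(tree, require_ultrametric = FALSE)
  eng <- pic_engine(tree, trait)
  structure(
    list(contrasts = stats::setNames(drop(eng$contrasts), eng$node_key),
         contrast_var = eng$contrast_var,
         n_tips = ape::Ntip(tree)),
    class = "pic_set"
  )
}

#' Through-origin correlation of two contrast sets
#'
#' Because contrasts have an arbitrary sign and zero expectation under
#' Brownian motion, their correlation is computed through the origin:
#' r = sum(x y) / sqrt(sum(x^2) sum(y^2)), with degrees of freedom
#' n_contrasts - 1 and a two-tailed p-value from the t distribution. On a
#' bifurcating tree with n tips this gives n - 1 contrasts and df = n - 2.
#'
#' @param x,y `"pic_set"` objects from [pic_contrasts()] on the same tree,
#'   or plain numeric vectors of equal length.
#' @return Object of class `"cor_result"`: `r`, `p`, `df`, `n`.
#' @export
pic_correlation <- function(x, y) {
  cx <- if (inherits(x, "pic_set")) x$contrasts else x
  cy <- if (inherits(y, "pic_set")) y$contrasts else y
  if (length(cx) != length(cy)) stop("contrast sets differ in length")
  if (inherits(x, "pic_set") && inherits(y, "pic_set") &&
      !identical(names(cx), names(cy))) {
    stop("contrast sets come from different trees or node orders")
  }
  sxx <- sum(cx^2); syy <- sum(cy^2)
  if (sxx == 0 || syy == 0) stop("zero-variance contrasts")
  r <- sum(cx * cy) / sqrt(sxx * syy)
  df <- length(cx) - 1L
  t_stat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(list(r = r, p = p, df = df, n = length(cx)), class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("r = %.4f, p = %.4g, df = %d\n", x$r, x$p, x$df))
  invisible(x)
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Recursive simulation from the root: each child value is its parent's
#' value plus a Normal(0, rate * branch length) increment.
#'
#' @param tree A `phylo` object.
#' @param rate Brownian rate sigma^2 per My (> 0).
#' @param root_state Trait value at the root.
#' @param n Number of independent replicate traits.
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip values when `n = 1`, otherwise a
#'   tips x n matrix with tip labels as rownames.
#' @export
bm_simulate <- function(tree, rate = 1, root_state = 0, n = 1, seed = NULL) {
  if (rate <= 0) stop("rate must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n_tip <- ape::Ntip(tree)
  n_nodes <- n_tip + tree$Nnode
  vals <- matrix(NA_real_, n_nodes, n)
  vals[n_tip + 1L, ] <- root_state
  # preorder: parents before children
  co <- ape::reorder.phylo(tree, "cladewise")
  incr <- matrix(stats::rnorm(nrow(co$edge) * n), nrow(co$edge), n)
  for (e in seq_len(nrow(co$edge))) {
    vals[co$edge[e, 2], ] <- vals[co$edge[e, 1], ] +
      sqrt(rate * co$edge.length[e]) * incr[e, ]
  }
  out <- vals[seq_len(n_tip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  if (n == 1) stats::setNames(out[, 1], tree$tip.label) else out
}

#' Null distribution of PIC correlations under uncorrelated Brownian motion
#'
#' Simulates `n_pairs` independent pairs of unit-rate Brownian traits on
#' the tree and computes the through-origin PIC correlation of each pair.
#' The min/max of the resulting values is the empirical null band against
#' which observed evolutionary correlations are judged.
#'
#' @param tree A bifurcating `phylo` object.
#' @param n_pairs Number of independent trait pairs (>= 1).
#' @param seed Optional integer seed.
#' @return Object of class `"null_dist"`: `r_values`, `min`, `max`,
#'   `ci95` (central 95% bounds), `n_pairs`.
#' @export
null_correlations <- function(tree, n_pairs = 1000, seed = NULL) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  traits <- bm_simulate(tree, rate = 1, root_state = 0, n = 2 * n_pairs,
                        seed = seed)
  eng <- pic_engine(tree, traits)
  cx <- eng$contrasts[, seq_len(n_pairs) * 2 - 1, drop = FALSE]
  cy <- eng$contrasts[, seq_len(n_pairs) * 2, drop = FALSE]
  r <- colSums(cx * cy) / sqrt(colSums(cx^2) * colSums(cy^2))
  structure(
    list(r_values = r, min = min(r), max = max(r),
         ci95 = stats::quantile(r, c(0.025, 0.975), names = FALSE),
         n_pairs = n_pairs, seed = seed),
    class = "null_dist"
  )
}

#' @export
print.null_dist <- function(x, ...) {
  cat(sprintf("BM null distribution (%d pairs): range [%.3f, %.3f], central 95%% [%.3f, %.3f]\n",
              x$n_pairs, x$min, x$max, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Grid of PIC correlations between two trait blocks, with null bounds
#'
#' Computes the through-origin PIC correlation for every column pair of
#' two species-by-trait matrices (e.g. the first three PC axes of each
#' jaw) and flags which correlations fall outside the empirical
#' Brownian-motion null band.
#'
#' @param tree Bifurcating `phylo`.
#' @param block_a,block_b Species x trait matrices (rownames = tip labels).
#' @param null A `"null_dist"` from [null_correlations()], or `NULL` to skip
#'   the flag.
#' @return Data frame with columns `trait_a`, `trait_b`, `r`, `p`, `df`,
#'   and (when `null` is given) `outside_null`.
#' @export
pic_correlation_grid <- function(tree, block_a, block_b, null = NULL) {
  pics_a <- lapply(seq_len(ncol(block_a)), function(j)
    pic_contrasts(tree, stats::setNames(block_a[, j], rownames(block_a))))
  pics_b <- lapply(seq_len(ncol(block_b)), function(j)
    pic_contrasts(tree, stats::setNames(block_b[, j], rownames(block_b))))
  na <- colnames(block_a); if (is.null(na)) na <- paste0("A", seq_len(ncol(block_a)))
  nb <- colnames(block_b); if (is.null(nb)) nb <- paste0("B", seq_len(ncol(block_b)))
  grid <- expand.grid(a = seq_along(pics_a), b = seq_along(pics_b))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cr <- pic_correlation(pics_a[[grid$a[i]]], pics_b[[grid$b[i]]])
    data.frame(trait_a = na[grid$a[i]], trait_b = nb[grid$b[i]],
               r = cr$r, p = cr$p, df = cr$df)
  })
  out <- do.call(rbind, rows)
  if (!is.null(null)) out$outside_null <- out$r < null$min | out$r > null$max
  out
}

# symmetric inverse square root with eigenvalue floor
inv_sqrt_sym <- function(C, floor = 1e-12) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) <= floor * max(e$values)) {
    stop("phylogenetic covariance matrix is computationally singular")
  }
  vals <- pmax(e$values, floor)
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

#' Phylogenetic two-block partial least squares
#'
#' Measures morphological integration between two multivariate blocks
#' (e.g. the aligned landmarks of two jaws) in an evolutionary framework:
#' each block is centered on its phylogenetic GLS mean, the evolutionary
#' cross-covariance R12 = X1c' C^-1 X2c / (n - 1) is decomposed by SVD,
#' and the paired scores are the phylogenetically transformed data
#' (C^-1/2 X_c) projected onto the first singular vectors. `r_pls` is the
#' Pearson correlation of those paired scores; significance comes from
#' permuting the species rows of the transformed second block (add-one
#' rule).
#'
#' @param block1,block2 Species x variable matrices, rownames = tip labels.
#' @param tree A `phylo` covering all rows.
#' @param n_permutations Permutations for the p-value (default 999).
#' @param seed Optional integer seed.
#' @return Object of class `"pls_result"`: `r_pls`, `p`, `u`, `v` (first
#'   singular vectors), `scores1`, `scores2`, `singular_values`.
#' @export
phylo_pls <- function(block1, block2, tree, n_permutations = 999, seed = NULL) {
  block1 <- as.matrix(block1); block2 <- as.matrix(block2)
  if (is.null(rownames(block1)) || is.null(rownames(block2))) {
    stop("blocks must carry species ids as rownames")
  }
  sp <- tree$tip.label
  if (!all(sp %in% rownames(block1)) || !all(sp %in% rownames(block2))) {
    stop("blocks must cover every tip of the tree")
  }
  if (length(sp) < 3) stop("need at least 3 species")
  X1 <- block1[sp, , drop = FALSE]; X2 <- block2[sp, , drop = FALSE]
  n <- length(sp)
  C <- phylo_covariance(tree)
  Cinv_half <- inv_sqrt_sym(C)
  Cinv <- Cinv_half %*% Cinv_half
  one <- rep(1, n)
  gls_mean <- function(X) drop(crossprod(one, Cinv %*% X)) / sum(Cinv)
  Z1 <- Cinv_half %*% sweep(X1, 2, gls_mean(X1))
  Z2 <- Cinv_half %*% sweep(X2, 2, gls_mean(X2))
  pls_r <- function(Z2x) {
    s <- svd(crossprod(Z1, Z2x) / (n - 1))
    if (s$d[1] <= 1e-14) return(NULL)
    s1 <- Z1 %*% s$u[, 1]; s2 <- Z2x %*% s$v[, 1]
    list(r = abs(stats::cor(s1, s2)), u = s$u[, 1], v = s$v[, 1],
         s1 = s1, s2 = s2, d = s$d)
  }
  obs <- pls_r(Z2)
  if (is.null(obs)) stop("cross-covariance between blocks has rank 0")
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_permutations)) {
    perm <- pls_r(Z2[sample.int(n), , drop = FALSE])
    if (!is.null(perm) && perm$r >= obs$r - 1e-12) exceed <- exceed + 1L
  }
  structure(
    list(r_pls = drop(obs$r), p = (exceed + 1) / (n_permutations + 1),
         u = obs$u, v = obs$v,
         scores1 = stats::setNames(drop(obs$s1), sp),
         scores2 = stats::setNames(drop(obs$s2), sp),
         singular_values = obs$d,
         n_permutations = n_permutations, seed = seed),
    class = "pls_result"
  )
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("phylogenetic two-block PLS: r = %.4f, p = %.4g (%d permutations)\n",
              x$r_pls, x$p, x$n_permutations))
  invisible(x)
}
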