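#' Pairwise Procrustes distance matrix between species mean shapes
#'
#' Divergence within one jaw is quantified as the Procrustes distance
#' between every pair of species mean shapes, using the full
#' multidimensional landmark data rather than a reduced ordination.
#'
#' @param means K x dims x n_species array (species ids as third
#'   dimnames), e.g. from [species_mean_shapes()].
#' @param scale Passed to [procrustes_distance()].
#' @return Symmetric matrix with zero diagonal and species ids as dimnames.
#' @export
pairwise_shape_distances <- function(means, scale = TRUE) {
  sp <- dimnames(means)[[3]]
  if (is.null(sp)) stop("species ids required as third dimnames")
  if (anyDuplicated(sp)) stop("duplicate species ids")
  n <- length(sp)
  if (n < 2) stop("need at least 2 species")
  d <- matrix(0, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- procrustes_distance(means[, , i], means[, , j],
                                                scale = scale)
    }
  }
  d
}

# lower-triangle vector of a square matrix
lower_tri <- function(m) m[lower.tri(m)]

# partial correlation of x and y given z (Pearson, first order)
partial_cor <- function(x, y, z) {
  r12 <- stats::cor(x, y); r13 <- stats::cor(x, z); r23 <- stats::cor(y, z)
  (r12 - r13 * r23) / sqrt((1 - r13^2) * (1 - r23^2))
}

#' Partial Mantel test between two distance matrices
#'
#' Tests the association between `d1` and `d2` while controlling for a
#' third matrix (typically patristic distances), using the first-order
#' partial Pearson correlation over the lower-triangle entries. The null
#' distribution is built by jointly permuting rows and columns of `d1` and
#' recomputing the statistic; the one-tailed p-value for a positive
#' association uses the add-one rule, so p is never exactly 0. If the
#' control matrix is constant it is bypassed (with a warning) and the
#' statistic degrades to the simple Mantel correlation of `d1` and `d2`.
#'
#' @param d1,d2 Symmetric distance matrices with identical dimnames.
#' @param control Control distance matrix (same labels); `NULL` for a
#'   simple Mantel test.
#' @param n_permutations Number of random permutations (>= 99); ignored
#'   when `exhaustive = TRUE`.
#' @param seed Optional integer seed for the permutations.
#' @param exhaustive Enumerate all n! label permutations (identity
#'   included) instead of sampling; the p-value is then the exact fraction
#'   of permutations with a statistic >= the observed one. Only sensible
#'   for small matrices.
#' @return An object of class `"mantel_result"`: `r`, `p`,
#'   `n_permutations`, `seed`, `partial` (logical).
#' @export
partial_mantel <- function(d1, d2, control = NULL, n_permutations = 999,
                           seed = NULL, exhaustive = FALSE) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  labs <- rownames(d1)
  if (is.null(labs)) stop("distance matrices must carry labels as dimnames")
  check <- function(m, what) {
    if (!identical(rownames(m), labs) || !identical(colnames(m), labs)) {
      stop(what, " labels do not match d1")
    }
  }
  check(d1, "d1"); check(d2, "d2")
  v1 <- lower_tri(d1); v2 <- lower_tri(d2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("constant distance matrix: Mantel statistic undefined")
  }
  partial <- !is.null(control)
  if (partial) {
    control <- as.matrix(control)
    check(control, "control")
    if (stats::sd(lower_tri(control)) == 0) {
      warning("constant control matrix; falling back to a simple Mantel test")
      partial <- FALSE
    }
  }
  stat <- function(m1) {
    a <- lower_tri(m1)
    if (partial) partial_cor(a, v2, lower_tri(control)) else stats::cor(a, v2)
  }
  r_obs <- stat(d1)
  n <- nrow(d1)
  if (exhaustive) {
    perms <- all_permutations(n)
    stats_all <- vapply(perms, function(p) stat(d1[p, p]), numeric(1))
    p_val <- mean(stats_all >= r_obs - 1e-12)
    n_perm <- length(perms)
  } else {
    if (n_permutations < 99) stop("n_permutations must be >= 99")
    if (!is.null(seed)) set.seed(seed)
    exceed <- 0L
    for (i in seq_len(n_permutations)) {
      p <- sample.int(n)
      if (stat(d1[p, p]) >= r_obs - 1e-12) exceed <- exceed + 1L
    }
    p_val <- (exceed + 1) / (n_permutations + 1)
    n_perm <- n_permutations
  }
  structure(
    list(r = r_obs, p = p_val, n_permutations = n_perm, seed = seed,
         partial = partial, exhaustive = exhaustive),
    class = "mantel_result"
  )
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%s Mantel test: r = %.4f, p = %.4g (%d %s permutations)\n",
              if (x$partial) "partial" else "simple", x$r, x$p,
              x$n_permutations,
              if (x$exhaustive) "exhaustive" else "random"))
  invisible(x)
}

# all permutations of 1..n as a list (n <= 8 guard keeps this sane)
all_permutations <- function(n) {
  if (n > 8) stop("exhaustive enumeration limited to n <= 8")
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos)
    }
  }
  out
}

#' Read / write a labeled square distance matrix as CSV
#'
#' @param file CSV path; first column holds the labels.
#' @return A labeled symmetric matrix.
#' @export
read_distance_csv <- function(file) {
  df <- utils::read.csv(file, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix must be symmetric")
  dimnames(m) <- list(rownames(df), rownames(df))
  m
}

#' @rdname read_distance_csv
#' @param m Labeled square matrix to write.
#' @export
write_distance_csv <- function(m, file) {
  utils::write.csv(as.data.frame(m), file)
  invisible(file)
}
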