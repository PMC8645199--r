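#' Assemble a landmark dataset
#'
#' Landmark configurations are stored geomorph-style as a 3-D array of
#' dimension K landmarks x dims x N specimens, bundled with a specimen
#' table mapping specimens to species.
#'
#' @param coords Numeric array K x dims x N (dims 2 or 3), or a list of
#'   K x dims matrices of identical shape.
#' @param specimen_id Character vector, length N, unique.
#' @param species_id Character vector, length N.
#' @param structure Label for the anatomical structure, e.g.
#'   `"oral_full_skeleton"`, `"oral_premaxilla"`, `"lpj_half"`, `"lpj_full"`.
#' @return An object of class `"landmark_set"`.
#' @export
landmark_set <- function(coords, specimen_id, species_id,
                         structure = "structure") {
  if (is.list(coords)) {
    dims <- unique(lapply(coords, dim))
    if (length(dims) != 1) stop("configurations differ in landmark count or dimension")
    coords <- array(unlist(coords), dim = c(dims[[1]], length(coords)))
  }
  if (length(dim(coords)) != 3) stop("coords must be a K x dims x N array")
  if (!dim(coords)[2] %in% 2:3) stop("landmark dimension must be 2 or 3")
  if (anyNA(coords)) stop("missing coordinates are not supported")
  n <- dim(coords)[3]
  specimen_id <- as.character(specimen_id)
  species_id <- as.character(species_id)
  if (length(specimen_id) != n || length(species_id) != n) {
    stop("specimen_id/species_id must match the number of configurations")
  }
  if (anyDuplicated(specimen_id)) stop("specimen ids must be unique")
  dimnames(coords)[[3]] <- specimen_id
  structure(
    list(coords = coords,
         specimens = data.frame(specimen_id = specimen_id,
                                species_id = species_id),
         structure = structure),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("landmark_set '%s': %d landmarks x %dD x %d specimens (%d species)\n",
              x$structure, d[1], d[2], d[3],
              length(unique(x$specimens$species_id))))
  invisible(x)
}

# centroid of one configuration (K x d matrix)
centroid <- function(m) colMeans(m)

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of all landmarks from
#' their centroid — the standard size measure in geometric morphometrics.
#'
#' @param m A K x dims coordinate matrix.
#' @return Positive scalar.
#' @export
centroid_size <- function(m) {
  sqrt(sum(scale(m, scale = FALSE)^2))
}

# Optimal rotation (det +1) aligning X onto ref, both centered:
# Kabsch via SVD of t(X) %*% ref.
optimal_rotation <- function(X, ref) {
  s <- svd(crossprod(X, ref))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(s$v)
  }
  R
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of all configurations: translation is removed
#' (centroids to the origin), size optionally standardized to unit centroid
#' size, and each configuration rotated to minimize its summed squared
#' distance to the current consensus; the consensus is re-estimated until
#' it changes by less than `tol` (summed squared coordinate change) or
#' `max_iter` iterations.
#'
#' @param lms A [landmark_set()] with at least two specimens.
#' @param scale Remove size by scaling every configuration to unit centroid
#'   size (default `TRUE`).
#' @param tol Convergence tolerance on the consensus update (default 1e-10).
#' @param max_iter Iteration cap (default 100).
#' @return An object of class `"gpa_fit"`: the input `landmark_set` with
#'   aligned coordinates, plus `centroid_sizes`, `consensus`, `scale`, and
#'   the iteration count.
#' @export
gpa <- function(lms, scale = TRUE, tol = 1e-10, max_iter = 100) {
  stopifnot(inherits(lms, "landmark_set"))
  a <- lms$coords
  n <- dim(a)[3]
  if (n < 2) stop("GPA needs at least 2 configurations")
  cs <- numeric(n)
  for (i in seq_len(n)) {
    m <- a[, , i]
    m <- sweep(m, 2, centroid(m))
    cs[i] <- sqrt(sum(m^2))
    if (cs[i] < 1e-12) {
      stop("degenerate configuration (all landmarks coincide): specimen ",
           lms$specimens$specimen_id[i])
    }
    if (scale) m <- m / cs[i]
    a[, , i] <- m
  }
  consensus <- a[, , 1]
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_len(n)) a[, , i] <- a[, , i] %*% optimal_rotation(a[, , i], consensus)
    new_consensus <- apply(a, c(1, 2), mean)
    if (scale) new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
    delta <- sum((new_consensus - consensus)^2)
    consensus <- new_consensus
    if (delta < tol || iter >= max_iter) break
  }
  # canonical orientation: rotate everything so the consensus lies on its
  # principal axes (largest-magnitude loading positive per axis, proper
  # rotation), making the result invariant to any common rigid motion of
  # the inputs
  sv <- svd(consensus)
  rot <- sv$v
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  if (det(rot) < 0) rot[, which.min(sv$d)] <- -rot[, which.min(sv$d)]
  consensus <- consensus %*% rot
  for (i in seq_len(n)) a[, , i] <- a[, , i] %*% rot
  names(cs) <- lms$specimens$specimen_id
  out <- lms
  out$coords <- a
  out$centroid_sizes <- cs
  out$consensus <- consensus
  out$scale <- scale
  out$iterations <- iter
  class(out) <- c("gpa_fit", "landmark_set")
  out
}

#' Mirror a half-configuration across its bilateral symmetry plane
#'
#' For bilaterally symmetric structures digitized on one side only
#' (e.g. a lower pharyngeal jaw with landmarks on the left half), the
#' paired landmarks are reflected across the least-squares symmetry plane
#' fitted through the midline landmarks, and the midline landmarks are
#' projected onto that plane. A 27-landmark half configuration with 12
#' midline and 15 paired landmarks therefore becomes a 42-landmark full
#' configuration.
#'
#' @param config A K x 3 coordinate matrix (one specimen).
#' @param midline_ids Indices of landmarks lying on the symmetry plane.
#' @param paired_ids Indices of landmarks to reflect; together with
#'   `midline_ids` these must partition `1:K`.
#' @return A (|midline| + 2 |paired|) x 3 matrix: the input landmarks in
#'   their original order (midline projected onto the plane), followed by
#'   the mirrored copies of the paired landmarks in `paired_ids` order.
#' @export
mirror_landmarks <- function(config, midline_ids, paired_ids) {
  config <- as.matrix(config)
  if (ncol(config) != 3) stop("mirroring requires 3-D coordinates")
  k <- nrow(config)
  if (!setequal(c(midline_ids, paired_ids), seq_len(k)) ||
      length(intersect(midline_ids, paired_ids))) {
    stop("midline_ids and paired_ids must partition the landmarks")
  }
  mid <- config[midline_ids, , drop = FALSE]
  if (nrow(mid) < 3) stop("need at least 3 midline landmarks to define a plane")
  ctr <- colMeans(mid)
  sv <- svd(sweep(mid, 2, ctr))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300)) {
    stop("midline landmarks are collinear; symmetry plane is undefined")
  }
  normal <- sv$v[, 3]
  plane_dist <- function(p) as.vector(sweep(p, 2, ctr) %*% normal)
  reflect <- function(p) p - 2 * outer(plane_dist(p), normal)
  project <- function(p) p - outer(plane_dist(p), normal)
  out <- config
  out[midline_ids, ] <- project(mid)
  mirrored <- reflect(config[paired_ids, , drop = FALSE])
  res <- rbind(out, mirrored)
  rownames(res) <- NULL
  res
}

#' Extract and re-center a landmark subset after whole-configuration GPA
#'
#' Takes the named landmarks verbatim from an existing alignment and only
#' translates them so the subset centroid sits at the origin: no
#' re-rotation and no re-scaling. The subset therefore keeps its size and
#' orientation relative to the whole configuration — for a premaxilla
#' embedded in a whole-skeleton alignment this preserves relative jaw size
#' and the jaw angle against the body axes, not just its shape.
#'
#' @param aligned A `"gpa_fit"` from [gpa()].
#' @param subset_ids Landmark indices to extract (the premaxilla uses 4).
#' @param n_expected Expected subset length (default 4); set `NULL` to skip.
#' @param structure Structure label for the result.
#' @return A `landmark_set` of the re-centered subset configurations.
#' @export
extract_recentered_subset <- function(aligned, subset_ids, n_expected = 4,
                                      structure = "oral_premaxilla") {
  stopifnot(inherits(aligned, "gpa_fit"))
  k <- dim(aligned$coords)[1]
  if (!is.null(n_expected) && length(subset_ids) != n_expected) {
    stop("expected ", n_expected, " subset landmarks, got ", length(subset_ids))
  }
  if (any(subset_ids < 1 | subset_ids > k)) stop("subset_ids out of range")
  sub <- aligned$coords[subset_ids, , , drop = FALSE]
  for (i in seq_len(dim(sub)[3])) {
    sub[, , i] <- sweep(sub[, , i], 2, centroid(sub[, , i]))
  }
  landmark_set(sub, aligned$specimens$specimen_id,
               aligned$specimens$species_id, structure = structure)
}

#' Species mean shapes from aligned specimens
#'
#' @param aligned A `landmark_set` (typically a `gpa_fit` or an extracted
#'   subset) whose specimens are already superimposed.
#' @return A K x dims x n_species array of coordinate-wise species means,
#'   species ids as the third dimnames, sorted by species id.
#' @export
species_mean_shapes <- function(aligned) {
  stopifnot(inherits(aligned, "landmark_set"))
  sp <- sort(unique(aligned$specimens$species_id))
  d <- dim(aligned$coords)
  out <- array(NA_real_, c(d[1], d[2], length(sp)), dimnames = list(NULL, NULL, sp))
  for (s in sp) {
    idx <- which(aligned$specimens$species_id == s)
    if (!length(idx)) stop("no specimens for species ", s)
    out[, , s] <- apply(aligned$coords[, , idx, drop = FALSE], c(1, 2), mean)
  }
  out
}

#' Procrustes distance between two configurations
#'
#' The square root of the summed squared coordinate differences after
#' optimally superimposing `b` onto `a` (translation + rotation, and
#' scaling to unit centroid size when `scale = TRUE`, matching the
#' alignment the shapes came from).
#'
#' @param a,b K x dims coordinate matrices with identical dimensions.
#' @param scale Standardize both shapes to unit centroid size first.
#' @return Non-negative scalar; 0 for identical shapes.
#' @export
procrustes_distance <- function(a, b, scale = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("configurations differ in landmarks or dimension")
  a <- sweep(a, 2, centroid(a)); b <- sweep(b, 2, centroid(b))
  if (scale) {
    a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  }
  b <- b %*% optimal_rotation(b, a)
  sqrt(sum((a - b)^2))
}

#' Principal component analysis of species mean shapes
#'
#' Eigen-decomposition (via SVD) of the species-level covariance of the
#' flattened, centered landmark coordinates. Axis signs are fixed so that
#' each axis's largest-magnitude loading is positive, making orientations
#' reproducible. Per-axis extreme shapes (consensus deformed to the
#' observed score range) are returned for interpretation.
#'
#' @param means K x dims x n_species array, e.g. from
#'   [species_mean_shapes()].
#' @return An object of class `"shape_pca"`: `scores` (species x axes,
#'   zero column means), `percent_variance`, `loadings`, `consensus`, and
#'   `axis_deformations` (per axis, the `lo`/`hi` extreme configurations).
#' @export
shape_pca <- function(means) {
  d <- dim(means)
  if (length(d) != 3 || d[3] < 3) stop("need at least 3 species mean shapes")
  sp <- dimnames(means)[[3]]
  X <- t(apply(means, 3, as.numeric))  # species x (K*dims)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  keep <- which(sv$d > max(sv$d) * 1e-12)
  load <- sv$v[, keep, drop = FALSE]
  # orient each axis so its largest |loading| is positive
  for (j in seq_len(ncol(load))) {
    m <- which.max(abs(load[, j]))
    if (load[m, j] < 0) load[, j] <- -load[, j]
  }
  scores <- Xc %*% load
  ev <- sv$d[keep]^2
  rownames(scores) <- sp
  colnames(scores) <- colnames(load) <- paste0("PC", seq_along(keep))
  deform <- lapply(seq_along(keep), function(j) {
    rng <- range(scores[, j])
    list(lo = array(ctr + rng[1] * load[, j], d[1:2]),
         hi = array(ctr + rng[2] * load[, j], d[1:2]))
  })
  names(deform) <- colnames(scores)
  structure(
    list(scores = scores,
         percent_variance = 100 * ev / sum(ev),
         loadings = load,
         consensus = array(ctr, d[1:2]),
         axis_deformations = deform),
    class = "shape_pca"
  )
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("shape_pca: %d species, %d axes\n", nrow(x$scores), ncol(x$scores)))
  pv <- round(x$percent_variance[seq_len(min(5, length(x$percent_variance)))], 1)
  cat("  % variance:", paste0(pv, "%", collapse = ", "),
      if (length(x$percent_variance) > 5) "..." else "", "\n")
  invisible(x)
}

# area of a (planar) polygon given vertex coordinates in order;
# 2-D uses the shoelace formula, 3-D the cross-product sum.
polygon_area <- function(v) {
  n <- nrow(v)
  if (n < 3) stop("a polygon needs at least 3 vertices")
  if (ncol(v) == 2) {
    x <- v[, 1]; y <- v[, 2]
    j <- c(2:n, 1)
    return(abs(sum(x * y[j] - x[j] * y)) / 2)
  }
  ctr <- colMeans(v)
  tot <- c(0, 0, 0)
  for (i in seq_len(n)) {
    jj <- if (i == n) 1L else i + 1L
    a <- v[i, ] - ctr; b <- v[jj, ] - ctr
    tot <- tot + c(a[2] * b[3] - a[3] * b[2],
                   a[3] * b[1] - a[1] * b[3],
                   a[1] * b[2] - a[2] * b[1])
  }
  sqrt(sum(tot^2)) / 2
}

#' Extract metric traits from a landmark configuration
#'
#' Supported trait definitions (each a named list with a `type` field):
#' \describe{
#'   \item{`angle`}{`from1`,`to1`,`from2`,`to2`: angle in degrees (0-180)
#'     between the vectors `from1 -> to1` and `from2 -> to2`.}
#'   \item{`distance_ratio`}{`a1`,`a2`,`b1`,`b2`: d(a1,a2) / d(b1,b2).}
#'   \item{`relative_length`}{`a1`,`a2`: d(a1,a2) / centroid size.}
#'   \item{`area_ratio`}{`inner`,`outer`: landmark index vectors defining
#'     two polygons; ratio of their areas (e.g. the proportion of a bone
#'     outline covered by the tooth field).}
#' }
#' Angles and ratios are invariant to rotation and translation;
#' `relative_length` and `area_ratio` are additionally scale-invariant.
#'
#' @param config K x dims coordinate matrix.
#' @param trait_defs Named list of trait definitions.
#' @return Named numeric vector, one value per trait.
#' @export
metric_traits <- function(config, trait_defs) {
  config <- as.matrix(config)
  k <- nrow(config)
  idx_ok <- function(i) all(i >= 1 & i <= k)
  seg_len <- function(i, j) sqrt(sum((config[i, ] - config[j, ])^2))
  out <- vapply(trait_defs, function(td) {
    switch(td$type,
      angle = {
        stopifnot(idx_ok(c(td$from1, td$to1, td$from2, td$to2)))
        v1 <- config[td$to1, ] - config[td$from1, ]
        v2 <- config[td$to2, ] - config[td$from2, ]
        if (sum(v1^2) < 1e-24 || sum(v2^2) < 1e-24) {
          stop("coincident landmarks define a zero-length vector")
        }
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      },
      distance_ratio = {
        stopifnot(idx_ok(c(td$a1, td$a2, td$b1, td$b2)))
        den <- seg_len(td$b1, td$b2)
        if (den < 1e-24) stop("coincident landmarks in ratio denominator")
        seg_len(td$a1, td$a2) / den
      },
      relative_length = {
        stopifnot(idx_ok(c(td$a1, td$a2)))
        seg_len(td$a1, td$a2) / centroid_size(config)
      },
      area_ratio = {
        stopifnot(idx_ok(c(td$inner, td$outer)))
        polygon_area(config[td$inner, , drop = FALSE]) /
          polygon_area(config[td$outer, , drop = FALSE])
      },
      stop("unknown trait type: ", td$type)
    )
  }, numeric(1))
  names(out) <- names(trait_defs)
  out
}
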