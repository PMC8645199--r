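# Synthetic radiation generator: an ultrametric pure-birth tree, jointly
# evolving trait blocks for two jaws with controllable cross-jaw coupling,
# and landmark datasets deformed along orthonormal shape axes with
# specimen-level noise and nuisance rigid motions. Emulates the structure
# of a cichlid-like radiation (~234 species in ~10 My, 10 / 5 specimens
# per species) so that every pipeline stage can be exercised without any
# external data.

#' Simulate an ultrametric pure-birth tree
#'
#' A Yule tree with exactly `n_tips` tips, branch lengths rescaled so the
#' root age equals `root_age` exactly. Tip labels are `sp001`, `sp002`, ...
#'
#' @param n_tips Number of tips (>= 2).
#' @param root_age Root age in My (> 0).
#' @param seed Optional integer seed; the tree is byte-reproducible given it.
#' @return An ultrametric `phylo` object.
#' @export
simulate_tree <- function(n_tips, root_age = 10, seed = NULL) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (root_age <= 0) stop("root_age must be > 0")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (root_age / depth)
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  tree
}

#' Define a simulation scenario for two coupled trait complexes
#'
#' Named coupling regimes:
#' \describe{
#'   \item{`coupled`}{constant cross-block correlation (default rho 0.9).}
#'   \item{`decoupled`}{rho 0 throughout.}
#'   \item{`late_decoupled`}{rho `rho_old` (default 0.8) on branch segments
#'     older than `change_age` (default 2 My) and `rho_young` (default 0)
#'     on younger segments; branches crossing the change age are split at
#'     it.}
#'   \item{`shifted_clade`}{decoupled traits plus a planted rate shift
#'     multiplying increment variance on all branches of a named clade.}
#' }
#' Coupling acts on the Brownian increments (the process), not on tip
#' values: matched axes of the two blocks (A1-B1, A2-B2, A3-B3) receive
#' correlated innovations.
#'
#' @param name One of the regimes above.
#' @param n_tips,root_age Tree size (defaults 234 tips, 10 My).
#' @param rho Cross-block correlation for the constant-coupling regimes.
#' @param rho_old,rho_young,change_age Age-dependent coupling
#'   (late_decoupled).
#' @param shifts List of `list(tips = <tip labels>, scalar = <multiplier>)`
#'   planted rate shifts; for `shifted_clade` with `shifts = NULL` a clade
#'   of roughly `n_tips / 5` tips is selected at generation time with a
#'   10x scalar.
#' @param rate_a,rate_b Per-axis Brownian rates of the two blocks
#'   (sigma^2 per My); defaults sit inside the rate model's default priors.
#' @param n_specimens Specimens per species, `c(a = ..., b = ...)`
#'   (defaults 10 and 5, matching typical 2-D X-ray vs micro-CT sampling).
#' @param specimen_noise_sd Within-species landmark noise sd (coordinate
#'   units of the unit-size templates).
#' @param seed Master seed of the scenario.
#' @return A list of class `"scenario"`.
#' @export
scenario <- function(name = c("coupled", "decoupled", "late_decoupled",
                              "shifted_clade"),
                     n_tips = 234, root_age = 10,
                     rho = NULL, rho_old = 0.8, rho_young = 0,
                     change_age = 2, shifts = NULL,
                     rate_a = rep(5e-5, 3), rate_b = rep(2.5e-4, 3),
                     n_specimens = c(a = 10, b = 5),
                     specimen_noise_sd = 0.005, seed = 1) {
  name <- match.arg(name)
  if (is.null(rho)) {
    rho <- switch(name, coupled = 0.9, decoupled = 0, shifted_clade = 0,
                  late_decoupled = NA_real_)
  }
  rhos <- c(rho, rho_old, rho_young)
  if (any(abs(rhos[!is.na(rhos)]) > 1)) stop("|rho| must be <= 1")
  if (!is.null(shifts) && any(vapply(shifts, function(s) s$scalar, 1) <= 0)) {
    stop("shift scalars must be > 0")
  }
  if (specimen_noise_sd < 0) stop("specimen_noise_sd must be >= 0")
  if (length(rate_a) != length(rate_b)) stop("blocks must have equal trait counts")
  structure(
    list(name = name, n_tips = n_tips, root_age = root_age, rho = rho,
         rho_old = rho_old, rho_young = rho_young, change_age = change_age,
         shifts = shifts, rate_a = rate_a, rate_b = rate_b,
         n_specimens = n_specimens, specimen_noise_sd = specimen_noise_sd,
         seed = seed),
    class = "scenario"
  )
}

# edges whose child lies inside the clade spanned by `tips`
clade_member_edges <- function(tree, tips) {
  if (length(tips) < 2) stop("a planted clade needs >= 2 tips")
  mrca <- ape::getMRCA(tree, tips)
  # descendants of the mrca (nodes + tips), excluding the stem branch
  desc <- integer(0)
  stack <- mrca
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    ch <- kids[[as.character(nd)]]
    desc <- c(desc, ch)
    stack <- c(stack, ch[ch > ape::Ntip(tree)])
  }
  which(tree$edge[, 2] %in% desc)
}

#' Simulate two coupled trait blocks along a tree
#'
#' Joint Brownian motion of the 2 x m trait vector: on each branch
#' (segment), matched axes of block A and block B receive Normal
#' increments with correlation rho and variances `rate_a[i] * length` and
#' `rate_b[i] * length` (times any planted clade scalar). For the
#' late-decoupled regime, branches crossing `change_age` are split there
#' so the old and young parts of a single branch carry different coupling.
#'
#' @param tree Ultrametric `phylo`.
#' @param scn A [scenario()].
#' @param seed Optional seed override (defaults to `scn$seed`).
#' @return List with `block_a`, `block_b` (tips x m matrices, rownames =
#'   tip labels) and `planted_edges` (edge indices carrying a shift).
#' @export
simulate_jaw_traits <- function(tree, scn, seed = scn$seed) {
  stopifnot(inherits(scn, "scenario"))
  if (!is.null(seed)) set.seed(seed)
  m <- length(scn$rate_a)
  n_tip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  rel <- rep(1, nrow(tree$edge))
  shifts <- scn$shifts
  if (scn$name == "shifted_clade" && is.null(shifts)) {
    target <- max(2L, round(scn$n_tips / 5))
    sizes <- vapply(clade_edge_sets(tree), length, 1L)
    pick <- which.min(abs(sizes - 2 * target))  # edges ~ 2x tips in a clade
    clade_tips <- tree$tip.label[intersect(
      tree$edge[clade_edge_sets(tree)[[pick]], 2], seq_len(n_tip))]
    shifts <- list(list(tips = clade_tips, scalar = 10))
  }
  planted <- integer(0)
  if (!is.null(shifts)) {
    for (s in shifts) {
      es <- clade_member_edges(tree, s$tips)
      rel[es] <- rel[es] * s$scalar
      planted <- union(planted, es)
    }
  }
  co <- ape::reorder.phylo(tree, "cladewise")
  edge_map <- match(paste(co$edge[, 1], co$edge[, 2]),
                    paste(tree$edge[, 1], tree$edge[, 2]))
  vals <- matrix(NA_real_, n_tip + tree$Nnode, 2 * m)
  root <- setdiff(co$edge[, 1], co$edge[, 2])[1]
  vals[root, ] <- 0
  late <- scn$name == "late_decoupled"
  for (e in seq_len(nrow(co$edge))) {
    parent <- co$edge[e, 1]; child <- co$edge[e, 2]
    older <- ages[parent]; younger <- ages[child]
    r <- rel[edge_map[e]]
    segs <- if (late && older > scn$change_age && younger < scn$change_age) {
      list(c(older - scn$change_age, scn$rho_old),
           c(scn$change_age - younger, scn$rho_young))
    } else if (late) {
      list(c(older - younger,
             if (younger >= scn$change_age) scn$rho_old else scn$rho_young))
    } else {
      list(c(older - younger, scn$rho))
    }
    x <- vals[parent, ]
    for (sg in segs) {
      len <- sg[1]; rho <- sg[2]
      if (len <= 0) next
      za <- stats::rnorm(m)
      zb <- rho * za + sqrt(1 - rho^2) * stats::rnorm(m)
      x[seq_len(m)] <- x[seq_len(m)] + sqrt(scn$rate_a * len * r) * za
      x[m + seq_len(m)] <- x[m + seq_len(m)] + sqrt(scn$rate_b * len * r) * zb
    }
    vals[child, ] <- x
  }
  tips <- vals[seq_len(n_tip), , drop = FALSE]
  ax <- paste0("A", seq_len(m)); bx <- paste0("B", seq_len(m))
  list(block_a = matrix(tips[, seq_len(m)], n_tip, m,
                        dimnames = list(tree$tip.label, ax)),
       block_b = matrix(tips[, m + seq_len(m)], n_tip, m,
                        dimnames = list(tree$tip.label, bx)),
       planted_edges = planted)
}

#' Default landmark templates for the synthetic datasets
#'
#' `default_premaxilla_template()` is a centered 4-landmark 2-D
#' quadrilateral standing in for the premaxilla;
#' `default_lpj_template()` is a centered 21-landmark 3-D
#' half-configuration (9 midline landmarks in the symmetry plane, 12
#' paired off-plane landmarks) standing in for one side of a lower
#' pharyngeal jaw; it returns `coords`, `midline_ids` and `paired_ids`.
#'
#' @return A coordinate matrix, or a list for the LPJ template.
#' @export
default_premaxilla_template <- function() {
  m <- rbind(c(0, 1), c(0.15, 0.1), c(1, 0), c(0.2, -0.25))
  m <- sweep(m, 2, colMeans(m))
  m / sqrt(sum(m^2))
}

#' @rdname default_premaxilla_template
#' @export
default_lpj_template <- function() {
  # 9 midline points along an arched anterior-posterior axis (y = 0 plane)
  s <- seq(0, 1, length.out = 9)
  midline <- cbind(s, 0, 0.2 * sin(pi * s))
  # 12 paired points fanning out to one side (y > 0), two rows of six
  t6 <- seq(0.05, 0.95, length.out = 6)
  paired <- rbind(cbind(t6, 0.3 + 0.2 * t6, 0.1 * cos(pi * t6)),
                  cbind(t6, 0.15 + 0.1 * t6, -0.1 + 0.05 * t6))
  coords <- rbind(midline, paired)
  coords <- sweep(coords, 2, colMeans(coords))
  list(coords = coords / sqrt(sum(coords^2)),
       midline_ids = 1:9, paired_ids = 10:21)
}

#' Orthonormal shape deformation basis for a template
#'
#' Builds `n_axes` deterministic deformation vectors (sinusoidal loading
#' patterns over the flattened coordinates), projects out the similarity
#' directions at the template (translations, scaling, infinitesimal
#' rotations) so the axes encode pure shape change, and orthonormalizes.
#'
#' @param template K x dims centered coordinate matrix.
#' @param n_axes Number of deformation axes (default 3).
#' @return A (K * dims) x n_axes matrix with orthonormal columns.
#' @export
make_deformation_basis <- function(template, n_axes = 3) {
  k <- nrow(template); d <- ncol(template); p <- k * d
  idx <- seq_len(p)
  raw <- vapply(seq_len(n_axes), function(j) sin(idx * (j + 0.5) + j^2),
                numeric(p))
  # similarity directions at the template
  trans <- vapply(seq_len(d), function(a) as.numeric(col(template) == a),
                  numeric(p))
  scal <- as.numeric(template)
  rots <- if (d == 2) {
    matrix(as.numeric(template %*% rbind(c(0, 1), c(-1, 0))), ncol = 1)
  } else {
    gens <- list(rbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 0)),
                 rbind(c(0, 0, 1), c(0, 0, 0), c(-1, 0, 0)),
                 rbind(c(0, 0, 0), c(0, 0, 1), c(0, -1, 0)))
    vapply(gens, function(g) as.numeric(template %*% g), numeric(p))
  }
  nuis <- qr.Q(qr(cbind(trans, scal, rots)))
  raw <- raw - nuis %*% crossprod(nuis, raw)
  q <- qr(raw)
  if (q$rank < n_axes) stop("template too small for the requested axis count")
  qr.Q(q)[, seq_len(n_axes), drop = FALSE]
}

# random proper rotation matrix (det +1) in d dimensions
random_rotation <- function(d) {
  q <- qr.Q(qr(matrix(stats::rnorm(d * d), d)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Deform a template along trait axes into a landmark dataset
#'
#' Each species' mean configuration is `template + basis %*% scores`; each
#' specimen adds iid Gaussian coordinate noise and a random rigid motion
#' plus scale (so downstream superimposition is genuinely exercised).
#'
#' @param trait_scores Species x n_axes score matrix, rownames = species.
#' @param template K x dims centered coordinate matrix.
#' @param deformation_basis (K * dims) x n_axes matrix with orthonormal
#'   columns (Gram deviation <= 1e-8), e.g. [make_deformation_basis()].
#' @param n_specimens Specimens per species.
#' @param noise_sd Specimen-level coordinate noise sd (>= 0).
#' @param structure Structure label of the result.
#' @param seed Optional integer seed.
#' @return A [landmark_set()] with `n_specimens` per species.
#' @export
traits_to_landmarks <- function(trait_scores, template, deformation_basis,
                                n_specimens = 5, noise_sd = 0.005,
                                structure = "structure", seed = NULL) {
  template <- as.matrix(template)
  k <- nrow(template); d <- ncol(template)
  gram <- crossprod(deformation_basis)
  if (max(abs(gram - diag(ncol(deformation_basis)))) > 1e-8) {
    stop("deformation basis columns must be orthonormal")
  }
  if (max(abs(colMeans(template))) > 1e-8) stop("template must be centered")
  if (nrow(deformation_basis) != k * d ||
      ncol(deformation_basis) != ncol(trait_scores)) {
    stop("basis dimensions do not match template / trait axes")
  }
  if (!is.null(seed)) set.seed(seed)
  sp <- rownames(trait_scores)
  if (is.null(sp)) stop("trait_scores must carry species ids as rownames")
  configs <- list(); ids <- character(0); species <- character(0)
  for (i in seq_along(sp)) {
    mean_cfg <- template +
      matrix(deformation_basis %*% trait_scores[i, ], k, d)
    for (j in seq_len(n_specimens)) {
      cfg <- mean_cfg + matrix(stats::rnorm(k * d, sd = noise_sd), k, d)
      cfg <- cfg %*% random_rotation(d) * exp(stats::runif(1, -0.3, 0.3))
      cfg <- sweep(cfg, 2, stats::runif(d, -0.5, 0.5), "+")
      configs[[length(configs) + 1L]] <- cfg
      ids <- c(ids, sprintf("%s_%02d", sp[i], j))
      species <- c(species, sp[i])
    }
  }
  landmark_set(configs, ids, species, structure = structure)
}

#' Generate a complete synthetic two-jaw dataset
#'
#' Ties the generators together under one master seed: tree, coupled trait
#' blocks, a 2-D premaxilla-like landmark dataset deformed along block A,
#' and a 3-D half-configuration LPJ-like dataset deformed along block B
#' (to be mirrored before alignment).
#'
#' @param scn A [scenario()].
#' @return List with `tree`, `traits` (block matrices + planted edges),
#'   `oral` (landmark_set, 2-D), `lpj_half` (landmark_set, 3-D),
#'   `lpj_midline_ids`, `lpj_paired_ids`, and the `scenario`.
#' @export
simulate_dataset <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  set.seed(scn$seed)
  tree <- simulate_tree(scn$n_tips, scn$root_age)
  traits <- simulate_jaw_traits(tree, scn, seed = NULL)
  premax <- default_premaxilla_template()
  lpj <- default_lpj_template()
  oral <- traits_to_landmarks(traits$block_a, premax,
                              make_deformation_basis(premax, ncol(traits$block_a)),
                              n_specimens = scn$n_specimens[[1]],
                              noise_sd = scn$specimen_noise_sd,
                              structure = "oral_premaxilla")
  lpj_half <- traits_to_landmarks(traits$block_b, lpj$coords,
                                  make_deformation_basis(lpj$coords, ncol(traits$block_b)),
                                  n_specimens = scn$n_specimens[[2]],
                                  noise_sd = scn$specimen_noise_sd,
                                  structure = "lpj_half")
  list(tree = tree, traits = traits, oral = oral, lpj_half = lpj_half,
       lpj_midline_ids = lpj$midline_ids, lpj_paired_ids = lpj$paired_ids,
       scenario = scn)
}

#' Simulate correlated branch-rate tables for two jaws
#'
#' Direct generator of per-branch relative rates with epoch-dependent
#' coupling, used to study the windowed rate-correlation machinery without
#' running the MCMC: log-normal rates whose log-scale correlation is
#' `rho_old` for branches whose midpoint age exceeds `change_age` and
#' `rho_young` otherwise.
#'
#' @param tree Ultrametric `phylo`.
#' @param rho_old,rho_young Log-scale correlations (defaults 0.8, 0).
#' @param change_age Epoch boundary in My (default 2).
#' @param sdlog Log-sd of the rates (default 0.8).
#' @param seed Optional integer seed.
#' @return List with `rates_a`, `rates_b` (`branch_rates` tables) and
#'   `old_branch` (logical per branch).
#' @export
simulate_branch_rates <- function(tree, rho_old = 0.8, rho_young = 0,
                                  change_age = 2, sdlog = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ep <- branch_epochs(tree)
  old <- (ep$older + ep$younger) / 2 > change_age
  rho <- ifelse(old, rho_old, rho_young)
  za <- stats::rnorm(nrow(ep))
  zb <- rho * za + sqrt(1 - rho^2) * stats::rnorm(nrow(ep))
  mk <- function(z) {
    structure(data.frame(branch = ep$branch, rate = exp(sdlog * z)),
              class = c("branch_rates", "data.frame"))
  }
  list(rates_a = mk(za), rates_b = mk(zb), old_branch = old)
}
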