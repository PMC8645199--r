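# internal: children-first schedule of internal nodes for the C++ pruning
# code: columns node, child1, child2, edge1, edge2 (ape 1-based numbering,
# root last). Requires a bifurcating tree.
vr_schedule <- function(tree) {
  child_edges <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  if (any(lengths(child_edges) != 2)) {
    stop("variable-rates model requires a bifurcating tree")
  }
  po <- ape::reorder.phylo(tree, "postorder")
  last_idx <- tapply(seq_len(nrow(po$edge)), po$edge[, 1], max)
  nodes <- as.integer(names(sort(last_idx)))
  sched <- t(vapply(nodes, function(nd) {
    es <- child_edges[[as.character(nd)]]
    c(nd, tree$edge[es, 2], es)
  }, integer(5)))
  colnames(sched) <- c("node", "child1", "child2", "edge1", "edge2")
  sched
}

#' Configuration for the variable-rates model MCMC
#'
#' Priors follow the uniform-box convention: per-trait uniform priors on
#' the ancestral state alpha and the base Brownian rate sigma^2. Rate
#' shifts carry a truncated log-normal magnitude prior and a truncated
#' Poisson prior on the number of shifts (with slot arrangements uniform
#' given the count). Defaults are desk-scale: 2e6 iterations with 2e5
#' burn-in, thinning every 200; production-scale chains simply raise these.
#'
#' @param alpha_prior Length-2 numeric `c(lo, hi)` applied to all traits,
#'   or a 2-column matrix with one row per trait.
#' @param sigma2_prior Same layout for the base rates (lo >= 0).
#' @param n_iterations,burnin,thin Chain length controls;
#'   `(n_iterations - burnin)` must be divisible by `thin`.
#' @param seed Integer seed; the chain is exactly reproducible given the
#'   configuration and seed.
#' @param shift_count_lambda Mean of the Poisson prior on the shift count.
#' @param scalar_prior List with `meanlog`, `sdlog`, `lo`, `hi` for the
#'   truncated log-normal prior on shift magnitudes.
#' @param allow_clade_scalars Allow clade-scoped scalars (multiplying every
#'   branch of the subtended clade) in addition to single-branch scalars.
#' @param alpha_window,sigma2_window Sliding-window half-widths of the
#'   uniform proposals, as a fraction of the prior range.
#' @param scalar_walk_sd Standard deviation of the multiplicative
#'   log-normal walk on existing scalars.
#' @param move_weights Relative weights of the five move types
#'   (alpha, sigma2, scalar update, birth, death).
#' @param prior_only Disable the likelihood (prior-recovery checks).
#' @return A list of class `"rate_model_config"`.
#' @export
rate_model_config <- function(alpha_prior = c(-1, 1),
                              sigma2_prior = c(0, 1e-4),
                              n_iterations = 2e6, burnin = 2e5, thin = 200,
                              seed = NULL,
                              shift_count_lambda = 1,
                              scalar_prior = list(meanlog = 0, sdlog = 1.5,
                                                  lo = 1e-3, hi = 1e3),
                              allow_clade_scalars = TRUE,
                              alpha_window = 0.1, sigma2_window = 0.1,
                              scalar_walk_sd = 0.5,
                              move_weights = c(alpha = 0.15, sigma2 = 0.15,
                                               scalar = 0.3, birth = 0.2,
                                               death = 0.2),
                              prior_only = FALSE) {
  as_bounds <- function(b, what, lo_min = -Inf) {
    if (is.null(dim(b))) b <- matrix(b, 1, 2)
    if (ncol(b) != 2 || any(!is.finite(b)) || any(b[, 1] >= b[, 2]) ||
        any(b[, 1] < lo_min)) {
      stop("invalid ", what, " prior bounds")
    }
    b
  }
  alpha_prior <- as_bounds(alpha_prior, "alpha")
  sigma2_prior <- as_bounds(sigma2_prior, "sigma2", lo_min = 0)
  if (burnin >= n_iterations) stop("burnin must be smaller than n_iterations")
  if ((n_iterations - burnin) %% thin != 0) {
    stop("thin must divide (n_iterations - burnin) evenly")
  }
  if (shift_count_lambda <= 0) stop("shift_count_lambda must be > 0")
  structure(
    list(alpha_prior = alpha_prior, sigma2_prior = sigma2_prior,
         n_iterations = n_iterations, burnin = burnin, thin = thin,
         seed = seed, shift_count_lambda = shift_count_lambda,
         scalar_prior = scalar_prior,
         allow_clade_scalars = allow_clade_scalars,
         alpha_window = alpha_window, sigma2_window = sigma2_window,
         scalar_walk_sd = scalar_walk_sd, move_weights = move_weights,
         prior_only = prior_only),
    class = "rate_model_config"
  )
}

# recycle per-trait prior bounds to K traits
expand_bounds <- function(b, K) {
  if (nrow(b) == 1) b <- b[rep(1, K), , drop = FALSE]
  if (nrow(b) != K) stop("prior bounds do not match the number of traits")
  b
}

#' Log-likelihood of the variable-rates Brownian-motion model
#'
#' Each branch length is multiplied by its relative rate (the product of
#' all scalars whose scope covers it); the log-likelihood is the sum over
#' traits of the multivariate-normal density of the tip values with mean
#' alpha_k and covariance sigma2_k times the rescaled phylogenetic
#' covariance, evaluated by Felsenstein pruning.
#'
#' @param traits Species x trait matrix, rownames = tip labels.
#' @param tree Bifurcating `phylo`.
#' @param alphas,sigma2s Numeric vectors, one entry per trait column.
#' @param shifts Optional data frame with columns `edge` (index into
#'   `tree$edge`), `scope` (`"branch"` or `"clade"`), `scalar` (> 0);
#'   `NULL` means plain Brownian motion on the unscaled tree.
#' @return The log-likelihood (scalar).
#' @export
vr_log_likelihood <- function(traits, tree, alphas, sigma2s, shifts = NULL) {
  traits <- as.matrix(traits)
  if (is.null(rownames(traits))) stop("traits must have tip labels as rownames")
  if (!all(tree$tip.label %in% rownames(traits))) stop("traits missing for some tips")
  traits <- traits[tree$tip.label, , drop = FALSE]
  K <- ncol(traits)
  if (length(alphas) != K || length(sigma2s) != K) {
    stop("alphas/sigma2s must have one entry per trait")
  }
  if (any(sigma2s <= 0)) stop("sigma2s must be > 0")
  rel <- relative_rates_from_shifts(tree, shifts)
  .vr_loglik_cpp(vr_schedule(tree), tree$edge.length, traits, rel,
                 as.numeric(alphas), as.numeric(sigma2s))
}

#' Per-branch relative rates implied by a shift set
#'
#' @param tree A `phylo` object.
#' @param shifts Data frame with `edge`, `scope`, `scalar` columns, or `NULL`.
#' @return Numeric vector over edges (default 1 everywhere).
#' @export
relative_rates_from_shifts <- function(tree, shifts = NULL) {
  rel <- rep(1, nrow(tree$edge))
  if (is.null(shifts) || nrow(shifts) == 0) return(rel)
  if (any(shifts$scalar <= 0)) stop("shift scalars must be > 0")
  cl <- clade_edge_sets(tree)
  for (i in seq_len(nrow(shifts))) {
    e <- shifts$edge[i]
    if (e < 1 || e > nrow(tree$edge)) stop("shift edge index out of range")
    if (shifts$scope[i] == "branch") {
      rel[e] <- rel[e] * shifts$scalar[i]
    } else if (shifts$scope[i] == "clade") {
      rel[cl[[e]]] <- rel[cl[[e]]] * shifts$scalar[i]
    } else {
      stop("shift scope must be 'branch' or 'clade'")
    }
  }
  rel
}

#' Run the reversible-jump variable-rates MCMC
#'
#' Metropolis-Hastings over ancestral states, base rates, and a varying
#' set of branch/clade rate scalars shared across traits. See
#' [rate_model_config()] for priors and proposal settings.
#'
#' @param traits Species x trait matrix (e.g. the first three PC scores of
#'   one jaw), rownames = tip labels.
#' @param tree Bifurcating ultrametric `phylo`.
#' @param config A [rate_model_config()].
#' @return Object of class `"vr_posterior"`: `samples` (data frame with
#'   iteration, log-likelihood, shift count, per-trait alpha and sigma2),
#'   `rel_rates` (samples x branches matrix of relative rates, branch ids
#'   as colnames), `shifts` (serialized shift sets), `acceptance` (per-move
#'   proposal/acceptance counts), plus the `config` and `tree`.
#' @export
run_mcmc <- function(traits, tree, config = rate_model_config()) {
  stopifnot(inherits(config, "rate_model_config"))
  validate_phylogeny(tree, require_ultrametric = FALSE)
  traits <- as.matrix(traits)
  if (is.null(rownames(traits))) stop("traits must have tip labels as rownames")
  missing <- setdiff(tree$tip.label, rownames(traits))
  if (length(missing)) stop("traits missing for tips: ", paste(missing, collapse = ", "))
  traits <- traits[tree$tip.label, , drop = FALSE]
  K <- ncol(traits)
  ab <- expand_bounds(config$alpha_prior, K)
  sb <- expand_bounds(config$sigma2_prior, K)
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- .vr_mcmc_cpp(
    vr_schedule(tree), tree$edge.length, clade_edge_sets(tree), traits,
    ab[, 1], ab[, 2], sb[, 1], sb[, 2],
    config$n_iterations, config$burnin, as.integer(config$thin),
    config$shift_count_lambda,
    config$scalar_prior$meanlog, config$scalar_prior$sdlog,
    config$scalar_prior$lo, config$scalar_prior$hi,
    config$allow_clade_scalars, config$prior_only,
    config$alpha_window * (ab[, 2] - ab[, 1]),
    config$sigma2_window * (sb[, 2] - sb[, 1]),
    config$scalar_walk_sd, as.numeric(config$move_weights))
  tn <- colnames(traits)
  if (is.null(tn)) tn <- paste0("trait", seq_len(K))
  samples <- data.frame(iteration = res$iteration,
                        logL = res$params[, 1],
                        n_shifts = res$params[, 2])
  for (k in seq_len(K)) samples[[paste0("alpha_", tn[k])]] <- res$params[, 2 + k]
  for (k in seq_len(K)) samples[[paste0("sigma2_", tn[k])]] <- res$params[, 2 + K + k]
  rel <- res$rel_rates
  colnames(rel) <- branch_ids(tree)
  acceptance <- data.frame(
    move = c("alpha", "sigma2", "scalar", "birth", "death"),
    proposed = res$proposed, accepted = res$accepted,
    rate = ifelse(res$proposed > 0, res$accepted / res$proposed, NA))
  structure(
    list(samples = samples, rel_rates = rel, shifts = res$shifts,
         acceptance = acceptance, traits = tn, config = config, tree = tree),
    class = "vr_posterior"
  )
}

#' @export
print.vr_posterior <- function(x, ...) {
  cat(sprintf("variable-rates posterior: %d retained samples, %d traits, %d branches\n",
              nrow(x$samples), length(x$traits), ncol(x$rel_rates)))
  cat(sprintf("  mean shift count %.2f; mean logL %.2f\n",
              mean(x$samples$n_shifts), mean(x$samples$logL)))
  invisible(x)
}

#' Effective sample size of an MCMC series
#'
#' N / (1 + 2 sum of autocorrelations), with the autocorrelation sum
#' truncated at the first non-positive pairwise sum
#' (rho_2m + rho_2m+1 <= 0; Geyer's initial positive sequence). Capped at
#' N. A value above ~200 is the conventional adequacy threshold.
#'
#' @param series Numeric vector, length >= 10, non-constant.
#' @return Effective sample size (scalar, <= length of series).
#' @export
ess <- function(series) {
  n <- length(series)
  if (n < 10) stop("series too short for an ESS estimate (need >= 10)")
  if (stats::sd(series) == 0) stop("constant series: ESS undefined")
  rho <- drop(stats::acf(series, lag.max = n - 1, plot = FALSE,
                         demean = TRUE)$acf)[-1]
  tau <- 1
  m <- 1
  while (m <= length(rho)) {
    pair <- rho[m] + if (m + 1 <= length(rho)) rho[m + 1] else 0
    if (pair <= 0) break
    tau <- tau + 2 * pair
    m <- m + 2
  }
  min(n, n / tau)
}

#' Split a posterior sample at per-trait rate thresholds
#'
#' Handles bimodal posteriors: an iteration belongs to optimum 1 if its
#' sigma^2 draws lie below the threshold for all traits, to optimum 2 if
#' at/above the threshold for all traits; iterations matching neither are
#' dropped (counted). Posterior probabilities of the optima are their
#' fractions of the full sample.
#'
#' @param posterior A `"vr_posterior"` from [run_mcmc()].
#' @param thresholds Numeric vector of sigma^2 cutoffs, one per trait.
#' @return List with `optimum1`, `optimum2` (subset `vr_posterior`
#'   objects, possibly with zero rows), `pp` (named length-2 vector),
#'   `n_dropped`.
#' @export
split_posterior <- function(posterior, thresholds) {
  stopifnot(inherits(posterior, "vr_posterior"))
  K <- length(posterior$traits)
  if (length(thresholds) != K) stop("need one threshold per trait")
  s2 <- as.matrix(posterior$samples[paste0("sigma2_", posterior$traits)])
  below <- sweep(s2, 2, thresholds, "<")
  low <- rowSums(below) == K
  high <- rowSums(!below) == K
  take <- function(idx) {
    out <- posterior
    out$samples <- posterior$samples[idx, , drop = FALSE]
    out$rel_rates <- posterior$rel_rates[idx, , drop = FALSE]
    out$shifts <- posterior$shifts[idx]
    out
  }
  n <- nrow(s2)
  list(optimum1 = take(low), optimum2 = take(high),
       pp = c(optimum1 = sum(low) / n, optimum2 = sum(high) / n),
       n_dropped = n - sum(low) - sum(high))
}

#' Posterior mean evolutionary rates per branch
#'
#' Arithmetic mean over retained iterations of each branch's relative rate
#' (the product of active scalars covering it; 1 when no shift applies).
#' The absolute variant multiplies each iteration's relative rate by that
#' iteration's sigma^2 for the chosen trait before averaging.
#'
#' @param posterior A `"vr_posterior"` (possibly a [split_posterior()]
#'   subset).
#' @param absolute Return absolute rates (sigma^2 x relative rate).
#' @param trait Trait name or index used for the absolute variant.
#' @return Data frame of class `"branch_rates"` with columns `branch`
#'   (branch id = child node: tip label or `"node<k>"`) and `rate`.
#' @export
summarize_rates <- function(posterior, absolute = FALSE, trait = 1) {
  stopifnot(inherits(posterior, "vr_posterior"))
  if (nrow(posterior$samples) == 0) stop("empty posterior sub-sample")
  rel <- posterior$rel_rates
  if (absolute) {
    if (is.numeric(trait)) trait <- posterior$traits[trait]
    s2 <- posterior$samples[[paste0("sigma2_", trait)]]
    rel <- rel * s2
  }
  structure(
    data.frame(branch = colnames(rel), rate = colMeans(rel),
               row.names = NULL),
    class = c("branch_rates", "data.frame")
  )
}
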