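# deterministic per-stage seed derived from the master seed, so each stage
# is reproducible independently of execution order
derive_seed <- function(master_seed, stage_index) {
  as.integer((as.double(master_seed) * 97 + stage_index * 10009) %% 2147483647)
}

#' Configuration of the full three-approach analysis
#'
#' Inputs may be given as file paths (Newick tree; TPS or long CSV
#' landmarks) or as in-memory objects (`phylo`, [landmark_set()]).
#'
#' @param tree `phylo` or path to a Newick file.
#' @param oral Oral-jaw landmarks (`landmark_set` or path). If
#'   `oral_subset_ids` is given the set is treated as a full-skeleton
#'   configuration: it is aligned whole (scaling on) and the subset is
#'   extracted and re-centered without re-rotation or re-scaling.
#' @param lpj Lower-pharyngeal-jaw half-configuration landmarks (3-D).
#' @param lpj_midline_ids,lpj_paired_ids Partition of the LPJ landmarks
#'   used for mirroring.
#' @param oral_subset_ids Optional landmark indices of the premaxilla
#'   within a full-skeleton oral dataset.
#' @param n_axes PC axes retained per jaw (default 3).
#' @param mantel_permutations,null_pairs,pls_permutations Monte Carlo sizes
#'   of the three Approach 1-2 tests.
#' @param rate_config_a,rate_config_b [rate_model_config()] per jaw; the
#'   defaults use the conventional uniform priors (sigma^2 up to 1e-4 for
#'   the oral jaw, 1e-3 for the LPJ).
#' @param window_width,merge_before,min_branches Time-window settings of
#'   Approach 3 (My; defaults 0.15, 8, 7).
#' @param master_seed Master seed from which all stage seeds derive.
#' @param output_dir Optional directory for per-stage outputs and the JSON
#'   report.
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(tree, oral, lpj,
                            lpj_midline_ids, lpj_paired_ids,
                            oral_subset_ids = NULL,
                            n_axes = 3,
                            mantel_permutations = 999,
                            null_pairs = 1000,
                            pls_permutations = 999,
                            rate_config_a = rate_model_config(sigma2_prior = c(0, 1e-4)),
                            rate_config_b = rate_model_config(sigma2_prior = c(0, 1e-3)),
                            window_width = 0.15, merge_before = 8,
                            min_branches = 7,
                            master_seed = 1, output_dir = NULL) {
  if (n_axes < 1) stop("must retain at least one PC axis")
  for (p in list(tree, oral, lpj)) {
    if (is.character(p) && !file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(as.list(environment()), class = "analysis_config")
}

load_tree_input <- function(x) {
  if (inherits(x, "phylo")) return(validate_phylogeny(x))
  read_newick(file = x)
}

load_landmark_input <- function(x, structure) {
  if (inherits(x, "landmark_set")) return(x)
  if (grepl("\\.tps$", x, ignore.case = TRUE)) {
    read_tps(x, structure = structure)
  } else {
    read_landmarks_csv(x, structure = structure)
  }
}

# drop specimens whose species is not in the tree, report counts
intersect_species <- function(lms, keep, what) {
  drop <- !(lms$specimens$species_id %in% keep)
  if (any(drop)) {
    warning(sprintf("%s: dropping %d specimens of %d species absent from the tree",
                    what, sum(drop), length(unique(lms$specimens$species_id[drop]))))
    lms$coords <- lms$coords[, , !drop, drop = FALSE]
    lms$specimens <- lms$specimens[!drop, ]
  }
  lms
}

#' Run the full three-approach decoupling analysis
#'
#' Executes, in order: landmark alignment (mirroring, GPA, optional subset
#' extraction, species means); Approach 1 (pairwise Procrustes divergence
#' matrices, partial Mantel against the patristic control); Approach 2
#' (shape PCA per jaw, PIC correlation grid against a Brownian null band,
#' phylogenetic two-block PLS); Approach 3 (variable-rates MCMC per jaw,
#' overall and time-windowed rate correlations). Each stage gets a seed
#' derived from the master seed, so two runs with the same configuration
#' produce identical results.
#'
#' @param config An [analysis_config()].
#' @return Object of class `"decoupling_report"`; see [make_report()].
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  stage <- function(i, name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }
  tree <- load_tree_input(config$tree)
  oral <- load_landmark_input(config$oral, "oral")
  lpj <- load_landmark_input(config$lpj, "lpj_half")

  # --- alignment ------------------------------------------------------
  aligned <- stage(1, "align", {
    shared <- intersect(tree$tip.label,
                        intersect(oral$specimens$species_id,
                                  lpj$specimens$species_id))
    if (length(shared) < 3) stop("fewer than 3 species shared between tree and landmarks")
    if (length(shared) < length(tree$tip.label)) {
      warning(sprintf("pruning tree from %d to %d species with landmark data",
                      length(tree$tip.label), length(shared)))
      tree <- prune_to_tips(tree, shared)
    }
    oral <- intersect_species(oral, shared, "oral")
    lpj <- intersect_species(lpj, shared, "lpj")
    oral_gpa <- gpa(oral, scale = TRUE)
    oral_aligned <- if (!is.null(config$oral_subset_ids)) {
      extract_recentered_subset(oral_gpa, config$oral_subset_ids)
    } else {
      oral_gpa
    }
    lpj_full <- lpj
    lpj_full$coords <- NULL
    full <- lapply(seq_len(dim(lpj$coords)[3]), function(i) {
      mirror_landmarks(lpj$coords[, , i], config$lpj_midline_ids,
                       config$lpj_paired_ids)
    })
    lpj_full <- landmark_set(full, lpj$specimens$specimen_id,
                             lpj$specimens$species_id, structure = "lpj_full")
    list(tree = tree,
         oral_means = species_mean_shapes(oral_aligned),
         lpj_means = species_mean_shapes(gpa(lpj_full, scale = TRUE)),
         n_species = length(shared))
  })
  tree <- aligned$tree

  # --- approach 1: divergence -----------------------------------------
  divergence <- stage(2, "divergence", {
    d_oral <- pairwise_shape_distances(aligned$oral_means, scale = FALSE)
    d_lpj <- pairwise_shape_distances(aligned$lpj_means, scale = FALSE)
    d_phy <- patristic_distances(tree)
    ord <- tree$tip.label
    mantel <- partial_mantel(d_oral[ord, ord], d_lpj[ord, ord], d_phy[ord, ord],
                             n_permutations = config$mantel_permutations,
                             seed = derive_seed(config$master_seed, 2))
    list(mantel = mantel, d_oral = d_oral, d_lpj = d_lpj, d_phy = d_phy)
  })

  # --- approach 2: evolutionary correlations --------------------------
  evocorr <- stage(3, "evocorr", {
    pca_oral <- shape_pca(aligned$oral_means)
    pca_lpj <- shape_pca(aligned$lpj_means)
    ax <- seq_len(min(config$n_axes, ncol(pca_oral$scores), ncol(pca_lpj$scores)))
    null <- null_correlations(tree, n_pairs = config$null_pairs,
                              seed = derive_seed(config$master_seed, 3))
    grid <- pic_correlation_grid(tree,
                                 pca_oral$scores[, ax, drop = FALSE],
                                 pca_lpj$scores[, ax, drop = FALSE], null)
    flat <- function(means) t(apply(means, 3, as.numeric))
    pls <- phylo_pls(flat(aligned$oral_means), flat(aligned$lpj_means), tree,
                     n_permutations = config$pls_permutations,
                     seed = derive_seed(config$master_seed, 4))
    list(pca_oral = pca_oral, pca_lpj = pca_lpj, null = null,
         grid = grid, pls = pls, axes = ax)
  })

  # --- approach 3: rates ----------------------------------------------
  rates <- stage(4, "rates", {
    run_one <- function(pca, cfg, stage_idx) {
      cfg$seed <- derive_seed(config$master_seed, stage_idx)
      run_mcmc(pca$scores[, evocorr$axes, drop = FALSE], tree, cfg)
    }
    post_a <- run_one(evocorr$pca_oral, config$rate_config_a, 5)
    post_b <- run_one(evocorr$pca_lpj, config$rate_config_b, 6)
    ess_of <- function(post) {
      cols <- setdiff(names(post$samples), "iteration")
      vapply(cols, function(cn) {
        x <- post$samples[[cn]]
        if (stats::sd(x) == 0) NA_real_ else ess(x)
      }, numeric(1))
    }
    list(post_a = post_a, post_b = post_b,
         rates_a = summarize_rates(post_a), rates_b = summarize_rates(post_b),
         ess_a = ess_of(post_a), ess_b = ess_of(post_b))
  })
  ratecorr <- stage(5, "ratecorr", {
    windows <- make_windows(max(node_ages(tree)), config$window_width,
                            config$merge_before)
    list(overall = overall_rate_correlation(rates$rates_a, rates$rates_b),
         windows = window_rate_correlation(rates$rates_a, rates$rates_b,
                                           tree, windows,
                                           config$min_branches))
  })

  report <- make_report(list(alignment = aligned, divergence = divergence,
                             evocorr = evocorr, rates = rates,
                             ratecorr = ratecorr, config = config))
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Assemble the analysis report
#'
#' Collects the per-stage outputs into a schema-checked report object with
#' a JSON-serializable `report` element and a human-readable `summary`.
#' Interpretation follows the decoupling rule: a correlation outside the
#' Brownian null band indicates morphological integration; one inside the
#' band is consistent with evolutionary decoupling.
#'
#' @param stages Named list of stage outputs from [run_full_analysis()].
#' @return Object of class `"decoupling_report"`.
#' @export
make_report <- function(stages) {
  if (!length(stages)) stop("no stage outputs to report")
  config <- stages$config
  rep <- list(master_seed = if (!is.null(config)) config$master_seed else NA)
  if (!is.null(stages$alignment)) {
    rep$n_species <- stages$alignment$n_species
  }
  if (!is.null(stages$divergence)) {
    m <- stages$divergence$mantel
    rep$approach1_mantel <- list(r = m$r, p = m$p,
                                 n_permutations = m$n_permutations)
  }
  if (!is.null(stages$evocorr)) {
    ev <- stages$evocorr
    rep$approach2_null <- list(min = ev$null$min, max = ev$null$max,
                               ci95 = ev$null$ci95, n_pairs = ev$null$n_pairs)
    rep$approach2_pic_grid <- ev$grid
    rep$approach2_pls <- list(r = ev$pls$r_pls, p = ev$pls$p)
    rep$approach2_percent_variance <- list(
      oral = ev$pca_oral$percent_variance[ev$axes],
      lpj = ev$pca_lpj$percent_variance[ev$axes])
  }
  if (!is.null(stages$rates)) {
    rep$approach3_ess <- list(oral = stages$rates$ess_a,
                              lpj = stages$rates$ess_b)
    rep$approach3_max_rate <- list(
      oral = max(stages$rates$rates_a$rate),
      lpj = max(stages$rates$rates_b$rate))
  }
  if (!is.null(stages$ratecorr)) {
    ov <- stages$ratecorr$overall
    rep$approach3_overall <- list(r = ov$r, p = ov$p, df = ov$df)
    rep$approach3_windows <- as.data.frame(stages$ratecorr$windows)
  }
  validate_report(rep)
  summary_lines <- report_summary(rep)
  structure(list(report = rep, summary = summary_lines, stages = stages),
            class = "decoupling_report")
}

report_summary <- function(rep) {
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  if (!is.null(rep$approach1_mantel)) {
    add("Approach 1 (divergence): partial Mantel r = %.3f, p = %.3g%s",
        rep$approach1_mantel$r, rep$approach1_mantel$p,
        if (rep$approach1_mantel$p <= 0.05) " (significant association)" else
          " (consistent with decoupling)")
  }
  if (!is.null(rep$approach2_pic_grid)) {
    g <- rep$approach2_pic_grid
    for (i in seq_len(nrow(g))) {
      add("Approach 2 (PIC): %s vs %s r = %.3f, p = %.3g -> %s",
          g$trait_a[i], g$trait_b[i], g$r[i], g$p[i],
          if (isTRUE(g$outside_null[i])) "integration (outside null band)" else
            "consistent with decoupling (within null band)")
    }
    add("Approach 2 (pPLS): r = %.3f, p = %.3g", rep$approach2_pls$r,
        rep$approach2_pls$p)
  }
  if (!is.null(rep$approach3_overall)) {
    add("Approach 3 (rates): overall r = %.3f, p = %.3g, df = %d",
        rep$approach3_overall$r, rep$approach3_overall$p,
        rep$approach3_overall$df)
  }
  lines
}

# minimal structural check against the shipped report schema
validate_report <- function(rep) {
  schema_file <- system.file("extdata", "report_schema.json",
                             package = "evodecouple")
  schema <- jsonlite::read_json(schema_file)
  for (field in names(schema$required_if_present)) {
    if (!is.null(rep[[field]])) {
      need <- unlist(schema$required_if_present[[field]])
      present <- vapply(need, function(f) {
        f %in% names(rep[[field]]) && !is.null(rep[[field]][[f]])
      }, logical(1))
      if (!all(present)) {
        stop("report schema violation: '", field, "' is missing ",
             paste(need[!present], collapse = ", "))
      }
    }
  }
  invisible(rep)
}

#' Write a report bundle to disk
#'
#' Writes `report.json` (deterministic given the configuration: no
#' wall-clock fields) and `summary.txt` into `dir`.
#'
#' @param report A `"decoupling_report"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "decoupling_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report$summary, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' @export
print.decoupling_report <- function(x, ...) {
  cat("decoupling analysis report\n")
  cat(paste0("  ", x$summary, "\n"), sep = "")
  invisible(x)
}
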