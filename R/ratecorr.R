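#' Branch epochs (age intervals) of an ultrametric tree
#'
#' Each branch exists over the half-open age interval
#' (parent age, child age]: `older` is the age of the parent node and
#' `younger` the age of the child node, both in My before present.
#'
#' @param tree Ultrametric `phylo`.
#' @return Data frame with columns `branch` (branch id = child node),
#'   `older`, `younger`.
#' @export
branch_epochs <- function(tree) {
  et <- edge_table(tree)
  data.frame(branch = branch_ids(tree), older = et$older,
             younger = et$younger, row.names = NULL)
}

#' Sliding time windows along a phylogeny
#'
#' A grid of fixed-width windows anchored at the present (age 0), ordered
#' oldest to youngest, with every window a half-open interval
#' (start, end]. Because few lineages exist near the root, all time before
#' `merge_before` is pooled into a single first window
#' (root_age, merge_before]; if `merge_before >= root_age` no merged
#' window is created and the grid alone covers the tree.
#'
#' @param root_age Root age in My.
#' @param width Window width in My (default 0.15).
#' @param merge_before Pool all branches older than this age (My, default 8).
#' @return Data frame with columns `start` (older bound), `end` (younger
#'   bound), `merged` (logical).
#' @export
make_windows <- function(root_age, width = 0.15, merge_before = 8) {
  if (width <= 0) stop("window width must be > 0")
  if (root_age <= 0) stop("root_age must be > 0")
  grid_top <- min(merge_before, root_age)
  ks <- seq_len(ceiling(grid_top / width))
  grid <- data.frame(start = width * rev(ks), end = width * (rev(ks) - 1),
                     merged = FALSE)
  if (merge_before < root_age) {
    grid <- rbind(data.frame(start = root_age, end = merge_before,
                             merged = TRUE), grid)
  }
  row.names(grid) <- NULL
  grid
}

# half-open overlap of branch epoch (older, younger] with window (start, end]
epoch_overlaps <- function(older, younger, start, end) {
  older > end & younger < start
}

#' Pearson correlation of branch rates between two trait complexes, per
#' time window
#'
#' Every branch whose epoch interval overlaps a window contributes its
#' rate pair to that window (a branch spanning several windows enters each
#' of them, unweighted). Windows with fewer than 3 branches yield no
#' correlation (`NA`); windows below `min_branches` are flagged `low_n`.
#' P-values are reported raw, without multiple-testing correction.
#'
#' @param rates_a,rates_b `"branch_rates"` data frames (or any data frame
#'   with `branch` and `rate` columns) covering every branch of `tree`.
#' @param tree Ultrametric `phylo`.
#' @param windows Data frame from [make_windows()]; `NULL` uses the
#'   defaults for this tree's root age.
#' @param min_branches Flag threshold for small windows (default 7).
#' @return Data frame of class `"window_corr"`: `start`, `end`, `merged`,
#'   `n_branches`, `r`, `p`, `low_n`.
#' @export
window_rate_correlation <- function(rates_a, rates_b, tree, windows = NULL,
                                    min_branches = 7) {
  ep <- branch_epochs(tree)
  ra <- rates_a$rate[match(ep$branch, rates_a$branch)]
  rb <- rates_b$rate[match(ep$branch, rates_b$branch)]
  if (anyNA(ra) || anyNA(rb)) stop("rate tables do not cover every branch of the tree")
  if (is.null(windows)) windows <- make_windows(max(node_ages(tree)))
  out <- windows
  out$n_branches <- NA_integer_
  out$r <- NA_real_
  out$p <- NA_real_
  for (w in seq_len(nrow(windows))) {
    inw <- epoch_overlaps(ep$older, ep$younger, windows$start[w], windows$end[w])
    out$n_branches[w] <- sum(inw)
    if (sum(inw) >= 3 && stats::sd(ra[inw]) > 0 && stats::sd(rb[inw]) > 0) {
      ct <- stats::cor.test(ra[inw], rb[inw], method = "pearson")
      out$r[w] <- unname(ct$estimate)
      out$p[w] <- ct$p.value
    }
  }
  out$low_n <- out$n_branches < min_branches
  class(out) <- c("window_corr", "data.frame")
  out
}

#' Overall Pearson correlation of branch rates between two trait complexes
#'
#' @param rates_a,rates_b Branch-rate tables (`branch`, `rate`) over the
#'   same branch set.
#' @param exclude Optional branch ids to drop (e.g. a single high-leverage
#'   branch whose influence is being probed).
#' @return `"cor_result"` with `r`, `p`, `df` (= n branches - 2), `n`.
#' @export
overall_rate_correlation <- function(rates_a, rates_b, exclude = NULL) {
  b <- intersect(rates_a$branch, rates_b$branch)
  if (!setequal(rates_a$branch, rates_b$branch)) {
    stop("rate tables cover different branch sets")
  }
  if (!is.null(exclude)) b <- setdiff(b, exclude)
  if (length(b) < 3) stop("need at least 3 branches")
  x <- rates_a$rate[match(b, rates_a$branch)]
  y <- rates_b$rate[match(b, rates_b$branch)]
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 df = length(b) - 2L, n = length(b)),
            class = "cor_result")
}

#' Plot windowed rate correlations through time
#'
#' Basic diagnostic line plot of Pearson's r per time window (x = window
#' midpoint age, oldest left), filled points marking windows with p < 0.05
#' and open points low-n windows.
#'
#' @param wc A `"window_corr"` data frame.
#' @param ... Passed to [graphics::plot()].
#' @return `wc`, invisibly.
#' @export
plot_window_correlations <- function(wc, ...) {
  mid <- (wc$start + wc$end) / 2
  graphics::plot(mid, wc$r, type = "l", xlim = rev(range(mid)),
                 xlab = "age (My before present)",
                 ylab = "rate correlation (Pearson's r)", ...)
  graphics::abline(h = 0, lty = 3)
  sig <- !is.na(wc$p) & wc$p < 0.05
  graphics::points(mid[sig], wc$r[sig], pch = 19)
  graphics::points(mid[wc$low_n], wc$r[wc$low_n], pch = 1)
  invisible(wc)
}
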