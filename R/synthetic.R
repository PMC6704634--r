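#' Simulate expression profiles with known pattern-group labels
#'
#' Generates a genes x conditions log2 expression matrix by reading the
#' classification model forward: each gene draws a pattern group from
#' `proportions`, a baseline mean `mu0 ~ Normal(baseline_mean, baseline_sd)`,
#' a signed effect `delta = s * Uniform(effect[1], effect[2])` with the sign
#' equiprobable (and `delta = 0` for the all-zero group), and condition
#' values `x_n ~ Normal(mu0 + delta * g_n, noise_sd)` under the group's
#' indicator vector. One `noise_sd` per gene across all conditions mirrors
#' the model's pooled-variance assumption.
#'
#' Defaults emulate the motivating six-condition microarray study: group
#' proportions matching the default priors (70 percent unregulated),
#' baseline log2 intensity around 7, regulated effects of 1-2 log2 units,
#' and condition noise of 0.2.
#'
#' @param n_genes number of genes to simulate.
#' @param patterns a `"pattern_groups"` object (default: the EGFR design's
#'   four groups).
#' @param proportions per-group sampling probabilities (default
#'   [default_priors()] of `patterns`).
#' @param baseline_mean,baseline_sd location and spread of the baseline
#'   mean draws (log2 scale).
#' @param effect length-2 vector, lower and upper bound of the absolute
#'   effect size (log2 units), `0 < effect[1] <= effect[2]`; can be
#'   length 1 for a fixed magnitude.
#' @param noise_sd within-gene condition standard deviation (> 0).
#' @param seed optional integer seed for reproducibility.
#' @return list with `x` (matrix with gene rownames and condition column
#'   names) and `truth` (data frame: `gene_id`, `group`, `mu0`, `delta`,
#'   `sigma`).
#' @examples
#' sim <- simulate_profiles(20, seed = 7)
#' table(sim$truth$group)
#' @export
simulate_profiles <- function(n_genes,
                              patterns = derive_pattern_groups(egfr_design()),
                              proportions = default_priors(patterns),
                              baseline_mean = 7, baseline_sd = 1,
                              effect = c(1, 2), noise_sd = 0.2,
                              seed = NULL) {
  stopifnot(inherits(patterns, "pattern_groups"))
  n_genes <- as.integer(n_genes)
  if (n_genes < 1L) stop("n_genes must be positive")
  proportions <- .check_proportions(proportions, patterns)
  if (length(effect) == 1L) effect <- c(effect, effect)
  if (length(effect) != 2L || effect[1] < 0 || effect[1] > effect[2])
    stop("effect must be 0 <= low <= high")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (baseline_sd < 0) stop("baseline_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  labels <- patterns$labels
  zero <- rowSums(patterns$indicators) == 0
  grp <- sample(labels, n_genes, replace = TRUE, prob = proportions)
  mu0 <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  sgn <- sample(c(-1, 1), n_genes, replace = TRUE)
  delta <- sgn * stats::runif(n_genes, effect[1], effect[2])
  delta[zero[match(grp, labels)]] <- 0
  n_cond <- ncol(patterns$indicators)
  G <- patterns$indicators[match(grp, labels), , drop = FALSE]
  mu <- mu0 + sweep(G, 1L, delta, `*`)
  x <- mu + matrix(stats::rnorm(n_genes * n_cond, sd = noise_sd),
                   n_genes, n_cond)
  ids <- sprintf("gene%0*d", nchar(n_genes), seq_len(n_genes))
  dimnames(x) <- list(ids, colnames(patterns$indicators))
  list(
    x = x,
    truth = data.frame(gene_id = ids, group = grp, mu0 = mu0,
                       delta = delta, sigma = noise_sd,
                       stringsAsFactors = FALSE)
  )
}

.check_proportions <- function(p, patterns) {
  labels <- patterns$labels
  if (is.null(names(p))) {
    if (length(p) != length(labels))
      stop("invalid proportions: need one entry per pattern group")
    names(p) <- labels
  }
  if (!setequal(names(p), labels))
    stop("invalid proportions: names do not match the pattern groups")
  p <- p[labels]
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("invalid proportions: must be non-negative and sum to 1")
  p
}

#' Recovery and calibration of a classification against simulated truth
#'
#' Compares assigned groups to the generating labels of
#' [simulate_profiles()]: overall and per-group accuracy, a truth x
#' assigned confusion matrix, and a posterior-calibration table binning
#' genes by the posterior of their assigned group into deciles and
#' contrasting the bin's mean posterior with its empirical accuracy.
#'
#' @param truth the `truth` data frame of a simulated dataset (or the full
#'   list returned by [simulate_profiles()]).
#' @param result a `"bgsc"` fit or a [classify_matrix()] data frame on the
#'   simulated matrix.
#' @return list with `accuracy`, `per_group_accuracy`, `confusion`,
#'   and `calibration` (data frame: `bin`, `n`, `mean_posterior`,
#'   `accuracy`).
#' @examples
#' sim <- simulate_profiles(200, seed = 3)
#' ev <- evaluate_recovery(sim$truth, bgsc(sim$x))
#' ev$accuracy
#' @export
evaluate_recovery <- function(truth, result) {
  if (is.list(truth) && !is.data.frame(truth) && !is.null(truth$truth))
    truth <- truth$truth
  if (inherits(result, "bgsc")) {
    assigned <- result$assigned
    ids <- rownames(result$x)
    post_assigned <- result$posterior[cbind(seq_along(assigned),
                                            match(assigned,
                                                  colnames(result$posterior)))]
  } else if (is.data.frame(result)) {
    assigned <- result$assigned_group
    ids <- result$gene_id
    pc <- paste0("posterior_", assigned)
    post_assigned <- vapply(seq_along(assigned),
                            function(i) result[[pc[i]]][i], numeric(1))
  } else {
    stop("result must be a 'bgsc' fit or a classify_matrix() data frame")
  }
  if (length(assigned) != nrow(truth))
    stop("truth and classification sizes differ (", nrow(truth), " vs ",
         length(assigned), ")")
  if (!is.null(ids) && !all(ids == truth$gene_id))
    stop("truth and classification gene ids do not match")
  groups <- sort(unique(c(truth$group, assigned)))
  hit <- assigned == truth$group
  confusion <- table(truth = factor(truth$group, groups),
                     assigned = factor(assigned, groups))
  per_group <- vapply(groups, function(g) {
    in_g <- truth$group == g
    if (!any(in_g)) return(NA_real_)
    mean(hit[in_g])
  }, numeric(1))
  bin <- cut(post_assigned, breaks = seq(0, 1, by = 0.1),
             include.lowest = TRUE, right = TRUE)
  calib <- data.frame(
    bin = levels(bin),
    n = as.integer(table(bin)),
    mean_posterior = as.numeric(tapply(post_assigned, bin, mean)),
    accuracy = as.numeric(tapply(hit, bin, mean)),
    stringsAsFactors = FALSE
  )
  list(accuracy = mean(hit), per_group_accuracy = per_group,
       confusion = confusion, calibration = calib)
}
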