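#' Log2 fold change of a regulated group fit
#'
#' The difference between the regulated-class and baseline-class mean
#' estimates, `mu1 - mu0`, on the log2 scale.
#'
#' @param fit a `"bgsc_group_fit"` from [fit_group()] (a regulated pattern:
#'   the all-zero group has a single mean and no fold change).
#' @return numeric log2 fold change.
#' @examples
#' log2_fold_change(fit_group(c(1, 3, 1, 3, 1, 1), c(0, 1, 0, 1, 0, 0)))
#' @export
log2_fold_change <- function(fit) {
  stopifnot(inherits(fit, "bgsc_group_fit"))
  if (is.na(fit$mu1))
    stop("fold change is undefined for the all-zero pattern group")
  fit$mu1 - fit$mu0
}

#' Satterthwaite standard error of a difference of class means
#'
#' With at least two values per class, the standard error is
#' `sqrt(s0^2/n0 + s1^2/n1)` with Welch-Satterthwaite degrees of freedom.
#' When a class holds a single value its variance is undefined; the pooled
#' model standard deviation `pooled_sd` is then used instead, giving
#' `pooled_sd * sqrt(1/n0 + 1/n1)` on `n0 + n1 - 2` degrees of freedom.
#'
#' @param values0 baseline-class values (length >= 1).
#' @param values1 regulated-class values (length >= 1).
#' @param pooled_sd pooled standard deviation used by the single-value
#'   fallback (required only in that case).
#' @return list with `se` and `df`.
#' @examples
#' satterthwaite_se(c(0, 1, 2), c(4, 5, 6))
#' @export
satterthwaite_se <- function(values0, values1, pooled_sd = NULL) {
  n0 <- length(values0); n1 <- length(values1)
  if (n0 < 1L || n1 < 1L) stop("both classes must be non-empty")
  if (n0 < 2L || n1 < 2L) {
    if (is.null(pooled_sd))
      stop("a class holds a single value; supply pooled_sd for the fallback")
    return(list(se = pooled_sd * sqrt(1 / n0 + 1 / n1), df = n0 + n1 - 2))
  }
  v0 <- stats::var(values0) / n0
  v1 <- stats::var(values1) / n1
  se <- sqrt(v0 + v1)
  den <- v0^2 / (n0 - 1) + v1^2 / (n1 - 1)
  df <- if (den > 0) (v0 + v1)^2 / den else n0 + n1 - 2
  list(se = se, df = df)
}

#' Select putative target genes of a pattern group
#'
#' Builds one call per gene assigned to the requested group: its posterior,
#' log2 fold change with Satterthwaite standard error, a direction call
#' (`up` / `down` when the fold change clears `fc_threshold` in magnitude,
#' else `none`), and a selection flag set when the posterior strictly
#' exceeds `posterior_threshold`. Selection is posterior-only; the fold
#' change threshold affects the direction call, not membership.
#'
#' @param object a `"bgsc"` fit (or a list of `"bgsc_classification"`
#'   objects together with `x`).
#' @param group pattern-group label to select from (default `"c"`, the
#'   confounded isoform II-IV group of the EGFR design).
#' @param posterior_threshold posterior cut (default 0.75, strict).
#' @param fc_threshold log2 fold-change magnitude for direction calls
#'   (default 0.5).
#' @return data frame sorted by descending posterior (ties: larger absolute
#'   fold change, then gene id) with columns `gene_id`, `posterior`,
#'   `log2fc`, `se`, `df`, `direction`, `selected`.
#' @examples
#' sim <- simulate_profiles(100, seed = 42)
#' fit <- bgsc(sim$x)
#' head(select_targets(fit, "c"))
#' @export
select_targets <- function(object, group = "c", posterior_threshold = 0.75,
                           fc_threshold = 0.5) {
  stopifnot(inherits(object, "bgsc"))
  labels <- object$patterns$labels
  if (!group %in% labels) stop("unknown pattern group: ", group)
  j <- match(group, labels)
  g <- object$patterns$indicators[j, ]
  if (all(g == 0L))
    stop("fold change is undefined for the all-zero pattern group")
  if (posterior_threshold <= 0 || posterior_threshold >= 1)
    stop("posterior_threshold must lie in (0, 1)")
  if (fc_threshold < 0) stop("fc_threshold must be non-negative")
  rows <- which(object$assigned == group)
  out <- data.frame(gene_id = character(0), posterior = numeric(0),
                    log2fc = numeric(0), se = numeric(0), df = numeric(0),
                    direction = character(0), selected = logical(0),
                    stringsAsFactors = FALSE)
  if (length(rows)) {
    fc <- object$mu1[rows, j] - object$mu0[rows, j]
    sw <- lapply(rows, function(i)
      satterthwaite_se(object$x[i, g == 0L], object$x[i, g == 1L],
                       pooled_sd = sqrt(max(object$sigma2[i, j],
                                            object$vfloor))))
    out <- data.frame(
      gene_id = rownames(object$x)[rows],
      posterior = unname(object$posterior[rows, j]),
      log2fc = unname(fc),
      se = vapply(sw, `[[`, numeric(1), "se"),
      df = vapply(sw, `[[`, numeric(1), "df"),
      stringsAsFactors = FALSE
    )
    out$direction <- ifelse(out$log2fc > fc_threshold, "up",
                            ifelse(out$log2fc < -fc_threshold, "down",
                                   "none"))
    out$selected <- out$posterior > posterior_threshold
    out <- out[order(-out$posterior, -abs(out$log2fc), out$gene_id), ]
    rownames(out) <- NULL
  }
  out
}

#' Cross-platform agreement of log2 fold changes
#'
#' Pearson correlation of paired per-gene fold changes measured on two
#' platforms (e.g. microarray vs qPCR).
#'
#' @param fc_platform1,fc_platform2 numeric vectors of matched per-gene
#'   log2 fold changes (same genes, same order; length >= 3).
#' @return list with `pearson_r` and `n`.
#' @examples
#' foldchange_agreement(c(1.2, -0.8, 0.6, -1.5), c(1.1, -0.7, 0.4, -1.6))
#' @export
foldchange_agreement <- function(fc_platform1, fc_platform2) {
  if (length(fc_platform1) != length(fc_platform2))
    stop("fold-change vectors must be matched gene-for-gene")
  n <- length(fc_platform1)
  if (n < 3L) stop("at least 3 paired fold changes are required")
  if (stats::sd(fc_platform1) == 0 || stats::sd(fc_platform2) == 0)
    stop("undefined correlation: zero variance in a fold-change vector")
  list(pearson_r = stats::cor(fc_platform1, fc_platform2), n = n)
}
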