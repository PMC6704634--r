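#' @export
print.bgsc <- function(x, ...) {
  cat("Bayesian gene selection fit\n")
  cat("  genes:      ", nrow(x$x), "\n", sep = "")
  cat("  conditions: ", ncol(x$x), " (stimulus ", x$design$stimulus, ")\n",
      sep = "")
  cat("  priors:     ",
      paste(sprintf("%s=%.3g", names(x$priors), x$priors), collapse = ", "),
      "\n", sep = "")
  tab <- table(factor(x$assigned, levels = x$patterns$labels))
  cat("  assigned per group:\n")
  print(tab)
  invisible(x)
}

#' Summarize a Bayesian gene selection fit
#'
#' Reports group sizes, the number of degenerate (zero-variance) profiles,
#' and — for a chosen target group — how many genes pass the posterior
#' selection threshold.
#'
#' @param object a `"bgsc"` fit.
#' @param group target group label (default the first confounded regulated
#'   group if present, else the second group).
#' @param posterior_threshold posterior cut used for the selection count
#'   (default 0.75).
#' @param ... unused.
#' @return An object of class `"summary.bgsc"`.
#' @export
summary.bgsc <- function(object, group = NULL, posterior_threshold = 0.75,
                         ...) {
  labels <- object$patterns$labels
  if (is.null(group)) {
    cand <- labels[object$patterns$confounded &
                     rowSums(object$patterns$indicators) > 0]
    group <- if (length(cand)) cand[1L] else labels[min(2L, length(labels))]
  }
  counts <- table(factor(object$assigned, levels = labels))
  sel <- sum(object$assigned == group &
               object$posterior[, group] > posterior_threshold)
  structure(
    list(n_genes = nrow(object$x), counts = counts,
         n_degenerate = sum(object$degenerate), group = group,
         posterior_threshold = posterior_threshold, n_selected = sel,
         mean_posterior = colMeans(object$posterior)),
    class = "summary.bgsc"
  )
}

#' @export
print.summary.bgsc <- function(x, ...) {
  cat("Bayesian gene selection summary\n")
  cat("  genes classified: ", x$n_genes, "\n", sep = "")
  cat("  per-group counts:\n")
  print(x$counts)
  cat("  mean posterior per group:\n")
  print(round(x$mean_posterior, 3))
  if (x$n_degenerate > 0)
    cat("  degenerate (zero-variance) profiles: ", x$n_degenerate, "\n",
        sep = "")
  cat("  genes in group '", x$group, "' with posterior > ",
      format(x$posterior_threshold), ": ", x$n_selected, "\n", sep = "")
  invisible(x)
}

#' Parameter estimates of the assigned group
#'
#' @param object a `"bgsc"` fit.
#' @param ... unused.
#' @return Matrix with one row per gene and columns `mu0`, `mu1`
#'   (`NA` for genes assigned the all-zero group) and `sigma2`, taken from
#'   the gene's assigned pattern group.
#' @export
coef.bgsc <- function(object, ...) {
  j <- match(object$assigned, object$patterns$labels)
  idx <- cbind(seq_len(nrow(object$x)), j)
  out <- cbind(mu0 = object$mu0[idx], mu1 = object$mu1[idx],
               sigma2 = object$sigma2[idx])
  rownames(out) <- rownames(object$x)
  out
}

#' Posterior probabilities or group assignments
#'
#' @param object a `"bgsc"` fit.
#' @param newdata optional expression matrix to classify with the same
#'   design and priors; default: the training matrix's results.
#' @param type `"group"` for assigned labels, `"posterior"` for the full
#'   posterior matrix.
#' @param ... unused.
#' @export
predict.bgsc <- function(object, newdata = NULL,
                         type = c("group", "posterior"), ...) {
  type <- match.arg(type)
  if (!is.null(newdata)) {
    object <- bgsc(newdata, design = object$design, priors = object$priors,
                   vfloor = object$vfloor)
  }
  if (type == "group") {
    stats::setNames(object$assigned, rownames(object$x))
  } else {
    object$posterior
  }
}

#' @export
fitted.bgsc <- function(object, ...) {
  j <- match(object$assigned, object$patterns$labels)
  out <- object$x
  for (i in seq_len(nrow(out))) {
    g <- object$patterns$indicators[j[i], ]
    m <- ifelse(g == 1L, object$mu1[i, j[i]], object$mu0[i, j[i]])
    out[i, ] <- m
  }
  out
}

#' @export
residuals.bgsc <- function(object, ...) {
  object$x - fitted(object)
}

#' Plot a gene's profile under every pattern group
#'
#' Draws the gene's log2 expression values across the conditions once per
#' pattern group, overlaying each group's fitted class means (solid line:
#' baseline mean; dashed line: regulated mean) and annotating the posterior
#' probability — a visual account of which pattern explains the profile
#' best.
#'
#' @param x a `"bgsc"` fit.
#' @param gene gene id or row index (default the first gene).
#' @param ... passed to [graphics::plot()].
#' @export
plot.bgsc <- function(x, gene = 1L, ...) {
  i <- if (is.character(gene)) match(gene, rownames(x$x)) else as.integer(gene)
  if (is.na(i) || i < 1L || i > nrow(x$x)) stop("unknown gene: ", gene)
  labels <- x$patterns$labels
  G <- length(labels)
  old <- graphics::par(mfrow = grDevices::n2mfrow(G),
                       mar = c(3.5, 3.5, 2.5, 0.5), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(old))
  xv <- x$x[i, ]
  for (j in seq_len(G)) {
    g <- x$patterns$indicators[j, ]
    graphics::plot(seq_along(xv), xv, pch = 19,
                   col = ifelse(g == 1L, "firebrick", "steelblue"),
                   xlab = "condition", ylab = "log2 expression",
                   main = sprintf("group %s  (posterior %.3f)", labels[j],
                                  x$posterior[i, j]), ...)
    graphics::abline(h = x$mu0[i, j], col = "steelblue")
    if (!is.na(x$mu1[i, j]))
      graphics::abline(h = x$mu1[i, j], col = "firebrick", lty = 2)
  }
  invisible(x)
}

#' Simulate expression matrices from the fitted per-gene models
#'
#' Parametric draws: each gene's new profile is sampled from the normal
#' model of its assigned pattern group, with the fitted class means and
#' variance.
#'
#' @param object a `"bgsc"` fit.
#' @param nsim number of matrices to draw.
#' @param seed optional seed.
#' @param ... unused.
#' @return A list of `nsim` matrices shaped like the training matrix.
#' @export
simulate.bgsc <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  j <- match(object$assigned, object$patterns$labels)
  sd_g <- sqrt(pmax(object$sigma2[cbind(seq_len(nrow(mu)), j)],
                    object$vfloor))
  lapply(seq_len(nsim), function(s) {
    e <- matrix(stats::rnorm(length(mu), sd = rep(sd_g, ncol(mu))),
                nrow(mu), ncol(mu))
    out <- mu + e
    dimnames(out) <- dimnames(object$x)
    out
  })
}
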