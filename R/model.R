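## Per-gene statistical core: group-specific normal likelihoods,
## closed-form estimators, BIC marginal-likelihood approximation and
## posterior classification.

#' Fit one pattern group's normal model to a single expression profile
#'
#' Under a pattern group with indicator vector `g`, the profile's values are
#' modelled as independent normals sharing one variance, with one mean for
#' the `g = 0` conditions and (for regulated groups) a second mean for the
#' `g = 1` conditions. Estimators are closed form: class means, and the
#' pooled squared deviation around the class means divided by
#' `n - (number of means)` — `n - 1` for the all-zero group, `n - 2`
#' otherwise (so denominators 5 and 4 for a six-condition design).
#'
#' @param x numeric profile (log2 expression), finite values.
#' @param indicator binary vector of the same length as `x` (a row of
#'   [derive_pattern_groups()]'s `indicators` matrix), or a group label
#'   together with `patterns`.
#' @param patterns optional `"pattern_groups"` object used to resolve
#'   `indicator` when it is given as a label.
#' @param vfloor variance floor; an estimated variance below it flags the
#'   fit as degenerate and is clamped so the likelihood stays finite.
#' @return A list of class `"bgsc_group_fit"`: `mu0`, `mu1` (`NA` for the
#'   all-zero group), `sigma2`, `n_params`, `log_likelihood`, `degenerate`,
#'   and the `indicator`.
#' @examples
#' fit_group(c(1, 3, 1, 3, 1, 5), c(0, 1, 0, 1, 0, 1))
#' @export
fit_group <- function(x, indicator, patterns = NULL, vfloor = 1e-12) {
  if (is.character(indicator)) {
    stopifnot(inherits(patterns, "pattern_groups"))
    indicator <- patterns$indicators[indicator, ]
  }
  x <- as.numeric(x)
  g <- as.integer(indicator)
  if (length(x) != length(g))
    stop("profile and pattern indicator have different lengths (",
         length(x), " vs ", length(g), ")")
  if (!all(is.finite(x))) stop("expression profile contains non-finite values")
  if (!all(g %in% c(0L, 1L))) stop("indicator must be binary")
  n <- length(x)
  if (any(g == 1L) && all(g == 1L))
    stop("regulated patterns need both indicator classes non-empty")
  if (all(g == 0L)) {
    mu0 <- mean(x)
    mu1 <- NA_real_
    sse <- sum((x - mu0)^2)
    df <- n - 1L
    k <- 2L
    mu_n <- rep(mu0, n)
  } else {
    mu0 <- mean(x[g == 0L])
    mu1 <- mean(x[g == 1L])
    sse <- sum((x[g == 0L] - mu0)^2) + sum((x[g == 1L] - mu1)^2)
    df <- n - 2L
    k <- 3L
    mu_n <- ifelse(g == 1L, mu1, mu0)
  }
  s2 <- sse / df
  degenerate <- s2 < vfloor
  s2_eval <- max(s2, vfloor)
  ll <- sum(stats::dnorm(x, mu_n, sqrt(s2_eval), log = TRUE))
  structure(
    list(mu0 = mu0, mu1 = mu1, sigma2 = s2, n_params = k,
         log_likelihood = ll, degenerate = degenerate, indicator = g),
    class = "bgsc_group_fit"
  )
}

#' BIC approximation to the log marginal likelihood
#'
#' Penalizes the maximized log-likelihood by half the parameter count times
#' the log number of observations, i.e. the marginal likelihood is
#' approximated (up to a constant shared by all models of the same data) by
#' the maximized likelihood divided by `sqrt(n_obs) ^ n_params`.
#'
#' @param log_likelihood maximized log-likelihood of the model.
#' @param n_params number of free parameters.
#' @param n_obs number of data points.
#' @return `log_likelihood - (n_params / 2) * log(n_obs)`.
#' @examples
#' exp(bic_log_marginal(log(4.22), 3, 6))  # 4.22 / sqrt(6)^3 = 0.287
#' @export
bic_log_marginal <- function(log_likelihood, n_params, n_obs) {
  if (any(n_obs < 1)) stop("n_obs must be at least 1")
  if (any(n_params < 0)) stop("n_params must be non-negative")
  log_likelihood - n_params / 2 * log(n_obs)
}

#' Posterior group probabilities from log marginals and priors
#'
#' Bayes' formula on the log scale with max-subtraction normalization, so
#' widely spread marginal likelihoods neither overflow nor underflow. The
#' computation uses the full-precision marginals; normalizing rounded
#' marginals gives visibly different posteriors.
#'
#' @param log_marginals named numeric vector of per-group log marginal
#'   likelihoods.
#' @param priors named numeric vector of prior probabilities over the same
#'   groups (non-negative, summing to 1; see [default_priors()]).
#' @return named numeric vector of posterior probabilities summing to 1.
#' @examples
#' lm <- bic_log_marginal(log(c(a = 0.004, b = 0.035, c = 4.22, d = 0.012)),
#'                        c(2, 3, 3, 3), 6)
#' round(group_posteriors(lm, c(a = 0.7, b = 0.1, c = 0.1, d = 0.1)), 3)
#' @export
group_posteriors <- function(log_marginals, priors) {
  if (!is.null(names(log_marginals)) && !is.null(names(priors))) {
    if (!setequal(names(log_marginals), names(priors)))
      stop("groups of log_marginals and priors do not coincide")
    priors <- priors[names(log_marginals)]
  } else if (length(log_marginals) != length(priors)) {
    stop("log_marginals and priors have different lengths")
  }
  if (any(priors < 0)) stop("invalid priors: negative prior probability")
  if (all(priors == 0)) stop("invalid priors: all prior mass is zero")
  lp <- log_marginals + log(priors)
  lp[priors == 0] <- -Inf
  m <- max(lp)
  w <- exp(lp - m)
  w / sum(w)
}

#' Default group priors
#'
#' Places prior mass 0.70 on the all-zero (unregulated) pattern group and
#' splits the remaining 0.30 equally over the regulated groups — the
#' assumption that roughly 70 percent of genes do not respond to the
#' stimulus. For the four-group EGFR design this is
#' `(a, b, c, d) = (0.70, 0.10, 0.10, 0.10)`.
#'
#' @param patterns a `"pattern_groups"` object.
#' @return named numeric vector of prior probabilities.
#' @export
default_priors <- function(patterns) {
  stopifnot(inherits(patterns, "pattern_groups"))
  G <- length(patterns$labels)
  zero <- rowSums(patterns$indicators) == 0
  if (G == 1L) return(stats::setNames(1, patterns$labels))
  p <- rep(0.30 / (G - sum(zero)), G)
  p[zero] <- 0.70 / max(sum(zero), 1L)
  stats::setNames(p, patterns$labels)
}

## vectorized all-group fit for a genes x conditions matrix; the engine
## behind classify_gene / classify_matrix / bgsc
.bgsc_fit_all <- function(X, patterns, priors, vfloor = 1e-12) {
  stopifnot(inherits(patterns, "pattern_groups"))
  n <- ncol(X)
  if (n != ncol(patterns$indicators))
    stop("matrix has ", n, " conditions but the design defines ",
         ncol(patterns$indicators))
  if (!all(is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1L, ]
    stop("non-finite expression value for gene '",
         rownames(X)[bad[1L]], "' (column ", bad[2L], ")")
  }
  labels <- patterns$labels
  G <- length(labels)
  ng <- nrow(X)
  mu0 <- mu1 <- s2 <- ll <- matrix(NA_real_, ng, G,
                                   dimnames = list(rownames(X), labels))
  kpar <- integer(G)
  for (j in seq_len(G)) {
    g <- patterns$indicators[j, ]
    if (all(g == 0L)) {
      m0 <- rowMeans(X)
      sse <- rowSums((X - m0)^2)
      df <- n - 1L
      kpar[j] <- 2L
      mu0[, j] <- m0
    } else {
      X0 <- X[, g == 0L, drop = FALSE]
      X1 <- X[, g == 1L, drop = FALSE]
      m0 <- rowMeans(X0)
      m1 <- rowMeans(X1)
      sse <- rowSums((X0 - m0)^2) + rowSums((X1 - m1)^2)
      df <- n - 2L
      kpar[j] <- 3L
      mu0[, j] <- m0
      mu1[, j] <- m1
    }
    s2[, j] <- sse / df
    s2e <- pmax(s2[, j], vfloor)
    ll[, j] <- -n / 2 * log(2 * pi * s2e) - sse / (2 * s2e)
  }
  lmarg <- sweep(ll, 2L, kpar / 2 * log(n))
  zero_g <- which(rowSums(patterns$indicators) == 0)[1L]
  # genes with essentially zero total variance: no information about
  # regulation, forced to the all-zero group with posterior 1
  all_degen <- s2[, zero_g] < vfloor
  part_degen <- rowSums(s2 < vfloor) > 0L & !all_degen
  lp <- sweep(lmarg, 2L, log(priors[labels]), "+")
  lp[, priors[labels] == 0] <- -Inf
  mx <- apply(lp, 1L, max)
  post <- exp(lp - mx)
  post <- post / rowSums(post)
  if (any(all_degen)) {
    post[all_degen, ] <- 0
    post[all_degen, zero_g] <- 1
  }
  if (any(part_degen))
    warning(sum(part_degen), " gene(s) hit the variance floor for some ",
            "pattern group; variance clamped to ", vfloor)
  # argmax with parsimony tie-break: posterior desc, fewer parameters,
  # alphabetical label
  assigned <- labels[max.col(post, ties.method = "first")]
  ties <- abs(post - apply(post, 1L, max)) < 1e-12
  multi <- which(rowSums(ties) > 1L)
  for (i in multi) {
    cand <- which(ties[i, ])
    cand <- cand[order(kpar[cand], labels[cand])]
    assigned[i] <- labels[cand[1L]]
  }
  if (any(all_degen)) assigned[all_degen] <- labels[zero_g]
  list(mu0 = mu0, mu1 = mu1, sigma2 = s2, log_likelihood = ll,
       log_marginal = lmarg, posterior = post, n_params = kpar,
       assigned = assigned, degenerate = all_degen,
       clamped = part_degen)
}

#' Classify one gene's expression profile
#'
#' Fits every pattern group's normal model to the profile, converts the
#' maximized likelihoods to BIC-approximated marginal likelihoods, applies
#' the priors, and assigns the group with the highest posterior. Posterior
#' ties are broken towards the group with fewer parameters, then
#' alphabetically. A profile whose total variance is below `vfloor` carries
#' no evidence of regulation and is assigned the all-zero group with
#' posterior 1 and `degenerate = TRUE`.
#'
#' @param x numeric expression profile of length `2 * T`.
#' @param patterns a `"pattern_groups"` object.
#' @param priors per-group prior probabilities; defaults to
#'   [default_priors()].
#' @param gene_id identifier used in error messages and output.
#' @param vfloor variance floor for degenerate handling.
#' @return A list of class `"bgsc_classification"`: `gene_id`, `fits`
#'   (named list of `"bgsc_group_fit"`), `log_marginal`, `posterior`,
#'   `assigned_group`, `degenerate`.
#' @examples
#' pats <- derive_pattern_groups(egfr_design())
#' cl <- classify_gene(c(0, 5, 0.1, 0, -0.1, 0.05), pats)
#' cl$assigned_group
#' @export
classify_gene <- function(x, patterns, priors = default_priors(patterns),
                          gene_id = "gene", vfloor = 1e-12) {
  X <- matrix(as.numeric(x), nrow = 1L,
              dimnames = list(gene_id, NULL))
  if (!all(is.finite(X)))
    stop("non-finite expression value in profile of gene '", gene_id, "'")
  priors <- .check_priors(priors, patterns)
  f <- .bgsc_fit_all(X, patterns, priors, vfloor)
  fits <- lapply(seq_along(patterns$labels), function(j)
    structure(list(mu0 = f$mu0[1L, j], mu1 = f$mu1[1L, j],
                   sigma2 = f$sigma2[1L, j], n_params = f$n_params[j],
                   log_likelihood = f$log_likelihood[1L, j],
                   degenerate = f$sigma2[1L, j] < vfloor,
                   indicator = patterns$indicators[j, ]),
              class = "bgsc_group_fit"))
  names(fits) <- patterns$labels
  structure(
    list(gene_id = gene_id, fits = fits,
         log_marginal = f$log_marginal[1L, ],
         posterior = f$posterior[1L, ],
         assigned_group = f$assigned[1L],
         degenerate = f$degenerate[1L]),
    class = "bgsc_classification"
  )
}

.check_priors <- function(priors, patterns) {
  labels <- patterns$labels
  if (is.null(names(priors))) {
    if (length(priors) != length(labels))
      stop("priors must have one entry per pattern group (",
           length(labels), ")")
    names(priors) <- labels
  }
  if (!setequal(names(priors), labels))
    stop("prior names do not match the pattern-group labels")
  priors <- priors[labels]
  if (any(priors < 0)) stop("invalid priors: negative prior probability")
  if (all(priors == 0)) stop("invalid priors: all prior mass is zero")
  if (abs(sum(priors) - 1) > 1e-9)
    stop("priors must sum to 1 (got ", format(sum(priors)), ")")
  priors
}

#' Classify every row of an expression matrix
#'
#' Row-wise application of [classify_gene()], vectorized internally; the
#' result for each gene is identical to the individual call and independent
#' of the other rows. Duplicate gene identifiers are disambiguated with
#' numeric suffixes and a warning.
#'
#' @param x numeric matrix or data frame, genes in rows, conditions in
#'   columns (rownames taken as gene ids).
#' @inheritParams classify_gene
#' @return A data frame with one row per gene: `gene_id`, one
#'   `posterior_<label>` column per group, `assigned_group`, `degenerate`.
#' @seealso [bgsc()] for the full model object with methods.
#' @export
classify_matrix <- function(x, patterns, priors = default_priors(patterns),
                            vfloor = 1e-12) {
  X <- .as_expr_matrix(x)
  if (nrow(X) < 1L) stop("expression matrix has no gene rows")
  priors <- .check_priors(priors, patterns)
  f <- .bgsc_fit_all(X, patterns, priors, vfloor)
  out <- data.frame(gene_id = rownames(X), stringsAsFactors = FALSE)
  for (lab in patterns$labels)
    out[[paste0("posterior_", lab)]] <- unname(f$posterior[, lab])
  out$assigned_group <- f$assigned
  out$degenerate <- f$degenerate
  out
}

.as_expr_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression input must be a numeric matrix or data frame")
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("gene%0*d", nchar(nrow(x)), seq_len(nrow(x)))
  if (anyDuplicated(rownames(x))) {
    warning("duplicate gene ids disambiguated with suffixes")
    rownames(x) <- make.unique(rownames(x), sep = "_")
  }
  x
}

#' Fit the Bayesian gene selection model to an expression matrix
#'
#' The main entry point. Derives the distinct expression-pattern groups
#' from the knockdown design, fits each group's two-mean (or one-mean)
#' normal model to every gene, approximates marginal likelihoods by the
#' Bayesian Information Criterion, and computes posterior group membership
#' probabilities. The returned object supports `print`, `summary`, `coef`,
#' `predict`, `fitted`, `residuals`, `plot` and `simulate`.
#'
#' @param x numeric matrix or data frame of normalized log2 expression,
#'   genes in rows, the design's `2 * T` conditions in columns. If column
#'   names match the design's [condition_labels()] (in any order) columns
#'   are reordered accordingly; otherwise they are used positionally (with
#'   a warning when names are present but unrecognized).
#' @param design a `"knockdown_design"`; default [egfr_design()].
#' @param priors per-group prior probabilities (default
#'   [default_priors()]).
#' @param vfloor variance floor for degenerate profiles.
#' @return An object of class `"bgsc"` with components `x`, `design`,
#'   `patterns`, `priors`, `posterior` (genes x groups), `assigned`,
#'   `mu0`, `mu1`, `sigma2`, `log_likelihood`, `log_marginal`,
#'   `n_params`, `degenerate`, `call`.
#' @examples
#' sim <- simulate_profiles(50, seed = 1)
#' fit <- bgsc(sim$x)
#' fit
#' table(truth = sim$truth$group, assigned = fit$assigned)
#' @export
bgsc <- function(x, design = egfr_design(),
                 priors = NULL, vfloor = 1e-12) {
  patterns <- derive_pattern_groups(design)
  if (is.null(priors)) priors <- default_priors(patterns)
  priors <- .check_priors(priors, patterns)
  X <- .as_expr_matrix(x)
  X <- .match_conditions(X, design)
  f <- .bgsc_fit_all(X, patterns, priors, vfloor)
  structure(
    list(x = X, design = design, patterns = patterns, priors = priors,
         posterior = f$posterior, assigned = f$assigned,
         mu0 = f$mu0, mu1 = f$mu1, sigma2 = f$sigma2,
         log_likelihood = f$log_likelihood, log_marginal = f$log_marginal,
         n_params = f$n_params, degenerate = f$degenerate,
         vfloor = vfloor, call = match.call()),
    class = "bgsc"
  )
}

## reorder matrix columns to the design's condition labels when the header
## names them; positional use (with warning if named but unmatched)
.match_conditions <- function(X, design) {
  want <- condition_labels(design)
  if (ncol(X) != length(want))
    stop("expression matrix has ", ncol(X), " columns but the design has ",
         length(want), " conditions")
  have <- colnames(X)
  if (!is.null(have) && all(want %in% have)) {
    X <- X[, want, drop = FALSE]
  } else {
    if (!is.null(have) && !all(have == ""))
      warning("column names do not match the design's condition labels; ",
              "matching by position")
    colnames(X) <- want
  }
  X
}
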