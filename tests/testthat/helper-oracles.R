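# Independent brute-force oracles, written against the definitions only —
# none of them call the package's fitting or design-reduction code paths.

# all channel subsets as a list, via binary counting over a 0/1 grid
oracle_all_subsets <- function(channels) {
  grid <- expand.grid(rep(list(0:1), length(channels)))
  lapply(seq_len(nrow(grid)), function(i) channels[grid[i, ] == 1])
}

# mode x treatment response by direct set logic
oracle_response <- function(regulators, knocked_down, channels) {
  surviving <- setdiff(channels, knocked_down)
  as.integer(length(intersect(regulators, surviving)) > 0)
}

# partition of all modes into identical-indicator classes; returns a set of
# "indicator|sorted-member-sets" strings, order-free for comparison
oracle_partition <- function(design) {
  subsets <- oracle_all_subsets(design$channels)
  key <- vapply(subsets, function(s) {
    resp <- vapply(design$treatments, oracle_response, integer(1),
                   regulators = s, channels = design$channels)
    ind <- rep(0L, 2L * length(resp))
    ind[2L * seq_along(resp)] <- resp
    paste(ind, collapse = "")
  }, character(1))
  member_str <- vapply(subsets, function(s)
    if (length(s)) paste(sort(s), collapse = "+") else "{}", character(1))
  sort(vapply(split(member_str, key), function(ms)
    paste(sort(ms), collapse = ";"), character(1)))
}

# same partition from the package's derive_pattern_groups, as strings
package_partition <- function(design) {
  pg <- derive_pattern_groups(design)
  modes <- enumerate_modes(design)
  sort(vapply(unname(pg$members), function(labs) {
    regs <- modes$regulators[match(labs, modes$label)]
    paste(sort(vapply(regs, function(s)
      if (length(s)) paste(sort(s), collapse = "+") else "{}",
      character(1))), collapse = ";")
  }, character(1)))
}

random_design <- function(k, t) {
  channels <- paste0("ch", seq_len(k))
  treatments <- c(list(control = character(0)),
                  lapply(seq_len(t - 1L), function(i)
                    sample(channels, sample.int(k, 1L))))
  names(treatments) <- c("control",
                         if (t > 1L) paste0("kd", seq_len(t - 1L)))
  knockdown_design(channels, treatments)
}

# numeric maximum-likelihood means by direct optimization (no closed form)
oracle_fit_means <- function(x, g) {
  if (all(g == 0)) {
    opt <- stats::optimize(function(m) sum((x - m)^2),
                           range(x) + c(-1, 1), tol = 1e-12)
    c(mu0 = opt$minimum, mu1 = NA_real_)
  } else {
    sse <- function(p) sum((x[g == 0] - p[1])^2) + sum((x[g == 1] - p[2])^2)
    opt <- stats::optim(c(mean(x), mean(x)), sse, method = "BFGS",
                        control = list(reltol = 1e-15))
    c(mu0 = opt$par[1], mu1 = opt$par[2])
  }
}

# full per-gene pipeline reimplemented independently (scalar, naive)
oracle_classify <- function(x, indicators, priors) {
  lp <- vapply(rownames(indicators), function(z) {
    g <- indicators[z, ]
    if (all(g == 0)) {
      m <- rep(mean(x), length(x)); k <- 2
      s2 <- sum((x - m)^2) / (length(x) - 1)
    } else {
      m <- ifelse(g == 1, mean(x[g == 1]), mean(x[g == 0])); k <- 3
      s2 <- sum((x - m)^2) / (length(x) - 2)
    }
    sum(dnorm(x, m, sqrt(s2), log = TRUE)) -
      k / 2 * log(length(x)) + log(priors[z])
  }, numeric(1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  list(posterior = p, assigned = names(which.max(p)))
}

egfr_patterns <- function() derive_pattern_groups(egfr_design())
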