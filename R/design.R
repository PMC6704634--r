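#' Construct a nested knockdown design
#'
#' A design consists of a set of regulator channels (receptor routes through
#' which a stimulus can drive transcription, e.g. distinct receptor isoform
#' classes), an ordered panel of knockdown treatments, and the name of the
#' stimulus. Each treatment silences a subset of the channels; the first
#' treatment must be the untreated control (silencing nothing). Every
#' treatment is measured without and with the stimulus, so a design with
#' `T` treatments yields `2 * T` experimental conditions, numbered so that
#' condition `2t - 1` is treatment `t` unstimulated and condition `2t` is
#' treatment `t` stimulated.
#'
#' @param channels character vector of unique channel names.
#' @param treatments named list; each element is a character vector naming
#'   the channels knocked down by that treatment (the control uses
#'   `character(0)`). The first element must be the control.
#' @param stimulus name of the stimulus applied in the even-numbered
#'   conditions (default `"EGF"`).
#' @return An object of class `"knockdown_design"`.
#' @seealso [egfr_design()], [enumerate_modes()], [derive_pattern_groups()]
#' @examples
#' d <- knockdown_design(
#'   channels   = c("r1", "r2"),
#'   treatments = list(control = character(0), kd_both = c("r1", "r2"))
#' )
#' d
#' @export
knockdown_design <- function(channels, treatments, stimulus = "EGF") {
  channels <- as.character(channels)
  if (length(channels) < 1L)
    stop("invalid design: at least one regulator channel is required")
  if (anyDuplicated(channels))
    stop("invalid design: channel names must be unique")
  if (!is.list(treatments) || length(treatments) < 1L)
    stop("invalid design: at least one treatment is required")
  if (is.null(names(treatments)) || any(!nzchar(names(treatments))) ||
      anyDuplicated(names(treatments)))
    stop("invalid design: treatments must have unique non-empty names")
  treatments <- lapply(treatments, as.character)
  bad <- vapply(treatments, function(kd) !all(kd %in% channels), logical(1))
  if (any(bad))
    stop("invalid design: treatment(s) ",
         paste(names(treatments)[bad], collapse = ", "),
         " knock down unknown channels")
  if (length(treatments[[1L]]) != 0L)
    stop("invalid design: the first treatment must be the control ",
         "(knocking down no channel)")
  structure(
    list(channels = channels, treatments = treatments,
         stimulus = as.character(stimulus)[1L]),
    class = "knockdown_design"
  )
}

#' The EGFR splice-variant knockdown design
#'
#' Built-in design of the motivating experiment: EGF stimulation of a
#' glioblastoma cell line in which genes can be regulated through the
#' full-length EGFR isoform I, through the truncated soluble EGFR isoforms
#' II-IV, or through other EGF-responsive receptors. The treatment panel is
#' nested: no RNAi (control), an siRNA silencing only splice variant I, and
#' an siRNA silencing all splice variants, giving six conditions
#' `x1 .. x6`.
#'
#' @return A `"knockdown_design"` with 3 channels and 3 treatments.
#' @examples
#' enumerate_modes(egfr_design())
#' @export
egfr_design <- function() {
  knockdown_design(
    channels = c("isoform_I", "isoforms_II_IV", "other_receptors"),
    treatments = list(
      control   = character(0),
      siRNA_I   = "isoform_I",
      siRNA_ALL = c("isoform_I", "isoforms_II_IV")
    ),
    stimulus = "EGF"
  )
}

#' @export
print.knockdown_design <- function(x, ...) {
  cat("Nested knockdown design\n")
  cat("  stimulus:  ", x$stimulus, "\n", sep = "")
  cat("  channels:  ", paste(x$channels, collapse = ", "), "\n", sep = "")
  cat("  treatments (knocked-down channels):\n")
  for (nm in names(x$treatments)) {
    kd <- x$treatments[[nm]]
    cat("    ", nm, ": ",
        if (length(kd)) paste(kd, collapse = ", ") else "-", "\n", sep = "")
  }
  cat("  conditions: ", paste(condition_labels(x), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Condition labels of a design
#'
#' Interleaved labels for the `2 * T` conditions: for each treatment, first
#' the unstimulated, then the stimulated condition
#' (`<treatment>` / `<treatment>_<stimulus>`).
#'
#' @param design a `"knockdown_design"`.
#' @return character vector of length `2 * length(design$treatments)`.
#' @export
condition_labels <- function(design) {
  stopifnot(inherits(design, "knockdown_design"))
  as.vector(rbind(names(design$treatments),
                  paste(names(design$treatments), design$stimulus,
                        sep = "_")))
}

## spreadsheet-style labels A..Z, AA, AB, ... for >26 modes
mode_labels <- function(n) {
  lab <- character(n)
  for (i in seq_len(n)) {
    j <- i; s <- ""
    while (j > 0L) {
      r <- (j - 1L) %% 26L
      s <- paste0(LETTERS[r + 1L], s)
      j <- (j - 1L) %/% 26L
    }
    lab[i] <- s
  }
  lab
}

## canonical ordering of channel subsets (see enumerate_modes docs)
order_subsets <- function(subsets, channels) {
  k <- length(channels)
  # precedence rank 1 = last design channel (the least specific regulator)
  rank_of <- stats::setNames(seq_len(k), rev(channels))
  keys <- vapply(subsets, function(s) {
    r <- sort(unname(rank_of[s]))
    key <- paste(sprintf("%02d", c(r, rep(0L, k - length(r)))),
                 collapse = "")
    paste0(min(length(s), 2L), key)
  }, character(1))
  order(keys)
}

#' Enumerate all regulation modes of a design
#'
#' A regulation mode is the subset of regulator channels through which the
#' stimulus drives a gene; `k` channels give `2^k` modes. Modes are labelled
#' `A`, `B`, `C`, ... in a canonical order: the unregulated (empty) mode
#' first, then the single-channel modes, then all multi-channel modes, with
#' ties broken by channel precedence (channels listed later in the design —
#' the broader, less specific regulators — sort first). For the built-in
#' EGFR design this reproduces the conventional labelling in which `H` is
#' regulation through isoform I together with isoforms II-IV.
#'
#' @param design a `"knockdown_design"`.
#' @return A data frame with columns `label`, `regulators` (list column of
#'   character vectors) and `size`.
#' @examples
#' enumerate_modes(egfr_design())
#' @export
enumerate_modes <- function(design) {
  stopifnot(inherits(design, "knockdown_design"))
  ch <- design$channels
  k <- length(ch)
  if (k < 1L) stop("invalid design: no channels")
  subsets <- lapply(seq_len(2^k) - 1L, function(m) ch[bitwAnd(m, 2^(seq_len(k) - 1L)) > 0L])
  subsets <- subsets[order_subsets(subsets, ch)]
  out <- data.frame(
    label = mode_labels(length(subsets)),
    size  = vapply(subsets, length, integer(1)),
    stringsAsFactors = FALSE
  )
  out$regulators <- subsets
  out[, c("label", "regulators", "size")]
}

#' Response of a regulation mode under a knockdown treatment
#'
#' A mode responds to the stimulus under a treatment if at least one of its
#' regulator channels survives the knockdown, i.e. if the mode's regulator
#' set intersects the channels not silenced by the treatment. Direction of
#' change (up or down) is deliberately collapsed to a binary flag.
#'
#' @param mode a mode label from [enumerate_modes()] or a character vector
#'   of regulator channel names (possibly empty).
#' @param treatment a treatment name from the design or a character vector
#'   of knocked-down channel names.
#' @param design a `"knockdown_design"`.
#' @return `1L` if the mode is stimulus-responsive under the treatment,
#'   `0L` otherwise.
#' @examples
#' d <- egfr_design()
#' mode_response("H", "siRNA_ALL", d)  # isoforms I + II-IV both silenced: 0
#' mode_response("C", "siRNA_I",   d)  # isoforms II-IV survive: 1
#' @export
mode_response <- function(mode, treatment, design) {
  stopifnot(inherits(design, "knockdown_design"))
  if (length(mode) == 1L && !mode %in% design$channels) {
    modes <- enumerate_modes(design)
    i <- match(mode, modes$label)
    if (is.na(i)) stop("unknown mode label: ", mode)
    mode <- modes$regulators[[i]]
  }
  if (!all(mode %in% design$channels))
    stop("mode regulators must be channels of the design")
  if (length(treatment) == 1L && treatment %in% names(design$treatments)) {
    treatment <- design$treatments[[treatment]]
  } else if (!all(treatment %in% design$channels)) {
    stop("unknown treatment")
  }
  surviving <- setdiff(design$channels, treatment)
  as.integer(length(intersect(mode, surviving)) > 0L)
}

#' Reduce regulation modes to distinct expression-pattern groups
#'
#' Tabulates every mode's binary stimulus response under every treatment and
#' groups modes whose responses are identical: modes in one group are
#' observationally equivalent under the design (confounded), so only the
#' pattern groups — not the individual modes — can be distinguished from
#' expression data. Each group carries a binary indicator vector
#' `g1 .. g_{2T}` over the interleaved conditions; unstimulated positions
#' (odd) are always 0 and position `2t` holds the group's response under
#' treatment `t`. Groups are labelled `a`, `b`, ... with the all-zero
#' (unregulated) pattern first, then by decreasing number of responsive
#' conditions, ties broken by the earliest responsive condition.
#'
#' For the built-in EGFR design this yields the four groups
#' `a = {A}` (unregulated), `b = {B, E, F, G}` (regulation reaching through
#' other receptors), `c = {C, H}` (regulation through isoforms II-IV but not
#' other receptors), and `d = {D}` (regulation through isoform I only).
#'
#' @param design a `"knockdown_design"`.
#' @return An object of class `"pattern_groups"`: a list with elements
#'   `labels`, `indicators` (binary matrix, one row per group, columns the
#'   design's conditions), `members` (named list of confounded mode labels),
#'   `confounded` (logical, `TRUE` where a group holds more than one mode)
#'   and `design`.
#' @examples
#' derive_pattern_groups(egfr_design())
#' @export
derive_pattern_groups <- function(design) {
  stopifnot(inherits(design, "knockdown_design"))
  modes <- enumerate_modes(design)
  trt <- names(design$treatments)
  resp <- vapply(trt, function(tn)
    vapply(modes$regulators, mode_response, integer(1),
           treatment = tn, design = design),
    integer(nrow(modes)))
  resp <- matrix(resp, nrow = nrow(modes),
                 dimnames = list(modes$label, trt))
  n_cond <- 2L * length(trt)
  ind <- matrix(0L, nrow(modes), n_cond)
  ind[, 2L * seq_along(trt)] <- resp
  key <- apply(ind, 1L, paste, collapse = "")
  groups <- split(modes$label, key)
  ukey <- names(groups)
  uind <- do.call(rbind, lapply(ukey, function(k)
    as.integer(strsplit(k, "")[[1L]])))
  nones <- rowSums(uind)
  first1 <- apply(uind, 1L, function(g)
    if (any(g == 1L)) which(g == 1L)[1L] else n_cond + 1L)
  ord <- order(nones != 0L, -nones, first1, ukey)
  uind <- uind[ord, , drop = FALSE]
  groups <- groups[ord]
  labels <- letters[seq_along(groups)]
  dimnames(uind) <- list(labels, condition_labels(design))
  names(groups) <- labels
  structure(
    list(labels = labels, indicators = uind, members = groups,
         confounded = lengths(groups) > 1L, design = design),
    class = "pattern_groups"
  )
}

#' @export
print.pattern_groups <- function(x, ...) {
  cat("Expression-pattern groups (", length(x$labels), " distinct patterns, ",
      sum(lengths(x$members)), " regulation modes)\n", sep = "")
  tab <- data.frame(
    group = x$labels,
    indicator = apply(x$indicators, 1L, paste, collapse = ""),
    modes = vapply(x$members, paste, character(1), collapse = ","),
    confounded = ifelse(x$confounded, "yes", "no"),
    row.names = NULL
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Read a knockdown design from a YAML file
#'
#' Expected keys: `channels` (list of names), `treatments` (list of maps
#' with `name` and `knocked_down`), and optionally `stimulus`. The string
#' `"egfr-default"` returns the built-in [egfr_design()].
#'
#' @param path path to a YAML design file, or `"egfr-default"`.
#' @return A `"knockdown_design"`.
#' @export
read_design <- function(path) {
  if (identical(path, "egfr-default")) return(egfr_design())
  if (!file.exists(path)) stop("design file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$channels) || is.null(y$treatments))
    stop("design file must define 'channels' and 'treatments'")
  tr <- lapply(y$treatments, function(t) {
    kd <- t$knocked_down
    if (is.null(kd)) character(0) else as.character(unlist(kd))
  })
  names(tr) <- vapply(y$treatments, function(t) as.character(t$name),
                      character(1))
  knockdown_design(
    channels = as.character(unlist(y$channels)),
    treatments = tr,
    stimulus = if (is.null(y$stimulus)) "EGF" else y$stimulus
  )
}
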