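#' Read a tab-separated expression matrix
#'
#' Expects a header row, a first column of gene/probe identifiers, and
#' real-valued log2 expression in the remaining columns (already
#' background-corrected and normalized upstream). Missing or non-numeric
#' cells are rejected with the offending row and column. When a design is
#' supplied, columns are matched to its condition labels by header name,
#' falling back to positional matching with a warning.
#'
#' @param path path to a tab-separated file.
#' @param design optional `"knockdown_design"` used to check and order the
#'   condition columns.
#' @return numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path, design = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L)
    stop("parse error in ", path, ": need an id column plus expression ",
         "columns")
  ids <- tab[[1L]]
  num <- tab[-1L]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) | !nzchar(trimws(num[[j]])))
    if (length(bad))
      stop("parse error in ", path, ", line ", bad[1L] + 1L, ", column '",
           names(num)[j], "': value '", num[[j]][bad[1L]],
           "' is missing or non-numeric")
    num[[j]] <- v
  }
  X <- as.matrix(num)
  rownames(X) <- ids
  X <- .as_expr_matrix(X)
  if (!is.null(design)) X <- .match_conditions(X, design)
  X
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_expression_matrix()]: first column `gene_id`, then one
#' column per condition.
#'
#' @param x numeric matrix with gene rownames.
#' @param path output path.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write classification and target-call results
#'
#' One row per gene in the input order of the fit: gene id, the per-group
#' posteriors at 6 significant digits, the assigned group, the assigned
#' posterior rounded to 3 decimals as a convenience column, and — for genes
#' assigned to the target group — fold change, standard error, direction
#' and the selection flag. The column order and sort are fixed, so
#' rewriting the same fit is byte-identical.
#'
#' @param object a `"bgsc"` fit.
#' @param path output path.
#' @param group target group for fold-change/selection columns (default
#'   `"c"` when present).
#' @param posterior_threshold,fc_threshold forwarded to
#'   [select_targets()].
#' @param annotation optional data frame mapping `gene_id` (or `probe_id`)
#'   to `gene_symbol`, joined into the output.
#' @return the path, invisibly.
#' @export
write_results <- function(object, path, group = NULL,
                          posterior_threshold = 0.75, fc_threshold = 0.5,
                          annotation = NULL) {
  stopifnot(inherits(object, "bgsc"))
  labels <- object$patterns$labels
  if (is.null(group))
    group <- if ("c" %in% labels) "c" else labels[length(labels)]
  cls <- data.frame(gene_id = rownames(object$x), stringsAsFactors = FALSE)
  for (lab in labels)
    cls[[paste0("posterior_", lab)]] <-
      signif(unname(object$posterior[, lab]), 6)
  cls$assigned_group <- object$assigned
  jj <- match(object$assigned, labels)
  cls$posterior_assigned_3dp <- sprintf(
    "%.3f", object$posterior[cbind(seq_len(nrow(cls)), jj)])
  cls$degenerate <- object$degenerate
  tg <- select_targets(object, group = group,
                       posterior_threshold = posterior_threshold,
                       fc_threshold = fc_threshold)
  m <- match(cls$gene_id, tg$gene_id)
  cls$log2fc <- ifelse(is.na(m), NA, signif(tg$log2fc[m], 6))
  cls$se <- ifelse(is.na(m), NA, signif(tg$se[m], 6))
  cls$direction <- ifelse(is.na(m), NA, tg$direction[m])
  cls$selected <- ifelse(is.na(m), NA, tg$selected[m])
  if (!is.null(annotation)) {
    key <- if ("gene_id" %in% names(annotation)) "gene_id" else
      if ("probe_id" %in% names(annotation)) "probe_id" else
        stop("annotation needs a gene_id or probe_id column")
    cls$gene_symbol <- annotation$gene_symbol[
      match(cls$gene_id, annotation[[key]])]
  }
  utils::write.table(cls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
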