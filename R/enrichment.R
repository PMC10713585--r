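#' Organ / cell-type annotation table
#'
#' @param table data.frame with columns `gene`, `context`, `kind`
#'   (`"organ"` or `"cell_type"`); (gene, context) pairs must be unique
#'   and every context must carry at least one gene.
#' @param background Character vector of all annotated genes (the
#'   enrichment universe); defaults to the genes present in `table`.
#' @return Object of class `annotation_table`.
#' @export
annotation_table <- function(table, background = NULL) {
  stopifnot(is.data.frame(table),
            all(c("gene", "context", "kind") %in% names(table)))
  if (!all(table$kind %in% c("organ", "cell_type")))
    stop("kind must be 'organ' or 'cell_type'")
  if (anyDuplicated(table[c("gene", "context")]))
    stop("(gene, context) pairs must be unique")
  if (is.null(background)) background <- unique(table$gene)
  if (!all(table$gene %in% background))
    stop("annotated genes missing from background")
  structure(list(table = table, background = unique(background)),
            class = "annotation_table")
}

#' Read / write an annotation table as TSV
#'
#' Columns: `gene<TAB>context<TAB>kind`. The background defaults to the
#' genes present in the file.
#' @param annotation An `annotation_table`.
#' @param path File path.
#' @export
write_annotation_table <- function(annotation, path) {
  utils::write.table(annotation$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_table
#' @export
read_annotation_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  annotation_table(tab)
}

# Pearson chi-square (no continuity correction) on a 2x2 table; zero
# margins give chi2 = 0, p = 1 by convention.
chisq_2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, c, b, d), 2L)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(chi2 = 0, p = 1))
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value))
}

#' Organ / cell-type enrichment of a gene set
#'
#' For every context of the requested kind, builds the 2x2 contingency
#' table of feature membership against context annotation over the
#' background universe, applies Pearson's chi-square test of independence
#' (no continuity correction), adjusts across contexts by
#' Benjamini-Hochberg, and reports `-log10(q)` in descending order.
#'
#' @param genes Character vector of feature genes. Genes outside the
#'   background are dropped with a warning.
#' @param annotation An [annotation_table()].
#' @param kind `"organ"` or `"cell_type"`.
#' @param q_threshold Significance threshold annotated in the output.
#' @return data.frame with columns `context`, `a`, `b`, `c`, `d` (cell
#'   counts: feature&context, feature&!context, !feature&context,
#'   !feature&!context), `odds_ratio`, `chi2`, `p`, `q`, `neg_log10_q`,
#'   `significant`; sorted by descending `neg_log10_q`, ties broken
#'   lexicographically by context.
#' @export
enrich <- function(genes, annotation, kind = c("organ", "cell_type"),
                   q_threshold = 0.05) {
  kind <- match.arg(kind)
  stopifnot(inherits(annotation, "annotation_table"))
  genes <- unique(genes)
  if (!length(genes)) stop("empty gene set")
  outside <- setdiff(genes, annotation$background)
  if (length(outside)) {
    warning(length(outside), " gene(s) outside the annotation background dropped")
    genes <- setdiff(genes, outside)
  }
  if (!length(genes)) stop("no feature gene is in the annotation background")
  tab <- annotation$table[annotation$table$kind == kind, , drop = FALSE]
  contexts <- sort(unique(tab$context))
  bg <- annotation$background
  n_bg <- length(bg)
  n_feat <- length(genes)
  rows <- lapply(contexts, function(ctx) {
    ctx_genes <- tab$gene[tab$context == ctx]
    a <- length(intersect(genes, ctx_genes))
    b <- n_feat - a
    c <- length(ctx_genes) - a
    d <- n_bg - a - b - c
    ts <- chisq_2x2(a, b, c, d)
    or <- (a * d) / (b * c)
    data.frame(context = ctx, a = a, b = b, c = c, d = d,
               odds_ratio = or, chi2 = ts$chi2, p = ts$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$neg_log10_q <- -log10(out$q)
  out$significant <- out$q < q_threshold
  out <- out[order(-out$neg_log10_q, out$context), , drop = FALSE]
  rownames(out) <- NULL
  out
}
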