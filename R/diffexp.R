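#' Quality-control filter for single-cell matrices
#'
#' Keeps cells with at least `min_genes` detected genes and at most
#' `max_pct_mito` percent mitochondrial RNA, the conventional two-filter
#' single-cell QC.
#'
#' @param sim List with `counts` (genes x cells) and `meta` carrying
#'   `n_genes_detected` and `percent_mito`.
#' @param min_genes Minimum detected genes per cell.
#' @param max_pct_mito Maximum mitochondrial percentage (0-100 scale).
#' @return Filtered list with `counts` and `meta`; the number of removed
#'   cells is reported via `message()`.
#' @export
qc_filter_cells <- function(sim, min_genes = 200, max_pct_mito = 20) {
  stopifnot(all(c("n_genes_detected", "percent_mito") %in% names(sim$meta)))
  if (ncol(sim$counts) == 0L) stop("empty matrix")
  keep <- sim$meta$n_genes_detected >= min_genes &
          sim$meta$percent_mito <= max_pct_mito
  if (!any(keep)) stop("QC filter removed all cells")
  message(sum(!keep), " cell(s) removed by QC filter")
  list(counts = sim$counts[, keep, drop = FALSE],
       meta = sim$meta[keep, , drop = FALSE])
}

#' Per-column size factors
#'
#' Bulk mode uses the median-of-ratios to the per-gene geometric-mean
#' pseudo-reference; when no gene is expressed in every sample it falls
#' back to library-size ratios with a warning. Single-cell mode is a
#' pooled estimate: cells are pooled (by `clusters`, or into library-size
#' ordered pools of about 50), pool pseudo-bulks are normalized by
#' median-of-ratios, and each cell scales its pool's factor by its
#' relative library size. Factors are rescaled to geometric mean 1.
#'
#' @param counts Non-negative integer matrix, genes x columns.
#' @param mode `"bulk"` or `"single_cell"`.
#' @param clusters Optional pooling labels for single-cell mode.
#' @return Positive numeric vector, one factor per column, geometric
#'   mean 1.
#' @export
size_factors <- function(counts, mode = c("bulk", "single_cell"),
                         clusters = NULL) {
  mode <- match.arg(mode)
  if (any(colSums(counts) == 0)) stop("all-zero column")
  sf <- if (mode == "bulk") {
    pos <- rowSums(counts > 0) == ncol(counts)
    if (!any(pos)) {
      warning("no all-nonzero gene; falling back to library-size ratios")
      colSums(counts)
    } else {
      logref <- rowMeans(log(counts[pos, , drop = FALSE]))
      apply(counts[pos, , drop = FALSE], 2, function(y)
        exp(stats::median(log(y) - logref)))
    }
  } else {
    lib <- colSums(counts)
    if (is.null(clusters)) {
      npool <- max(2L, min(ceiling(ncol(counts) / 50), 20L))
      clusters <- cut(rank(lib, ties.method = "first"), npool, labels = FALSE)
    }
    clusters <- as.character(clusters)
    pools <- split(seq_len(ncol(counts)), clusters)
    pb <- vapply(pools, function(j) rowSums(counts[, j, drop = FALSE]),
                 numeric(nrow(counts)))
    pf <- if (length(pools) < 2) stats::setNames(1, names(pools)) else {
      pos <- rowSums(pb > 0) == ncol(pb)
      if (!any(pos)) {
        colSums(pb) / mean(colSums(pb))
      } else {
        logref <- rowMeans(log(pb[pos, , drop = FALSE]))
        apply(pb[pos, , drop = FALSE], 2, function(y)
          exp(stats::median(log(y) - logref)))
      }
    }
    # a pool's factor is shared; cells modulate it by relative library size
    out <- numeric(ncol(counts))
    for (p in names(pools)) {
      j <- pools[[p]]
      out[j] <- pf[[p]] * lib[j] / mean(lib[j])
    }
    out
  }
  sf <- sf / exp(mean(log(sf)))
  unname(sf)
}

# Method-of-moments NB dispersion, pooled across the two groups on
# size-factor-normalized counts, floored at 1e-8 (means floored at 1e-6).
mom_dispersion <- function(q, x) {
  ests <- unlist(lapply(split(q, x), function(qq) {
    if (length(qq) < 2) return(NULL)
    m <- max(mean(qq), 1e-6)
    (stats::var(qq) - m) / m^2
  }))
  max(mean(ests), 1e-8)
}

fit_nb_gene <- function(y, x, sf, mode) {
  if (all(y == 0))
    return(list(log2fc = 0, p = NA_real_, base_mean = 0))
  q <- y / sf
  disp <- mom_dispersion(q, x)
  fam <- MASS::negative.binomial(theta = 1 / disp)
  fit <- tryCatch(
    suppressWarnings(stats::glm(y ~ x, family = fam, offset = log(sf),
                                control = stats::glm.control(maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged)
    return(list(log2fc = NA_real_, p = NA_real_, base_mean = mean(q)))
  est <- stats::coef(fit)[["x"]]
  if (mode == "bulk") {
    # fixed-dispersion NB: the GLM scale is 1, not the Pearson estimate
    co <- stats::summary.glm(fit, dispersion = 1)$coefficients
    z <- est / co["x", "Std. Error"]
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    red <- tryCatch(
      suppressWarnings(stats::glm(y ~ 1, family = fam, offset = log(sf),
                                  control = stats::glm.control(maxit = 100))),
      error = function(e) NULL)
    if (is.null(red))
      return(list(log2fc = est / log(2), p = NA_real_, base_mean = mean(q)))
    lrt <- max(red$deviance - fit$deviance, 0)
    tt <- sign(est) * sqrt(lrt)
    p <- 2 * stats::pt(-abs(tt), df = length(y) - 2)
  }
  list(log2fc = est / log(2), p = p, base_mean = mean(q))
}

#' Negative-binomial differential expression test
#'
#' Per gene: NB GLM with log link on size-factor offsets, gene-wise
#' method-of-moments dispersion floored at 1e-8. Bulk mode uses a Wald
#' test on the group coefficient (normal reference); single-cell mode a
#' likelihood-ratio test referred to a t distribution with residual
#' degrees of freedom. P-values are BH-adjusted and genes are flagged as
#' differentially expressed when `|log2fc| >= lfc_threshold` and
#' `padj < alpha`.
#'
#' Groups are canonicalised internally (sorted levels) and the sign
#' flipped to match `contrast`, so swapping the contrast negates every
#' log2 fold change exactly and preserves every p-value.
#'
#' @param counts Non-negative integer matrix, genes x samples (cells).
#' @param groups Length-`ncol(counts)` group labels; exactly two levels,
#'   each with at least two columns.
#' @param mode `"bulk"` (Wald) or `"single_cell"` (LRT / t reference).
#' @param contrast Length-2 character `c(numerator, denominator)`;
#'   default: sorted levels, second vs first.
#' @param lfc_threshold,alpha DEgene definition thresholds
#'   (`|log2fc| >= 1`, `padj < 0.05` by default).
#' @param sf Optional size factors; computed by [size_factors()] when
#'   missing.
#' @return data.frame `gene`, `base_mean`, `log2fc`, `p`, `padj`,
#'   `is_degene`.
#' @export
nb_de_test <- function(counts, groups, mode = c("bulk", "single_cell"),
                       contrast = NULL, lfc_threshold = 1, alpha = 0.05,
                       sf = NULL) {
  mode <- match.arg(mode)
  if (any(counts %% 1 != 0) || any(counts < 0)) stop("non-integer counts")
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(counts))
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("exactly two groups required")
  if (any(table(groups) < 2)) stop("each group needs >= 2 columns")
  if (is.null(contrast)) contrast <- c(lev[2], lev[1])
  stopifnot(setequal(contrast, lev))
  flip <- if (contrast[1] == lev[2]) 1 else -1
  if (is.null(sf)) sf <- size_factors(counts, mode)
  x <- as.numeric(groups == lev[2])
  res <- lapply(seq_len(nrow(counts)), function(i)
    fit_nb_gene(counts[i, ], x, sf, mode))
  out <- data.frame(gene = rownames(counts),
                    base_mean = vapply(res, `[[`, numeric(1), "base_mean"),
                    log2fc = flip * vapply(res, `[[`, numeric(1), "log2fc"),
                    p = vapply(res, `[[`, numeric(1), "p"),
                    stringsAsFactors = FALSE)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out$is_degene <- !is.na(out$padj) & !is.na(out$log2fc) &
    is.finite(out$log2fc) & abs(out$log2fc) >= lfc_threshold & out$padj < alpha
  rownames(out) <- NULL
  out
}

#' Per-cell-type expression summaries
#'
#' For each (gene, cell type): the fraction of cells with a nonzero
#' count and the mean over cells of `log(1 + count per 10,000)` (natural
#' log of counts scaled to 10,000 per cell).
#'
#' @param sim List with `counts` and `meta` (needs `cell_type`;
#'   `organ` is propagated when present).
#' @return data.frame `gene`, `cell_type`, `organ` (if available),
#'   `frac_expressing`, `mean_log_cp10k`.
#' @export
summarize_expression <- function(sim) {
  stopifnot("cell_type" %in% names(sim$meta))
  counts <- sim$counts
  tot <- colSums(counts)
  tot[tot == 0] <- 1
  lcp <- log1p(sweep(counts, 2, 1e4 / tot, `*`))
  ct <- sim$meta$cell_type
  cts <- sort(unique(ct))
  rows <- lapply(cts, function(cc) {
    j <- ct == cc
    data.frame(gene = rownames(counts), cell_type = cc,
               frac_expressing = rowMeans(counts[, j, drop = FALSE] > 0),
               mean_log_cp10k = rowMeans(lcp[, j, drop = FALSE]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if ("organ" %in% names(sim$meta)) {
    org <- unique(sim$meta$organ)
    out$organ <- if (length(org) == 1L) org else
      sim$meta$organ[match(out$cell_type, sim$meta$cell_type)]
    out <- out[, c("gene", "cell_type", "organ", "frac_expressing",
                   "mean_log_cp10k")]
  }
  rownames(out) <- NULL
  out
}

#' Per-cell-type differential expression between two conditions
#'
#' Runs [nb_de_test()] in single-cell mode within each cell type shared
#' by the two matrices; cell types with fewer than two cells in either
#' condition are skipped with a warning.
#'
#' @param cond_sim,ref_sim Lists with `counts` and `meta` (needs
#'   `cell_type` and `condition`) for the condition of interest (e.g.
#'   IPF) and the reference (e.g. healthy donors).
#' @param ... Passed to [nb_de_test()] (e.g. `lfc_threshold`, `alpha`).
#' @return Named list (by cell type) of [nb_de_test()] result
#'   data.frames; log2 fold changes are condition vs reference.
#' @export
per_celltype_de <- function(cond_sim, ref_sim, ...) {
  shared_ct <- intersect(unique(cond_sim$meta$cell_type),
                         unique(ref_sim$meta$cell_type))
  only <- setdiff(union(cond_sim$meta$cell_type, ref_sim$meta$cell_type),
                  shared_ct)
  for (cc in only) warning("cell type present in one condition only, skipped: ", cc)
  if (!length(shared_ct)) stop("no shared cell types")
  genes <- intersect(rownames(cond_sim$counts), rownames(ref_sim$counts))
  cond_lab <- unique(cond_sim$meta$condition)[1]
  ref_lab <- unique(ref_sim$meta$condition)[1]
  if (identical(cond_lab, ref_lab)) ref_lab <- paste0(ref_lab, ".ref")
  out <- list()
  for (cc in sort(shared_ct)) {
    m1 <- cond_sim$counts[genes, cond_sim$meta$cell_type == cc, drop = FALSE]
    m0 <- ref_sim$counts[genes, ref_sim$meta$cell_type == cc, drop = FALSE]
    mat <- cbind(m0, m1)
    nonzero <- colSums(mat) > 0
    mat <- mat[, nonzero, drop = FALSE]
    grp <- c(rep(ref_lab, ncol(m0)), rep(cond_lab, ncol(m1)))[nonzero]
    if (sum(grp == cond_lab) < 2 || sum(grp == ref_lab) < 2) {
      warning("fewer than 2 usable cells per condition, skipped: ", cc)
      next
    }
    out[[cc]] <- nb_de_test(mat, grp, mode = "single_cell",
                            contrast = c(cond_lab, ref_lab), ...)
  }
  if (!length(out)) stop("no cell type had enough cells in both conditions")
  out
}
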