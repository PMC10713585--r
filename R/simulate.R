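#' Specification for a planted-structure disease-omics corpus
#'
#' Describes the generative ground truth used to emulate a multi-disease,
#' three-modality gene-set corpus: a fixed number of latent topics, each
#' owning a per-modality gene pool (disjoint by default), and diseases whose
#' gene sets are drawn from their active topics' pools plus uniform noise.
#'
#' @param n_diseases Number of diseases.
#' @param n_genes_per_modality Vocabulary size per modality (scalar or a
#'   named length-3 vector over `Ae`, `Bm`, `Gv`).
#' @param n_topics_true Number of planted topics.
#' @param genes_per_disease Mean gene-set size per modality (Poisson mean,
#'   floored at 1).
#' @param noise_rate Fraction in `[0,1]` of genes drawn uniformly from the
#'   whole vocabulary instead of from the disease's topic pools.
#' @param topic_overlap Number of genes each topic pool shares with the
#'   next pool (0 = fully disjoint pools).
#' @param mixture_prob Probability that a disease is driven by two topics
#'   rather than one.
#' @param seed Integer seed.
#' @return Object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_diseases = 240, n_genes_per_modality = 300,
                        n_topics_true = 6, genes_per_disease = 30,
                        noise_rate = 0.1, topic_overlap = 0,
                        mixture_prob = 0.3, seed = 1) {
  if (length(n_genes_per_modality) == 1L)
    n_genes_per_modality <- stats::setNames(rep(n_genes_per_modality, 3), MODALITIES)
  stopifnot(setequal(names(n_genes_per_modality), MODALITIES))
  n_genes_per_modality <- n_genes_per_modality[MODALITIES]
  if (noise_rate < 0 || noise_rate > 1) stop("noise_rate must be in [0,1]")
  if (n_diseases < 1 || n_topics_true < 1 || any(n_genes_per_modality < 1) ||
      genes_per_disease < 1)
    stop("all counts must be >= 1")
  if (any(n_topics_true > n_genes_per_modality))
    stop("topic count exceeds the distinguishable gene pool of a modality")
  structure(list(n_diseases = as.integer(n_diseases),
                 n_genes_per_modality = stats::setNames(
                   as.integer(n_genes_per_modality), MODALITIES),
                 n_topics_true = as.integer(n_topics_true),
                 genes_per_disease = genes_per_disease,
                 noise_rate = noise_rate, topic_overlap = as.integer(topic_overlap),
                 mixture_prob = mixture_prob, seed = as.integer(seed)),
            class = "corpus_spec")
}

topic_pools <- function(spec) {
  K <- spec$n_topics_true
  lapply(stats::setNames(MODALITIES, MODALITIES), function(m) {
    V <- spec$n_genes_per_modality[[m]]
    vocab <- sprintf("%s_g%04d", m, seq_len(V))
    cut_idx <- split(seq_len(V), cut(seq_len(V), K, labels = FALSE))
    lapply(seq_len(K), function(k) {
      idx <- cut_idx[[k]]
      if (spec$topic_overlap > 0) {
        nxt <- cut_idx[[if (k == K) 1L else k + 1L]]
        idx <- c(idx, utils::head(nxt, spec$topic_overlap))
      }
      vocab[idx]
    })
  })
}

#' Simulate a disease-omics corpus with planted topic structure
#'
#' Each disease activates one or two topics; every gene token is drawn
#' from an active topic's modality pool, or (with probability
#' `noise_rate`) uniformly from the modality vocabulary. The returned
#' `truth` records which topics generated each disease, so downstream
#' recovery tests have an oracle.
#'
#' @param spec A [corpus_spec()].
#' @return List with elements `corpus` (a `disease_corpus`), `truth`
#'   (data.frame: `disease_id`, `primary_topic`, list-columns `topics`,
#'   `weights`), and `pools` (per-modality list of per-topic gene pools).
#' @export
simulate_disease_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$seed)
  K <- spec$n_topics_true
  pools <- topic_pools(spec)
  vocab <- lapply(stats::setNames(MODALITIES, MODALITIES), function(m)
    sprintf("%s_g%04d", m, seq_len(spec$n_genes_per_modality[[m]])))

  records <- vector("list", spec$n_diseases)
  topics_l <- vector("list", spec$n_diseases)
  weights_l <- vector("list", spec$n_diseases)
  for (i in seq_len(spec$n_diseases)) {
    n_active <- 1L + stats::rbinom(1L, 1L, spec$mixture_prob)
    tk <- sample.int(K, n_active)
    w <- stats::rgamma(n_active, 1); w <- w / sum(w)
    mg <- lapply(stats::setNames(MODALITIES, MODALITIES), function(m) {
      size <- max(1L, stats::rpois(1L, spec$genes_per_disease))
      is_noise <- stats::runif(size) < spec$noise_rate
      g <- character(size)
      n_noise <- sum(is_noise)
      if (n_noise) g[is_noise] <- sample(vocab[[m]], n_noise, replace = TRUE)
      if (size - n_noise) {
        zz <- tk[sample.int(n_active, size - n_noise, replace = TRUE, prob = w)]
        g[!is_noise] <- vapply(zz, function(k)
          sample(pools[[m]][[k]], 1L), character(1))
      }
      unique(g)
    })
    records[[i]] <- disease_record(sprintf("D%04d", i),
                                   sprintf("Synthetic disease %04d", i), mg)
    topics_l[[i]] <- tk
    weights_l[[i]] <- w
  }
  truth <- data.frame(disease_id = sprintf("D%04d", seq_len(spec$n_diseases)),
                      primary_topic = vapply(seq_len(spec$n_diseases), function(i)
                        topics_l[[i]][which.max(weights_l[[i]])], integer(1)),
                      stringsAsFactors = FALSE)
  truth$topics <- topics_l
  truth$weights <- weights_l
  list(corpus = disease_corpus(records), truth = truth, pools = pools,
       spec = spec)
}

#' Destroy cross-modality structure by permuting modality assignments
#'
#' Independently permutes, within each modality, which disease each gene
#' set belongs to. Marginal per-modality statistics are preserved while
#' the association between a disease's modalities is destroyed; imputation
#' on such a corpus is a null baseline (AUC about 0.5).
#'
#' @param corpus A `disease_corpus` where every disease has all modalities.
#' @param seed Integer seed.
#' @return A permuted `disease_corpus`.
#' @export
permute_corpus_modalities <- function(corpus, seed = 1) {
  set.seed(seed)
  n <- length(corpus)
  perms <- lapply(MODALITIES, function(m) sample.int(n))
  names(perms) <- MODALITIES
  recs <- lapply(seq_len(n), function(i) {
    mg <- lapply(stats::setNames(MODALITIES, MODALITIES), function(m)
      corpus[[perms[[m]][i]]]$modality_genes[[m]])
    mg <- mg[!vapply(mg, is.null, logical(1))]
    disease_record(corpus[[i]]$disease_id, corpus[[i]]$name, mg)
  })
  disease_corpus(recs)
}

#' Specification for simulated bulk RNA-seq counts
#'
#' Negative-binomial counts for two groups with planted log2 fold changes.
#' Defaults emulate the IPF-cohort contrast (95 IPF vs 204 non-IPF lung
#' disease subjects).
#'
#' @param n_genes Number of genes (ignored when `gene_names` given).
#' @param n_per_group Named length-2 integer vector of samples per group;
#'   planted `log2fc` applies to the second group relative to the first.
#' @param planted_de data.frame with columns `gene`, `log2fc` (may be empty).
#' @param base_mean Per-gene base mean (scalar, vector, or `NULL` for
#'   log-normal draws around 50).
#' @param dispersion Per-gene NB dispersion (scalar or vector), > 0.
#' @param gene_names Optional explicit gene symbols.
#' @param seed Integer seed.
#' @return Object of class `bulk_sim_spec`.
#' @export
bulk_sim_spec <- function(n_genes = 2000,
                          n_per_group = c(nonIPF = 204, IPF = 95),
                          planted_de = NULL, base_mean = NULL,
                          dispersion = 0.1, gene_names = NULL, seed = 1) {
  if (!is.null(gene_names)) n_genes <- length(gene_names)
  stopifnot(length(n_per_group) == 2L, all(n_per_group >= 1),
            !is.null(names(n_per_group)))
  if (any(dispersion <= 0)) stop("dispersions must be > 0")
  if (!is.null(base_mean) && any(base_mean <= 0)) stop("base means must be > 0")
  if (is.null(planted_de))
    planted_de <- data.frame(gene = character(0), log2fc = numeric(0))
  structure(list(n_genes = as.integer(n_genes), n_per_group = n_per_group,
                 planted_de = planted_de, base_mean = base_mean,
                 dispersion = dispersion, gene_names = gene_names,
                 seed = as.integer(seed)),
            class = "bulk_sim_spec")
}

#' Specification for simulated single-cell RNA-seq counts
#'
#' One NB draw per gene and cell; cell-type-specific means are set via
#' `celltype_means`, and condition effects (e.g. an IPF lung) via
#' `planted_de`, optionally restricted to one cell type. The default base
#' mean is low so that unlisted genes are detected in only a small
#' fraction of cells, emulating single-cell sparsity.
#'
#' @param genes Character vector of gene symbols.
#' @param n_cells_per_type Named integer vector: cells per cell type.
#' @param organ Organ label attached to every cell.
#' @param condition Condition label (e.g. `"healthy"`, `"IPF"`).
#' @param base_mean Default per-gene per-cell mean count.
#' @param dispersion NB dispersion (> 0).
#' @param celltype_means Optional data.frame `gene`, `cell_type`, `mean`
#'   overriding the base mean for specific (gene, cell type) pairs.
#' @param planted_de Optional data.frame `gene`, `log2fc`, `cell_type`
#'   (NA cell_type = all cell types): multiplies the mean by `2^log2fc`.
#' @param n_high_mito Number of cells planted with high mitochondrial
#'   percentage (for QC-filter tests); they are the first cells of the
#'   first cell type.
#' @param seed Integer seed.
#' @return Object of class `sc_sim_spec`.
#' @export
sc_sim_spec <- function(genes, n_cells_per_type, organ = "organ",
                        condition = "healthy", base_mean = 0.02,
                        dispersion = 0.5, celltype_means = NULL,
                        planted_de = NULL, n_high_mito = 0L, seed = 1) {
  stopifnot(is.character(genes), length(genes) > 0,
            !is.null(names(n_cells_per_type)), all(n_cells_per_type >= 1))
  if (base_mean <= 0) stop("base means must be > 0")
  if (dispersion <= 0) stop("dispersions must be > 0")
  structure(list(genes = genes, n_cells_per_type = n_cells_per_type,
                 organ = organ, condition = condition, base_mean = base_mean,
                 dispersion = dispersion, celltype_means = celltype_means,
                 planted_de = planted_de, n_high_mito = as.integer(n_high_mito),
                 seed = as.integer(seed)),
            class = "sc_sim_spec")
}

#' Simulate an RNA-seq count matrix
#'
#' Counts are drawn `NB(mean * sizefactor * 2^(log2fc * group), dispersion)`.
#' Bulk mode returns a genes-by-samples matrix with a `group` column in the
#' metadata; single-cell mode a genes-by-cells matrix with `cell_type`,
#' `organ`, `condition`, `percent_mito` and `n_genes_detected` columns.
#'
#' @param spec A [bulk_sim_spec()] or [sc_sim_spec()].
#' @param mode `"bulk"` or `"single_cell"` (inferred from the spec class
#'   when missing).
#' @return List with `counts` (integer matrix, genes x columns) and
#'   `meta` (data.frame keyed 1:1 to columns).
#' @export
simulate_counts <- function(spec, mode = c("bulk", "single_cell")) {
  if (missing(mode))
    mode <- if (inherits(spec, "sc_sim_spec")) "single_cell" else "bulk"
  mode <- match.arg(mode)
  if (mode == "bulk") simulate_counts_bulk(spec) else simulate_counts_sc(spec)
}

simulate_counts_bulk <- function(spec) {
  stopifnot(inherits(spec, "bulk_sim_spec"))
  set.seed(spec$seed)
  G <- spec$n_genes
  genes <- if (!is.null(spec$gene_names)) spec$gene_names
           else sprintf("gene%05d", seq_len(G))
  mu0 <- if (is.null(spec$base_mean)) stats::rlnorm(G, log(50), 1)
         else rep_len(spec$base_mean, G)
  disp <- rep_len(spec$dispersion, G)
  lfc <- stats::setNames(rep(0, G), genes)
  if (nrow(spec$planted_de)) {
    keep <- spec$planted_de$gene %in% genes
    lfc[spec$planted_de$gene[keep]] <- spec$planted_de$log2fc[keep]
  }
  grp_names <- names(spec$n_per_group)
  group <- rep(grp_names, times = spec$n_per_group)
  n <- length(group)
  sf <- 2^stats::rnorm(n, 0, 0.2)
  is_trt <- as.numeric(group == grp_names[2])
  counts <- matrix(0L, G, n, dimnames = list(genes,
                   sprintf("s%03d_%s", seq_len(n), group)))
  for (j in seq_len(n)) {
    mu <- mu0 * sf[j] * 2^(lfc * is_trt[j])
    counts[, j] <- stats::rnbinom(G, mu = mu, size = 1 / disp)
  }
  meta <- data.frame(sample = colnames(counts), group = group,
                     stringsAsFactors = FALSE)
  list(counts = counts, meta = meta)
}

simulate_counts_sc <- function(spec) {
  stopifnot(inherits(spec, "sc_sim_spec"))
  set.seed(spec$seed)
  genes <- spec$genes
  G <- length(genes)
  cts <- names(spec$n_cells_per_type)
  cell_type <- rep(cts, times = spec$n_cells_per_type)
  n <- length(cell_type)
  # per-cell-type mean profile
  mu_ct <- matrix(spec$base_mean, G, length(cts),
                  dimnames = list(genes, cts))
  if (!is.null(spec$celltype_means)) {
    cm <- spec$celltype_means
    keep <- cm$gene %in% genes & cm$cell_type %in% cts
    cm <- cm[keep, , drop = FALSE]
    mu_ct[cbind(match(cm$gene, genes), match(cm$cell_type, cts))] <- cm$mean
  }
  if (!is.null(spec$planted_de) && nrow(spec$planted_de)) {
    de <- spec$planted_de
    for (i in seq_len(nrow(de))) {
      g <- match(de$gene[i], genes)
      if (is.na(g)) next
      tgt <- if (is.null(de$cell_type) || is.na(de$cell_type[i])) cts
             else de$cell_type[i]
      mu_ct[g, tgt] <- mu_ct[g, tgt] * 2^de$log2fc[i]
    }
  }
  sf <- 2^stats::rnorm(n, 0, 0.3)
  counts <- matrix(0L, G, n, dimnames = list(genes,
                   sprintf("%s_c%04d_%s", spec$condition, seq_len(n), cell_type)))
  for (j in seq_len(n)) {
    counts[, j] <- stats::rnbinom(G, mu = mu_ct[, cell_type[j]] * sf[j],
                                  size = 1 / spec$dispersion)
  }
  percent_mito <- stats::runif(n, 0.5, 10)
  if (spec$n_high_mito > 0) {
    idx <- seq_len(min(spec$n_high_mito, n))
    percent_mito[idx] <- stats::runif(length(idx), 30, 80)
  }
  meta <- data.frame(cell = colnames(counts), cell_type = cell_type,
                     organ = spec$organ, condition = spec$condition,
                     percent_mito = percent_mito,
                     n_genes_detected = colSums(counts > 0),
                     stringsAsFactors = FALSE)
  list(counts = counts, meta = meta)
}

#' Write / read a count matrix as Matrix Market plus TSV metadata
#'
#' Writes `<prefix>.mtx` (sparse Matrix Market), `<prefix>_genes.tsv`
#' (row names) and `<prefix>_meta.tsv` (column metadata).
#'
#' @param sim List with `counts` and `meta` as from [simulate_counts()].
#' @param prefix Output path prefix.
#' @return `write_counts_mm` invisibly returns the three paths;
#'   `read_counts_mm` returns a list with `counts` and `meta`.
#' @export
write_counts_mm <- function(sim, prefix) {
  paths <- c(mtx = paste0(prefix, ".mtx"),
             genes = paste0(prefix, "_genes.tsv"),
             meta = paste0(prefix, "_meta.tsv"))
  Matrix::writeMM(methods::as(Matrix::Matrix(sim$counts, sparse = TRUE),
                              "generalMatrix"), paths["mtx"])
  writeLines(rownames(sim$counts), paths["genes"])
  utils::write.table(sim$meta, paths["meta"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' @rdname write_counts_mm
#' @export
read_counts_mm <- function(prefix) {
  counts <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  storage.mode(counts) <- "integer"
  genes <- readLines(paste0(prefix, "_genes.tsv"))
  meta <- utils::read.table(paste0(prefix, "_meta.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  rownames(counts) <- genes
  colnames(counts) <- meta[[1]]
  list(counts = counts, meta = meta)
}

#' Simulate an organ / cell-type gene annotation table
#'
#' Emulates a protein-atlas-style annotation: every context (organ or cell
#' type) receives background genes at a base rate, and one designated
#' context is enriched for a given gene set by a fold factor (default 5x),
#' planting the over-representation that the enrichment stage must recover.
#'
#' @param feature_genes Genes to over-represent in the enriched contexts.
#' @param organs,cell_types Context names; the first of each is enriched.
#' @param n_background Number of background filler genes.
#' @param base_rate Probability a background gene is annotated to a context.
#' @param enrichment_fold Fold increase of the annotation rate of
#'   `feature_genes` in the first organ and first cell type.
#' @param seed Integer seed.
#' @return An `annotation_table` (see [annotation_table()]).
#' @export
simulate_annotation <- function(feature_genes,
                                organs = c("liver", "lung", "kidney", "brain",
                                           "heart", "bone marrow", "thyroid gland",
                                           "adipose tissue"),
                                cell_types = c("hepatocytes", "macrophages",
                                               "fibroblasts", "t-cells",
                                               "endothelial cells", "kupffer cells"),
                                n_background = 1500, base_rate = 0.08,
                                enrichment_fold = 5, seed = 1) {
  set.seed(seed)
  background <- unique(c(feature_genes, sprintf("BGGENE%04d", seq_len(n_background))))
  draw <- function(contexts, kind) {
    do.call(rbind, lapply(seq_along(contexts), function(ci) {
      rate <- rep(base_rate, length(background))
      if (ci == 1L)
        rate[background %in% feature_genes] <- min(1, base_rate * enrichment_fold)
      keep <- stats::runif(length(background)) < rate
      if (!any(keep)) keep[1] <- TRUE
      data.frame(gene = background[keep], context = contexts[ci], kind = kind,
                 stringsAsFactors = FALSE)
    }))
  }
  annotation_table(rbind(draw(organs, "organ"), draw(cell_types, "cell_type")),
                   background)
}
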