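#' Pipeline configuration
#'
#' Names every input of the end-to-end run, or requests synthetic
#' generation of all of them under `out_dir/inputs`. Thresholds default
#' to the published analysis choices (`lfc_threshold = 1`,
#' `alpha = 0.05`, `q_threshold = 0.05`).
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; every stage seed derives from it.
#' @param synthetic When `TRUE`, all inputs are generated with planted
#'   structure before the stages run.
#' @param inputs Named list of input paths (required when
#'   `synthetic = FALSE`): `corpus`, `annotation`, `bulk_prefix`,
#'   `sc_liver_prefix`, `sc_lung_prefix`, `sc_lung_ipf_prefix`,
#'   `sc_lung_donor_prefix`, `lr_table`, `kgml_dir`, `symbol_map`,
#'   `latent_features`.
#' @param params Named list of overrides; see Details.
#' @details Tunable parameters (with defaults): `topics` (list: `K = 5`,
#'   `n_diseases = 120`, `noise_rate = 0.1`, `n_eval = 10`,
#'   `n_iter = 300`, `burn_in = 150`), `top_fraction = 0.05`,
#'   `exclusion_patterns`, `lfc_threshold = 1`, `alpha = 0.05`,
#'   `q_threshold = 0.05`, `min_frac = 0.1`, `qc` (list:
#'   `min_genes = 10`, `max_pct_mito = 20`), `primary_organ = "lung"`,
#'   `partner_organ = "liver"`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, synthetic = TRUE,
                            inputs = NULL, params = list()) {
  defaults <- list(
    topics = list(K = 5, n_diseases = 120, noise_rate = 0.1,
                  genes_per_disease = 25, n_genes_per_modality = 250,
                  n_eval = 10, n_iter = 300, burn_in = 150),
    top_fraction = 0.05,
    exclusion_patterns = DEFAULT_EXCLUSION_PATTERNS,
    lfc_threshold = 1, alpha = 0.05, q_threshold = 0.05, min_frac = 0.1,
    qc = list(min_genes = 10, max_pct_mito = 20),
    primary_organ = "lung", partner_organ = "liver")
  for (nm in names(params)) {
    if (is.list(defaults[[nm]]) && is.list(params[[nm]]))
      defaults[[nm]][names(params[[nm]])] <- params[[nm]]
    else defaults[[nm]] <- params[[nm]]
  }
  if (!synthetic && is.null(inputs)) stop("inputs required when synthetic = FALSE")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 synthetic = synthetic, inputs = inputs, params = defaults),
            class = "pipeline_config")
}

with_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

sc_gene_universe <- function(fixtures) {
  db_genes <- sort(unique(unlist(split_subunits(
    c(fixtures$lr_db$ligand, fixtures$lr_db$receptor)))))
  unique(c(db_genes, fixtures$latent_features, sprintf("HKG%02d", 1:20)))
}

hk_means <- function(cell_types, mean = 5) {
  expand.grid(gene = sprintf("HKG%02d", 1:20), cell_type = cell_types,
              stringsAsFactors = FALSE) |> cbind(mean = mean)
}

liver_celltype_means <- function() {
  cts <- c("hepatocyte", "endothelial", "cholangiocyte", "t_cell", "kupffer_cell")
  rbind(
    data.frame(gene = "KNG1",
               cell_type = c("hepatocyte", "endothelial", "cholangiocyte", "t_cell"),
               mean = c(20, 1.5, 1.2, 0.8)),
    expand.grid(gene = c("IL6R", "IL6ST"),
                cell_type = c("endothelial", "cholangiocyte", "hepatocyte"),
                stringsAsFactors = FALSE) |> cbind(mean = 5),
    data.frame(gene = "PCK1",
               cell_type = c("hepatocyte", "endothelial", "cholangiocyte", "t_cell"),
               mean = c(20, 2, 1.5, 1)),
    hk_means(cts))
}

lung_celltype_means <- function() {
  cts <- c("macrophage", "fibroblast", "AT1", "AT2", "endothelial", "dendritic")
  rbind(
    expand.grid(gene = "BDKRB1", cell_type = cts,
                stringsAsFactors = FALSE) |> cbind(mean = 1),
    data.frame(gene = "IL6",
               cell_type = c("fibroblast", "endothelial", "macrophage", "dendritic"),
               mean = c(5, 4, 1, 1)),
    expand.grid(gene = c("CALM1", "CALM2", "CALM3"), cell_type = cts,
                stringsAsFactors = FALSE) |> cbind(mean = 5),
    hk_means(cts))
}

lung_ipf_planted_de <- function() {
  rbind(
    data.frame(gene = "BDKRB1", log2fc = 10, cell_type = "macrophage"),
    data.frame(gene = c("CALM1", "CALM2", "CALM3"), log2fc = 1.5,
               cell_type = "macrophage"),
    data.frame(gene = "IL6", log2fc = -1.2,
               cell_type = c("endothelial", "dendritic")))
}

# generate all six pipeline inputs with planted structure
make_synthetic_inputs <- function(out_dir, seed, params) {
  in_dir <- file.path(out_dir, "inputs")
  fixtures <- build_table_fixtures(in_dir)
  tp <- params$topics

  sim <- simulate_disease_corpus(corpus_spec(
    n_diseases = tp$n_diseases, n_topics_true = tp$K,
    noise_rate = tp$noise_rate, genes_per_disease = tp$genes_per_disease,
    n_genes_per_modality = tp$n_genes_per_modality, seed = seed + 11L))
  corpus <- sim$corpus
  # give a handful of diseases respiratory names so name exclusion bites
  resp <- c("Pulmonary disorder", "Lung syndrome", "Fibrosis condition",
            "Respiratory ailment", "Chest disease", "Pneumonitis-like illness")
  for (i in seq_along(resp)) corpus[[i]]$name <- resp[i]
  write_disease_corpus(corpus, file.path(in_dir, "corpus.gmt"))

  ann <- simulate_annotation(fixtures$latent_features, seed = seed + 12L)
  write_annotation_table(ann, file.path(in_dir, "annotation.tsv"))

  genes_bulk <- unique(c(fixtures$degenes, fixtures$latent_features,
                         sc_gene_universe(fixtures),
                         sprintf("BULKF%03d", 1:450)))
  planted <- data.frame(gene = fixtures$degenes,
                        log2fc = rep(c(2, -2), length.out = length(fixtures$degenes)))
  bulk <- simulate_counts(bulk_sim_spec(gene_names = genes_bulk,
                                        planted_de = planted, seed = seed + 13L))
  write_counts_mm(bulk, file.path(in_dir, "bulk"))

  sc_genes <- sc_gene_universe(fixtures)
  liver <- simulate_counts(sc_sim_spec(
    sc_genes, c(hepatocyte = 120, endothelial = 80, cholangiocyte = 60,
                t_cell = 60, kupffer_cell = 40),
    organ = "liver", condition = "healthy",
    celltype_means = liver_celltype_means(), n_high_mito = 10,
    seed = seed + 14L))
  write_counts_mm(liver, file.path(in_dir, "sc_liver"))

  lung_cts <- c(macrophage = 100, fibroblast = 80, AT1 = 60, AT2 = 80,
                endothelial = 60, dendritic = 40)
  lung <- simulate_counts(sc_sim_spec(
    sc_genes, lung_cts, organ = "lung", condition = "healthy",
    celltype_means = lung_celltype_means(), seed = seed + 15L))
  write_counts_mm(lung, file.path(in_dir, "sc_lung"))

  donor <- simulate_counts(sc_sim_spec(
    sc_genes, lung_cts, organ = "lung", condition = "donor",
    celltype_means = lung_celltype_means(), seed = seed + 16L))
  write_counts_mm(donor, file.path(in_dir, "sc_lung_donor"))

  ipf <- simulate_counts(sc_sim_spec(
    sc_genes, lung_cts, organ = "lung", condition = "IPF",
    celltype_means = lung_celltype_means(),
    planted_de = lung_ipf_planted_de(), seed = seed + 17L))
  write_counts_mm(ipf, file.path(in_dir, "sc_lung_ipf"))

  list(corpus = file.path(in_dir, "corpus.gmt"),
       annotation = file.path(in_dir, "annotation.tsv"),
       bulk_prefix = file.path(in_dir, "bulk"),
       sc_liver_prefix = file.path(in_dir, "sc_liver"),
       sc_lung_prefix = file.path(in_dir, "sc_lung"),
       sc_lung_ipf_prefix = file.path(in_dir, "sc_lung_ipf"),
       sc_lung_donor_prefix = file.path(in_dir, "sc_lung_donor"),
       lr_table = file.path(in_dir, "lr_pairs.tsv"),
       kgml_dir = file.path(in_dir, "kgml"),
       symbol_map = file.path(in_dir, "symbol_map.tsv"),
       latent_features = file.path(in_dir, "latent_features.txt"))
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the end-to-end mechanism-map pipeline
#'
#' Executes topics -> enrichment -> differential expression -> bridging
#' -> pathway mining -> map assembly, writing every intermediate table
#' and the final map (GraphML + JSON) under `config$out_dir`, plus a
#' `manifest.json` recording the package version, seed, parameters and
#' MD5 checksums of every artifact. A failing stage aborts with the
#' stage name; artifacts written before the failure are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `map`, `manifest`, `artifacts`
#'   (paths), `degenes`, `bridges`, `hits`, and `auc`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$params
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  inputs <- if (config$synthetic) {
    with_stage("simulate", make_synthetic_inputs(out_dir, seed, p))
  } else config$inputs

  ## topics: imputation AUC plus a worked latent-feature extraction on
  ## the synthetic corpus world
  tp <- p$topics
  topics_out <- with_stage("topics", {
    corpus <- read_disease_corpus(inputs$corpus)
    auc_res <- evaluate_auc(corpus, K = tp$K, n_eval = tp$n_eval,
                            n_iter = tp$n_iter, burn_in = tp$burn_in,
                            seed = seed + 21L)
    eligible <- names(corpus)[vapply(corpus, function(r)
      all(lengths(r$modality_genes[MODALITIES]) > 0), logical(1))]
    qid <- eligible[length(eligible)]
    query_full <- corpus[[qid]]
    train <- disease_corpus(unname(corpus[setdiff(names(corpus), qid)]))
    fit <- fit_topic_model(train, K = tp$K, n_iter = tp$n_iter,
                           burn_in = tp$burn_in, seed = seed + 22L)
    qry <- disease_record(query_full$disease_id, query_full$name,
                          query_full$modality_genes[c("Bm", "Gv")])
    gen <- impute_modality(fit, qry, "Ae", corpus = train, seed = seed + 23L)
    latent <- extract_latent_features(gen, query_full, train,
                                      exclusion_patterns = p$exclusion_patterns,
                                      top_fraction = p$top_fraction)
    rel <- disease_relatedness(latent, train)
    dir.create(file.path(out_dir, "topics"), showWarnings = FALSE)
    write_tsv(data.frame(modality = names(auc_res$auc), auc = auc_res$auc),
              file.path(out_dir, "topics", "imputation_auc.tsv"))
    write_tsv(utils::head(gen[c("gene", "modality", "score")], 200),
              file.path(out_dir, "topics", "generated_features.tsv"))
    write_tsv(latent$features[c("gene", "modality", "score")],
              file.path(out_dir, "topics", "latent_features.tsv"))
    write_tsv(rel, file.path(out_dir, "topics", "disease_relatedness.tsv"))
    list(auc = auc_res$auc, latent = latent)
  })

  ## enrichment of the (fixture-world) latent features
  with_stage("enrich", {
    features <- readLines(inputs$latent_features)
    ann <- read_annotation_table(inputs$annotation)
    dir.create(file.path(out_dir, "enrichment"), showWarnings = FALSE)
    for (kind in c("organ", "cell_type"))
      write_tsv(enrich(features, ann, kind, q_threshold = p$q_threshold),
                file.path(out_dir, "enrichment", paste0(kind, ".tsv")))
  })

  ## bulk differential expression: IPF vs non-IPF
  degenes <- with_stage("de", {
    bulk <- read_counts_mm(inputs$bulk_prefix)
    res <- nb_de_test(bulk$counts, bulk$meta$group, mode = "bulk",
                      contrast = c("IPF", "nonIPF"),
                      lfc_threshold = p$lfc_threshold, alpha = p$alpha)
    dir.create(file.path(out_dir, "de"), showWarnings = FALSE)
    write_tsv(res, file.path(out_dir, "de", "bulk_de.tsv"))
    dg <- res$gene[res$is_degene]
    writeLines(dg, file.path(out_dir, "de", "degenes.txt"))
    dg
  })

  ## ligand-receptor bridging and cross-organ filtering
  bridge_out <- with_stage("bridge", {
    if (!file.exists(inputs$lr_table))
      stop("ligand-receptor table not found: ", inputs$lr_table)
    db <- read_lr_table(inputs$lr_table)
    lig <- identify_ligands(degenes, db)
    rec <- identify_receptors(degenes, db)
    liver <- read_counts_mm(inputs$sc_liver_prefix)
    liver <- qc_filter_cells(liver, p$qc$min_genes, p$qc$max_pct_mito)
    liver_summ <- summarize_expression(liver)
    cross_lig <- cross_organ_candidates(lig, liver_summ, p$partner_organ,
                                        min_frac = p$min_frac)
    cross_rec <- cross_organ_candidates(rec, liver_summ, p$partner_organ,
                                        min_frac = p$min_frac)
    dir.create(file.path(out_dir, "bridge"), showWarnings = FALSE)
    write_tsv(lig$pairs, file.path(out_dir, "bridge", "degene_ligand_pairs.tsv"))
    write_tsv(rec$pairs, file.path(out_dir, "bridge", "degene_receptor_pairs.tsv"))
    write_tsv(cross_lig$pairs, file.path(out_dir, "bridge", "cross_organ_ligand_pairs.tsv"))
    write_tsv(cross_rec$pairs, file.path(out_dir, "bridge", "cross_organ_receptor_pairs.tsv"))
    list(lig = lig, rec = rec, cross_lig = cross_lig, cross_rec = cross_rec,
         liver_summ = liver_summ)
  })

  ## KGML pathway mining
  hits <- with_stage("mine", {
    smap <- utils::read.table(inputs$symbol_map, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    files <- sort(list.files(inputs$kgml_dir, pattern = "[.]xml$",
                             full.names = TRUE))
    if (!length(files)) stop("no KGML files in ", inputs$kgml_dir)
    graphs <- lapply(files, parse_kgml, symbol_map = smap)
    features <- readLines(inputs$latent_features)
    hits_lig <- find_targets(graphs, bridge_out$lig$pairs, features)
    hits_rec <- find_targets(graphs, bridge_out$rec$pairs, features)
    dir.create(file.path(out_dir, "mine"), showWarnings = FALSE)
    write_tsv(hits_lig, file.path(out_dir, "mine", "targets_degene_ligand.tsv"))
    write_tsv(hits_rec, file.path(out_dir, "mine", "targets_degene_receptor.tsv"))
    rbind(hits_lig, hits_rec)
  })

  ## expression localization and final map
  map <- with_stage("map", {
    lung <- read_counts_mm(inputs$sc_lung_prefix)
    lung <- qc_filter_cells(lung, p$qc$min_genes, p$qc$max_pct_mito)
    lung_summ <- summarize_expression(lung)
    ipf <- read_counts_mm(inputs$sc_lung_ipf_prefix)
    donor <- read_counts_mm(inputs$sc_lung_donor_prefix)
    ct_de <- per_celltype_de(ipf, donor, lfc_threshold = p$lfc_threshold,
                             alpha = p$alpha)
    dir.create(file.path(out_dir, "map"), showWarnings = FALSE)
    ct_tab <- do.call(rbind, lapply(names(ct_de), function(cc)
      cbind(cell_type = cc, ct_de[[cc]])))
    write_tsv(ct_tab, file.path(out_dir, "map", "lung_celltype_de.tsv"))
    summaries <- stats::setNames(list(lung_summ, bridge_out$liver_summ),
                                 c(p$primary_organ, p$partner_organ))
    m <- assemble_map(list(bridge_out$cross_lig, bridge_out$cross_rec), hits,
                      summaries, p$primary_organ, p$partner_organ)
    write_tsv(m$nodes[, c("id", "label", "organ", "role", "top_celltypes")],
              file.path(out_dir, "map", "map_nodes.tsv"))
    write_tsv(m$edges, file.path(out_dir, "map", "map_edges.tsv"))
    write_mechanism_map(m, graphml = file.path(out_dir, "map", "map.graphml"),
                        json = file.path(out_dir, "map", "map.json"))
    m
  })

  ## manifest with checksums of every artifact
  manifest <- with_stage("manifest", {
    files <- sort(list.files(out_dir, recursive = TRUE, full.names = FALSE))
    files <- setdiff(files, "manifest.json")
    sums <- tools::md5sum(file.path(out_dir, files))
    man <- list(package = "crossorgan",
                version = as.character(utils::packageVersion("crossorgan")),
                seed = seed, params = p,
                files = as.list(stats::setNames(unname(sums), files)))
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    man
  })

  invisible(list(map = map, manifest = manifest,
                 artifacts = file.path(out_dir,
                   sort(list.files(out_dir, recursive = TRUE))),
                 degenes = degenes, bridges = bridge_out, hits = hits,
                 auc = topics_out$auc))
}
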