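#' Fixture ligand-receptor database, gene lists, and pathway files
#'
#' Builds, entirely in code, the tabular and KGML inputs needed by the
#' bridging, mining and map stages: a curated ligand-receptor pair table
#' containing the published IPF lung pairs plus 20 decoy pairs whose
#' members never occur in the DEgene list; a 112-gene DEgene list (the
#' real ligand/receptor symbols plus clearly-synthetic filler); an
#' 83-gene latent-feature list (the six pathway-positioned features plus
#' synthetic filler); five synthetic KGML pathway files whose directed
#' topology realizes the published receptor-to-feature positions, one
#' decoy pathway with no feature connection, and one group-entry demo
#' file; and a KEGG-id-to-symbol map covering every pathway gene. All
#' KGML content and KEGG ids are synthetic stand-ins built for offline
#' use; only the gene symbols and the relative positions are real.
#'
#' @param dir Optional directory; when given, every fixture is also
#'   written to disk (TSV / text / KGML XML) and the paths are returned.
#' @return List with `lr_db` (data.frame `ligand`, `receptor`,
#'   `evidence`; subunits `;`-joined), `degenes`, `latent_features`,
#'   `pathways` (named list of pathway specs for [write_kgml()]),
#'   `symbol_map` (data.frame `kegg_id`, `symbol`), and, when `dir` is
#'   given, `paths`.
#' @export
build_table_fixtures <- function(dir = NULL) {
  lr_db <- fixture_lr_db()
  degenes <- fixture_degenes()
  latent <- fixture_latent_features()
  pathways <- fixture_pathways()
  symbol_map <- fixture_symbol_map(pathways)

  out <- list(lr_db = lr_db, degenes = degenes, latent_features = latent,
              pathways = pathways, symbol_map = symbol_map)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    kgml_dir <- file.path(dir, "kgml")
    dir.create(kgml_dir, showWarnings = FALSE)
    paths <- c(
      lr_db = write_lr_table(lr_db, file.path(dir, "lr_pairs.tsv")),
      degenes = {
        writeLines(degenes, file.path(dir, "degenes.txt"))
        file.path(dir, "degenes.txt")
      },
      latent_features = {
        writeLines(latent, file.path(dir, "latent_features.txt"))
        file.path(dir, "latent_features.txt")
      },
      symbol_map = {
        utils::write.table(symbol_map, file.path(dir, "symbol_map.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        file.path(dir, "symbol_map.tsv")
      })
    kgml_paths <- vapply(names(pathways), function(id) {
      write_kgml(pathways[[id]], symbol_map, file.path(kgml_dir, paste0(id, ".xml")))
    }, character(1))
    out$paths <- c(as.list(paths), list(kgml = kgml_paths))
  }
  out
}

# Published lung ligand-receptor pairs (27 unique) plus 20 decoys.
fixture_lr_db <- function() {
  published <- rbind(
    c("CCL18", "ACKR1", "PMID: 26740381"),
    c("CXCL9", "ACKR1", "PMID: 26740381"),
    c("CXCL10", "ACKR1", "PMID: 26740381"),
    c("CXCL11", "ACKR1", "PMID: 26740381"),
    c("CXCL9", "CXCR3", "KEGG: hsa04060"),
    c("CXCL10", "CXCR3", "KEGG: hsa04060"),
    c("CXCL11", "CXCR3", "KEGG: hsa04060"),
    c("CXCL11", "ACKR3", "KEGG: hsa04060"),
    c("IL6", "IL6R;IL6ST", "KEGG: hsa04060"),
    c("IFNG", "IFNGR1;IFNGR2", "KEGG: hsa04060"),
    c("SELE", "CEACAM1", "PMID: 1378450"),
    c("SELE", "CD44", "PMC4571854"),
    c("SELE", "GLG1", "PMID: 11404363"),
    c("PF4V1", "CXCR3", "KEGG: hsa04060"),
    c("CXCL13", "CXCR3", "KEGG: hsa04060"),
    c("PF4", "CXCR3", "KEGG: hsa04060"),
    c("CXCL13", "CXCR5", "KEGG: hsa04060"),
    c("CXCL16", "CXCR6", "KEGG: hsa04060"),
    c("KNG1", "BDKRB1", "KEGG: hsa04080"),
    c("SLURP1", "CHRNA1", "KEGG: hsa04080"),
    c("SLURP2", "CHRNA1", "KEGG: hsa04080"),
    c("ENTPD1", "TMIGD3", "PMID: 21677139"),
    c("DSG1", "DSC3", "PMID: 27298358"),
    c("DSG2", "DSC3", "PMID: 27298358"),
    c("CD274", "PDCD1", "PMID: 23954143"),
    c("PDCD1LG2", "PDCD1", "PMID: 23954143"),
    c("SELPLG", "SELE", "PMC4571854"))
  decoys <- rbind(
    c("WNT5A", "FZD4"), c("EGF", "EGFR"), c("TGFB1", "TGFBR1;TGFBR2"),
    c("VEGFA", "KDR"), c("HGF", "MET"), c("BMP2", "BMPR1A;BMPR2"),
    c("DLL1", "NOTCH1"), c("JAG1", "NOTCH2"), c("NGF", "NTRK1"),
    c("BDNF", "NTRK2"), c("GDF15", "RET"), c("CSF1", "CSF1R"),
    c("FLT3LG", "FLT3"), c("KITLG", "KIT"), c("EPO", "EPOR"),
    c("GH1", "GHR"), c("PRL", "PRLR"), c("LEP", "LEPR"),
    c("INS", "INSR"), c("ANGPT1", "TEK"))
  data.frame(ligand = c(published[, 1], decoys[, 1]),
             receptor = c(published[, 2], decoys[, 2]),
             evidence = c(published[, 3], rep("synthetic decoy", nrow(decoys))),
             stringsAsFactors = FALSE)
}

# 112-gene DEgene list: the 15 published ligand/receptor DEgene symbols
# plus synthetic filler disjoint from the L-R database and pathways.
fixture_degenes <- function() {
  c("CCL18", "CXCL9", "CXCL10", "CXCL11", "IL6", "IFNG", "SELE",
    "CXCR3", "CXCR5", "CXCR6", "BDKRB1", "CHRNA1", "TMIGD3", "DSC3", "PDCD1",
    sprintf("IPFDEG%03d", seq_len(97)))
}

# 83-gene latent-feature list: the six pathway-positioned features plus
# synthetic filler absent from every fixture pathway.
fixture_latent_features <- function() {
  c("ELMO1", "CAMK4", "PCK1", "CALM1", "CALM2", "CALM3",
    sprintf("LATF%03d", seq_len(77)))
}

# Synthetic pathway topologies realizing the published receptor-feature
# positions. Node names are labels; `sym` gives the gene symbols carried
# by the entry (several symbols = one multi-gene entry, as real KGML does
# for the calmodulin genes).
fixture_pathways <- function() {
  pw <- function(title, nodes, edges) list(title = title, nodes = nodes,
                                           edges = edges)
  list(
    # chemokine signaling: CXCR3/5/6 converge on a shared chain to ELMO1
    hsa04062 = pw("Chemokine signaling (synthetic)",
      list(CXCR3 = "CXCR3", CXCR5 = "CXCR5", CXCR6 = "CXCR6", GNB1 = "GNB1",
           PIK3CG = "PIK3CG", DOCK2 = "DOCK2", ELMO1 = "ELMO1"),
      rbind(c("CXCR3", "GNB1", "activation"), c("CXCR5", "GNB1", "activation"),
            c("CXCR6", "GNB1", "activation"), c("GNB1", "PIK3CG", "activation"),
            c("PIK3CG", "DOCK2", "activation"), c("DOCK2", "ELMO1", "binding/association"))),
    # osteoclast differentiation: IFNGR1/2 to CAMK4
    hsa04380 = pw("Osteoclast differentiation (synthetic)",
      list(IFNGR1 = "IFNGR1", IFNGR2 = "IFNGR2", JAK2 = "JAK2",
           STAT1 = "STAT1", CAMK4 = "CAMK4"),
      rbind(c("IFNGR1", "JAK2", "activation"), c("IFNGR2", "JAK2", "activation"),
            c("JAK2", "STAT1", "activation"), c("STAT1", "CAMK4", "expression"))),
    # PI3K-Akt signaling: IL6R to PCK1 (IL6ST deliberately absent)
    hsa04151 = pw("PI3K-Akt signaling (synthetic)",
      list(IL6R = "IL6R", PIK3CA = "PIK3CA", AKT1 = "AKT1", FOXO1 = "FOXO1",
           PCK1 = "PCK1"),
      rbind(c("IL6R", "PIK3CA", "activation"), c("PIK3CA", "AKT1", "activation"),
            c("AKT1", "FOXO1", "inhibition"), c("FOXO1", "PCK1", "expression"))),
    # cytomegalovirus infection: calmodulins upstream of IL6 and its receptor
    hsa05163 = pw("Human cytomegalovirus infection (synthetic)",
      list(CALM = c("CALM1", "CALM2", "CALM3"), NFKB1 = "NFKB1", IL6 = "IL6",
           IL6R = "IL6R"),
      rbind(c("CALM", "NFKB1", "activation"), c("NFKB1", "IL6", "expression"),
            c("IL6", "IL6R", "binding/association"))),
    # pathways in cancer: KNG1-BDKRB1 down to the calmodulins
    hsa05200 = pw("Pathways in cancer (synthetic)",
      list(KNG1 = "KNG1", BDKRB1 = "BDKRB1", GNAQ = "GNAQ", PLCB1 = "PLCB1",
           CALM = c("CALM1", "CALM2", "CALM3")),
      rbind(c("KNG1", "BDKRB1", "binding/association"),
            c("BDKRB1", "GNAQ", "activation"), c("GNAQ", "PLCB1", "activation"),
            c("PLCB1", "CALM", "activation"))),
    # decoy: no ligand-receptor member, no latent feature
    hsa04911 = pw("Insulin secretion (synthetic decoy)",
      list(GCK = "GCK", ABCC8 = "ABCC8", KCNJ11 = "KCNJ11",
           CACNA1C = "CACNA1C", SNAP25 = "SNAP25"),
      rbind(c("GCK", "ABCC8", "inhibition"), c("ABCC8", "KCNJ11", "inhibition"),
            c("KCNJ11", "CACNA1C", "activation"), c("CACNA1C", "SNAP25", "activation"))),
    # group-entry dialect demo: a two-gene group signaling to DLG4
    hsa99999 = pw("Group-entry demo (synthetic)",
      list(GRIN1 = "GRIN1", GRIN2A = "GRIN2A",
           NMDAR = list(group = c("GRIN1", "GRIN2A")), DLG4 = "DLG4"),
      rbind(c("NMDAR", "DLG4", "binding/association"))))
}

# Assign synthetic KEGG ids ("hsa:1001", ...) to every pathway symbol.
fixture_symbol_map <- function(pathways = fixture_pathways()) {
  syms <- unique(unlist(lapply(pathways, function(p)
    unlist(lapply(p$nodes, function(nd) if (is.list(nd)) character(0) else nd)))))
  data.frame(kegg_id = sprintf("hsa:%d", 1000L + seq_along(syms)),
             symbol = syms, stringsAsFactors = FALSE)
}

#' Write a pathway spec as a KGML XML file
#'
#' Emits the minimal KGML dialect consumed by [parse_kgml()]: `entry`
#' tags of type `gene` (attribute `name` holding one or more KEGG ids) or
#' `group` (with `component` children), and `relation` tags whose
#' `entry1`/`entry2` attributes define directed edges.
#'
#' @param pathway One element of `build_table_fixtures()$pathways`.
#' @param symbol_map data.frame `kegg_id`, `symbol`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_kgml <- function(pathway, symbol_map, path) {
  labels <- names(pathway$nodes)
  pid <- sub("[.]xml$", "", basename(path))
  doc <- xml2::xml_new_root("pathway", name = paste0("path:", pid), org = "hsa",
                            title = pathway$title)
  for (i in seq_along(labels)) {
    nd <- pathway$nodes[[i]]
    if (is.list(nd)) {
      e <- xml2::xml_add_child(doc, "entry", id = as.character(i),
                               name = "undefined", type = "group")
      for (comp in nd$group)
        xml2::xml_add_child(e, "component",
                            id = as.character(match(comp, labels)))
    } else {
      ids <- symbol_map$kegg_id[match(nd, symbol_map$symbol)]
      ids[is.na(ids)] <- paste0("hsa:", nd[is.na(ids)])
      xml2::xml_add_child(doc, "entry", id = as.character(i),
                          name = paste(ids, collapse = " "), type = "gene")
    }
  }
  for (j in seq_len(nrow(pathway$edges))) {
    r <- xml2::xml_add_child(doc, "relation",
                             entry1 = as.character(match(pathway$edges[j, 1], labels)),
                             entry2 = as.character(match(pathway$edges[j, 2], labels)),
                             type = "PPrel")
    xml2::xml_add_child(r, "subtype", name = pathway$edges[j, 3], value = "-->")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
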