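split_subunits <- function(x) strsplit(trimws(x), ";", fixed = TRUE)

#' Read / write a ligand-receptor pair table
#'
#' TSV with columns `ligand_subunits`, `receptor_subunits` (semicolon-
#' joined gene symbols; multi-subunit complexes allowed) and `evidence`.
#'
#' @param db data.frame with columns `ligand`, `receptor`, `evidence`
#'   (subunits `;`-joined).
#' @param path File path.
#' @export
write_lr_table <- function(db, path) {
  utils::write.table(
    data.frame(ligand_subunits = db$ligand, receptor_subunits = db$receptor,
               evidence = db$evidence),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' @rdname write_lr_table
#' @export
read_lr_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  validate_lr_db(data.frame(ligand = tab$ligand_subunits,
                            receptor = tab$receptor_subunits,
                            evidence = tab$evidence, stringsAsFactors = FALSE))
}

validate_lr_db <- function(db) {
  stopifnot(is.data.frame(db), all(c("ligand", "receptor") %in% names(db)))
  if (!nrow(db)) stop("empty ligand-receptor database")
  db$ligand <- trimws(db$ligand)
  db$receptor <- trimws(db$receptor)
  if (any(!nzchar(db$ligand)) || any(!nzchar(db$receptor)))
    stop("subunit lists must be non-empty")
  if (anyDuplicated(db[c("ligand", "receptor")]))
    stop("duplicated (ligand, receptor) pair")
  if (is.null(db$evidence)) db$evidence <- ""
  db
}

side_hits <- function(db, side, degenes) {
  subs <- split_subunits(db[[side]])
  vapply(subs, function(s) any(s %in% degenes), logical(1))
}

bridge <- function(degenes, db, direction) {
  db <- validate_lr_db(db)
  degenes <- trimws(degenes)
  de_side <- if (direction == "degene_is_ligand") "ligand" else "receptor"
  partner_side <- if (direction == "degene_is_ligand") "receptor" else "ligand"
  keep <- side_hits(db, de_side, degenes)
  pairs <- db[keep, , drop = FALSE]
  pairs <- pairs[order(pairs$ligand, pairs$receptor), , drop = FALSE]
  rownames(pairs) <- NULL
  de_genes <- sort(unique(unlist(split_subunits(pairs[[de_side]]))))
  de_genes <- intersect(de_genes, degenes)
  partner_genes <- sort(unique(unlist(split_subunits(pairs[[partner_side]]))))
  structure(list(direction = direction, pairs = pairs,
                 degene_side_genes = de_genes,
                 partner_side_genes = partner_genes),
            class = "bridge_result")
}

#' @export
print.bridge_result <- function(x, ...) {
  cat("bridge_result (", x$direction, "): ", nrow(x$pairs), " pairs; ",
      length(x$degene_side_genes), " DE-side genes, ",
      length(x$partner_side_genes), " partner genes\n", sep = "")
  invisible(x)
}

#' Identify ligands (receptors) among differentially expressed genes
#'
#' `identify_ligands()` returns every ligand-receptor pair whose ligand
#' side has at least one subunit in the DEgene list, together with the
#' distinct DE-side ligands and their partner receptors;
#' `identify_receptors()` is the mirror on the receptor side. A
#' multi-subunit complex counts as "in the DEgene list" when any of its
#' subunits is. Matching is exact and case-sensitive after whitespace
#' trimming; results do not depend on database row order.
#'
#' @param degenes Character vector of DE gene symbols.
#' @param db Ligand-receptor data.frame (`ligand`, `receptor`,
#'   `evidence`; subunits `;`-joined).
#' @return Object of class `bridge_result`: `direction`, `pairs`
#'   (data.frame subset of `db`), `degene_side_genes`,
#'   `partner_side_genes`.
#' @export
identify_ligands <- function(degenes, db) bridge(degenes, db, "degene_is_ligand")

#' @rdname identify_ligands
#' @export
identify_receptors <- function(degenes, db) bridge(degenes, db, "degene_is_receptor")

#' Filter bridged pairs to those expressed in a partner organ
#'
#' Keeps pairs whose partner-side subunits are ALL expressed (fraction of
#' expressing cells `>= min_frac`) in at least one cell type of the
#' target organ; each retained subunit is annotated with its
#' maximal-expression cell type (by mean log CP10K). A complex joins the
#' DEgene list via any subunit, but must be fully expressed in the
#' partner organ to support cross-organ signaling.
#'
#' @param bridge A `bridge_result`.
#' @param partner_summaries [summarize_expression()] output covering the
#'   partner organ (an `organ` column is required).
#' @param target_organ Organ to require expression in.
#' @param min_frac Minimum expressing-cell fraction (0 keeps everything
#'   expressed in at least zero cells, i.e. an identity filter).
#' @return A `bridge_result` whose `pairs` carry an additional
#'   `partner_celltypes` column (`;`-joined `gene=cell_type` records).
#' @export
cross_organ_candidates <- function(bridge, partner_summaries, target_organ,
                                   min_frac = 0.1) {
  stopifnot(inherits(bridge, "bridge_result"),
            all(c("gene", "cell_type", "organ", "frac_expressing",
                  "mean_log_cp10k") %in% names(partner_summaries)))
  ss <- partner_summaries[partner_summaries$organ == target_organ, , drop = FALSE]
  if (!nrow(ss)) stop("organ absent from summaries: ", target_organ)
  partner_side <- if (bridge$direction == "degene_is_ligand") "receptor" else "ligand"
  best_ct <- function(g) {
    rows <- ss[ss$gene == g & ss$frac_expressing >= min_frac, , drop = FALSE]
    if (!nrow(rows)) return(NA_character_)
    rows$cell_type[which.max(rows$mean_log_cp10k)]
  }
  subs <- split_subunits(bridge$pairs[[partner_side]])
  ct <- lapply(subs, function(s) vapply(s, best_ct, character(1)))
  keep <- vapply(ct, function(x) length(x) > 0 && !any(is.na(x)), logical(1))
  pairs <- bridge$pairs[keep, , drop = FALSE]
  pairs$partner_celltypes <- vapply(ct[keep], function(x)
    paste(paste0(names(x), "=", x), collapse = ";"), character(1))
  rownames(pairs) <- NULL
  out <- bridge
  out$pairs <- pairs
  out$degene_side_genes <- intersect(
    sort(unique(unlist(split_subunits(
      pairs[[if (partner_side == "receptor") "ligand" else "receptor"]])))),
    bridge$degene_side_genes)
  out$partner_side_genes <- sort(unique(unlist(split_subunits(pairs[[partner_side]]))))
  out
}
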