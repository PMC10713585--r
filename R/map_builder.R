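pair_key <- function(ligand, receptor) paste(ligand, receptor, sep = "|")

node_label <- function(genes) paste(genes, collapse = "/")

# top cell types (by mean log CP10K averaged over the node's genes) from
# one organ's expression summaries
top_celltypes <- function(genes, summaries, n = 3) {
  ss <- summaries[summaries$gene %in% genes, , drop = FALSE]
  if (!nrow(ss)) return("")
  agg <- stats::aggregate(cbind(mean_log_cp10k = ss$mean_log_cp10k),
                          by = list(cell_type = ss$cell_type), FUN = mean)
  agg <- agg[order(-agg$mean_log_cp10k, agg$cell_type), , drop = FALSE]
  agg <- utils::head(agg, n)
  paste(sprintf("%s (%.2f)", agg$cell_type, agg$mean_log_cp10k), collapse = "; ")
}

#' Assemble the inter-organ mechanism map
#'
#' Fuses cross-organ ligand-receptor survivors, pathway-mining hits, and
#' expression localization into one organ-annotated directed graph: a
#' `direct_lr` edge per surviving pair (ligand organ to receptor organ),
#' a `pathway` edge per matched hit (receptor to feature for downstream
#' hits, placed in the receptor's organ; feature to ligand for upstream
#' hits, placed in the ligand's organ), and an `unknown` ("?") edge from
#' every terminal feature node back to each map ligand in its own organ.
#' Feature genes with identical hit profiles collapse into one node
#' (e.g. the three calmodulin genes). Every node carries its top-3 cell
#' types by mean log CP10K in its organ.
#'
#' @param bridges List of `bridge_result` objects whose pairs survived
#'   [cross_organ_candidates()]; their `direction` places the DEgene
#'   side in `primary_organ` and the partner side in `partner_organ`.
#' @param hits A `target_hits` data.frame ([find_targets()]); only hits
#'   matching a surviving pair are used.
#' @param summaries_by_organ Named list (by organ) of
#'   [summarize_expression()] outputs.
#' @param primary_organ Organ of the DEgene side (e.g. `"lung"`).
#' @param partner_organ Partner organ (e.g. `"liver"`).
#' @return Object of class `mechanism_map`: `nodes` (data.frame `id`,
#'   `label`, `organ`, `role`, `top_celltypes`, list-column `genes`) and
#'   `edges` (data.frame `from`, `to`, `kind`, `pathway_ids`,
#'   `provenance`).
#' @export
assemble_map <- function(bridges, hits, summaries_by_organ,
                         primary_organ = "lung", partner_organ = "liver") {
  if (inherits(bridges, "bridge_result")) bridges <- list(bridges)
  n_pairs <- sum(vapply(bridges, function(b) nrow(b$pairs), integer(1)))

  node_acc <- list()   # id -> list(genes, organ, role)
  edge_acc <- list()   # list(from, to, kind, pathway_ids, provenance)
  add_node <- function(genes, organ, role) {
    id <- paste0(node_label(genes), "@", organ)
    if (is.null(node_acc[[id]]))
      node_acc[[id]] <<- list(genes = genes, organ = organ, role = role)
    id
  }
  add_edge <- function(from, to, kind, pathway_ids = "", provenance = "") {
    edge_acc[[length(edge_acc) + 1L]] <<-
      list(from = from, to = to, kind = kind, pathway_ids = pathway_ids,
           provenance = provenance)
  }
  finalize <- function() {
    nodes <- data.frame(
      id = as.character(names(node_acc)),
      label = vapply(node_acc, function(x) node_label(x$genes), character(1)),
      organ = vapply(node_acc, `[[`, character(1), "organ"),
      role = vapply(node_acc, `[[`, character(1), "role"),
      stringsAsFactors = FALSE)
    nodes$genes <- lapply(node_acc, `[[`, "genes")
    nodes$top_celltypes <- vapply(seq_len(nrow(nodes)), function(i) {
      ss <- summaries_by_organ[[nodes$organ[i]]]
      if (is.null(ss)) "" else top_celltypes(nodes$genes[[i]], ss)
    }, character(1))
    nodes <- nodes[order(nodes$organ, nodes$role, nodes$id), , drop = FALSE]
    edges <- if (length(edge_acc))
      unique(do.call(rbind, lapply(edge_acc, function(e)
        data.frame(e, stringsAsFactors = FALSE))))
    else data.frame(from = character(0), to = character(0),
                    kind = character(0), pathway_ids = character(0),
                    provenance = character(0), stringsAsFactors = FALSE)
    edges <- edges[order(edges$kind, edges$from, edges$to), , drop = FALSE]
    rownames(nodes) <- rownames(edges) <- NULL
    structure(list(nodes = nodes, edges = edges), class = "mechanism_map")
  }

  if (n_pairs == 0L) {
    warning("no surviving ligand-receptor pairs; empty map")
    return(finalize())
  }

  # ligand-receptor backbone
  pair_info <- list()
  for (b in bridges) {
    lig_organ <- if (b$direction == "degene_is_ligand") primary_organ else partner_organ
    rec_organ <- if (b$direction == "degene_is_ligand") partner_organ else primary_organ
    for (i in seq_len(nrow(b$pairs))) {
      lig <- split_subunits(b$pairs$ligand[i])[[1]]
      rec <- split_subunits(b$pairs$receptor[i])[[1]]
      lid <- add_node(lig, lig_organ, "ligand")
      rid <- add_node(rec, rec_organ, "receptor")
      add_edge(lid, rid, "direct_lr", "",
               sprintf("pair %s -> %s (%s)", node_label(lig), node_label(rec),
                       b$direction))
      pair_info[[pair_key(b$pairs$ligand[i], b$pairs$receptor[i])]] <-
        list(lig = lig, rec = rec, lig_organ = lig_organ,
             rec_organ = rec_organ, lig_node = lid, rec_node = rid)
    }
  }

  # attach pathway hits to surviving pairs
  matched <- list()
  if (!is.null(hits) && nrow(hits)) {
    for (h in seq_len(nrow(hits))) {
      for (pk in names(pair_info)) {
        pi <- pair_info[[pk]]
        lig_ok <- all(strsplit(hits$ligand[h], "/", fixed = TRUE)[[1]] %in% pi$lig)
        rec_ok <- all(strsplit(hits$receptor[h], "/", fixed = TRUE)[[1]] %in% pi$rec)
        if (lig_ok && rec_ok)
          matched[[length(matched) + 1L]] <-
            cbind(hits[h, , drop = FALSE], pair = pk, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(matched)) {
    mh <- do.call(rbind, matched)
    class(mh) <- "data.frame"
    mh$organ <- ifelse(mh$position == "Downstream",
                       vapply(mh$pair, function(pk) pair_info[[pk]]$rec_organ,
                              character(1)),
                       vapply(mh$pair, function(pk) pair_info[[pk]]$lig_organ,
                              character(1)))
    # features with identical (pair, pathway, position, organ) profiles
    # collapse into one node
    sig <- vapply(split(mh, mh$feature), function(d)
      paste(sort(paste(d$pair, d$pathway, d$position, d$organ)), collapse = " || "),
      character(1))
    for (s in unique(sig)) {
      genes <- sort(names(sig)[sig == s])
      sub <- mh[mh$feature == genes[1], , drop = FALSE]
      for (org in unique(sub$organ)) {
        fid <- add_node(genes, org, "feature")
        so <- sub[sub$organ == org, , drop = FALSE]
        # one edge per (pair, position); pathways aggregated on the edge
        for (gk in unique(paste(so$pair, so$position))) {
          d <- so[paste(so$pair, so$position) == gk, , drop = FALSE]
          pi <- pair_info[[d$pair[1]]]
          pws <- paste(sort(unique(d$pathway)), collapse = ";")
          prov <- sprintf("hits %s:%s-%s:%s:%s", pws, d$ligand[1],
                          d$receptor[1], node_label(genes), d$position[1])
          if (d$position[1] == "Downstream")
            add_edge(pi$rec_node, fid, "pathway", pws, prov)
          else
            add_edge(fid, pi$lig_node, "pathway", pws, prov)
        }
      }
    }
  }

  # "?" edges: terminal feature nodes point back to same-organ map ligands
  from_ids <- vapply(edge_acc, `[[`, character(1), "from")
  for (id in names(node_acc)) {
    nd <- node_acc[[id]]
    if (nd$role != "feature" || id %in% from_ids) next
    for (lid in names(node_acc)) {
      ln <- node_acc[[lid]]
      if (ln$role == "ligand" && ln$organ == nd$organ)
        add_edge(id, lid, "unknown", "",
                 sprintf("no pathway link from %s to %s", id, lid))
    }
  }
  finalize()
}

#' @export
print.mechanism_map <- function(x, ...) {
  cat("mechanism_map:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    arrow <- c(direct_lr = "->", pathway = "~>", unknown = "?>")
    for (i in seq_len(nrow(x$edges))) {
      lab <- if (nzchar(x$edges$pathway_ids[i]))
        paste0(" [", x$edges$pathway_ids[i], "]") else ""
      cat(" ", x$edges$from[i], arrow[[x$edges$kind[i]]], x$edges$to[i],
          lab, "\n")
    }
  }
  invisible(x)
}

#' Convert a mechanism map to an igraph object
#'
#' @param map A `mechanism_map`.
#' @return Directed `igraph` with node attributes `label`, `organ`,
#'   `role`, `top_celltypes` and edge attributes `kind`, `pathway_ids`,
#'   `provenance`.
#' @export
map_to_igraph <- function(map) {
  v <- map$nodes[, c("id", "label", "organ", "role", "top_celltypes")]
  names(v)[1] <- "name"
  igraph::graph_from_data_frame(map$edges, directed = TRUE, vertices = v)
}

#' Serialize a mechanism map to GraphML and JSON
#'
#' @param map A `mechanism_map`.
#' @param graphml,json Output paths (either may be `NULL`).
#' @return Invisibly, the written paths.
#' @export
write_mechanism_map <- function(map, graphml = NULL, json = NULL) {
  if (!is.null(graphml))
    igraph::write_graph(map_to_igraph(map), graphml, format = "graphml")
  if (!is.null(json)) {
    payload <- list(
      nodes = map$nodes[, c("id", "label", "organ", "role", "top_celltypes")],
      edges = map$edges)
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(c(graphml = graphml, json = json))
}
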