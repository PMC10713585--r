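#' Parse a KGML pathway file into a directed graph
#'
#' Nodes are KGML `entry` tags (the `name` attribute holds one or more
#' KEGG ids, mapped to gene symbols via `symbol_map`); edges run from the
#' `entry1` to the `entry2` attribute of each `relation` tag. Group
#' entries are expanded: every edge touching a group is replicated to
#' each of its component entries, and the group node itself is not part
#' of the traversal graph. Compound and other non-gene entries are kept
#' as traversable intermediate nodes. Relations referencing a missing
#' entry are skipped with a warning; gene ids absent from `symbol_map`
#' are retained with an empty symbol set (warning).
#'
#' @param xml_file Path to a KGML XML file.
#' @param symbol_map data.frame with columns `kegg_id`, `symbol`.
#' @return Object of class `pathway_graph`: `pathway_id`, `nodes`
#'   (data.frame `entry_id`, `type`, list-columns `kegg_ids`,
#'   `symbols`), `edges` (data.frame `from`, `to`, `subtype`), and
#'   `graph` (directed `igraph` on entry ids).
#' @export
parse_kgml <- function(xml_file, symbol_map) {
  doc <- xml2::read_xml(xml_file)
  pathway_id <- sub("^path:", "", xml2::xml_attr(doc, "name"))
  entries <- xml2::xml_find_all(doc, "./entry")
  ids <- xml2::xml_attr(entries, "id")
  types <- xml2::xml_attr(entries, "type")
  kegg_ids <- strsplit(xml2::xml_attr(entries, "name"), " +")
  components <- lapply(entries, function(e)
    xml2::xml_attr(xml2::xml_find_all(e, "./component"), "id"))
  symbols <- lapply(seq_along(ids), function(i) {
    if (types[i] != "gene") return(character(0))
    s <- symbol_map$symbol[match(kegg_ids[[i]], symbol_map$kegg_id)]
    if (anyNA(s))
      warning(pathway_id, ": unmapped KEGG id(s) ",
              paste(kegg_ids[[i]][is.na(s)], collapse = ", "))
    sort(unique(s[!is.na(s)]))
  })
  nodes <- data.frame(entry_id = ids, type = types, stringsAsFactors = FALSE)
  nodes$kegg_ids <- kegg_ids
  nodes$symbols <- symbols
  nodes$components <- components

  rels <- xml2::xml_find_all(doc, "./relation")
  edges <- data.frame(
    from = xml2::xml_attr(rels, "entry1"),
    to = xml2::xml_attr(rels, "entry2"),
    subtype = vapply(rels, function(r) {
      st <- xml2::xml_find_first(r, "./subtype")
      if (inherits(st, "xml_missing")) NA_character_ else xml2::xml_attr(st, "name")
    }, character(1)),
    stringsAsFactors = FALSE)
  missing_ref <- !(edges$from %in% ids) | !(edges$to %in% ids)
  if (any(missing_ref)) {
    warning(pathway_id, ": ", sum(missing_ref),
            " relation(s) reference a missing entry; skipped")
    edges <- edges[!missing_ref, , drop = FALSE]
  }
  # expand group endpoints to their components
  expand <- function(id) {
    i <- match(id, ids)
    if (types[i] == "group") components[[i]] else id
  }
  if (nrow(edges)) {
    exp_rows <- lapply(seq_len(nrow(edges)), function(j) {
      expand.grid(from = expand(edges$from[j]), to = expand(edges$to[j]),
                  stringsAsFactors = FALSE)[, 1:2, drop = FALSE] |>
        cbind(subtype = edges$subtype[j])
    })
    edges <- unique(do.call(rbind, exp_rows))
  }
  rownames(edges) <- NULL
  traversal_nodes <- ids[types != "group"]
  graph <- igraph::graph_from_data_frame(
    edges[edges$from %in% traversal_nodes & edges$to %in% traversal_nodes,
          c("from", "to"), drop = FALSE],
    directed = TRUE, vertices = traversal_nodes)
  structure(list(pathway_id = pathway_id, nodes = nodes, edges = edges,
                 graph = graph),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("pathway_graph", x$pathway_id, ":", nrow(x$nodes), "entries,",
      nrow(x$edges), "directed edges\n")
  invisible(x)
}

# entry ids (non-group) whose symbol set contains `sym`
entries_for_symbol <- function(pg, sym) {
  hit <- vapply(seq_len(nrow(pg$nodes)), function(i)
    pg$nodes$type[i] != "group" && sym %in% pg$nodes$symbols[[i]], logical(1))
  pg$nodes$entry_id[hit]
}

# set of entry ids reachable from `entry` along directed edges (path
# length >= 1; the start node is included only if a cycle returns to it)
reachable_entries <- function(pg, entry, mode = "out") {
  nb <- igraph::neighbors(pg$graph, entry, mode = mode)
  if (!length(nb)) return(character(0))
  reach <- unique(unlist(lapply(nb, function(v)
    names(igraph::subcomponent(pg$graph, v, mode = mode)))))
  reach
}

#' Find latent-feature targets of ligand-receptor pairs in pathways
#'
#' For every pathway containing a pair member and a feature, emits a
#' `Downstream` hit when a directed path (any length, relation subtypes
#' ignored) runs from an anchor node to the feature, and an `Upstream`
#' hit when a path runs from the feature to an anchor. Anchors are the
#' receptor subunits present in the pathway, one hit row per subunit (so
#' a two-subunit receptor yields one row per subunit found); when no
#' receptor subunit is present, the ligand subunits anchor the search.
#' Features that are themselves subunits of the pair never produce hits.
#'
#' @param graphs List of [parse_kgml()] results.
#' @param pairs data.frame with columns `ligand`, `receptor` (subunits
#'   `;`-joined), e.g. `bridge_result$pairs`.
#' @param features Character vector of latent feature gene symbols.
#' @return data.frame of class `target_hits` with columns `pathway`,
#'   `ligand`, `receptor`, `feature`, `position`
#'   (`"Downstream"`/`"Upstream"`), deduplicated and sorted.
#' @export
find_targets <- function(graphs, pairs, features) {
  stopifnot(nrow(pairs) > 0)
  rows <- list()
  add <- function(pathway, ligand, receptor, feature, position)
    rows[[length(rows) + 1L]] <<- data.frame(
      pathway = pathway, ligand = ligand, receptor = receptor,
      feature = feature, position = position, stringsAsFactors = FALSE)
  for (pg in graphs) {
    feat_entries <- lapply(stats::setNames(features, features), function(f)
      entries_for_symbol(pg, f))
    present_feats <- features[lengths(feat_entries) > 0]
    if (!length(present_feats)) next
    down_cache <- new.env(parent = emptyenv())
    reach_down <- function(e) {
      if (is.null(down_cache[[e]])) down_cache[[e]] <- reachable_entries(pg, e, "out")
      down_cache[[e]]
    }
    up_cache <- new.env(parent = emptyenv())
    reach_up <- function(e) {
      if (is.null(up_cache[[e]])) up_cache[[e]] <- reachable_entries(pg, e, "in")
      up_cache[[e]]
    }
    for (i in seq_len(nrow(pairs))) {
      lig_sub <- split_subunits(pairs$ligand[i])[[1]]
      rec_sub <- split_subunits(pairs$receptor[i])[[1]]
      rec_present <- rec_sub[vapply(rec_sub, function(s)
        length(entries_for_symbol(pg, s)) > 0, logical(1))]
      if (length(rec_present)) {
        anchors <- rec_present
        anchor_role <- "receptor"
      } else {
        anchors <- lig_sub[vapply(lig_sub, function(s)
          length(entries_for_symbol(pg, s)) > 0, logical(1))]
        anchor_role <- "ligand"
      }
      if (!length(anchors)) next
      for (a in anchors) {
        a_entries <- entries_for_symbol(pg, a)
        lig_lab <- if (anchor_role == "receptor") paste(lig_sub, collapse = "/") else a
        rec_lab <- if (anchor_role == "receptor") a else paste(rec_sub, collapse = "/")
        for (f in setdiff(present_feats, c(lig_sub, rec_sub))) {
          fe <- feat_entries[[f]]
          down <- any(vapply(a_entries, function(e)
            any(setdiff(fe, e) %in% reach_down(e)), logical(1)))
          up <- any(vapply(a_entries, function(e)
            any(setdiff(fe, e) %in% reach_up(e)), logical(1)))
          if (down) add(pg$pathway_id, lig_lab, rec_lab, f, "Downstream")
          if (up) add(pg$pathway_id, lig_lab, rec_lab, f, "Upstream")
        }
      }
    }
  }
  out <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(pathway = character(0), ligand = character(0),
               receptor = character(0), feature = character(0),
               position = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$pathway, out$ligand, out$receptor, out$feature,
                   out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("target_hits", "data.frame")
  out
}
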