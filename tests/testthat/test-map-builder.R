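# hand-built inputs mirroring the published lung-liver instance
toy_bridges <- function() {
  lig <- structure(list(
    direction = "degene_is_ligand",
    pairs = data.frame(ligand = "IL6", receptor = "IL6R;IL6ST",
                       evidence = "t", stringsAsFactors = FALSE),
    degene_side_genes = "IL6",
    partner_side_genes = c("IL6R", "IL6ST")), class = "bridge_result")
  rec <- structure(list(
    direction = "degene_is_receptor",
    pairs = data.frame(ligand = "KNG1", receptor = "BDKRB1",
                       evidence = "t", stringsAsFactors = FALSE),
    degene_side_genes = "BDKRB1",
    partner_side_genes = "KNG1"), class = "bridge_result")
  list(lig, rec)
}

toy_hits <- function() {
  data.frame(
    pathway = c("hsa04151", "hsa05163", "hsa05163", "hsa05163",
                "hsa05200", "hsa05200", "hsa05200"),
    ligand = c("IL6", "IL6", "IL6", "IL6", "KNG1", "KNG1", "KNG1"),
    receptor = c("IL6R", "IL6R", "IL6R", "IL6R", "BDKRB1", "BDKRB1", "BDKRB1"),
    feature = c("PCK1", "CALM1", "CALM2", "CALM3", "CALM1", "CALM2", "CALM3"),
    position = c("Downstream", "Upstream", "Upstream", "Upstream",
                 "Downstream", "Downstream", "Downstream"),
    stringsAsFactors = FALSE)
}

toy_summaries <- function() {
  list(
    liver = data.frame(
      gene = c("KNG1", "IL6R", "IL6ST", "PCK1"),
      cell_type = "hepatocyte", organ = "liver",
      frac_expressing = 0.8, mean_log_cp10k = c(3, 1, 1, 2.5),
      stringsAsFactors = FALSE),
    lung = data.frame(
      gene = c("IL6", "BDKRB1", "CALM1", "CALM2", "CALM3"),
      cell_type = "macrophage", organ = "lung",
      frac_expressing = 0.5, mean_log_cp10k = c(1, 0.5, 2, 2, 2),
      stringsAsFactors = FALSE))
}

test_that("the assembled map realizes the published lung-liver loop", {
  map <- assemble_map(toy_bridges(), toy_hits(), toy_summaries())
  edge_str <- paste(map$edges$from, map$edges$kind, map$edges$to)
  expect_setequal(edge_str, c(
    "KNG1@liver direct_lr BDKRB1@lung",
    "IL6@lung direct_lr IL6R/IL6ST@liver",
    "BDKRB1@lung pathway CALM1/CALM2/CALM3@lung",
    "CALM1/CALM2/CALM3@lung pathway IL6@lung",
    "IL6R/IL6ST@liver pathway PCK1@liver",
    "PCK1@liver unknown KNG1@liver"))
  expect_identical(
    map$edges$pathway_ids[map$edges$from == "BDKRB1@lung"], "hsa05200")
  expect_identical(
    map$edges$pathway_ids[map$edges$to == "IL6@lung"], "hsa05163")
  expect_identical(sum(map$edges$kind == "unknown"), 1L)
  # organs partition the nodes and cell-type evidence is attached
  expect_setequal(map$nodes$organ[map$nodes$label %in% c("KNG1", "PCK1")],
                  "liver")
  expect_match(map$nodes$top_celltypes[map$nodes$id == "KNG1@liver"],
               "hepatocyte")
})

test_that("the map is well-formed with full provenance", {
  map <- assemble_map(toy_bridges(), toy_hits(), toy_summaries())
  expect_true(all(map$edges$from %in% map$nodes$id))
  expect_true(all(map$edges$to %in% map$nodes$id))
  expect_true(all(nzchar(map$edges$provenance)))
  expect_true(all(nzchar(map$edges$pathway_ids[map$edges$kind == "pathway"])))
  expect_true(all(map$edges$pathway_ids[map$edges$kind != "pathway"] == ""))
  expect_false(anyDuplicated(map$nodes$id) > 0)
})

test_that("without pathway hits the map has only direct edges", {
  map <- assemble_map(toy_bridges(), toy_hits()[0, ], toy_summaries())
  expect_setequal(unique(map$edges$kind), "direct_lr")
  expect_identical(nrow(map$edges), 2L)
})

test_that("deleting a feature removes exactly the edges citing it", {
  full <- assemble_map(toy_bridges(), toy_hits(), toy_summaries())
  no_pck1 <- assemble_map(toy_bridges(),
                          toy_hits()[toy_hits()$feature != "PCK1", ],
                          toy_summaries())
  gone <- setdiff(paste(full$edges$from, full$edges$to),
                  paste(no_pck1$edges$from, no_pck1$edges$to))
  # the PCK1 pathway edge and its "?" closure disappear; nothing else
  expect_setequal(gone, c("IL6R/IL6ST@liver PCK1@liver",
                          "PCK1@liver KNG1@liver"))
})

test_that("empty bridges give an empty map with a warning", {
  empty <- structure(list(direction = "degene_is_ligand",
                          pairs = data.frame(ligand = character(0),
                                             receptor = character(0),
                                             evidence = character(0)),
                          degene_side_genes = character(0),
                          partner_side_genes = character(0)),
                     class = "bridge_result")
  expect_warning(map <- assemble_map(list(empty), toy_hits()[0, ],
                                     toy_summaries()), "empty map")
  expect_identical(nrow(map$nodes), 0L)
  expect_identical(nrow(map$edges), 0L)
})

test_that("maps serialize to GraphML and JSON", {
  map <- assemble_map(toy_bridges(), toy_hits(), toy_summaries())
  d <- withr::local_tempdir()
  write_mechanism_map(map, graphml = file.path(d, "m.graphml"),
                      json = file.path(d, "m.json"))
  g <- igraph::read_graph(file.path(d, "m.graphml"), format = "graphml")
  expect_equal(igraph::vcount(g), nrow(map$nodes))
  expect_equal(igraph::ecount(g), nrow(map$edges))
  js <- jsonlite::read_json(file.path(d, "m.json"))
  expect_length(js$nodes, nrow(map$nodes))
  expect_length(js$edges, nrow(map$edges))
})

test_that("a missing ligand-receptor table aborts in the bridge stage", {
  d <- withr::local_tempdir()
  inputs <- suppressWarnings(suppressMessages(
    crossorgan:::make_synthetic_inputs(d, seed = 3,
      pipeline_config(d, seed = 3)$params)))
  unlink(inputs$lr_table)
  cfg <- pipeline_config(file.path(d, "out"), seed = 3, synthetic = FALSE,
                         inputs = inputs,
                         params = list(topics = list(n_iter = 60, burn_in = 30,
                                                     n_eval = 2)))
  expect_error(suppressWarnings(suppressMessages(run_pipeline(cfg))),
               "stage 'bridge'")
})
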