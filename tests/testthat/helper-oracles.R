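# Independent oracles used across test files.

# textbook 2x2 chi-square: n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
chi2_formula <- function(a, b, c, d) {
  n <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  if (den == 0) return(0)
  n * (a * d - b * c)^2 / den
}

# brute-force transitive closure (Floyd-Warshall style) on an adjacency
# matrix; closure[i, j] is TRUE iff a path of length >= 1 runs i -> j
brute_closure <- function(adj) {
  n <- nrow(adj)
  reach <- adj
  for (k in seq_len(n))
    for (i in seq_len(n))
      if (reach[i, k]) reach[i, ] <- reach[i, ] | reach[k, ]
  reach
}

# random directed graph as an adjacency matrix
random_digraph <- function(n, p = 0.1) {
  adj <- matrix(stats::runif(n * n) < p, n, n)
  diag(adj) <- FALSE
  dimnames(adj) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  adj
}

# minimal planted corpus: two disjoint single-topic groups
two_topic_corpus <- function(n_diseases = 10, seed = 1) {
  simulate_disease_corpus(corpus_spec(
    n_diseases = n_diseases, n_genes_per_modality = 60, n_topics_true = 2,
    genes_per_disease = 12, noise_rate = 0, mixture_prob = 0, seed = seed))
}

# bundle used by bridging / mining tests
fixture_bundle <- function() {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  fx <- build_table_fixtures(dir)
  list(fx = fx, db = read_lr_table(fx$paths$lr_db))
}

published_table3 <- function() {
  data.frame(
    pathway = c(rep("hsa04062", 3), rep("hsa04380", 2), "hsa04151",
                rep("hsa05163", 3)),
    ligand = c("CXCL9", "CXCL10", "CXCL11", "IFNG", "IFNG", "IL6",
               "IL6", "IL6", "IL6"),
    receptor = c("CXCR3", "CXCR3", "CXCR3", "IFNGR1", "IFNGR2", "IL6R",
                 "IL6R", "IL6R", "IL6R"),
    feature = c("ELMO1", "ELMO1", "ELMO1", "CAMK4", "CAMK4", "PCK1",
                "CALM1", "CALM2", "CALM3"),
    position = c(rep("Downstream", 6), rep("Upstream", 3)),
    stringsAsFactors = FALSE)
}

published_table4 <- function() {
  data.frame(
    pathway = c(rep("hsa04062", 8), rep("hsa05200", 3)),
    ligand = c("PF4V1", "CXCL9", "CXCL10", "CXCL11", "CXCL13", "CXCL13",
               "PF4", "CXCL16", "KNG1", "KNG1", "KNG1"),
    receptor = c("CXCR3", "CXCR3", "CXCR3", "CXCR3", "CXCR3", "CXCR5",
                 "CXCR3", "CXCR6", "BDKRB1", "BDKRB1", "BDKRB1"),
    feature = c(rep("ELMO1", 8), "CALM1", "CALM2", "CALM3"),
    position = rep("Downstream", 11),
    stringsAsFactors = FALSE)
}

sort_hits <- function(h) {
  h <- as.data.frame(h)
  h <- h[order(h$pathway, h$ligand, h$receptor, h$feature, h$position), ,
         drop = FALSE]
  rownames(h) <- NULL
  h[c("pathway", "ligand", "receptor", "feature", "position")]
}
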