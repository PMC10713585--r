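test_that("theta and phi are normalized and deterministic under a seed", {
  sim <- two_topic_corpus(12, seed = 2)
  fit1 <- fit_topic_model(sim$corpus, K = 2, n_iter = 60, burn_in = 30, seed = 5)
  fit2 <- fit_topic_model(sim$corpus, K = 2, n_iter = 60, burn_in = 30, seed = 5)
  expect_equal(unname(rowSums(fit1$theta)), rep(1, 12), tolerance = 1e-9)
  for (m in MODALITIES)
    expect_equal(unname(rowSums(fit1$phi[[m]])), rep(1, 2), tolerance = 1e-9)
  expect_identical(fit1$theta, fit2$theta)
  expect_identical(fit1$phi, fit2$phi)
})

test_that("a single-disease, single-topic model has theta = 1", {
  corp <- disease_corpus(list(disease_record("D1", "only disease",
    list(Ae = c("g1", "g2"), Bm = "g3"))))
  fit <- fit_topic_model(corp, K = 1, n_iter = 20, burn_in = 10, seed = 1)
  expect_equal(unname(fit$theta[1, 1]), 1, tolerance = 1e-12)
})

test_that("planted two-topic partition is recovered exactly (ARI = 1)", {
  sim <- two_topic_corpus(24, seed = 7)
  fit <- fit_topic_model(sim$corpus, K = 2, n_iter = 150, burn_in = 75, seed = 3)
  lab <- apply(fit$theta, 1, which.max)
  expect_equal(mclust::adjustedRandIndex(lab, sim$truth$primary_topic), 1)
})

test_that("fit validates its inputs", {
  sim <- two_topic_corpus(5, seed = 1)
  expect_error(fit_topic_model(sim$corpus, K = 9), "K must be")
  expect_error(fit_topic_model(sim$corpus, K = 2, alpha = 0), "positive")
  expect_error(fit_topic_model(sim$corpus, K = 2, n_iter = 10, burn_in = 10),
               "burn_in")
})

test_that("imputed scores are a probability distribution over the vocabulary", {
  sim <- two_topic_corpus(16, seed = 4)
  fit <- fit_topic_model(sim$corpus, K = 2, n_iter = 100, burn_in = 50, seed = 2)
  rec <- sim$corpus[[3]]
  qry <- disease_record(rec$disease_id, rec$name, rec$modality_genes[c("Bm", "Gv")])
  gen <- impute_modality(fit, qry, "Ae", corpus = sim$corpus, seed = 6)
  expect_equal(sum(gen$score), 1, tolerance = 1e-9)
  expect_false(rec$disease_id %in% unlist(gen$source_diseases))
  expect_error(impute_modality(fit, rec, "Ae"), "already has")
})

test_that("top imputed genes come from the query's planted topic pool", {
  sim <- two_topic_corpus(20, seed = 8)
  fit <- fit_topic_model(sim$corpus, K = 2, n_iter = 150, burn_in = 75, seed = 2)
  i <- 5
  rec <- sim$corpus[[i]]
  topic <- sim$truth$primary_topic[i]
  qry <- disease_record(rec$disease_id, rec$name, rec$modality_genes[c("Bm", "Gv")])
  gen <- impute_modality(fit, qry, "Ae", seed = 7)
  pool <- sim$pools$Ae[[topic]]
  expect_true(all(head(gen$gene, 15) %in% pool))
})

test_that("a K = 1 model ranks genes by corpus-wide frequency", {
  sim <- two_topic_corpus(15, seed = 9)
  fit <- fit_topic_model(sim$corpus, K = 1, n_iter = 40, burn_in = 20, seed = 1)
  rec <- sim$corpus[[2]]
  qry <- disease_record(rec$disease_id, rec$name, rec$modality_genes[c("Bm", "Gv")])
  gen <- impute_modality(fit, qry, "Ae", seed = 3)
  freq <- table(unlist(modality_sets(sim$corpus, "Ae")))
  freq <- freq[gen$gene]
  # scores must be monotone in frequency (ties collapse to equal scores)
  expect_true(all(diff(as.integer(freq[order(-gen$score)])) <= 0))
})

test_that("the rank AUC matches pROC and behaves at the extremes", {
  set.seed(10)
  labels <- c(rep(TRUE, 30), rep(FALSE, 70))
  scores <- rnorm(100) + labels
  ours <- crossorgan:::auc_score(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                        quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
  expect_equal(crossorgan:::auc_score(as.numeric(labels), labels), 1)
  null_auc <- replicate(50, crossorgan:::auc_score(rnorm(400),
                                                   rep(c(TRUE, FALSE), 200)))
  expect_lt(abs(mean(null_auc) - 0.5), 0.05)
})

test_that("latent-feature extraction applies self and name exclusion", {
  gen <- data.frame(gene = c("gA", "gB", "gC", "gD"),
                    modality = "Ae",
                    score = c(0.4, 0.3, 0.2, 0.1), stringsAsFactors = FALSE)
  gen$source_diseases <- list(c("D1", "D2"), "D1", "D3", "D2")
  corp <- disease_corpus(list(
    disease_record("D1", "Idiopathic Pulmonary Fibrosis", list(Ae = "x1")),
    disease_record("D2", "Diabetes Mellitus", list(Ae = "x2")),
    disease_record("D3", "Chronic Respiratory Failure", list(Ae = "x3"))))
  qry <- disease_record("Q", "query disease", list(Ae = "gC", Bm = "zz"))
  latent <- extract_latent_features(gen, qry, corp, top_fraction = 1)
  # D1 matches "Pulmonary", D3 matches the "Respir" prefix wildcard
  expect_setequal(latent$excluded_diseases, c("D1", "D3"))
  # gB: only source D1 excluded -> dropped; gC: in the query's own genes
  expect_setequal(latent$features$gene, c("gA", "gD"))
  # gA keeps only the retained source D2
  expect_identical(latent$features$source_diseases[[
    which(latent$features$gene == "gA")]], "D2")
  # order invariance
  latent2 <- extract_latent_features(gen[4:1, ], qry, corp, top_fraction = 1)
  expect_identical(latent$features, latent2$features)
  expect_error(extract_latent_features(gen, qry, corp, top_fraction = 0),
               "top_fraction")
})

test_that("extraction returns an empty set when all genes are self-derived", {
  gen <- data.frame(gene = c("gA", "gB"), modality = "Ae", score = c(0.6, 0.4),
                    stringsAsFactors = FALSE)
  gen$source_diseases <- list("D1", "D1")
  corp <- disease_corpus(list(disease_record("D1", "other disease",
                                             list(Ae = "x1"))))
  qry <- disease_record("Q", "query", list(Ae = c("gA", "gB"), Bm = "zz"))
  latent <- extract_latent_features(gen, qry, corp, top_fraction = 1)
  expect_identical(nrow(latent$features), 0L)
})

test_that("disease relatedness counts match direct counting and conserve totals", {
  gen <- data.frame(gene = sprintf("g%d", 1:7), modality = "Ae",
                    score = seq(0.7, 0.1, by = -0.1), stringsAsFactors = FALSE)
  gen$source_diseases <- c(rep(list(c("DD", "DE")), 5), list("DE"), list("DF"))
  corp <- disease_corpus(list(
    disease_record("DD", "disease D", list(Ae = "x")),
    disease_record("DE", "disease E", list(Ae = "x")),
    disease_record("DF", "disease F", list(Ae = "x"))))
  qry <- disease_record("Q", "query", list(Ae = "zz"))
  latent <- extract_latent_features(gen, qry, corp, top_fraction = 1)
  rel <- disease_relatedness(latent, corp)
  expect_identical(rel$count[rel$disease_id == "DD"], 5L)
  expect_identical(rel$count[rel$disease_id == "DE"], 6L)
  # conservation: total counts = total retained source links
  expect_identical(sum(rel$count),
                   length(unlist(latent$features$source_diseases)))
  # descending order with name tie-break, and the display filter
  expect_identical(rel$disease_id, c("DE", "DD", "DF"))
  expect_identical(nrow(disease_relatedness(latent, corp, min_count = 5)), 1L)
})

test_that("single feature with two source diseases counts each once", {
  gen <- data.frame(gene = "g1", modality = "Bm", score = 1,
                    stringsAsFactors = FALSE)
  gen$source_diseases <- list(c("DA", "DB"))
  corp <- disease_corpus(list(disease_record("DA", "a", list(Ae = "x")),
                              disease_record("DB", "b", list(Ae = "x"))))
  qry <- disease_record("Q", "query", list(Ae = "zz"))
  latent <- extract_latent_features(gen, qry, corp, top_fraction = 1)
  rel <- disease_relatedness(latent, corp)
  expect_identical(rel$count, c(1L, 1L))
})
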