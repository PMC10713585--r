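#' Fit a multi-field LDA topic model to a disease corpus
#'
#' Multi-modal generative topic model: each disease draws a single topic
#' distribution `theta` shared across modalities, and each topic owns an
#' independent gene distribution `phi` per modality (Ae/Bm/Gv). Inference
#' is collapsed Gibbs sampling; point estimates of `theta` and `phi` are
#' means over post-burn-in sweeps.
#'
#' @param corpus A `disease_corpus`; every disease must carry at least
#'   one gene.
#' @param K Number of topics (`1 <= K <=` number of diseases).
#' @param alpha Document-topic Dirichlet concentration (default `1/K`).
#' @param beta Topic-gene Dirichlet concentration, scalar or named
#'   per-modality vector.
#' @param n_iter Total Gibbs sweeps; `burn_in` of them are discarded.
#' @param burn_in Number of discarded initial sweeps (`< n_iter`).
#' @param seed Integer seed, or `NULL` to continue the current RNG stream.
#' @return Object of class `topic_fit` with elements `theta` (diseases x
#'   topics, rows sum to 1), `phi` (per-modality topics x genes matrices,
#'   rows sum to 1), `vocab`, and the hyperparameters.
#' @export
fit_topic_model <- function(corpus, K, alpha = 1 / K, beta = 0.01,
                            n_iter = 500, burn_in = 250, seed = 1) {
  stopifnot(inherits(corpus, "disease_corpus"))
  if (length(corpus) == 0L) stop("empty corpus")
  if (K < 1 || K > length(corpus)) stop("K must be in [1, number of diseases]")
  if (alpha <= 0 || any(beta <= 0)) stop("hyperparameters must be positive")
  if (burn_in < 0 || burn_in >= n_iter) stop("need 0 <= burn_in < n_iter")
  if (length(beta) == 1L) beta <- stats::setNames(rep(beta, 3), MODALITIES)
  beta <- beta[MODALITIES]

  vocab <- lapply(stats::setNames(MODALITIES, MODALITIES), function(m)
    sort(unique(unlist(lapply(corpus, function(r) r$modality_genes[[m]])))))
  ids <- names(corpus)

  doc <- integer(0); mod <- integer(0); word <- integer(0)
  for (d in seq_along(corpus)) {
    for (mi in seq_along(MODALITIES)) {
      g <- corpus[[d]]$modality_genes[[MODALITIES[mi]]]
      if (is.null(g) || !length(g)) next
      w <- match(g, vocab[[mi]])
      doc <- c(doc, rep.int(d, length(w)))
      mod <- c(mod, rep.int(mi, length(w)))
      word <- c(word, w)
    }
  }
  if (!length(doc)) stop("corpus contains no genes")

  if (!is.null(seed)) set.seed(seed)
  res <- gibbs_fit_cpp(doc - 1L, mod - 1L, word - 1L,
                       D = length(corpus), M = 3L,
                       V = lengths(vocab), K = as.integer(K),
                       alpha = alpha, beta = unname(beta),
                       n_iter = as.integer(n_iter), burn_in = as.integer(burn_in))
  theta <- res$theta
  dimnames(theta) <- list(ids, paste0("topic", seq_len(K)))
  phi <- lapply(seq_along(MODALITIES), function(mi) {
    p <- res$phi[[mi]]
    dimnames(p) <- list(paste0("topic", seq_len(K)), vocab[[mi]])
    p
  })
  names(phi) <- MODALITIES
  structure(list(K = K, alpha = alpha, beta = beta, theta = theta, phi = phi,
                 vocab = vocab, n_iter = n_iter, burn_in = burn_in, seed = seed),
            class = "topic_fit")
}

#' @export
print.topic_fit <- function(x, ...) {
  cat("topic_fit: K =", x$K, "topics over", nrow(x$theta), "diseases;",
      "vocab:", paste(names(x$vocab), lengths(x$vocab), sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Impute a missing modality for a query disease
#'
#' Folds the query into a fitted model (Gibbs over the query's tokens
#' only, with `phi` frozen), then scores every gene `g` of the missing
#' modality as `sum_k theta_query[k] * phi[k, missing][g]`; scores sum to
#' one over the modality vocabulary.
#'
#' @param fit A `topic_fit`.
#' @param query A `disease_record` lacking exactly the `missing` modality.
#' @param missing The modality to generate (`"Ae"`, `"Bm"` or `"Gv"`).
#' @param corpus The training corpus, used to annotate each generated
#'   gene with its source diseases (diseases whose same-modality set
#'   contains the gene; the query itself is excluded).
#' @param n_iter,burn_in Gibbs sweeps for the fold-in.
#' @param seed Integer seed, or `NULL` to continue the current RNG stream.
#' @return A data.frame of class `generated_features` ranked by
#'   descending score: columns `gene`, `modality`, `score`, and the
#'   list-column `source_diseases`.
#' @export
impute_modality <- function(fit, query, missing, corpus = NULL,
                            n_iter = 200, burn_in = 100, seed = NULL) {
  stopifnot(inherits(fit, "topic_fit"), inherits(query, "disease_record"),
            missing %in% MODALITIES)
  if (!is.null(query$modality_genes[[missing]]))
    stop("query already has the '", missing, "' modality")
  mod <- integer(0); word <- integer(0)
  for (mi in seq_along(MODALITIES)) {
    m <- MODALITIES[mi]
    if (m == missing) next
    g <- query$modality_genes[[m]]
    if (is.null(g)) next
    w <- match(g, fit$vocab[[m]])
    w <- w[!is.na(w)]
    mod <- c(mod, rep.int(mi, length(w)))
    word <- c(word, w)
  }
  if (!length(word))
    stop("query has no genes in the training vocabulary")
  if (!is.null(seed)) set.seed(seed)
  theta_q <- gibbs_fold_in_cpp(mod - 1L, word - 1L, fit$K, unname(fit$phi),
                               fit$alpha, as.integer(n_iter), as.integer(burn_in))
  scores <- as.numeric(theta_q %*% fit$phi[[missing]])
  genes <- fit$vocab[[missing]]
  out <- data.frame(gene = genes, modality = missing, score = scores,
                    stringsAsFactors = FALSE)
  src <- rep(list(character(0)), length(genes))
  if (!is.null(corpus)) {
    sets <- modality_sets(corpus, missing)
    sets <- sets[names(sets) != query$disease_id]
    idx <- split(rep(names(sets), lengths(sets)),
                 factor(unlist(sets, use.names = FALSE), levels = genes))
    src <- lapply(idx, unique)
  }
  out$source_diseases <- unname(src)
  out <- out[order(-out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "query_disease") <- query$disease_id
  attr(out, "theta") <- as.numeric(theta_q)
  class(out) <- c("generated_features", "data.frame")
  out
}

# Mann-Whitney AUC of a score against binary labels (ties averaged).
auc_score <- function(scores, labels) {
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Held-out AUC evaluation of missing-modality imputation
#'
#' For `n_eval` diseases carrying all three modalities: remove the
#' disease from the corpus, fit the model on the remainder, then for each
#' modality delete it from the held-out disease, impute it, and compute
#' the AUC of the imputed scores against true membership of the deleted
#' gene set. One fit (excluding all evaluation diseases) is shared by all
#' fold-ins.
#'
#' @inheritParams fit_topic_model
#' @param n_eval Number of evaluation diseases (all three modalities
#'   required; sampled at random among the eligible).
#' @param n_iter,burn_in Gibbs sweeps for the fit (fold-ins use
#'   `n_iter/2`, `burn_in/2`).
#' @return List with `auc` (named per-modality macro-averages), `per_disease`
#'   (data.frame `disease_id`, `modality`, `auc`), and `eval_ids`.
#' @export
evaluate_auc <- function(corpus, K, alpha = 1 / K, beta = 0.01,
                         n_eval = 30, n_iter = 500, burn_in = 250, seed = 1) {
  stopifnot(inherits(corpus, "disease_corpus"))
  eligible <- names(corpus)[vapply(corpus, function(r)
    all(MODALITIES %in% names(r$modality_genes)) &&
      all(lengths(r$modality_genes[MODALITIES]) > 0), logical(1))]
  if (!length(eligible)) stop("no disease carries all three modalities")
  if (!is.null(seed)) set.seed(seed)
  eval_ids <- if (length(eligible) <= n_eval) eligible
              else sample(eligible, n_eval)
  train <- disease_corpus(unname(corpus[setdiff(names(corpus), eval_ids)]))
  fit <- fit_topic_model(train, K = K, alpha = alpha, beta = beta,
                         n_iter = n_iter, burn_in = burn_in, seed = NULL)
  rows <- list()
  for (id in eval_ids) {
    rec <- corpus[[id]]
    for (m in MODALITIES) {
      truth <- rec$modality_genes[[m]]
      qry <- disease_record(rec$disease_id, rec$name,
                            rec$modality_genes[setdiff(names(rec$modality_genes), m)])
      gen <- tryCatch(
        impute_modality(fit, qry, m, n_iter = max(20, n_iter %/% 2),
                        burn_in = max(10, burn_in %/% 2), seed = NULL),
        error = function(e) NULL)
      a <- if (is.null(gen)) NA_real_
           else auc_score(gen$score, gen$gene %in% truth)
      rows[[length(rows) + 1L]] <- data.frame(disease_id = id, modality = m,
                                              auc = a, stringsAsFactors = FALSE)
    }
  }
  per_disease <- do.call(rbind, rows)
  auc <- vapply(stats::setNames(MODALITIES, MODALITIES), function(m)
    mean(per_disease$auc[per_disease$modality == m], na.rm = TRUE), numeric(1))
  list(auc = auc, per_disease = per_disease, eval_ids = eval_ids)
}

#' Diseases excluded by name patterns
#'
#' Case-insensitive substring matching; a trailing wildcard is implicit,
#' so `"Respir"` and `"Pneumo"` behave as prefix-wildcards anywhere in
#' the name.
#'
#' @param corpus A `disease_corpus`.
#' @param patterns Character vector of name fragments.
#' @return Character vector of matching disease ids.
#' @export
name_excluded_diseases <- function(corpus, patterns) {
  if (!length(patterns)) return(character(0))
  nm <- vapply(corpus, function(r) r$name, character(1))
  hit <- Reduce(`|`, lapply(patterns, function(p)
    grepl(p, nm, ignore.case = TRUE, fixed = FALSE)))
  names(corpus)[hit]
}

#' Default disease-name exclusion patterns
#'
#' The respiratory-disease name fragments used to remove obviously
#' query-related source diseases when extracting latent features.
#' @export
DEFAULT_EXCLUSION_PATTERNS <- c("Pulmonary", "Lung", "Fibrosis", "Respir",
                                "Chest", "Pneumo")

#' Extract latent disease features from imputed genes
#'
#' Keeps the top-scoring fraction of the generated ranking, then removes
#' (i) genes already present in any of the query's own modality sets and
#' (ii) features whose source diseases, after dropping diseases matched
#' by the name-exclusion patterns, are empty. Surviving features keep
#' their filtered source-disease sets.
#'
#' @param generated A `generated_features` data.frame from
#'   [impute_modality()] (with source diseases populated).
#' @param query The query `disease_record`.
#' @param corpus The training corpus (for disease names).
#' @param exclusion_patterns See [name_excluded_diseases()].
#' @param top_fraction Fraction in `(0, 1]` of the ranked vocabulary kept.
#' @return Object of class `latent_feature_set`: list with `features`
#'   (data.frame `gene`, `modality`, `score`, list-column
#'   `source_diseases`), `query_disease`, `excluded_diseases`.
#' @export
extract_latent_features <- function(generated, query, corpus,
                                    exclusion_patterns = DEFAULT_EXCLUSION_PATTERNS,
                                    top_fraction = 0.01) {
  stopifnot(inherits(generated, "data.frame"), inherits(query, "disease_record"))
  if (!(top_fraction > 0 && top_fraction <= 1))
    stop("top_fraction must be in (0, 1]")
  gen <- generated[order(-generated$score, generated$gene), , drop = FALSE]
  gen <- utils::head(gen, ceiling(top_fraction * nrow(gen)))
  own <- unique(unlist(query$modality_genes))
  gen <- gen[!(gen$gene %in% own), , drop = FALSE]
  excluded <- name_excluded_diseases(corpus, exclusion_patterns)
  gen$source_diseases <- lapply(gen$source_diseases, setdiff, y = excluded)
  gen <- gen[lengths(gen$source_diseases) > 0L, , drop = FALSE]
  rownames(gen) <- NULL
  structure(list(features = gen, query_disease = query$disease_id,
                 excluded_diseases = excluded),
            class = "latent_feature_set")
}

#' @export
print.latent_feature_set <- function(x, ...) {
  cat("latent_feature_set:", nrow(x$features), "features for query",
      x$query_disease, "(", length(x$excluded_diseases),
      "diseases name-excluded )\n")
  invisible(x)
}

#' Disease relatedness counts from latent features
#'
#' Counts, for each corpus disease, how many latent features list it
#' among their (post-exclusion) source diseases; higher counts mean the
#' disease is more related to the query.
#'
#' @param latent A `latent_feature_set`.
#' @param corpus The corpus (for disease names).
#' @param min_count Optional display filter: keep rows with
#'   `count > min_count` (the published figure uses 20).
#' @return data.frame `disease_id`, `disease_name`, `count`, sorted by
#'   descending count, ties broken by name.
#' @export
disease_relatedness <- function(latent, corpus, min_count = NULL) {
  stopifnot(inherits(latent, "latent_feature_set"))
  src <- unlist(latent$features$source_diseases, use.names = FALSE)
  if (!length(src))
    return(data.frame(disease_id = character(0), disease_name = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  tab <- table(src)
  nm <- vapply(names(tab), function(id)
    if (id %in% names(corpus)) corpus[[id]]$name else id, character(1))
  out <- data.frame(disease_id = names(tab), disease_name = unname(nm),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$disease_name), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(min_count)) out <- out[out$count > min_count, , drop = FALSE]
  out
}
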