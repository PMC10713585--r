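#' @useDynLib crossorgan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Disease-omics modalities
#'
#' The three gene-set modalities attached to each disease: altered
#' expression (`Ae`), biomarker (`Bm`), and genetic variation (`Gv`).
#' @export
MODALITIES <- c("Ae", "Bm", "Gv")

#' Create a disease record
#'
#' A disease record holds one disease and its per-modality gene sets.
#' A modality may be absent (`NULL`), but at least one must be present.
#'
#' @param disease_id Unique identifier string.
#' @param name Human-readable disease name (used by name-based exclusion).
#' @param modality_genes Named list mapping a subset of
#'   `c("Ae","Bm","Gv")` to character vectors of gene symbols.
#' @return An object of class `disease_record`.
#' @export
disease_record <- function(disease_id, name, modality_genes) {
  stopifnot(is.character(disease_id), length(disease_id) == 1L, nzchar(disease_id))
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.list(modality_genes) || length(modality_genes) == 0L)
    stop("at least one modality must be present")
  bad <- setdiff(names(modality_genes), MODALITIES)
  if (length(bad)) stop("unknown modalities: ", paste(bad, collapse = ", "))
  modality_genes <- lapply(modality_genes, function(g) {
    g <- unique(as.character(g))
    if (any(!nzchar(g))) stop("gene symbols must be non-empty strings")
    sort(g)
  })
  if (all(lengths(modality_genes) == 0L))
    stop("at least one modality must contain a gene")
  structure(list(disease_id = disease_id, name = name,
                 modality_genes = modality_genes),
            class = "disease_record")
}

#' Assemble a disease corpus
#'
#' @param records List of [disease_record()] objects with unique ids.
#' @return Object of class `disease_corpus` (a named list of records).
#' @export
disease_corpus <- function(records) {
  stopifnot(length(records) > 0L)
  ids <- vapply(records, function(r) r$disease_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate disease ids")
  names(records) <- ids
  structure(records, class = "disease_corpus")
}

#' @export
print.disease_corpus <- function(x, ...) {
  nmod <- table(unlist(lapply(x, function(r) names(r$modality_genes))))
  cat("disease_corpus:", length(x), "diseases; modality coverage:",
      paste(names(nmod), nmod, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Write / read a disease corpus in GMT-like text form
#'
#' One line per (disease, modality):
#' `disease_id<TAB>name<TAB>modality<TAB>gene1<TAB>gene2...`
#'
#' @param corpus A `disease_corpus`.
#' @param path File path.
#' @return `write_disease_corpus` invisibly returns `path`;
#'   `read_disease_corpus` returns a `disease_corpus`.
#' @export
write_disease_corpus <- function(corpus, path) {
  lines <- unlist(lapply(corpus, function(r) {
    vapply(names(r$modality_genes), function(m) {
      paste(c(r$disease_id, r$name, m, r$modality_genes[[m]]), collapse = "\t")
    }, character(1))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_disease_corpus
#' @export
read_disease_corpus <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  recs <- lapply(split(parts, factor(ids, levels = unique(ids))), function(pp) {
    mg <- lapply(pp, function(p) if (length(p) > 3L) p[-(1:3)] else character(0))
    names(mg) <- vapply(pp, `[`, character(1), 3L)
    disease_record(pp[[1]][1], pp[[1]][2], mg)
  })
  disease_corpus(unname(recs))
}

#' Per-disease gene sets for one modality
#'
#' @param corpus A `disease_corpus`.
#' @param modality One of `MODALITIES`.
#' @return Named list (by disease id) of gene symbol vectors; diseases
#'   lacking the modality are omitted.
#' @export
modality_sets <- function(corpus, modality) {
  stopifnot(modality %in% MODALITIES)
  out <- lapply(corpus, function(r) r$modality_genes[[modality]])
  out[!vapply(out, is.null, logical(1))]
}
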