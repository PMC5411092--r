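#' Read a gene-phenotype annotation corpus
#'
#' Three-column TSV: `gene_id`, `phenotype_id`, `source` with source one of
#' `human`, `mouse`, `zebrafish`. Every phenotype class must exist in the
#' hierarchy.
#'
#' @param path TSV path.
#' @param hierarchy a `pp_hierarchy` to validate against (optional).
#' @return a tibble with columns `gene_id`, `phenotype_id`, `source`.
#' @export
read_annotation_corpus <- function(path, hierarchy = NULL) {
  tb <- read_strict_tsv(path, c("gene_id", "phenotype_id", "source"))
  validate_corpus(tb, hierarchy)
}

validate_corpus <- function(corpus, hierarchy = NULL) {
  corpus <- tibble::as_tibble(corpus)
  bad_src <- setdiff(unique(corpus$source), c("human", "mouse", "zebrafish"))
  if (length(bad_src) > 0) {
    rlang::abort(paste0("Unknown annotation source(s): ",
                        paste(bad_src, collapse = ", ")))
  }
  if (!is.null(hierarchy)) {
    missing <- setdiff(unique(corpus$phenotype_id), hierarchy$nodes)
    if (length(missing) > 0) {
      rlang::abort(paste0("Corpus phenotype classes absent from hierarchy: ",
                          paste(missing, collapse = ", ")))
    }
  }
  corpus
}

#' Information content of phenotype classes over an annotation corpus
#'
#' Annotations are propagated to all ancestors (true-path rule) and
#' `IC(c) = -ln(n_c / N)` in nats, where `n_c` counts genes annotated to `c`
#' directly or by propagation and `N` is the total number of genes in the
#' corpus. Classes no gene reaches receive the corpus minimum frequency
#' `1 / N` (so pairwise similarity is always finite). `IC(root) = 0` and IC
#' is monotone non-decreasing from parent to child.
#'
#' @param corpus tibble (`gene_id`, `phenotype_id`, `source`), see
#'   [read_annotation_corpus()].
#' @param hierarchy a `pp_hierarchy`.
#' @param sources restrict the corpus to these sources before counting
#'   (`"human"`, `"mouse"`, `"zebrafish"`); defaults to all three.
#' @return a `pp_ic` tibble with columns `class_id`, `n_genes`, `ic`.
#' @export
compute_ic <- function(corpus, hierarchy,
                       sources = c("human", "mouse", "zebrafish")) {
  corpus <- validate_corpus(corpus, hierarchy)
  corpus <- corpus[corpus$source %in% sources, ]
  if (nrow(corpus) == 0) {
    rlang::abort("Empty annotation corpus (after source filtering)")
  }
  genes <- unique(corpus$gene_id)
  n_total <- length(genes)
  counts <- stats::setNames(integer(length(hierarchy$nodes)), hierarchy$nodes)
  for (g in genes) {
    direct <- unique(corpus$phenotype_id[corpus$gene_id == g])
    anc <- hierarchy$nodes[colSums(hierarchy$subsumes[direct, , drop = FALSE]) > 0]
    counts[anc] <- counts[anc] + 1L
  }
  ic <- -log(pmax(counts, 1L) / n_total)
  out <- tibble::tibble(class_id = hierarchy$nodes, n_genes = as.integer(counts),
                        ic = unname(ic))
  attr(out, "n_total_genes") <- n_total
  class(out) <- c("pp_ic", class(out))
  out
}

ic_vector <- function(ic) stats::setNames(ic$ic, ic$class_id)

#' Resnik pairwise similarity
#'
#' The information content of the most informative common ancestor (MICA) of
#' two classes, each counted among its own ancestors.
#'
#' @param c1,c2 phenotype class IDs.
#' @param ic a `pp_ic` table from [compute_ic()].
#' @param hierarchy a `pp_hierarchy`.
#' @return non-negative similarity in nats.
#' @export
resnik_pairwise <- function(c1, c2, ic, hierarchy) {
  for (cc in c(c1, c2)) {
    if (!cc %in% hierarchy$nodes) {
      rlang::abort(paste0("Unknown phenotype class: '", cc, "'"))
    }
  }
  common <- hierarchy$subsumes[c1, ] & hierarchy$subsumes[c2, ]
  max(ic_vector(ic)[hierarchy$nodes[common]])
}

# Full class-by-class Resnik matrix; built once per world and reused by the
# cohort pipeline (max-accumulation over each ancestor's IC).
resnik_matrix <- function(ic, hierarchy) {
  icv <- ic_vector(ic)[hierarchy$nodes]
  n <- length(hierarchy$nodes)
  m <- matrix(0, n, n, dimnames = list(hierarchy$nodes, hierarchy$nodes))
  ord <- order(icv) # ascending: later (more informative) ancestors overwrite
  for (k in ord) {
    desc <- hierarchy$subsumes[, k]
    if (any(desc)) m[desc, desc] <- icv[[k]]
  }
  m
}

#' Best-matching-average (BMA) profile similarity
#'
#' Symmetric two-direction best-match average:
#' `BMA(p, g) = (mean_x max_y res(x, y) + mean_y max_x res(x, y)) / 2`
#' over `x` in `p`, `y` in `g`.
#'
#' @param p,g non-empty character vectors of phenotype class IDs.
#' @param ic a `pp_ic` table.
#' @param hierarchy a `pp_hierarchy`.
#' @param res optional precomputed Resnik matrix (class x class).
#' @return non-negative similarity.
#' @export
bma_similarity <- function(p, g, ic, hierarchy, res = NULL) {
  if (length(p) == 0 || length(g) == 0) {
    rlang::abort("BMA similarity requires two non-empty phenotype sets")
  }
  if (is.null(res)) {
    pm <- outer(p, g, Vectorize(function(a, b) resnik_pairwise(a, b, ic, hierarchy)))
  } else {
    pm <- res[p, g, drop = FALSE]
  }
  (mean(apply(pm, 1, max)) + mean(apply(pm, 2, max))) / 2
}

#' Normalize per-profile gene similarity scores to \[0, 1\]
#'
#' Divides each gene's raw similarity by the maximum over genes for the
#' profile, so the best-matching gene maps to 1. If the maximum is zero all
#' values map to zero.
#'
#' @param raw a tibble with columns `gene_id`, `raw`, or a named numeric
#'   vector.
#' @return a tibble with columns `gene_id`, `raw`, `normalized`.
#' @export
normalize_profile_scores <- function(raw) {
  if (is.numeric(raw)) {
    raw <- tibble::tibble(gene_id = names(raw), raw = unname(raw))
  }
  raw <- tibble::as_tibble(raw)
  if (nrow(raw) == 0) rlang::abort("No gene scores to normalize")
  mx <- max(raw$raw)
  raw$normalized <- if (mx > 0) raw$raw / mx else 0
  raw
}

#' Similarity between a patient profile and every gene in the corpus
#'
#' Filters the corpus to the active source configuration, pools each gene's
#' remaining annotations into one set, computes BMA Resnik similarity against
#' the profile, and normalizes per profile. The three canonical
#' configurations are `sources = "human"` (known disease genes),
#' `sources = c("mouse", "zebrafish")` (model organisms only) and all three
#' together.
#'
#' @param profile character vector of phenotype class IDs (non-empty).
#' @param corpus annotation corpus tibble.
#' @param ic a `pp_ic` table computed under the same source configuration.
#' @param hierarchy a `pp_hierarchy`.
#' @param sources active annotation sources.
#' @param res optional precomputed Resnik matrix.
#' @return a tibble `gene_id`, `raw`, `normalized` (one row per gene with
#'   annotations under the configuration).
#' @export
profile_gene_similarity <- function(profile, corpus, ic, hierarchy,
                                    sources = c("human", "mouse", "zebrafish"),
                                    res = NULL) {
  if (length(profile) == 0) rlang::abort("Empty phenotype profile")
  missing <- setdiff(profile, hierarchy$nodes)
  if (length(missing) > 0) {
    rlang::abort(paste0("Profile classes absent from hierarchy: ",
                        paste(missing, collapse = ", ")))
  }
  corpus <- corpus[corpus$source %in% sources, ]
  if (nrow(corpus) == 0) rlang::abort("No annotations under the active sources")
  gene_sets <- split(corpus$phenotype_id, corpus$gene_id)
  raw <- vapply(
    gene_sets,
    function(g) bma_similarity(profile, unique(g), ic, hierarchy, res = res),
    numeric(1)
  )
  normalize_profile_scores(raw)
}
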