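#' The 60-feature variant representation
#'
#' Each (variant, patient-profile) pair is represented by 60 features, in
#' this fixed serialization order:
#'
#' 1. `score_1`, `score_2`, `score_3` — the three pathogenicity scores
#'    (missing values allowed; imputed at model time);
#' 2. `zygosity` — `1` het, `2` hom;
#' 3. `moi` — mode of inheritance of the presented disease/profile:
#'    `1` Dominant, `2` Recessive, `3` X-linked, `4` Other;
#' 4. `flag_01` ... `flag_54` — binary indicators, flag `k` set iff any
#'    profile class is subsumed (reflexively) by the k-th high-level panel
#'    class;
#' 5. `similarity` — the normalized phenotype similarity in \[0, 1\] between
#'    the profile and the variant's (closest) gene.
#'
#' @return character vector of the 60 feature names in order.
#' @export
feature_names <- function() {
  c("score_1", "score_2", "score_3", "zygosity", "moi",
    sprintf("flag_%02d", 1:54), "similarity")
}

zygosity_code <- function(genotype) {
  if (any(!genotype %in% c("het", "hom"))) {
    rlang::abort("Uncalled genotypes must be filtered before feature building")
  }
  ifelse(genotype == "hom", 2L, 1L)
}

moi_code <- function(moi) {
  moi[is.na(moi)] <- "Other"
  m <- match(moi, moi_levels())
  if (anyNA(m)) {
    rlang::abort(paste0("Unknown MOI value(s): ",
                        paste(unique(moi[is.na(m)]), collapse = ", ")))
  }
  m
}

#' Derive a high-level phenotype panel from a hierarchy
#'
#' For real vocabularies the panel is the curated list of upper-level
#' phenotype classes; for generated worlds it is derived from the hierarchy
#' by breadth-first order from the root (shallow, broad classes first),
#' truncated to `size` or padded by repeating the root (a constant flag,
#' harmless to the classifier).
#'
#' @param hierarchy a `pp_hierarchy`.
#' @param size panel length (the classifier expects 54).
#' @return character vector of `size` class IDs.
#' @export
derive_panel <- function(hierarchy, size = 54L) {
  # breadth-first over the edge list, root first
  lvl <- stats::setNames(rep(NA_integer_, length(hierarchy$nodes)), hierarchy$nodes)
  lvl[hierarchy$root] <- 0L
  frontier <- hierarchy$root
  while (length(frontier) > 0) {
    kids <- hierarchy$edges$child[hierarchy$edges$parent %in% frontier]
    kids <- kids[is.na(lvl[kids])]
    kids <- unique(kids)
    if (length(kids) == 0) break
    lvl[kids] <- lvl[frontier[1]] + 1L
    frontier <- kids
  }
  ord <- order(lvl, hierarchy$nodes, na.last = TRUE)
  panel <- hierarchy$nodes[ord]
  panel <- panel[!is.na(lvl[panel])]
  panel <- setdiff(panel, hierarchy$root)
  panel <- c(panel, rep(hierarchy$root, max(0, size - length(panel))))
  panel[seq_len(size)]
}

#' High-level phenotype flags for a profile
#'
#' Flag `k` is 1 iff any profile class is subsumed by panel class `k`
#' (reflexive closure).
#'
#' @param profile character vector of phenotype class IDs.
#' @param hierarchy a `pp_hierarchy`.
#' @param panel character vector of exactly 54 class IDs.
#' @return integer vector of length 54 named `flag_01..flag_54`.
#' @export
toplevel_phenotype_flags <- function(profile, hierarchy, panel) {
  if (length(panel) != 54) {
    rlang::abort(paste0("Panel must contain exactly 54 classes, got ",
                        length(panel)))
  }
  missing <- setdiff(c(profile, panel), hierarchy$nodes)
  if (length(missing) > 0) {
    rlang::abort(paste0("Classes absent from hierarchy: ",
                        paste(missing, collapse = ", ")))
  }
  sub <- hierarchy$subsumes[profile, panel, drop = FALSE]
  stats::setNames(as.integer(colSums(sub) > 0), sprintf("flag_%02d", 1:54))
}

#' Build feature vectors for variants against a patient profile
#'
#' Produces one 60-feature row per variant (see [feature_names()]) plus the
#' identifying metadata columns `chrom`, `pos`, `ref`, `alt`, `gene`. The
#' similarity feature is the profile's normalized similarity to the
#' variant's assigned gene, 0 when the variant is unassigned or its gene has
#' no phenotype annotations under the active sources. Missing pathogenicity
#' scores stay missing (imputed by the model). `build_features()` is a pure
#' function of its inputs.
#'
#' @param variants a `pp_variants` tibble with called genotypes and gene
#'   assignments.
#' @param profile character vector of phenotype class IDs.
#' @param sim normalized gene-similarity tibble from
#'   [profile_gene_similarity()].
#' @param panel 54-class panel.
#' @param hierarchy a `pp_hierarchy`.
#' @param moi mode of inheritance presented with the profile (default
#'   `"Other"` when unknown).
#' @return a tibble: metadata columns then the 60 features.
#' @export
build_features <- function(variants, profile, sim, panel, hierarchy,
                           moi = "Other") {
  flags <- toplevel_phenotype_flags(profile, hierarchy, panel)
  simv <- stats::setNames(sim$normalized, sim$gene_id)
  gene_sim <- ifelse(is.na(variants$gene), 0,
                     unname(simv[variants$gene]))
  gene_sim[is.na(gene_sim)] <- 0
  out <- tibble::tibble(
    chrom = variants$chrom, pos = variants$pos,
    ref = variants$ref, alt = variants$alt, gene = variants$gene,
    score_1 = variants$score_1, score_2 = variants$score_2,
    score_3 = variants$score_3,
    zygosity = zygosity_code(variants$genotype),
    moi = moi_code(rep(moi, nrow(variants)))
  )
  for (k in seq_along(flags)) out[[names(flags)[k]]] <- unname(flags[k])
  out$similarity <- gene_sim
  out
}
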