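# Independent brute-force oracles used to validate the reasoner, the
# similarity engine and the AUC estimator. These deliberately share no code
# with the package internals: reachability comes from igraph, everything else
# is direct enumeration.

oracle_reach <- function(ontology, use_partof = FALSE) {
  edges <- rbind(
    as.matrix(ontology$isa[, c("child", "parent")]),
    if (use_partof) as.matrix(ontology$partof[, c("part", "whole")])
  )
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges), directed = TRUE,
    vertices = data.frame(name = ontology$classes)
  )
  d <- igraph::distances(g, mode = "out")
  is.finite(d)[ontology$classes, ontology$classes, drop = FALSE]
}

oracle_reaches <- function(mat, child, parent) {
  if (parent == "owl:Thing") return(TRUE)
  if (child == "owl:Thing") return(FALSE)
  mat[child, parent]
}

# Pairwise subsumption decision, written independently from the package's
# eq_subsumed_by: same stated rules, different machinery.
oracle_pair <- function(child, parent, isa, both) {
  ent <- if (parent$E$wrapped) {
    parent$E$class == "owl:Thing" ||
      oracle_reaches(both, child$E$class, parent$E$class)
  } else {
    parent$E$class == "owl:Thing" ||
      (!child$E$wrapped && oracle_reaches(isa, child$E$class, parent$E$class))
  }
  if (!ent) return(FALSE)
  if (!oracle_reaches(isa, child$Q$class, parent$Q$class)) return(FALSE)
  match_quals <- function(cq, pq) {
    if (nrow(pq) == 0) return(TRUE)
    all(vapply(seq_len(nrow(pq)), function(k) {
      m <- if (pq$relation[k] == "part-of") both else isa
      any(cq$relation == pq$relation[k] &
            vapply(cq$filler, oracle_reaches, logical(1), mat = m,
                   parent = pq$filler[k])[cq$relation == pq$relation[k]])
    }, logical(1)))
  }
  match_quals(child$E$quals, parent$E$quals) &&
    match_quals(child$Q$mods, parent$Q$mods)
}

# Full subsumption relation by O(n^2) pairwise decisions plus a fixed-point
# pass for has-part intersections and transitivity.
oracle_subsumption <- function(defs, ontology) {
  isa <- oracle_reach(ontology, use_partof = FALSE)
  both <- oracle_reach(ontology, use_partof = TRUE)
  ids <- names(defs)
  n <- length(ids)
  m <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in ids) {
    for (j in ids) m[i, j] <- oracle_pair(defs[[i]], defs[[j]], isa, both)
  }
  for (d in defs) {
    for (p in d$parts) if (p %in% ids) m[d$id, p] <- TRUE
  }
  repeat {
    changed <- FALSE
    for (i in ids) {
      up <- ids[m[i, ]]
      more <- unique(unlist(lapply(up, function(j) ids[m[j, ]])))
      new <- setdiff(more, ids[m[i, ]])
      if (length(new)) { m[i, new] <- TRUE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Flatten a definition list exactly like infer_hierarchy does (including the
# implicit root), so oracle and implementation describe the same node set.
flatten_defs <- function(definitions) {
  defs <- list()
  push <- function(d) {
    if (is.null(defs[[d$id]])) defs[[d$id]] <- d
    for (p in attr(d, "part_defs") %||% list()) defs <- push(p)
    defs
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  for (d in definitions) defs <- push(d)
  if (is.null(defs[[pheno_root()]])) {
    root <- structure(list(
      id = pheno_root(),
      E = list(class = "owl:Thing", wrapped = TRUE,
               quals = tibble::tibble(relation = character(), filler = character())),
      Q = list(class = "owl:Thing",
               mods = tibble::tibble(relation = character(), filler = character())),
      abstract = FALSE, parts = character()
    ), class = "pp_eq")
    defs[[pheno_root()]] <- root
  }
  lapply(defs, function(d) { attr(d, "part_defs") <- NULL; d })
}

# IC by direct counting over an oracle ancestor matrix (rows = class,
# cols = ancestor; from oracle_subsumption), independent of the package's
# subsumes matrix and edge output.
oracle_ic <- function(corpus, anc) {
  nodes <- rownames(anc)
  anc_of <- function(cls) nodes[anc[cls, ]]
  genes <- unique(corpus$gene_id)
  n <- length(genes)
  vapply(nodes, function(cl) {
    cnt <- sum(vapply(genes, function(gn) {
      direct <- corpus$phenotype_id[corpus$gene_id == gn]
      cl %in% unique(unlist(lapply(direct, anc_of)))
    }, logical(1)))
    -log(max(cnt, 1) / n)
  }, numeric(1))
}

oracle_resnik <- function(c1, c2, icv, anc) {
  nodes <- rownames(anc)
  max(icv[intersect(nodes[anc[c1, ]], nodes[anc[c2, ]])])
}

oracle_bma <- function(p, g, icv, anc) {
  pm <- matrix(0, length(p), length(g))
  for (i in seq_along(p)) {
    for (j in seq_along(g)) {
      pm[i, j] <- oracle_resnik(p[i], g[j], icv, anc)
    }
  }
  (mean(apply(pm, 1, max)) + mean(apply(pm, 2, max))) / 2
}

oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
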