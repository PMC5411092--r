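#' Infer the phenotype subsumption hierarchy
#'
#' A restricted reasoner for the fragment produced by the phene-pattern
#' rewriting rules. A phenotype `P1 = (E1, Q1)` is subsumed by
#' `P2 = (E2, Q2)` iff
#'
#' * **entity**: when `E2` is part-of-wrapped (abstract S-classes,
#'   `inheres-in-part-of` definitions), `E1`'s class must reach `E2`'s class
#'   under the reflexive-transitive closure of is-a and part-of edges;
#'   otherwise `E1` must be unwrapped and reach `E2` under the is-a closure
#'   alone;
#' * **quality**: `Q1`'s class reaches `Q2`'s class under the quality is-a
#'   closure; and
#' * **qualifiers**: every qualifier/modifier conjunct of the parent is
#'   matched by a child conjunct with the same relation whose filler reaches
#'   the parent's (so a conjunct may be absent in the parent, or subsume the
#'   child's; a parent conjunct with no child counterpart blocks
#'   subsumption). `part-of` qualifier fillers are compared under the
#'   is-a + part-of closure, all others under is-a alone.
#'
#' `has-part` intersections additionally force the phenotype under each of
#' its part-definitions' classes. The emitted edge set is the transitive
#' reduction of the inferred relation; mutually subsuming classes are
#' canonicalized under a representative so the edges remain a DAG. Every
#' class reaches the universal phenotype root.
#'
#' @param definitions list of `pp_eq` definitions (e.g. from
#'   [rewrite_axiom()], [generate_abstract_class()],
#'   [make_zebrafish_class()]). Each definition may carry nested part
#'   definitions in its `part_defs` attribute; these are folded in.
#' @param ontology the grounding `pp_ontology`.
#' @return a `pp_hierarchy`: list with `nodes`, `edges`
#'   (tibble `child`, `parent`: the transitive reduction), `root`, `subsumes`
#'   (logical matrix, `subsumes[i, j]` iff class `i` is subsumed by class
#'   `j`, reflexive), and `defs`.
#' @export
infer_hierarchy <- function(definitions, ontology) {
  defs <- list()
  push <- function(d) {
    if (is.null(defs[[d$id]])) defs[[d$id]] <<- d
    for (p in attr(d, "part_defs") %||% list()) push(p)
  }
  for (d in definitions) push(d)
  root_id <- pheno_root()
  if (is.null(defs[[root_id]])) {
    root_def <- eq_definition(root_id, ont_top(), ont_top(), e_wrapped = TRUE)
    defs[[root_id]] <- root_def
  }
  defs <- lapply(defs, function(d) { attr(d, "part_defs") <- NULL; d })

  isa_cl <- ont_closure(ontology, use_partof = FALSE)
  both_cl <- ont_closure(ontology, use_partof = TRUE)

  ids <- names(defs)
  n <- length(ids)
  sub <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      sub[i, j] <- eq_subsumed_by(defs[[ids[i]]], defs[[ids[j]]], isa_cl, both_cl)
    }
  }
  # has-part intersections: P below each part class, then re-close.
  for (d in defs) {
    for (p in d$parts) if (p %in% ids) sub[d$id, p] <- TRUE
  }
  sub <- bool_transitive_closure(sub)

  structure(
    list(
      nodes = ids,
      edges = subsumption_edges(sub),
      root = root_id,
      subsumes = sub,
      defs = defs
    ),
    class = "pp_hierarchy"
  )
}

#' @export
print.pp_hierarchy <- function(x, ...) {
  cat("<pp_hierarchy> ", length(x$nodes), " classes, ", nrow(x$edges),
      " edges, root ", x$root, "\n", sep = "")
  invisible(x)
}

#' @rdname infer_hierarchy
#' @export
pheno_root <- function() "PHENO:root"

# Decision procedure for one ordered pair: is `child` subsumed by `parent`?
eq_subsumed_by <- function(child, parent, isa_cl, both_cl) {
  # entity
  if (parent$E$class == ont_top() && parent$E$wrapped) {
    ent_ok <- TRUE
  } else if (parent$E$wrapped) {
    ent_ok <- reaches(both_cl, child$E$class, parent$E$class)
  } else {
    ent_ok <- !child$E$wrapped && reaches(isa_cl, child$E$class, parent$E$class)
  }
  if (!ent_ok) return(FALSE)
  # quality
  if (!reaches(isa_cl, child$Q$class, parent$Q$class)) return(FALSE)
  quals_compatible(child$E$quals, parent$E$quals, isa_cl, both_cl) &&
    quals_compatible(child$Q$mods, parent$Q$mods, isa_cl, both_cl)
}

# Every parent conjunct must be matched by a child conjunct of the same
# relation whose filler reaches the parent's filler.
quals_compatible <- function(child_q, parent_q, isa_cl, both_cl) {
  if (nrow(parent_q) == 0) return(TRUE)
  for (k in seq_len(nrow(parent_q))) {
    rel <- parent_q$relation[[k]]
    fil <- parent_q$filler[[k]]
    cl <- if (rel == "part-of") both_cl else isa_cl
    cand <- child_q$filler[child_q$relation == rel]
    if (!any(vapply(cand, function(cf) reaches(cl, cf, fil), logical(1)))) {
      return(FALSE)
    }
  }
  TRUE
}

bool_transitive_closure <- function(m) {
  repeat {
    nxt <- m | ((m %*% m) > 0)
    if (identical(nxt, m)) return(m)
    m <- nxt
  }
}

# Turn a reflexive subsumption matrix into a DAG edge list: collapse
# equivalence groups (mutual subsumption) under a lexicographically smallest
# representative, transitively reduce the strict relation between
# representatives, then attach non-representative members to their
# representative.
subsumption_edges <- function(sub) {
  ids <- rownames(sub)
  equiv <- sub & t(sub)
  rep_of <- vapply(ids, function(i) min(ids[equiv[i, ]]), character(1))
  reps <- unique(rep_of)
  strict <- sub[reps, reps, drop = FALSE] & !t(sub[reps, reps, drop = FALSE])
  # transitive reduction: drop edges implied through an intermediate node
  implied <- (strict %*% strict) > 0
  reduced <- strict & !implied
  e_child <- character(0)
  e_parent <- character(0)
  if (length(reps) > 1) {
    w <- which(reduced, arr.ind = TRUE)
    e_child <- reps[w[, 1]]
    e_parent <- reps[w[, 2]]
  }
  dup <- ids[rep_of != ids]
  tibble::tibble(
    child = c(e_child, dup),
    parent = c(e_parent, rep_of[dup])
  )
}

#' Ancestors of a phenotype class
#'
#' @param hierarchy a `pp_hierarchy`.
#' @param class_id a phenotype class ID.
#' @param include_self include the class itself (reflexive closure)?
#' @return character vector of ancestor class IDs.
#' @export
pheno_ancestors <- function(hierarchy, class_id, include_self = TRUE) {
  if (!class_id %in% hierarchy$nodes) {
    rlang::abort(paste0("Unknown phenotype class: '", class_id, "'"))
  }
  anc <- hierarchy$nodes[hierarchy$subsumes[class_id, ]]
  if (!include_self) anc <- setdiff(anc, class_id)
  anc
}

#' Write / read an inferred hierarchy as TSV
#'
#' The hierarchy is externalized as an edge list (`child`, `parent`) plus a
#' class-metadata table (`class_id`, `abstract`, `entity`, `wrapped`,
#' `quality`).
#'
#' @param hierarchy a `pp_hierarchy`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_hierarchy <- function(hierarchy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_plain(hierarchy$edges, file.path(dir, "hierarchy_edges.tsv"))
  meta <- tibble::tibble(
    class_id = hierarchy$nodes,
    abstract = vapply(hierarchy$defs, function(d) d$abstract, logical(1)),
    entity = vapply(hierarchy$defs, function(d) d$E$class, character(1)),
    wrapped = vapply(hierarchy$defs, function(d) d$E$wrapped, logical(1)),
    quality = vapply(hierarchy$defs, function(d) d$Q$class, character(1))
  )
  write_tsv_plain(meta, file.path(dir, "hierarchy_classes.tsv"))
  invisible(dir)
}

#' Tidy a phenotype hierarchy into its edge list
#'
#' @param x a `pp_hierarchy`.
#' @param ... unused.
#' @return a tibble with columns `child`, `parent`.
#' @method tidy pp_hierarchy
#' @export
tidy.pp_hierarchy <- function(x, ...) x$edges

#' @method glance pp_hierarchy
#' @export
glance.pp_hierarchy <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$nodes),
    n_edges = nrow(x$edges),
    n_abstract = sum(vapply(x$defs, function(d) d$abstract, logical(1))),
    root = x$root
  )
}
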