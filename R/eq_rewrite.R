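#' EQ phenotype definitions and the phene-pattern rewriting rules
#'
#' Every phenotype class is normalized to the phene pattern
#' `P EquivalentTo: has-part some (E and has-quality some Q)`: an affected
#' entity `E` (anatomical structure or process, possibly wrapped in
#' `part-of` and extended by qualifier conjuncts) bearing a quality `Q`
#' (possibly extended by modifier conjuncts). [rewrite_axiom()] turns a raw
#' conjunct list into this normal form; [generate_abstract_class()] and
#' [make_zebrafish_class()] mint the additional classes the integrated
#' ontology needs.
#'
#' @name eq-definitions
NULL

eq_relations <- c(
  "modifier", "inheres-in", "inheres-in-part-of", "towards", "has-quality",
  "exists-during", "has-part", "part-of", "has-central-participant",
  "results-from", "occurs-in"
)

qual_tb <- function(relation = character(), filler = character()) {
  tibble::tibble(relation = as.character(relation), filler = as.character(filler))
}

# Internal constructor for a normalized EQ definition.
eq_definition <- function(id, e_class, q_class,
                          e_wrapped = FALSE,
                          e_quals = qual_tb(),
                          q_mods = qual_tb(),
                          abstract = FALSE,
                          parts = character()) {
  structure(
    list(
      id = id,
      E = list(class = e_class, wrapped = e_wrapped, quals = e_quals),
      Q = list(class = q_class, mods = q_mods),
      abstract = abstract,
      parts = parts
    ),
    class = "pp_eq"
  )
}

#' @export
print.pp_eq <- function(x, ...) {
  ewrap <- if (x$E$wrapped) paste0("part-of(", x$E$class, ")") else x$E$class
  equal <- if (nrow(x$E$quals)) {
    paste0(" and ", paste(x$E$quals$relation, x$E$quals$filler, collapse = " and "))
  } else ""
  qmod <- if (nrow(x$Q$mods)) {
    paste0(" and ", paste(x$Q$mods$relation, x$Q$mods$filler, collapse = " and "))
  } else ""
  cat("<pp_eq> ", x$id, if (x$abstract) " [abstract]" else "",
      "\n  E: ", ewrap, equal, "\n  Q: ", x$Q$class, qmod, "\n", sep = "")
  if (length(x$parts)) cat("  parts:", paste(x$parts, collapse = ", "), "\n")
  invisible(x)
}

# Stable textual normal form, used to hash generated class IDs so repeated
# builds are bit-identical.
eq_signature <- function(def) {
  qs <- function(tb) {
    if (nrow(tb) == 0) return("")
    ord <- order(tb$relation, tb$filler)
    paste(tb$relation[ord], tb$filler[ord], sep = "=", collapse = ";")
  }
  paste0(
    "E:", def$E$class, "|w:", as.integer(def$E$wrapped), "|eq:", qs(def$E$quals),
    "|Q:", def$Q$class, "|qm:", qs(def$Q$mods), "|abs:", as.integer(def$abstract)
  )
}

eq_hash_id <- function(prefix, def) {
  paste0(prefix, ":", substr(digest::digest(eq_signature(def), algo = "sha1"), 1, 12))
}

check_filler <- function(filler, ontology) {
  if (filler == ont_top()) return(invisible(TRUE))
  if (!filler %in% ontology$classes) {
    rlang::abort(paste0("Unresolvable filler: '", filler, "' is not a declared class"))
  }
  invisible(TRUE)
}

#' Rewrite a raw EQ axiom into the phene pattern
#'
#' Applies the rewriting rules to the conjuncts of a raw phenotype
#' definition, left to right in input order, starting from
#' `E = Q = owl:Thing`:
#'
#' * `modifier X` — attach `X` as a modifier of `Q`;
#' * `inheres-in X` — set `E`'s class to `X`;
#' * `inheres-in-part-of X` — set `E` to `part-of X`;
#' * `has-quality X` — the first occurrence sets `Q`'s class (the primary
#'   quality of the phene pattern); later occurrences attach to `E` as
#'   qualifier conjuncts;
#' * `towards`, `exists-during`, `part-of`, `has-central-participant`,
#'   `results-from`, `occurs-in` with filler `X` — attach `(relation, X)` to
#'   `E` as a qualifier conjunct;
#' * `has-part X1 ... has-part Xn` — treated as an intersection: each filler
#'   is rewritten recursively and the phenotype is subsumed by each
#'   conjunct's phenotype class.
#'
#' Repeated applications of the same attachment rule compose by conjunction.
#' An unknown relation, or a filler that does not resolve against the entity
#' ontology, is an error naming the offender.
#'
#' @param raw a list with elements `phenotype_id` (class ID) and `conjuncts`
#'   (tibble with columns `relation`, `filler`; zero rows allowed). For
#'   `has-part` conjuncts the filler may name an expression in `expressions`.
#' @param ontology a `pp_ontology` the fillers resolve against.
#' @param expressions named list of nested conjunct tibbles referenced by
#'   `has-part` fillers.
#' @return a `pp_eq` definition; nested `has-part` conjuncts are returned in
#'   the `part_defs` attribute as a list of `pp_eq`.
#' @export
rewrite_axiom <- function(raw, ontology, expressions = list()) {
  conj <- tibble::as_tibble(raw$conjuncts)
  def <- eq_definition(raw$phenotype_id, ont_top(), ont_top())
  part_defs <- list()
  q_set <- FALSE
  for (k in seq_len(nrow(conj))) {
    rel <- conj$relation[[k]]
    fil <- conj$filler[[k]]
    if (!rel %in% eq_relations) {
      rlang::abort(paste0("Unknown relation: '", rel, "'"))
    }
    if (rel == "has-part") {
      if (fil %in% names(expressions)) {
        sub_raw <- list(
          phenotype_id = paste0(raw$phenotype_id, "/part", length(part_defs) + 1),
          conjuncts = expressions[[fil]]
        )
      } else {
        check_filler(fil, ontology)
        sub_raw <- list(
          phenotype_id = paste0(raw$phenotype_id, "/part", length(part_defs) + 1),
          conjuncts = qual_tb("inheres-in", fil)
        )
      }
      sub <- rewrite_axiom(sub_raw, ontology, expressions)
      sub$id <- eq_hash_id("PART", sub)
      part_defs <- c(part_defs, list(sub), attr(sub, "part_defs"))
      attr(sub, "part_defs") <- NULL
      def$parts <- c(def$parts, sub$id)
      next
    }
    check_filler(fil, ontology)
    if (rel == "modifier") {
      def$Q$mods <- rbind(def$Q$mods, qual_tb("modifier", fil))
    } else if (rel == "inheres-in") {
      def$E$class <- fil
      def$E$wrapped <- FALSE
    } else if (rel == "inheres-in-part-of") {
      def$E$class <- fil
      def$E$wrapped <- TRUE
    } else if (rel == "has-quality") {
      if (!q_set) {
        def$Q$class <- fil
        q_set <- TRUE
      } else {
        def$E$quals <- rbind(def$E$quals, qual_tb("has-quality", fil))
      }
    } else {
      def$E$quals <- rbind(def$E$quals, qual_tb(rel, fil))
    }
  }
  attr(def, "part_defs") <- part_defs
  def
}

#' Generate the abstract parthood (S-) class for an entity
#'
#' For each distinct entity `E` occurring in a rewritten definition an
#' additional abstract class `S` is minted with
#' `S EquivalentTo: has-part some (part-of some (E and has-quality some
#' owl:Thing))`. These classes are absent from the source vocabularies and
#' exist purely to make the phenotype hierarchy follow the parthood structure
#' of the anatomy/physiology ontologies: every concrete phenotype whose
#' entity is part of some whole `E` becomes a subclass of `S(E)`.
#'
#' The class ID is a deterministic hash of the normalized definition, so the
#' call is idempotent: the same `E` always yields the same class.
#'
#' @param e_class entity class ID (or `owl:Thing`).
#' @param ontology a `pp_ontology`.
#' @return an abstract `pp_eq` definition.
#' @export
generate_abstract_class <- function(e_class, ontology) {
  check_filler(e_class, ontology)
  def <- eq_definition(
    id = "pending", e_class = e_class, q_class = ont_top(),
    e_wrapped = TRUE, abstract = TRUE
  )
  def$id <- eq_hash_id("S", def)
  def
}

#' Generate a phenotype class from a zebrafish-style direct EQ annotation
#'
#' Zebrafish phenotypes are annotated with entity and quality classes
#' directly rather than through a precomposed phenotype vocabulary; one
#' phenotype class is minted per unique combination. With a second entity
#' `E2` the pattern is
#' `has-part some (E1 and has-quality some (Q and towards some E2))`.
#'
#' @param e1 affected entity class ID.
#' @param q quality class ID.
#' @param e2 optional second entity (the `towards` target).
#' @param ontology a `pp_ontology`.
#' @return a `pp_eq` definition; identical `(E1, Q, E2)` combinations yield
#'   identical class IDs.
#' @export
make_zebrafish_class <- function(e1, q, e2 = NULL, ontology) {
  check_filler(e1, ontology)
  check_filler(q, ontology)
  mods <- qual_tb()
  if (!is.null(e2)) {
    check_filler(e2, ontology)
    mods <- qual_tb("towards", e2)
  }
  def <- eq_definition(id = "pending", e_class = e1, q_class = q, q_mods = mods)
  def$id <- eq_hash_id("ZP", def)
  def
}

#' Read raw EQ axioms from a TSV
#'
#' Expects columns `phenotype_id`, `relation`, `filler`, one conjunct per
#' row; conjunct order within a phenotype follows row order. Rows whose
#' `phenotype_id` starts with `expr:` define nested expressions referenced by
#' `has-part` fillers rather than phenotype classes of their own.
#'
#' @param path TSV path.
#' @return a list with elements `raw` (named list of raw axioms, one per
#'   phenotype) and `expressions` (named list of conjunct tibbles).
#' @export
read_eq_axioms <- function(path) {
  tb <- read_strict_tsv(path, c("phenotype_id", "relation", "filler"))
  is_expr <- startsWith(tb$phenotype_id, "expr:")
  split_conj <- function(d) {
    ids <- unique(d$phenotype_id)
    stats::setNames(
      lapply(ids, function(id) d[d$phenotype_id == id, c("relation", "filler")]),
      ids
    )
  }
  expressions <- split_conj(tb[is_expr, ])
  groups <- split_conj(tb[!is_expr, ])
  raw <- lapply(names(groups), function(id) {
    list(phenotype_id = id, conjuncts = groups[[id]])
  })
  names(raw) <- names(groups)
  list(raw = raw, expressions = expressions)
}
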