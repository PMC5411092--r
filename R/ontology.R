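#' Construct an entity ontology
#'
#' An entity ontology holds the anatomy/physiology/quality classes that ground
#' phenotype definitions: a set of class IDs, is-a edges and part-of edges.
#' The union of the two edge sets must form a DAG and every edge endpoint must
#' be a declared class. The universal top class `"owl:Thing"` is implicit: it
#' subsumes every class and need not be declared.
#'
#' @param classes character vector of class IDs.
#' @param isa tibble/data frame with columns `child`, `parent` (is-a edges).
#' @param partof tibble/data frame with columns `part`, `whole` (part-of
#'   edges).
#' @param disjoint optional tibble with columns `a`, `b` recording
#'   disjointness declarations (kept only so [strip_disjointness()] has
#'   something to strip).
#' @return an object of class `pp_ontology`.
#' @export
entity_ontology <- function(classes, isa = NULL, partof = NULL, disjoint = NULL) {
  empty2 <- function(nm) {
    tb <- tibble::tibble(a = character(), b = character())
    names(tb) <- nm
    tb
  }
  isa <- if (is.null(isa)) empty2(c("child", "parent")) else tibble::as_tibble(isa)
  partof <- if (is.null(partof)) empty2(c("part", "whole")) else tibble::as_tibble(partof)
  disjoint <- if (is.null(disjoint)) empty2(c("a", "b")) else tibble::as_tibble(disjoint)
  classes <- unique(as.character(classes))
  endpoints <- c(isa$child, isa$parent, partof$part, partof$whole)
  undeclared <- setdiff(setdiff(endpoints, ont_top()), classes)
  if (length(undeclared) > 0) {
    rlang::abort(paste0(
      "Edge endpoints not declared as classes: ",
      paste(undeclared, collapse = ", ")
    ))
  }
  ont <- structure(
    list(classes = classes, isa = isa, partof = partof, disjoint = disjoint),
    class = "pp_ontology"
  )
  cyc <- find_cycle(ont)
  if (!is.null(cyc)) {
    rlang::abort(paste0(
      "is-a/part-of edges contain a cycle: ",
      paste(cyc, collapse = " -> ")
    ))
  }
  ont
}

ont_top <- function() "owl:Thing"

#' @export
print.pp_ontology <- function(x, ...) {
  cat(
    "<pp_ontology> ", length(x$classes), " classes, ",
    nrow(x$isa), " is-a, ", nrow(x$partof), " part-of, ",
    nrow(x$disjoint), " disjointness\n",
    sep = ""
  )
  invisible(x)
}

# Detect a cycle in the union of is-a and part-of edges; returns the cycle as
# a vector of class IDs, or NULL.
find_cycle <- function(ont) {
  edges <- rbind(
    stats::setNames(as.data.frame(ont$isa), c("from", "to")),
    stats::setNames(as.data.frame(ont$partof), c("from", "to"))
  )
  adj <- split(edges$to, factor(edges$from, levels = ont$classes))
  state <- stats::setNames(integer(length(ont$classes)), ont$classes) # 0 new, 1 open, 2 done
  path <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return(invisible(NULL))
    state[[v]] <<- 1L
    path <<- c(path, v)
    for (w in adj[[v]]) {
      if (state[[w]] == 1L) {
        found <<- c(path[which(path == w)[1]:length(path)], w)
        return(invisible(NULL))
      }
      if (state[[w]] == 0L) visit(w)
    }
    state[[v]] <<- 2L
    path <<- path[-length(path)]
    invisible(NULL)
  }
  for (v in ont$classes) if (state[[v]] == 0L) visit(v)
  found
}

#' Read an OBO-style flat ontology file
#'
#' Parses the minimal OBO dialect used for fixtures: `[Term]` stanzas with
#' `id:`, `name:`, `is_a:`, `relationship: part_of` and `disjoint_from:`
#' lines. Anything else inside a stanza is ignored; a malformed tag line is an
#' error reported with its line number.
#'
#' @param path path to the OBO file.
#' @return a `pp_ontology` (disjointness declarations retained; use
#'   [strip_disjointness()] to drop them).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  classes <- character(0)
  isa <- list()
  partof <- list()
  disjoint <- list()
  cur <- NA_character_
  in_term <- FALSE
  first_tok <- function(x) sub("\\s*(!.*)?$", "", sub("^\\s*", "", x))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "!")) next
    if (grepl("^\\[", ln)) {
      in_term <- identical(ln, "[Term]")
      cur <- NA_character_
      next
    }
    if (!in_term) next
    if (!grepl("^[A-Za-z_]+\\s*:", ln)) {
      rlang::abort(paste0("Malformed OBO line ", i, ": '", lines[[i]], "'"))
    }
    tag <- sub("\\s*:.*$", "", ln)
    val <- sub("^[A-Za-z_]+\\s*:\\s*", "", ln)
    if (tag == "id") {
      cur <- first_tok(val)
      classes <- c(classes, cur)
    } else if (is.na(cur) && tag %in% c("is_a", "relationship", "disjoint_from")) {
      rlang::abort(paste0("OBO line ", i, ": tag '", tag, "' before any id"))
    } else if (tag == "is_a") {
      isa[[length(isa) + 1]] <- c(cur, first_tok(val))
    } else if (tag == "relationship") {
      parts <- strsplit(first_tok(val), "\\s+")[[1]]
      if (length(parts) >= 2 && parts[[1]] == "part_of") {
        partof[[length(partof) + 1]] <- c(cur, parts[[2]])
      }
    } else if (tag == "disjoint_from") {
      disjoint[[length(disjoint) + 1]] <- c(cur, first_tok(val))
    }
  }
  if (length(classes) == 0) {
    rlang::warn("OBO source declares no [Term] stanzas; returning an empty ontology")
  }
  to_tb <- function(lst, nm) {
    if (length(lst) == 0) {
      tb <- tibble::tibble(a = character(), b = character())
    } else {
      m <- do.call(rbind, lst)
      tb <- tibble::tibble(a = m[, 1], b = m[, 2])
    }
    names(tb) <- nm
    tb
  }
  entity_ontology(
    classes,
    isa = to_tb(isa, c("child", "parent")),
    partof = to_tb(partof, c("part", "whole")),
    disjoint = to_tb(disjoint, c("a", "b"))
  )
}

#' Remove disjointness axioms from an ontology
#'
#' Disjointness declarations can make the integrated phenotype ontology
#' inconsistent once classes from several species-specific vocabularies are
#' merged, so they are dropped wholesale before inference. All other axioms
#' are preserved.
#'
#' @param x a `pp_ontology` or a path to an OBO file.
#' @return a `pp_ontology` with zero disjointness declarations.
#' @export
strip_disjointness <- function(x) {
  if (is.character(x)) x <- read_obo(x)
  stopifnot(inherits(x, "pp_ontology"))
  x$disjoint <- x$disjoint[0, ]
  x
}

# Reflexive-transitive reachability over the named edge sets. Returns a logical
# matrix reach[i, j] = TRUE iff class i reaches class j (i.e. j is an ancestor
# of i under the chosen closure). Hand-rolled BFS: this closure is the
# reasoner's substrate and is cross-checked against an independent oracle in
# the tests.
ont_closure <- function(ont, use_partof = FALSE) {
  cls <- ont$classes
  n <- length(cls)
  idx <- stats::setNames(seq_len(n), cls)
  up <- vector("list", n) # parents of each class
  add_edges <- function(up, from, to) {
    for (k in seq_along(from)) {
      i <- idx[[from[[k]]]]
      up[[i]] <- c(up[[i]], idx[[to[[k]]]])
    }
    up
  }
  up <- add_edges(up, ont$isa$child, ont$isa$parent)
  if (use_partof) up <- add_edges(up, ont$partof$part, ont$partof$whole)
  reach <- diag(TRUE, n)
  # iterative BFS per node; ontology is a DAG so this terminates
  for (i in seq_len(n)) {
    frontier <- up[[i]]
    while (length(frontier) > 0) {
      new <- frontier[!reach[i, frontier]]
      reach[i, new] <- TRUE
      frontier <- unique(unlist(up[new]))
    }
  }
  dimnames(reach) <- list(cls, cls)
  reach
}

# Reachability test that treats the implicit top class as universal ancestor.
reaches <- function(closure, child, parent) {
  if (parent == ont_top()) return(TRUE)
  if (child == ont_top()) return(FALSE)
  isTRUE(closure[child, parent])
}
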