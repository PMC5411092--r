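# Shared fixtures: tiny worked ontologies built in code, random ontology
# generator for reasoner property tests, and cached objects shared by the
# long-running acceptance checks.

vkey <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

# The worked similarity toy: entities a1, a2 below a; a and b below org.
# Phenotypes P:<entity> with quality Top. IC corpus: g1 {A1}, g2 {A2}, g3 {B}.
toy_similarity_world <- function() {
  ont <- entity_ontology(
    classes = c("org", "a", "b", "a1", "a2"),
    isa = tibble::tibble(child = c("a", "b", "a1", "a2"),
                         parent = c("org", "org", "a", "a"))
  )
  defs <- lapply(c("org", "a", "b", "a1", "a2"), function(e) {
    rewrite_axiom(list(
      phenotype_id = paste0("P:", e),
      conjuncts = tibble::tibble(relation = "inheres-in", filler = e)
    ), ont)
  })
  h <- infer_hierarchy(defs, ont)
  corpus <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    phenotype_id = c("P:a1", "P:a2", "P:b"),
    source = "human"
  )
  list(ontology = ont, hierarchy = h, corpus = corpus,
       ic = compute_ic(corpus, h))
}

# Random entity ontology + EQ definitions for reasoner stress tests.
# n_pheno phenotype classes (plus S-classes and the root) stay under the
# 200-class scale the oracle test targets.
random_reasoner_world <- function(seed, n_entities = 15, n_pheno = 25) {
  set.seed(seed)
  ents <- sprintf("RE:%02d", seq_len(n_entities))
  layer <- c(1L, sample(2:4, n_entities - 1, replace = TRUE))
  isa <- NULL; partof <- NULL
  for (i in seq_along(ents)[layer > 1]) {
    pool <- ents[layer < layer[i]]
    isa <- rbind(isa, data.frame(child = ents[i], parent = sample(pool, 1)))
    if (stats::runif(1) < 0.4) {
      partof <- rbind(partof,
                      data.frame(part = ents[i], whole = sample(pool, 1)))
    }
  }
  quals <- c("RQ:root", "RQ:a", "RQ:b", "RQ:a1")
  qisa <- data.frame(child = c("RQ:a", "RQ:b", "RQ:a1"),
                     parent = c("RQ:root", "RQ:root", "RQ:a"))
  mods <- c("RM:m", "RM:m1")
  misa <- data.frame(child = "RM:m1", parent = "RM:m")
  ont <- entity_ontology(
    classes = c(ents, quals, mods),
    isa = rbind(stats::setNames(isa, c("child", "parent")), qisa, misa),
    partof = if (is.null(partof)) NULL else partof
  )
  defs <- list()
  for (k in seq_len(n_pheno)) {
    e <- sample(ents, 1)
    q <- sample(quals, 1)
    conj <- tibble::tibble(
      relation = if (stats::runif(1) < 0.25) "inheres-in-part-of" else "inheres-in",
      filler = e
    )
    conj <- rbind(conj, tibble::tibble(relation = "has-quality", filler = q))
    if (stats::runif(1) < 0.3) {
      conj <- rbind(conj, tibble::tibble(relation = "modifier",
                                         filler = sample(mods, 1)))
    }
    if (stats::runif(1) < 0.2) {
      conj <- rbind(conj, tibble::tibble(relation = "towards",
                                         filler = sample(ents, 1)))
    }
    d <- rewrite_axiom(list(phenotype_id = sprintf("RP:%03d", k),
                            conjuncts = conj), ont)
    defs[[d$id]] <- d
  }
  for (e in unique(sample(ents, min(6, n_entities)))) {
    d <- generate_abstract_class(e, ont)
    defs[[d$id]] <- d
  }
  list(ontology = ont, defs = defs)
}

# --- cached long-running fixtures (built once per test run) -----------------

.acc_cache <- new.env(parent = emptyenv())

acc_world <- function() {
  if (is.null(.acc_cache$world)) {
    .acc_cache$world <- generate_toy_world(seed = 20260101)
  }
  .acc_cache$world
}

acc_model <- function(mode = "mixed") {
  key <- paste0("model_", mode)
  if (is.null(.acc_cache[[key]])) {
    w <- acc_world()
    lab <- make_labeled_table(w, n_benign = 60L, per_disease = 3L, seed = 41L)
    res <- list(hierarchy = w$hierarchy, corpus = w$corpus, panel = w$panel,
                ic = w$ic, res = w$res)
    ex <- make_training_set(lab, w$diseases, mode, seed = 42L, resources = res)
    .acc_cache[[key]] <- train_model(ex, mode, seed = 43L)
  }
  .acc_cache[[key]]
}

acc_training_set <- function(mode = "mixed") {
  key <- paste0("examples_", mode)
  if (is.null(.acc_cache[[key]])) {
    w <- acc_world()
    lab <- make_labeled_table(w, n_benign = 60L, per_disease = 3L, seed = 41L)
    res <- list(hierarchy = w$hierarchy, corpus = w$corpus, panel = w$panel,
                ic = w$ic, res = w$res)
    .acc_cache[[key]] <- make_training_set(lab, w$diseases, mode, seed = 42L,
                                           resources = res)
  }
  .acc_cache[[key]]
}
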