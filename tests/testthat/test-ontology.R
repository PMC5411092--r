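# Ontology construction: OBO parsing, EQ rewriting, abstract/zebrafish class
# generation, and the restricted subsumption reasoner.

heart_ontology <- function() {
  entity_ontology(
    classes = c("Heart", "HeartChamber", "LeftVentricle", "Limb",
                "Enlarged", "SeverelyEnlarged", "Small", "Abnormal",
                "Fin", "Malformed", "DecreasedAmount", "Collagen"),
    isa = tibble::tibble(
      child = c("LeftVentricle", "SeverelyEnlarged"),
      parent = c("HeartChamber", "Enlarged")
    ),
    partof = tibble::tibble(part = "HeartChamber", whole = "Heart")
  )
}

test_that("OBO parsing keeps structure and strip_disjointness removes only disjointness", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: X:1", "name: heart",
    "[Term]", "id: X:2", "is_a: X:1", "disjoint_from: X:3",
    "[Term]", "id: X:3", "relationship: part_of X:1", "disjoint_from: X:2"
  ), path)
  ont <- read_obo(path)
  expect_equal(length(ont$classes), 3)
  expect_equal(nrow(ont$isa), 1)
  expect_equal(nrow(ont$partof), 1)
  expect_equal(nrow(ont$disjoint), 2)
  stripped <- strip_disjointness(ont)
  expect_equal(nrow(stripped$disjoint), 0)
  expect_identical(stripped$isa, ont$isa)
  expect_identical(stripped$partof, ont$partof)
  expect_identical(stripped$classes, ont$classes)

  bad <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: X:1", "this is not a tag line"), bad)
  expect_error(read_obo(bad), "line 3")

  empty <- withr::local_tempfile(fileext = ".obo")
  writeLines("! nothing here", empty)
  expect_warning(ont0 <- read_obo(empty), "empty")
  expect_equal(length(ont0$classes), 0)
})

test_that("entity ontology rejects undeclared endpoints and cycles", {
  expect_error(
    entity_ontology("A", isa = tibble::tibble(child = "A", parent = "B")),
    "not declared"
  )
  expect_error(
    entity_ontology(
      c("A", "B"),
      isa = tibble::tibble(child = "A", parent = "B"),
      partof = tibble::tibble(part = "B", whole = "A")
    ),
    "cycle"
  )
})

test_that("rewrite_axiom applies the rewriting rules in conjunct order", {
  ont <- heart_ontology()
  d <- rewrite_axiom(list(
    phenotype_id = "P1",
    conjuncts = tibble::tibble(relation = c("inheres-in", "has-quality"),
                               filler = c("Heart", "Enlarged"))
  ), ont)
  expect_equal(d$E$class, "Heart")
  expect_false(d$E$wrapped)
  expect_equal(d$Q$class, "Enlarged")

  # empty conjunct list leaves the owl:Thing initialization in place
  d0 <- rewrite_axiom(list(
    phenotype_id = "P0",
    conjuncts = tibble::tibble(relation = character(), filler = character())
  ), ont)
  expect_equal(d0$E$class, "owl:Thing")
  expect_equal(d0$Q$class, "owl:Thing")

  d2 <- rewrite_axiom(list(
    phenotype_id = "P2",
    conjuncts = tibble::tibble(
      relation = c("inheres-in-part-of", "has-quality", "modifier"),
      filler = c("Limb", "Small", "Abnormal"))
  ), ont)
  expect_equal(d2$E$class, "Limb")
  expect_true(d2$E$wrapped)
  expect_equal(d2$Q$class, "Small")
  expect_equal(d2$Q$mods$filler, "Abnormal")
})

test_that("rewrite_axiom rejects unknown relations and unresolvable fillers by name", {
  ont <- heart_ontology()
  expect_error(
    rewrite_axiom(list(phenotype_id = "P",
                       conjuncts = tibble::tibble(relation = "caused-by",
                                                  filler = "Heart")), ont),
    "caused-by"
  )
  expect_error(
    rewrite_axiom(list(phenotype_id = "P",
                       conjuncts = tibble::tibble(relation = "inheres-in",
                                                  filler = "Spleen")), ont),
    "Spleen"
  )
})

test_that("has-part conjuncts become recursively rewritten part definitions", {
  ont <- heart_ontology()
  exprs <- list("expr:1" = tibble::tibble(
    relation = c("inheres-in", "has-quality"), filler = c("Heart", "Enlarged")))
  d <- rewrite_axiom(list(
    phenotype_id = "P",
    conjuncts = tibble::tibble(relation = c("has-part", "has-part"),
                               filler = c("expr:1", "Limb"))
  ), ont, expressions = exprs)
  parts <- attr(d, "part_defs")
  expect_length(parts, 2)
  expect_equal(d$parts, vapply(parts, function(x) x$id, character(1)))
  expect_equal(parts[[1]]$E$class, "Heart")
  expect_equal(parts[[1]]$Q$class, "Enlarged")
  expect_equal(parts[[2]]$E$class, "Limb")
  # subsumed by each part class after inference
  h <- infer_hierarchy(list(d), ont)
  for (p in d$parts) expect_true(h$subsumes["P", p])
})

test_that("abstract S-classes are idempotent and S(Top) matches the root extension", {
  ont <- heart_ontology()
  s1 <- generate_abstract_class("Heart", ont)
  s2 <- generate_abstract_class("Heart", ont)
  expect_identical(s1$id, s2$id)
  expect_true(s1$abstract)
  expect_true(s1$E$wrapped)
  expect_equal(s1$Q$class, "owl:Thing")

  s_top <- generate_abstract_class("owl:Thing", ont)
  p <- rewrite_axiom(list(
    phenotype_id = "P1",
    conjuncts = tibble::tibble(relation = c("inheres-in", "has-quality"),
                               filler = c("Heart", "Enlarged"))
  ), ont)
  h <- infer_hierarchy(list(s_top, p), ont)
  # S(Top) and the universal root subsume each other (equal extension)
  expect_true(h$subsumes[s_top$id, pheno_root()])
  expect_true(h$subsumes[pheno_root(), s_top$id])
})

test_that("zebrafish classes reuse IDs per unique combination and attach towards to Q", {
  ont <- heart_ontology()
  z1 <- make_zebrafish_class("Fin", "Malformed", ontology = ont)
  z2 <- make_zebrafish_class("Fin", "Malformed", ontology = ont)
  expect_identical(z1$id, z2$id)
  expect_equal(z1$E$class, "Fin")
  expect_equal(z1$Q$class, "Malformed")
  expect_equal(nrow(z1$Q$mods), 0)

  z3 <- make_zebrafish_class("Fin", "DecreasedAmount", e2 = "Collagen",
                             ontology = ont)
  expect_equal(z3$Q$class, "DecreasedAmount")
  expect_equal(z3$Q$mods,
               tibble::tibble(relation = "towards", filler = "Collagen"))
  expect_false(identical(z1$id, z3$id))
  expect_error(make_zebrafish_class("Fin", "NoSuchQuality", ontology = ont),
               "NoSuchQuality")
})

test_that("the reasoner reproduces the worked subsumption cases", {
  ont <- heart_ontology()
  p1 <- rewrite_axiom(list(
    phenotype_id = "P:LV",
    conjuncts = tibble::tibble(relation = c("inheres-in", "has-quality"),
                               filler = c("LeftVentricle", "Enlarged"))
  ), ont)
  s_heart <- generate_abstract_class("Heart", ont)
  p_sev <- rewrite_axiom(list(
    phenotype_id = "P:sev",
    conjuncts = tibble::tibble(relation = c("inheres-in", "has-quality"),
                               filler = c("Heart", "SeverelyEnlarged"))
  ), ont)
  p_enl <- rewrite_axiom(list(
    phenotype_id = "P:enl",
    conjuncts = tibble::tibble(relation = c("inheres-in", "has-quality"),
                               filler = c("Heart", "Enlarged"))
  ), ont)
  h <- infer_hierarchy(list(p1, s_heart, p_sev, p_enl), ont)
  # entity path LeftVentricle -isa-> HeartChamber -partof-> Heart
  expect_true(h$subsumes["P:LV", s_heart$id])
  # reflexivity
  for (n in h$nodes) expect_true(h$subsumes[n, n])
  # quality closure SeverelyEnlarged is-a Enlarged
  expect_true(h$subsumes["P:sev", "P:enl"])
  expect_false(h$subsumes["P:enl", "P:sev"])
  # everything reaches the root
  expect_true(all(h$subsumes[, pheno_root()]))
  # an unmodified parent quality does not subsume across entities
  expect_false(h$subsumes["P:enl", "P:LV"])
})

test_that("the reasoner agrees with the brute-force oracle on random ontologies", {
  for (seed in 1:10) {
    rw <- random_reasoner_world(seed)
    h <- infer_hierarchy(rw$defs, rw$ontology)
    oracle <- oracle_subsumption(flatten_defs(rw$defs), rw$ontology)
    expect_identical(h$subsumes[rownames(oracle), colnames(oracle)], oracle,
                     info = paste("seed", seed))
  }
})

test_that("adding entity edges never removes phenotype subsumptions", {
  rw <- random_reasoner_world(99)
  h1 <- infer_hierarchy(rw$defs, rw$ontology)
  ont2 <- rw$ontology
  # add a fresh is-a edge between two previously unrelated entities
  ents <- grep("^RE:", ont2$classes, value = TRUE)
  pair <- c("RE:14", "RE:02")
  ont2$isa <- rbind(ont2$isa, tibble::tibble(child = pair[1], parent = pair[2]))
  expect_null(phenoprio:::find_cycle(ont2))
  h2 <- infer_hierarchy(rw$defs, ont2)
  expect_true(all(h2$subsumes[h1$nodes, h1$nodes] >= h1$subsumes))
})

test_that("rebuilding a hierarchy from its own definitions is idempotent", {
  rw <- random_reasoner_world(7)
  h1 <- infer_hierarchy(rw$defs, rw$ontology)
  h2 <- infer_hierarchy(h1$defs, rw$ontology)
  expect_identical(h1$edges, h2$edges)
  expect_identical(h1$subsumes, h2$subsumes)
})

test_that("concrete phenotypes pass through the S-class of every containing whole", {
  ont <- heart_ontology()
  p1 <- rewrite_axiom(list(
    phenotype_id = "P:LV",
    conjuncts = tibble::tibble(relation = c("inheres-in", "has-quality"),
                               filler = c("LeftVentricle", "Enlarged"))
  ), ont)
  s_heart <- generate_abstract_class("Heart", ont)
  s_chamber <- generate_abstract_class("HeartChamber", ont)
  h <- infer_hierarchy(list(p1, s_heart, s_chamber), ont)
  expect_true(h$subsumes["P:LV", s_heart$id])
  expect_true(h$subsumes["P:LV", s_chamber$id])
  # and the S-classes themselves chain up to the root
  expect_true(h$subsumes[s_chamber$id, s_heart$id])
})

test_that("hierarchy edge lists round-trip through the TSV writer", {
  rw <- random_reasoner_world(3)
  h <- infer_hierarchy(rw$defs, rw$ontology)
  dir <- withr::local_tempdir()
  write_hierarchy(h, dir)
  edges <- utils::read.delim(file.path(dir, "hierarchy_edges.tsv"),
                             colClasses = "character")
  expect_equal(nrow(edges), nrow(h$edges))
  meta <- utils::read.delim(file.path(dir, "hierarchy_classes.tsv"),
                            colClasses = "character")
  expect_setequal(meta$class_id, h$nodes)
})
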