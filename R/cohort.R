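#' Generate a self-contained toy world for the pipeline
#'
#' Builds every input the prioritization pipeline consumes: a random entity
#' DAG (is-a plus part-of) with a fixed quality/modifier vocabulary, raw EQ
#' axioms rewritten into phenotype classes, the inferred hierarchy, a
#' gene-phenotype annotation corpus, a disease table with modes of
#' inheritance, gene intervals, and the truth map from disease to causal
#' gene. The construction guarantees a recoverable signal: every gene
#' carries private phenotype classes (grounded in entities no other gene
#' uses) and each disease's profile is its causal gene's annotation set, so
#' under the separable signal model the causal gene is the profile's unique
#' best match.
#'
#' Everything is deterministic per seed.
#'
#' @param params list: `n_genes` (default 24), `n_diseases` (default 12,
#'   `<= n_genes`), `phenotypes_per_disease` (default 4, `>= 1`), `depth`
#'   (entity DAG depth, default 4), `n_shared_entities` (default 8),
#'   `private_per_gene` (private phenotype classes per gene; default
#'   `phenotypes_per_disease - 1`), `shared_per_gene` (annotations drawn
#'   from the shared pool per gene, default 1; larger values make genes
#'   phenotypically confusable, so profile depth matters more),
#'   `sim_decay` (fraction of each causal gene's annotations removed before
#'   corpus construction, default 0).
#' @param seed integer seed.
#' @return a `pp_world` list: `ontology`, `defs`, `hierarchy`, `corpus`,
#'   `diseases`, `genes`, `truth`, `ic`, `res` (Resnik matrix), `panel`,
#'   `params`, `seed`.
#' @export
generate_toy_world <- function(params = list(), seed = 1L) {
  p <- utils::modifyList(list(
    n_genes = 24L, n_diseases = 12L, phenotypes_per_disease = 4L,
    depth = 4L, n_shared_entities = 8L, private_per_gene = NULL,
    shared_per_gene = 1L, sim_decay = 0
  ), params)
  if (p$phenotypes_per_disease < 1) {
    rlang::abort("phenotypes_per_disease must be >= 1")
  }
  if (p$n_diseases > p$n_genes) {
    rlang::abort("n_diseases cannot exceed n_genes")
  }
  private_per_gene <- p$private_per_gene %||%
    max(1L, p$phenotypes_per_disease - 1L)
  n_entities <- p$n_genes * private_per_gene + p$n_shared_entities
  if (p$depth < 1 && n_entities > 1) {
    rlang::abort("depth 0 is inconsistent with more than one entity")
  }
  set.seed(seed)

  # --- entity DAG ------------------------------------------------------
  ents <- sprintf("E:%03d", seq_len(n_entities))
  layer <- c(rep(1L, 2), sample(2:max(2, p$depth), n_entities - 2, replace = TRUE))
  isa <- list(); partof <- list()
  for (i in seq_along(ents)[layer > 1]) {
    pool <- ents[layer < layer[i]]
    par <- sample(pool, 1)
    isa[[length(isa) + 1]] <- c(ents[i], par)
    if (stats::runif(1) < 0.2 && length(pool) > 1) {
      isa[[length(isa) + 1]] <- c(ents[i], sample(setdiff(pool, par), 1))
    }
    if (stats::runif(1) < 0.35) {
      partof[[length(partof) + 1]] <- c(ents[i], sample(pool, 1))
    }
  }
  qual <- quality_vocabulary()
  ontology <- entity_ontology(
    classes = c(ents, qual$classes),
    isa = tibble::tibble(
      child = c(vapply(isa, `[`, "", 1), qual$isa$child),
      parent = c(vapply(isa, `[`, "", 2), qual$isa$parent)
    ),
    partof = tibble::tibble(
      part = vapply(partof, `[`, "", 1),
      whole = vapply(partof, `[`, "", 2)
    )
  )

  # --- phenotype classes via the rewrite rules -------------------------
  leaf_q <- qual$leaves
  defs <- list()
  pheno_of_entity <- list() # entity -> phenotype ids
  add_def <- function(d) defs[[d$id]] <<- d
  for (e in ents) {
    qs <- sample(leaf_q, 2)
    for (q in qs) {
      conj <- qual_tb(c("inheres-in", "has-quality"), c(e, q))
      if (stats::runif(1) < 0.15) {
        conj <- rbind(conj, qual_tb("modifier", "M:abnormal"))
      }
      if (stats::runif(1) < 0.10) {
        conj <- rbind(conj, qual_tb("towards", sample(ents, 1)))
      }
      raw <- list(phenotype_id = paste0("P:", e, ":", q), conjuncts = conj)
      d <- rewrite_axiom(raw, ontology)
      add_def(d)
      pheno_of_entity[[e]] <- c(pheno_of_entity[[e]], d$id)
    }
  }
  # a few zebrafish-style direct EQ classes
  for (k in seq_len(4)) {
    e1 <- sample(ents, 1)
    d <- make_zebrafish_class(e1, sample(leaf_q, 1),
                              e2 = if (k %% 2 == 0) sample(ents, 1) else NULL,
                              ontology = ontology)
    add_def(d)
    pheno_of_entity[[e1]] <- c(pheno_of_entity[[e1]], d$id)
  }
  # abstract S-classes for every distinct entity
  for (e in unique(ents)) add_def(generate_abstract_class(e, ontology))

  hierarchy <- infer_hierarchy(defs, ontology)

  # --- genes, corpus, diseases ----------------------------------------
  genes <- sprintf("G%03d", seq_len(p$n_genes))
  shared_ents <- ents[seq_len(p$n_shared_entities)]
  private_ents <- split(
    ents[p$n_shared_entities + seq_len(p$n_genes * private_per_gene)],
    rep(seq_len(p$n_genes), each = private_per_gene)
  )
  corpus_rows <- list()
  gene_annot <- list()
  shared_pool <- unique(unlist(pheno_of_entity[shared_ents]))
  for (gi in seq_along(genes)) {
    own <- vapply(private_ents[[gi]],
                  function(e) sample(pheno_of_entity[[e]], 1), character(1))
    shared <- sample(shared_pool, min(p$shared_per_gene, length(shared_pool)))
    ann <- unique(c(own, shared))
    if (p$sim_decay > 0) {
      drop_n <- floor(p$sim_decay * length(ann))
      if (drop_n >= length(ann)) drop_n <- length(ann) - 1L
      if (drop_n > 0) ann <- ann[-sample(length(ann), drop_n)]
    }
    gene_annot[[genes[gi]]] <- ann
    src <- sample(c("human", "mouse", "zebrafish"), length(ann), replace = TRUE)
    corpus_rows[[gi]] <- tibble::tibble(gene_id = genes[gi],
                                        phenotype_id = ann, source = src)
  }
  corpus <- dplyr::bind_rows(corpus_rows)

  causal <- sample(genes, p$n_diseases)
  moi <- sample(moi_levels(), p$n_diseases, replace = TRUE,
                prob = c(0.4, 0.35, 0.1, 0.15))
  diseases <- tibble::tibble(
    disease_id = sprintf("D%03d", seq_len(p$n_diseases)),
    moi = moi,
    phenotypes = lapply(causal, function(g) {
      ann <- gene_annot[[g]]
      ann[seq_len(min(length(ann), p$phenotypes_per_disease))]
    })
  )
  truth <- tibble::tibble(disease_id = diseases$disease_id, causal_gene = causal)

  # --- gene intervals (two chromosomes, non-overlapping) ---------------
  gene_tab <- tibble::tibble(
    chrom = paste0("chr", (seq_len(p$n_genes) - 1) %% 2 + 1),
    start = 1000L + 2000L * ((seq_len(p$n_genes) - 1) %/% 2),
    gene_id = genes
  )
  gene_tab$end <- gene_tab$start + 1000L

  ic <- compute_ic(corpus, hierarchy)
  world <- structure(
    list(
      ontology = ontology, defs = defs, hierarchy = hierarchy,
      corpus = corpus, diseases = diseases,
      genes = gene_tab[, c("chrom", "start", "end", "gene_id")],
      truth = truth, ic = ic, res = resnik_matrix(ic, hierarchy),
      panel = derive_panel(hierarchy), params = p, seed = seed
    ),
    class = "pp_world"
  )
  world
}

#' @export
print.pp_world <- function(x, ...) {
  cat("<pp_world> ", length(x$hierarchy$nodes), " phenotype classes, ",
      nrow(x$genes), " genes, ", nrow(x$diseases), " diseases (seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

# Fixed quality + modifier vocabulary shared by every generated world.
quality_vocabulary <- function() {
  isa <- tibble::tribble(
    ~child, ~parent,
    "Q:size", "Q:quality",
    "Q:shape", "Q:quality",
    "Q:amount", "Q:quality",
    "Q:functionality", "Q:quality",
    "Q:increased_size", "Q:size",
    "Q:decreased_size", "Q:size",
    "Q:severely_increased_size", "Q:increased_size",
    "Q:malformed", "Q:shape",
    "Q:increased_amount", "Q:amount",
    "Q:decreased_amount", "Q:amount",
    "Q:absent", "Q:decreased_amount",
    "Q:impaired", "Q:functionality",
    "M:abnormal", "M:modifier",
    "M:severe", "M:abnormal"
  )
  classes <- unique(c(isa$child, isa$parent))
  leaves <- setdiff(isa$child, isa$parent)
  leaves <- leaves[startsWith(leaves, "Q:")]
  list(classes = classes, isa = isa, leaves = leaves)
}

# Truncated-normal score draw for the two signal models: benign scores
# centre on 0.3, pathogenic on 0.8. Under the separable signal the two
# supports are clamped apart; under the noisy signal they overlap with the
# requested sigma.
draw_scores <- function(n, pathogenic, signal) {
  mu <- if (pathogenic) 0.8 else 0.3
  if (identical(signal$type, "separable")) {
    sd <- 0.05
    lo <- if (pathogenic) 0.65 else 0
    hi <- if (pathogenic) 1 else 0.55
  } else {
    sd <- signal$sigma %||% 0.15
    lo <- 0; hi <- 1
  }
  matrix(pmin(hi, pmax(lo, stats::rnorm(3 * n, mu, sd))), ncol = 3)
}

#' Generate a labeled training table from a world
#'
#' Emits `per_disease` pathogenic variants inside each disease's causal gene
#' and `n_benign` benign variants in random genes, with pathogenicity scores
#' drawn from the corresponding signal model. Training variants are placed
#' in the first half of each gene interval; [spike_in_case()] uses the
#' second half, so training and spiked variants never share coordinates.
#'
#' @param world a `pp_world`.
#' @param n_benign number of benign variants (default 40).
#' @param per_disease pathogenic variants per disease (default 2).
#' @param signal signal model, e.g. `list(type = "separable")` or
#'   `list(type = "noisy", sigma = 0.15)`.
#' @param seed integer seed.
#' @return a labeled tibble ready for [make_training_set()] (scores and
#'   genes attached).
#' @export
make_labeled_table <- function(world, n_benign = 40L, per_disease = 2L,
                               signal = list(type = "separable"), seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (i in seq_len(nrow(world$truth))) {
    g <- world$genes[world$genes$gene_id == world$truth$causal_gene[i], ]
    pos <- sample(seq(g$start, g$start + 499L), per_disease)
    ref <- sample(bases, per_disease, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    sc <- draw_scores(per_disease, TRUE, signal)
    rows[[length(rows) + 1]] <- tibble::tibble(
      chrom = g$chrom, pos = pos, ref = ref, alt = alt,
      label = "pathogenic", disease_id = world$truth$disease_id[i],
      gene = g$gene_id, exonic = TRUE,
      score_1 = sc[, 1], score_2 = sc[, 2], score_3 = sc[, 3]
    )
  }
  gi <- sample(nrow(world$genes), n_benign, replace = TRUE)
  g <- world$genes[gi, ]
  ref <- sample(bases, n_benign, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  sc <- draw_scores(n_benign, FALSE, signal)
  rows[[length(rows) + 1]] <- tibble::tibble(
    chrom = g$chrom,
    pos = g$start + sample(0:499, n_benign, replace = TRUE),
    ref = ref, alt = alt, label = "benign", disease_id = NA_character_,
    gene = g$gene_id, exonic = TRUE,
    score_1 = sc[, 1], score_2 = sc[, 2], score_3 = sc[, 3]
  )
  dplyr::bind_rows(rows)
}

#' Spike a single causative variant into a background of benign variants
#'
#' Emulates the spike-in benchmark: background variants are placed uniformly
#' over genic (fraction `fraction_exonic`) and intergenic space with MAF and
#' scores drawn from the benign signal model (a small fraction uncalled,
#' common, or unscored, to exercise the filters); exactly one causative
#' variant is inserted into the disease's causal gene with zygosity
#' consistent with the MOI (hom if recessive, else random) and scores from
#' the pathogenic signal model. The truth record is returned separately and
#' never written into pipeline-visible files.
#'
#' @param world a `pp_world`.
#' @param disease_id a disease in the world.
#' @param background_n number of background variants.
#' @param signal signal model (see [make_labeled_table()]).
#' @param seed integer seed.
#' @param fraction_exonic fraction of background variants inside gene
#'   intervals.
#' @return a `pp_case` list: `variants` (a `pp_variants` tibble with scores
#'   and MAF attached, genes unassigned), `disease_id`, `profile`, `moi`,
#'   `truth` (list `key`, `gene`, `genotype`).
#' @export
spike_in_case <- function(world, disease_id, background_n = 500L,
                          signal = list(type = "separable"), seed = 1L,
                          fraction_exonic = 0.9) {
  di <- match(disease_id, world$diseases$disease_id)
  if (is.na(di)) rlang::abort(paste0("Unknown disease: ", disease_id))
  causal <- world$truth$causal_gene[world$truth$disease_id == disease_id]
  g <- world$genes[world$genes$gene_id == causal, ]
  if (nrow(g) == 0) rlang::abort(paste0("Causal gene absent: ", causal))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  n_ex <- round(background_n * fraction_exonic)
  n_int <- background_n - n_ex
  gi <- sample(nrow(world$genes), n_ex, replace = TRUE)
  chrom_max <- vapply(unique(world$genes$chrom), function(ch) {
    max(world$genes$end[world$genes$chrom == ch]) + 5000
  }, numeric(1))
  ex <- tibble::tibble(
    chrom = world$genes$chrom[gi],
    pos = world$genes$start[gi] +
      sample(0:999, n_ex, replace = TRUE)
  )
  int_chrom <- sample(names(chrom_max), n_int, replace = TRUE)
  intergenic <- tibble::tibble(
    chrom = int_chrom,
    pos = vapply(int_chrom, function(ch) {
      repeat {
        cand <- sample.int(chrom_max[[ch]], 1)
        gg <- world$genes[world$genes$chrom == ch, ]
        if (!any(gg$start <= cand & cand < gg$end)) return(as.numeric(cand))
      }
    }, numeric(1))
  )
  bg <- dplyr::bind_rows(ex, intergenic)
  n <- nrow(bg)
  bg$ref <- sample(bases, n, replace = TRUE)
  bg$alt <- vapply(bg$ref, function(r) sample(setdiff(bases, r), 1), character(1))
  u <- stats::runif(n)
  bg$genotype <- as.character(ifelse(u < 0.03, "uncalled",
                                     ifelse(u < 0.5, "het", "hom")))
  um <- stats::runif(n)
  bg$maf <- ifelse(um < 0.2, NA_real_,
                   ifelse(um < 0.8, stats::runif(n, 0, 0.005),
                          stats::runif(n, 0.02, 0.3)))
  sc <- draw_scores(n, FALSE, signal)
  for (k in 1:3) {
    col <- sc[, k]
    col[stats::runif(n) < 0.05] <- NA_real_
    bg[[paste0("score_", k)]] <- col
  }

  # causative variant in the spike half of the causal gene
  moi <- world$diseases$moi[di]
  repeat {
    cpos <- g$start + 500L + sample.int(500L, 1) - 1L
    if (!cpos %in% bg$pos[bg$chrom == g$chrom]) break
  }
  cref <- sample(bases, 1)
  calt <- sample(setdiff(bases, cref), 1)
  cgt <- if (identical(moi, "Recessive")) "hom" else sample(c("het", "hom"), 1)
  csc <- draw_scores(1, TRUE, signal)
  causative <- tibble::tibble(
    chrom = g$chrom, pos = cpos, ref = cref, alt = calt, genotype = cgt,
    maf = NA_real_, score_1 = csc[1, 1], score_2 = csc[1, 2],
    score_3 = csc[1, 3]
  )
  variants <- dplyr::bind_rows(bg, causative)
  variants <- variants[sample(nrow(variants)), ] # shuffle row order
  variants$gene <- NA_character_
  variants$exonic <- NA
  class(variants) <- c("pp_variants", class(variants))
  structure(
    list(
      variants = variants,
      disease_id = disease_id,
      profile = world$diseases$phenotypes[[di]],
      moi = moi,
      truth = list(key = variant_key(g$chrom, cpos, cref, calt),
                   gene = causal, genotype = cgt)
    ),
    class = "pp_case"
  )
}

#' Perturb a patient phenotype profile
#'
#' Three perturbation modes emulating imperfect phenotyping:
#' `"comorbid"` unions the profile with a uniformly sampled different
#' disease's phenotypes; `"dropout"` removes each class independently with
#' probability `p` (default 1/3), resampling if the profile would be emptied
#' (at least one class always survives); `"two-variant"` returns the ID of
#' the most phenotypically similar *other* disease (by BMA similarity
#' between disease profiles), the disease whose causative variant is spiked
#' in alongside.
#'
#' @param profile character vector of phenotype class IDs.
#' @param mode `"comorbid"`, `"dropout"` or `"two-variant"`.
#' @param world a `pp_world`.
#' @param seed integer seed.
#' @param p dropout probability.
#' @param disease_id the profile's own disease (excluded from sampling).
#' @return a perturbed profile (character vector), or for `"two-variant"`
#'   the selected disease ID.
#' @export
perturb_profile <- function(profile, mode, world, seed = 1L, p = 1 / 3,
                            disease_id = NULL) {
  set.seed(seed)
  if (identical(mode, "comorbid")) {
    pool <- setdiff(world$diseases$disease_id, disease_id)
    other <- if (length(pool) == 1) pool else sample(pool, 1)
    union(profile, world$diseases$phenotypes[[match(other, world$diseases$disease_id)]])
  } else if (identical(mode, "dropout")) {
    for (attempt in 1:50) {
      keep <- stats::runif(length(profile)) >= p
      if (any(keep)) return(profile[keep])
    }
    # degenerate p ~ 1: resampling cannot succeed, retain one class
    profile[sample(length(profile), 1)]
  } else if (identical(mode, "two-variant")) {
    if (is.null(disease_id)) rlang::abort("two-variant mode needs disease_id")
    pool <- setdiff(world$diseases$disease_id, disease_id)
    sims <- vapply(pool, function(d) {
      other <- world$diseases$phenotypes[[match(d, world$diseases$disease_id)]]
      bma_similarity(profile, other, world$ic, world$hierarchy, res = world$res)
    }, numeric(1))
    pool[which.max(sims)]
  } else {
    rlang::abort(paste0("Unknown perturbation mode: '", mode, "'"))
  }
}

#' Write a spike-in case to disk as pipeline inputs
#'
#' Emits `variants.vcf`, `scores_1.tsv` … `scores_3.tsv`, `maf.tsv` and
#' `profile.txt` under `dir`; the truth record goes to
#' `file.path(truth_dir)` (kept apart so no pipeline input leaks the
#' answer).
#'
#' @param case a `pp_case`.
#' @param dir case input directory.
#' @param truth_dir directory for the truth JSON (default `NULL`: not
#'   written).
#' @return `dir`, invisibly.
#' @export
write_case <- function(case, dir, truth_dir = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- case$variants
  write_vcf(v, file.path(dir, "variants.vcf"))
  for (k in 1:3) {
    sk <- v[!is.na(v[[paste0("score_", k)]]), ]
    write_tsv_plain(
      tibble::tibble(chrom = sk$chrom, pos = sk$pos, ref = sk$ref,
                     alt = sk$alt, score = sk[[paste0("score_", k)]]),
      file.path(dir, paste0("scores_", k, ".tsv"))
    )
  }
  mk <- v[!is.na(v$maf), ]
  write_tsv_plain(
    tibble::tibble(chrom = mk$chrom, pos = mk$pos, ref = mk$ref,
                   alt = mk$alt, maf = mk$maf),
    file.path(dir, "maf.tsv")
  )
  writeLines(case$profile, file.path(dir, "profile.txt"))
  if (!is.null(truth_dir)) {
    dir.create(truth_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(case$truth,
                         file.path(truth_dir, paste0(basename(dir), ".json")),
                         auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Simulate a complete spike-in cohort
#'
#' One case per draw from the world's diseases (cycled), each a VCF-sized
#' variant set with one causative spike-in.
#'
#' @param world a `pp_world`.
#' @param n_cases number of cases.
#' @param background_n background variants per case.
#' @param signal signal model.
#' @param seed integer seed; case `i` uses `seed + i`.
#' @param fraction_exonic fraction of exonic background variants.
#' @return a tibble `case_id`, `disease_id`, `case` (list-column of
#'   `pp_case`).
#' @export
simulate_cohort <- function(world, n_cases = 50L, background_n = 500L,
                            signal = list(type = "separable"), seed = 1L,
                            fraction_exonic = 0.9) {
  ids <- rep(world$diseases$disease_id, length.out = n_cases)
  cases <- lapply(seq_len(n_cases), function(i) {
    spike_in_case(world, ids[i], background_n = background_n,
                  signal = signal, seed = seed + i,
                  fraction_exonic = fraction_exonic)
  })
  tibble::tibble(
    case_id = sprintf("case_%03d", seq_len(n_cases)),
    disease_id = ids,
    case = cases
  )
}
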