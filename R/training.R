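#' Expand variants into candidate disease-causing genotypes
#'
#' A recessive disease requires a homozygous variant, so Recessive yields a
#' single homozygote genotype; any other mode of inheritance yields both a
#' heterozygote and a homozygote genotype.
#'
#' @param variants a tibble with a `moi` column (one of the four collapsed
#'   values).
#' @return the tibble with one row per (variant, zygosity), `genotype` set.
#' @export
expand_genotypes <- function(variants) {
  variants <- tibble::as_tibble(variants)
  bad <- setdiff(unique(variants$moi), moi_levels())
  if (length(bad) > 0) {
    rlang::abort(paste0("MOI must be one of ",
                        paste(moi_levels(), collapse = "/"), "; got ",
                        paste(bad, collapse = ", ")))
  }
  reps <- ifelse(variants$moi == "Recessive", 1L, 2L)
  out <- variants[rep(seq_len(nrow(variants)), reps), ]
  geno <- unlist(lapply(seq_len(nrow(variants)), function(i) {
    if (variants$moi[i] == "Recessive") "hom" else c("het", "hom")
  }))
  out$genotype <- geno
  out
}

#' Construct a labeled training set with mode-specific negative sampling
#'
#' Positives are pathogenic variants paired with their own disease's
#' phenotype profile, expanded into candidate genotypes by MOI. Two negative
#' pools exist: *pathogenic non-causative* (the same pathogenic genotypes
#' paired with a uniformly sampled different disease's profile and MOI) and
#' *benign non-causative* (benign variants expanded under a random disease's
#' MOI and paired with its profile). `mode` selects the composition:
#' `"pathogenic"` and `"benign"` use one pool only; `"mixed"` takes a 50/50
#' blend, subsampling the larger pool to the size of the smaller (seeded).
#'
#' Diseases without phenotype annotations cannot supply a profile and are
#' excluded (with a message).
#'
#' @param labeled labeled variant tibble from [read_labeled_variants()],
#'   gene-assigned and score-attached.
#' @param diseases disease tibble from [read_disease_table()].
#' @param mode one of `"pathogenic"`, `"benign"`, `"mixed"`.
#' @param seed integer seed controlling disease mismatching and subsampling.
#' @param resources list with `hierarchy`, `corpus`, `panel`, optional
#'   `sources` and `res` (precomputed Resnik matrix) used to compute the
#'   similarity and flag features.
#' @return a tibble of feature rows plus `label`
#'   (`causative`/`non-causative`), `provenance` and `disease_id`.
#' @export
make_training_set <- function(labeled, diseases, mode, seed, resources) {
  mode <- match.arg(mode, c("pathogenic", "benign", "mixed"))
  diseases <- diseases[lengths(diseases$phenotypes) > 0, ]
  dropped <- attr(diseases, "n_dropped")
  if (nrow(diseases) < 2) {
    rlang::abort("Need at least 2 phenotype-annotated diseases to mismatch profiles")
  }
  hierarchy <- resources$hierarchy
  corpus <- resources$corpus
  panel <- resources$panel
  sources <- resources$sources %||% c("human", "mouse", "zebrafish")
  ic <- resources$ic %||% compute_ic(corpus, hierarchy, sources = sources)
  res <- resources$res %||% resnik_matrix(ic, hierarchy)

  sim_cache <- new.env(parent = emptyenv())
  sim_for <- function(disease_id) {
    if (is.null(sim_cache[[disease_id]])) {
      prof <- diseases$phenotypes[[match(disease_id, diseases$disease_id)]]
      sim_cache[[disease_id]] <- profile_gene_similarity(
        prof, corpus, ic, hierarchy, sources = sources, res = res)
    }
    sim_cache[[disease_id]]
  }
  feat_for <- function(variants, disease_id) {
    i <- match(disease_id, diseases$disease_id)
    build_features(variants, diseases$phenotypes[[i]], sim_for(disease_id),
                   panel, hierarchy, moi = diseases$moi[[i]])
  }

  set.seed(seed)
  path <- labeled[labeled$label == "pathogenic" &
                    labeled$disease_id %in% diseases$disease_id, ]
  if (nrow(path) == 0) rlang::abort("No pathogenic variants with annotated diseases")
  path$moi <- diseases$moi[match(path$disease_id, diseases$disease_id)]
  path_exp <- expand_genotypes(path)

  build_rows <- function(exp_tab, disease_ids, label, provenance) {
    pieces <- lapply(unique(disease_ids), function(d) {
      sel <- disease_ids == d
      ft <- feat_for(exp_tab[sel, ], d)
      ft$label <- label
      ft$provenance <- provenance
      ft$disease_id <- d
      ft
    })
    dplyr::bind_rows(pieces)
  }

  positives <- build_rows(path_exp, path_exp$disease_id,
                          "causative", "pathogenic-causative")

  # pathogenic non-causative: same genotypes, mismatched disease
  other <- vapply(path_exp$disease_id, function(d) {
    pool <- setdiff(diseases$disease_id, d)
    if (length(pool) == 1) pool else sample(pool, 1)
  }, character(1))
  path_nc <- build_rows(path_exp, other, "non-causative",
                        "pathogenic-non-causative")

  benign <- labeled[labeled$label == "benign", ]
  benign_nc <- NULL
  if (nrow(benign) > 0) {
    bdis <- sample(diseases$disease_id, nrow(benign), replace = TRUE)
    benign$disease_id <- bdis
    benign$moi <- diseases$moi[match(bdis, diseases$disease_id)]
    benign_exp <- expand_genotypes(benign)
    benign_nc <- build_rows(benign_exp, benign_exp$disease_id,
                            "non-causative", "benign-non-causative")
  }

  negatives <- switch(
    mode,
    pathogenic = path_nc,
    benign = {
      if (is.null(benign_nc)) rlang::abort("benign mode requires benign variants")
      benign_nc
    },
    mixed = {
      if (is.null(benign_nc)) rlang::abort("mixed mode requires benign variants")
      n_each <- min(nrow(path_nc), nrow(benign_nc))
      dplyr::bind_rows(
        path_nc[sample(nrow(path_nc), n_each), ],
        benign_nc[sample(nrow(benign_nc), n_each), ]
      )
    }
  )
  out <- dplyr::bind_rows(positives, negatives)
  class(out) <- c("pp_examples", class(out))
  out
}

# Which features are categorical (imputed by mode rather than median)?
categorical_features <- function() c("zygosity", "moi", sprintf("flag_%02d", 1:54))

#' Fit and apply the missing-value imputer
#'
#' Missing numeric features are replaced by the feature's median, missing
#' categorical features by its mode. At training time the statistics are
#' label-conditional (a transparent analogue of decision-tree fractional
#' imputation); the imputer also stores pooled statistics, which are applied
#' at prediction time when labels are unknown. A feature missing in every
#' training example is an error naming the feature.
#'
#' @param examples training tibble from [make_training_set()].
#' @return `impute_missing()`: the examples with no missing feature values,
#'   with the fitted `pp_imputer` in the `imputer` attribute.
#' @export
impute_missing <- function(examples) {
  imp <- fit_imputer(examples)
  out <- apply_imputer(imp, examples, by_label = TRUE)
  attr(out, "imputer") <- imp
  out
}

fit_imputer <- function(examples) {
  feats <- feature_names()
  stat_of <- function(x, categorical) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
    if (categorical) as.numeric(names(sort(table(x), decreasing = TRUE))[1])
    else stats::median(x)
  }
  pooled <- vapply(feats, function(f) {
    stat_of(examples[[f]], f %in% categorical_features())
  }, numeric(1))
  all_missing <- names(pooled)[is.na(pooled)]
  if (length(all_missing) > 0) {
    rlang::abort(paste0("Feature(s) missing in every example: ",
                        paste(all_missing, collapse = ", ")))
  }
  by_label <- lapply(split(seq_len(nrow(examples)), examples$label), function(ix) {
    vapply(feats, function(f) {
      stat_of(examples[[f]][ix], f %in% categorical_features())
    }, numeric(1))
  })
  structure(list(pooled = pooled, by_label = by_label), class = "pp_imputer")
}

apply_imputer <- function(imputer, tab, by_label = FALSE) {
  for (f in feature_names()) {
    miss <- is.na(tab[[f]])
    if (!any(miss)) next
    if (by_label && !is.null(tab$label)) {
      for (lb in unique(tab$label[miss])) {
        v <- imputer$by_label[[lb]][[f]]
        if (is.na(v)) v <- imputer$pooled[[f]]
        tab[[f]][miss & tab$label == lb] <- v
      }
    } else {
      tab[[f]][miss] <- imputer$pooled[[f]]
    }
  }
  tab
}

#' Train a random-forest causative-variant classifier
#'
#' 100 trees of unlimited depth, 6 candidate features per split, seeded; the
#' prediction score is the forest's probability estimate (fraction of trees
#' voting causative). The three training modes differ only in the negative
#' pool (see [make_training_set()]): the pathogenic-negative model cannot
#' separate classes on pathogenicity scores (both sides are pathogenic) and
#' so leans on phenotype similarity; the benign-negative model is the
#' reverse; the mixed model balances the two.
#'
#' @param examples imputed or raw training tibble (missing values are
#'   imputed internally).
#' @param mode negative-sampling mode label stored with the model.
#' @param seed integer seed.
#' @return a `pp_model`: forest, feature signature, imputer, mode, seed.
#' @export
train_model <- function(examples, mode = "mixed", seed = 1L) {
  if (length(unique(examples$label)) < 2) {
    rlang::abort("Training requires both causative and non-causative examples")
  }
  imp <- attr(examples, "imputer")
  if (is.null(imp) || anyNA(as.matrix(examples[feature_names()]))) {
    examples <- impute_missing(examples)
    imp <- attr(examples, "imputer")
  }
  x <- as.data.frame(examples[feature_names()])
  y <- factor(examples$label, levels = c("non-causative", "causative"))
  set.seed(seed)
  forest <- randomForest::randomForest(
    x = x, y = y, ntree = 100, mtry = 6, nodesize = 1, maxnodes = NULL
  )
  structure(
    list(forest = forest, features = feature_names(), imputer = imp,
         mode = mode, seed = seed),
    class = "pp_model"
  )
}

#' @export
print.pp_model <- function(x, ...) {
  cat("<pp_model> random forest (", x$forest$ntree, " trees, mtry ",
      x$forest$mtry, "), negative mode '", x$mode, "', seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Causative probability for feature rows
#'
#' @param object a `pp_model`.
#' @param newdata tibble containing the 60 feature columns (missing values
#'   filled from the model's stored imputation table).
#' @param ... unused.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict.pp_model <- function(object, newdata, ...) {
  newdata <- apply_imputer(object$imputer, newdata, by_label = FALSE)
  x <- as.data.frame(newdata[object$features])
  unname(stats::predict(object$forest, x, type = "prob")[, "causative"])
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney estimator: the probability a random positive scores above a
#' random negative, ties counted one half (equivalent to the brute-force
#' pairwise comparison).
#'
#' @param scores numeric prediction scores.
#' @param labels logical or 0/1 vector, TRUE = positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    rlang::abort("ROC AUC requires both positive and negative labels")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

f_measure <- function(scores, labels, threshold = 0.5) {
  labels <- as.logical(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels)
  if (tp == 0) return(0)
  prec <- tp / sum(pred)
  rec <- tp / sum(labels)
  2 * prec * rec / (prec + rec)
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by label; each fold's model is trained (with
#' imputation fitted inside the fold) on the remaining folds and evaluated on
#' the held-out fold.
#'
#' @param examples training tibble from [make_training_set()].
#' @param k number of folds (>= 2).
#' @param seed integer seed for fold assignment and per-fold training.
#' @return a `pp_cv` object: tibble of per-fold `auc` and `f_measure`, with
#'   pooled metrics in attributes (`glance()` returns them).
#' @export
crossvalidate <- function(examples, k = 10L, seed = 1L) {
  if (k < 2) rlang::abort("k must be at least 2")
  labs <- examples$label
  counts <- table(labs)
  if (length(counts) < 2) rlang::abort("Both labels required")
  if (min(counts) < k) {
    rlang::abort(paste0("Smallest class has ", min(counts),
                        " examples; cannot stratify into ", k, " folds"))
  }
  set.seed(seed)
  fold <- integer(length(labs))
  for (lb in names(counts)) {
    ix <- which(labs == lb)
    fold[ix] <- sample(rep(seq_len(k), length.out = length(ix)))
  }
  pooled_scores <- numeric(length(labs))
  per_fold <- lapply(seq_len(k), function(f) {
    train <- examples[fold != f, ]
    test <- examples[fold == f, ]
    m <- train_model(train, mode = "cv", seed = seed + f)
    sc <- predict(m, test)
    pooled_scores[fold == f] <<- sc
    tibble::tibble(
      fold = f,
      auc = roc_auc(sc, test$label == "causative"),
      f_measure = f_measure(sc, test$label == "causative")
    )
  })
  out <- dplyr::bind_rows(per_fold)
  attr(out, "pooled_auc") <- roc_auc(pooled_scores, labs == "causative")
  attr(out, "pooled_f") <- f_measure(pooled_scores, labs == "causative")
  attr(out, "k") <- k
  class(out) <- c("pp_cv", class(out))
  out
}

#' @method glance pp_cv
#' @export
glance.pp_cv <- function(x, ...) {
  tibble::tibble(
    k = attr(x, "k"),
    mean_auc = mean(x$auc),
    mean_f = mean(x$f_measure),
    pooled_auc = attr(x, "pooled_auc"),
    pooled_f = attr(x, "pooled_f")
  )
}

#' Serialize / restore a trained model
#'
#' The artifact embeds the feature signature and imputation table so a
#' restored model validates its inputs.
#'
#' @param model a `pp_model`.
#' @param path file path.
#' @return `path` / the restored `pp_model`.
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "pp_model") || !identical(m$features, feature_names())) {
    rlang::abort("Not a compatible model artifact (feature signature mismatch)")
  }
  m
}
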