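#' Filter a patient's variants before ranking
#'
#' Applies, in order: (1) remove variants whose genotype was not confidently
#' called as het or hom; (2) for a recessive mode of inheritance, remove
#' heterozygous variants (the disease requires a 1/1 call); (3) remove
#' variants whose known minor allele frequency exceeds the cutoff (default
#' 1%; a missing MAF is treated as rare and retained). Each variant is
#' counted against the first rule that removes it.
#'
#' @param variants a `pp_variants` tibble.
#' @param moi mode of inheritance (`Dominant`, `Recessive`, `X-linked`,
#'   `Other`); only `Recessive` adds a zygosity filter.
#' @param maf_cutoff MAF cutoff in (0, 1].
#' @return the kept variants, with a `filter_log` attribute (tibble `rule`,
#'   `removed`); retrieve with [filter_log()].
#' @export
filter_variants <- function(variants, moi = "Other", maf_cutoff = 0.01) {
  stopifnot(maf_cutoff > 0, maf_cutoff <= 1)
  n0 <- nrow(variants)
  uncalled <- variants$genotype == "uncalled"
  variants <- variants[!uncalled, ]
  rec_het <- if (identical(moi, "Recessive")) variants$genotype == "het"
             else rep(FALSE, nrow(variants))
  variants <- variants[!rec_het, ]
  common <- !is.na(variants$maf) & variants$maf > maf_cutoff
  variants <- variants[!common, ]
  log <- tibble::tibble(
    rule = c("uncalled_genotype", "recessive_het", "maf_above_cutoff"),
    removed = c(sum(uncalled), sum(rec_het), sum(common))
  )
  attr(log, "n_input") <- n0
  attr(variants, "filter_log") <- log
  variants
}

#' @rdname filter_variants
#' @param x a filtered `pp_variants` tibble.
#' @export
filter_log <- function(x) attr(x, "filter_log")

#' Rank variants by causative probability
#'
#' Builds the 60-feature representation of every kept variant against the
#' patient profile, scores it with the trained model, and sorts descending.
#' Ties are broken deterministically: higher mean of the available
#' pathogenicity scores, then chromosome, then position ascending.
#'
#' @param kept filtered `pp_variants` tibble.
#' @param profile character vector of phenotype class IDs.
#' @param model a `pp_model`.
#' @param sim normalized gene-similarity tibble for this profile.
#' @param panel 54-class panel.
#' @param hierarchy a `pp_hierarchy`.
#' @param moi mode of inheritance presented with the profile.
#' @return a `pp_ranked` tibble: `rank`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `genotype`, `prob`, `similarity`, `score_1..3`.
#' @export
rank_variants <- function(kept, profile, model, sim, panel, hierarchy,
                          moi = "Other") {
  if (nrow(kept) == 0) {
    rlang::warn("No variants left to rank")
    out <- tibble::tibble(
      rank = integer(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), gene = character(),
      genotype = character(), prob = numeric(), similarity = numeric(),
      score_1 = numeric(), score_2 = numeric(), score_3 = numeric()
    )
    class(out) <- c("pp_ranked", class(out))
    return(out)
  }
  feats <- build_features(kept, profile, sim, panel, hierarchy, moi = moi)
  prob <- predict(model, feats)
  mean_score <- rowMeans(cbind(kept$score_1, kept$score_2, kept$score_3),
                         na.rm = TRUE)
  mean_score[is.nan(mean_score)] <- -Inf
  ord <- order(-prob, -mean_score, kept$chrom, kept$pos)
  out <- tibble::tibble(
    rank = seq_len(nrow(kept)),
    chrom = kept$chrom[ord], pos = kept$pos[ord],
    ref = kept$ref[ord], alt = kept$alt[ord],
    gene = kept$gene[ord], genotype = kept$genotype[ord],
    prob = prob[ord], similarity = feats$similarity[ord],
    score_1 = kept$score_1[ord], score_2 = kept$score_2[ord],
    score_3 = kept$score_3[ord]
  )
  class(out) <- c("pp_ranked", class(out))
  out
}

#' Run the end-to-end prioritization pipeline
#'
#' read VCF -> split alleles -> attach scores and MAF -> assign genes ->
#' filter -> profile-gene similarity -> features -> impute -> predict ->
#' rank. Every stage's record count is logged in the result's provenance.
#'
#' @param vcf path to the patient's single-sample VCF.
#' @param profile character vector of phenotype class IDs (all must exist in
#'   the hierarchy).
#' @param config list with elements `hierarchy`, `corpus`, `panel`, `model`,
#'   `genes` (interval tibble), `score_tables` (list of up to 3),
#'   `maf_table` (optional), `moi` (default `"Other"`), `maf_cutoff`
#'   (default 0.01), `sources` (default all three), and optionally
#'   precomputed `ic` / `res`.
#' @return a `pp_ranked` tibble with a `provenance` attribute (list with
#'   stage counts, filter log, MOI, sources, model mode).
#' @export
run_pipeline <- function(vcf, profile, config) {
  hierarchy <- config$hierarchy
  missing <- setdiff(profile, hierarchy$nodes)
  if (length(missing) > 0) {
    rlang::abort(paste0("Profile classes absent from hierarchy: ",
                        paste(missing, collapse = ", ")))
  }
  moi <- config$moi %||% "Other"
  sources <- config$sources %||% c("human", "mouse", "zebrafish")
  stage <- list()
  variants <- read_vcf(vcf)
  stage$read <- nrow(variants)
  variants <- attach_scores(variants, config$score_tables %||% list())
  variants <- attach_maf(variants, config$maf_table)
  variants <- assign_gene(variants, config$genes)
  kept <- filter_variants(variants, moi = moi,
                          maf_cutoff = config$maf_cutoff %||% 0.01)
  stage$kept <- nrow(kept)
  ic <- config$ic %||% compute_ic(config$corpus, hierarchy, sources = sources)
  res <- config$res
  sim <- profile_gene_similarity(profile, config$corpus, ic, hierarchy,
                                 sources = sources, res = res)
  ranked <- rank_variants(kept, profile, config$model, sim, config$panel,
                          hierarchy, moi = moi)
  attr(ranked, "provenance") <- list(
    vcf = vcf,
    profile = profile,
    moi = moi,
    sources = sources,
    model_mode = config$model$mode,
    stage_counts = stage,
    filter_log = as.data.frame(filter_log(kept))
  )
  ranked
}

#' Write a ranked result as TSV plus JSON provenance
#'
#' @param ranked a `pp_ranked` tibble.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_ranked <- function(ranked, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_plain(as.data.frame(ranked), file.path(dir, "ranked_variants.tsv"))
  prov <- attr(ranked, "provenance")
  if (!is.null(prov)) {
    jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}

#' @method tidy pp_ranked
#' @export
tidy.pp_ranked <- function(x, ...) tibble::as_tibble(x)

#' @method glance pp_ranked
#' @export
glance.pp_ranked <- function(x, ...) {
  tibble::tibble(
    n_ranked = nrow(x),
    top_prob = if (nrow(x)) x$prob[1] else NA_real_,
    top_gene = if (nrow(x)) x$gene[1] else NA_character_
  )
}

#' Plot the score profile of a ranked variant list
#'
#' Causative probability against rank, the spike the clinician scans for.
#'
#' @param object a `pp_ranked` tibble.
#' @param top_n show only the first `top_n` ranks.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot pp_ranked
#' @export
autoplot.pp_ranked <- function(object, top_n = 50, ...) {
  d <- tibble::as_tibble(object)[seq_len(min(top_n, nrow(object))), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$prob)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "rank", y = "causative probability") +
    ggplot2::theme_minimal()
}
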