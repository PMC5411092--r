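#' Rank a spike-in case in memory
#'
#' Convenience driver used by the evaluation experiments: gene assignment,
#' filtering, similarity, feature building and ranking for one generated
#' case, without file round-trips. An alternative profile (e.g. a perturbed
#' one) may be substituted.
#'
#' @param world a `pp_world`.
#' @param case a `pp_case`.
#' @param model a `pp_model`.
#' @param profile override the case profile (default: the case's own).
#' @param maf_cutoff MAF filter cutoff.
#' @param sources active annotation sources.
#' @return a `pp_ranked` tibble.
#' @export
score_case <- function(world, case, model, profile = NULL,
                       maf_cutoff = 0.01,
                       sources = c("human", "mouse", "zebrafish")) {
  profile <- profile %||% case$profile
  v <- assign_gene(case$variants, world$genes)
  kept <- filter_variants(v, moi = case$moi, maf_cutoff = maf_cutoff)
  ic <- world$ic
  res <- world$res
  if (!setequal(sources, c("human", "mouse", "zebrafish"))) {
    ic <- compute_ic(world$corpus, world$hierarchy, sources = sources)
    res <- resnik_matrix(ic, world$hierarchy)
  }
  sim <- profile_gene_similarity(profile, world$corpus, ic, world$hierarchy,
                                 sources = sources, res = res)
  rank_variants(kept, profile, model, sim, world$panel, world$hierarchy,
                moi = case$moi)
}

#' Rank of the causative variant in a ranked result
#'
#' @param ranked a `pp_ranked` tibble.
#' @param truth_key the causative variant's `chrom:pos:ref:alt` key.
#' @return integer rank, or `NA` if the variant received no rank (e.g. was
#'   filtered out). A key matching several ranked variants is an error.
#' @export
causative_rank <- function(ranked, truth_key) {
  key <- variant_key(ranked$chrom, ranked$pos, ranked$ref, ranked$alt)
  hit <- which(key == truth_key)
  if (length(hit) > 1) {
    rlang::abort(paste0("Truth key matches ", length(hit), " variants: ",
                        truth_key))
  }
  if (length(hit) == 0) NA_integer_ else ranked$rank[hit]
}

#' Top-k recovery summary over a cohort
#'
#' Counts cases whose causative variant was recovered at rank 1 and within
#' the top 10. Cases where the causative variant received no rank are
#' excluded from the percentage denominator but reported in `n_total`.
#' The median rank is the lower median for even counts.
#'
#' @param ranks integer vector of causative-variant ranks (`NA` = unranked),
#'   or a tibble with a `rank` column.
#' @return a `pp_recovery` tibble with one row: `n_total`, `n_ranked`,
#'   `n_top1`, `n_top10`, `pct_top1`, `pct_top10`, `median_rank`.
#' @export
rank_recovery <- function(ranks) {
  if (is.data.frame(ranks)) ranks <- ranks$rank
  r <- ranks[!is.na(ranks)]
  lower_median <- function(x) {
    if (length(x) == 0) return(NA_real_)
    sort(x)[floor((length(x) + 1) / 2)]
  }
  out <- tibble::tibble(
    n_total = length(ranks),
    n_ranked = length(r),
    n_top1 = sum(r == 1),
    n_top10 = sum(r <= 10),
    pct_top1 = if (length(r)) 100 * sum(r == 1) / length(r) else NA_real_,
    pct_top10 = if (length(r)) 100 * sum(r <= 10) / length(r) else NA_real_,
    median_rank = lower_median(r)
  )
  class(out) <- c("pp_recovery", class(out))
  out
}

#' Spearman correlation between profile information content and rank
#'
#' The information content of a profile is the sum of its classes' IC. A
#' negative correlation means richer (deeper) phenotyping yields better
#' (smaller) causative-variant ranks.
#'
#' @param profile_ic numeric vector: summed IC per case.
#' @param ranks integer vector of causative ranks per case.
#' @return Spearman's rho, or `NA` (with a message) when either input is
#'   constant.
#' @export
ic_rank_correlation <- function(profile_ic, ranks) {
  keep <- !is.na(profile_ic) & !is.na(ranks)
  profile_ic <- profile_ic[keep]; ranks <- ranks[keep]
  if (length(ranks) < 3) rlang::abort("Need at least 3 ranked cases")
  if (stats::sd(profile_ic) == 0 || stats::sd(ranks) == 0) {
    rlang::inform("Constant IC or rank; correlation undefined")
    return(NA_real_)
  }
  stats::cor(profile_ic, ranks, method = "spearman")
}

#' Sum of information content over a profile
#'
#' @param profile character vector of phenotype class IDs.
#' @param ic a `pp_ic` table.
#' @return numeric scalar (nats).
#' @export
profile_ic_sum <- function(profile, ic) {
  sum(ic_vector(ic)[profile])
}

#' Run the noise / two-variant experiment suite over a cohort
#'
#' For each case, ranks the causative variant under the clean condition and
#' under the requested perturbations: `"comorbid"` (a second disease's
#' phenotypes added), `"dropout"` (each phenotype dropped with probability
#' 1/3) and `"two-variant"` (the variant of the most phenotypically similar
#' other disease spiked in alongside; reported as the paired ranks of v1 and
#' v2 under v1's profile).
#'
#' @param world a `pp_world`.
#' @param cohort tibble from [simulate_cohort()].
#' @param model a `pp_model`.
#' @param conditions subset of `c("clean", "comorbid", "dropout",
#'   "two-variant")`.
#' @param seed integer seed for the perturbations.
#' @param dropout_p dropout probability.
#' @return a list: `ranks` (tibble `case_id`, `condition`, `rank`),
#'   `recovery` (one `pp_recovery` row per condition), `two_variant`
#'   (tibble `case_id`, `rank_v1`, `rank_v2` when requested).
#' @export
experiment_suite <- function(world, cohort, model,
                             conditions = c("clean", "comorbid", "dropout"),
                             seed = 1L, dropout_p = 1 / 3) {
  rank_rows <- list()
  twovar <- NULL
  for (i in seq_len(nrow(cohort))) {
    case <- cohort$case[[i]]
    cid <- cohort$case_id[i]
    for (cond in setdiff(conditions, "two-variant")) {
      prof <- switch(
        cond,
        clean = case$profile,
        comorbid = perturb_profile(case$profile, "comorbid", world,
                                   seed = seed + i, disease_id = case$disease_id),
        dropout = perturb_profile(case$profile, "dropout", world,
                                  seed = seed + i, p = dropout_p)
      )
      ranked <- score_case(world, case, model, profile = prof)
      rank_rows[[length(rank_rows) + 1]] <- tibble::tibble(
        case_id = cid, condition = cond,
        rank = causative_rank(ranked, case$truth$key)
      )
    }
    if ("two-variant" %in% conditions) {
      d2 <- perturb_profile(case$profile, "two-variant", world,
                            seed = seed + i, disease_id = case$disease_id)
      case2 <- spike_in_case(world, d2,
                             background_n = 0L,
                             signal = list(type = "separable"),
                             seed = seed + 10000L + i)
      v2 <- case2$variants[nrow(case2$variants), ] # the causative row
      merged <- case
      # drop any background variant sharing v2's key so each truth key is
      # unique in the merged case
      k1 <- paste(case$variants$chrom, case$variants$pos,
                  case$variants$ref, case$variants$alt, sep = ":")
      merged$variants <- dplyr::bind_rows(
        case$variants[k1 != case2$truth$key, ], v2)
      class(merged$variants) <- class(case$variants)
      ranked <- score_case(world, merged, model)
      twovar <- dplyr::bind_rows(twovar, tibble::tibble(
        case_id = cid,
        rank_v1 = causative_rank(ranked, case$truth$key),
        rank_v2 = causative_rank(ranked, case2$truth$key)
      ))
    }
  }
  ranks <- dplyr::bind_rows(rank_rows)
  if (nrow(ranks) == 0) {
    ranks <- tibble::tibble(case_id = character(), condition = character(),
                            rank = integer())
  }
  recovery <- dplyr::bind_rows(lapply(
    split(ranks, ranks$condition),
    function(d) dplyr::bind_cols(tibble::tibble(condition = d$condition[1]),
                                 rank_recovery(d$rank))
  ))
  list(ranks = ranks, recovery = recovery, two_variant = twovar)
}

#' @method glance pp_recovery
#' @export
glance.pp_recovery <- function(x, ...) tibble::as_tibble(x)

#' Plot recovery percentages per condition
#'
#' @param object tibble of per-condition recovery rows (as returned in
#'   `experiment_suite()$recovery`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_recovery <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("condition", "pct_top1", "pct_top10")],
    cols = c("pct_top1", "pct_top10"),
    names_to = "metric", values_to = "pct"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$pct,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(y = "% of ranked cases", x = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
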