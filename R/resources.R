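#' Read a single-sample VCF into a variant tibble
#'
#' Parses a VCF v4.x file with a `GT` FORMAT field and exactly one sample.
#' Multi-allelic rows are split into one record per alternate allele; the
#' genotype of each split record is `het` if the call combines the reference
#' allele with that alternate, `hom` if it is that alternate twice, and
#' `uncalled` otherwise (missing calls `./.`, half-calls, absent GT, and
#' multi-allelic calls such as `1/2` that are neither simply het nor hom with
#' respect to a single alternate). Positions stay 1-based.
#'
#' @param path VCF path.
#' @return a `pp_variants` tibble: `chrom`, `pos`, `ref`, `alt`, `genotype`,
#'   plus placeholder columns `maf`, `score_1..3`, `gene`, `exonic` filled by
#'   [attach_maf()], [attach_scores()] and [assign_gene()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2) {
    rlang::abort(paste0("VCF has no sample genotype columns: ", path))
  }
  if (ncol(gt) > 2) {
    rlang::abort(paste0("Multi-sample VCF not supported (",
                        ncol(gt) - 1, " samples): ", path))
  }
  fix <- v@fix
  n <- nrow(fix)
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  for (i in seq_len(n)) {
    if (is.na(pos[i]) || pos[i] < 1 ||
        is.na(fix[i, "REF"]) || fix[i, "REF"] == "" ||
        is.na(fix[i, "ALT"]) || fix[i, "ALT"] == "") {
      rlang::abort(paste0("Malformed VCF data row ", i, " in ", path))
    }
  }
  gt_str <- vapply(seq_len(n), function(i) {
    fmt <- strsplit(gt[i, 1], ":")[[1]]
    smp <- strsplit(gt[i, 2], ":")[[1]]
    k <- which(fmt == "GT")
    if (length(k) == 0 || length(smp) < k[1]) NA_character_ else smp[k[1]]
  }, character(1))

  rows <- lapply(seq_len(n), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    geno <- vapply(seq_along(alts), function(a) classify_gt(gt_str[i], a),
                   character(1))
    tibble::tibble(chrom = fix[i, "CHROM"], pos = pos[i],
                   ref = fix[i, "REF"], alt = alts, genotype = geno)
  })
  out <- dplyr::bind_rows(rows)
  out$maf <- NA_real_
  out$score_1 <- NA_real_
  out$score_2 <- NA_real_
  out$score_3 <- NA_real_
  out$gene <- NA_character_
  out$exonic <- NA
  class(out) <- c("pp_variants", class(out))
  out
}

# Classify a GT string with respect to alt allele index `a` (1-based).
classify_gt <- function(gt, a) {
  if (is.na(gt)) return("uncalled")
  al <- strsplit(gt, "[/|]")[[1]]
  if (length(al) != 2 || any(al == ".") ||
      anyNA(suppressWarnings(as.integer(al)))) {
    return("uncalled")
  }
  al <- sort(as.integer(al))
  if (al[1] == a && al[2] == a) return("hom")
  if (al[1] == 0 && al[2] == a) return("het")
  "uncalled"
}

#' Write variants back out as a minimal single-sample VCF
#'
#' @param variants a `pp_variants` tibble.
#' @param path output path.
#' @param sample sample name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, sample = "SAMPLE") {
  gt_of <- function(g) switch(g, het = "0/1", hom = "1/1", "./.")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT\t%s",
                  variants$chrom, variants$pos, variants$ref, variants$alt,
                  vapply(variants$genotype, gt_of, character(1)))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read gene intervals (BED-like TSV)
#'
#' Columns `chrom`, `start`, `end`, `gene_id`; intervals are 0-based
#' half-open and may overlap across genes.
#'
#' @param path TSV path.
#' @return a tibble with typed columns.
#' @export
read_gene_intervals <- function(path) {
  tb <- read_strict_tsv(path, c("chrom", "start", "end", "gene_id"))
  tb$start <- as.integer(tb$start)
  tb$end <- as.integer(tb$end)
  if (any(tb$start >= tb$end)) {
    rlang::abort("Gene intervals must satisfy start < end")
  }
  tb
}

#' Read a per-variant pathogenicity score table
#'
#' Columns `chrom`, `pos`, `ref`, `alt`, `score`, keyed by
#' `chrom:pos:ref:alt`. One table per score source.
#'
#' @param path TSV path.
#' @return a tibble with a `key` column added.
#' @export
read_score_table <- function(path) {
  tb <- read_strict_tsv(path, c("chrom", "pos", "ref", "alt", "score"))
  tb$pos <- as.integer(tb$pos)
  tb$score <- as.numeric(tb$score)
  tb$key <- variant_key(tb$chrom, tb$pos, tb$ref, tb$alt)
  tb
}

#' Read a minor-allele-frequency table
#'
#' Columns `chrom`, `pos`, `ref`, `alt`, `maf` with `maf` in \[0, 1\].
#'
#' @param path TSV path.
#' @return a tibble with a `key` column added.
#' @export
read_maf_table <- function(path) {
  tb <- read_strict_tsv(path, c("chrom", "pos", "ref", "alt", "maf"))
  tb$pos <- as.integer(tb$pos)
  tb$maf <- as.numeric(tb$maf)
  if (any(!is.na(tb$maf) & (tb$maf < 0 | tb$maf > 1))) {
    rlang::abort("MAF values must lie in [0, 1]")
  }
  tb$key <- variant_key(tb$chrom, tb$pos, tb$ref, tb$alt)
  tb
}

moi_levels <- function() c("Dominant", "Recessive", "X-linked", "Other")

#' Collapse raw mode-of-inheritance labels to the four feature values
#'
#' Source tables distinguish Dominant, Recessive, Multifactorial, Others,
#' Sporadic, X-linked and Y-linked; the classifier uses Dominant, Recessive,
#' X-linked and Other, so Multifactorial/Others/Sporadic/Y-linked collapse
#' to Other.
#'
#' @param moi character vector of raw labels.
#' @return character vector over the four collapsed values.
#' @export
collapse_moi <- function(moi) {
  known <- c("Dominant", "Recessive", "Multifactorial", "Others", "Sporadic",
             "X-linked", "Y-linked", "Other")
  bad <- setdiff(unique(moi), known)
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown mode-of-inheritance label(s): ",
                        paste(bad, collapse = ", ")))
  }
  out <- moi
  out[moi %in% c("Multifactorial", "Others", "Sporadic", "Y-linked")] <- "Other"
  out
}

#' Read a disease-phenotype / mode-of-inheritance table
#'
#' Long TSV with columns `disease_id`, `moi`, `phenotype_id` (one phenotype
#' per row; a row with empty `phenotype_id` declares a disease without
#' phenotype annotations). MOI labels are collapsed via [collapse_moi()].
#'
#' @param path TSV path.
#' @param hierarchy optional `pp_hierarchy` to validate phenotype IDs.
#' @return a nested tibble: `disease_id`, `moi`, `phenotypes` (list-column).
#' @export
read_disease_table <- function(path, hierarchy = NULL) {
  tb <- read_strict_tsv(path, c("disease_id", "moi", "phenotype_id"))
  tb$moi <- collapse_moi(tb$moi)
  if (!is.null(hierarchy)) {
    missing <- setdiff(stats::na.omit(unique(tb$phenotype_id)), hierarchy$nodes)
    if (length(missing) > 0) {
      rlang::abort(paste0("Disease phenotype classes absent from hierarchy: ",
                          paste(missing, collapse = ", ")))
    }
  }
  ids <- unique(tb$disease_id)
  tibble::tibble(
    disease_id = ids,
    moi = unname(vapply(ids, function(d) tb$moi[tb$disease_id == d][1],
                        character(1))),
    phenotypes = lapply(ids, function(d) {
      as.character(stats::na.omit(tb$phenotype_id[tb$disease_id == d]))
    })
  )
}

#' Read a labeled (ClinVar-like) variant table
#'
#' Columns `chrom`, `pos`, `ref`, `alt`, `significance`, `disease_id`.
#' Significance codes follow the ClinVar convention: `5` = pathogenic,
#' `2` = benign; other codes are dropped with a message. Pathogenic rows must
#' carry a disease ID; a variant causal for several diseases appears as
#' several rows.
#'
#' @param path TSV path.
#' @return a tibble `chrom`, `pos`, `ref`, `alt`, `label`
#'   (`pathogenic`/`benign`), `disease_id`.
#' @export
read_labeled_variants <- function(path) {
  tb <- read_strict_tsv(path, c("chrom", "pos", "ref", "alt", "significance",
                                "disease_id"))
  tb$pos <- as.integer(tb$pos)
  keep <- tb$significance %in% c("2", "5")
  if (any(!keep)) {
    rlang::inform(paste0("Dropping ", sum(!keep),
                         " row(s) with significance codes other than 2/5"))
  }
  tb <- tb[keep, ]
  tb$label <- ifelse(tb$significance == "5", "pathogenic", "benign")
  if (any(tb$label == "pathogenic" & (is.na(tb$disease_id) | tb$disease_id == ""))) {
    rlang::abort("Pathogenic rows must carry a disease_id")
  }
  tb$significance <- NULL
  tb
}

#' Assign each variant to its containing or closest gene
#'
#' A variant inside at least one gene interval gets the containing gene
#' (ties broken by smallest start) and is flagged exonic; otherwise the gene
#' minimizing the distance to the nearest contained coordinate wins
#' (`start - pos` upstream, `pos - (end - 1)` downstream), distance ties
#' again broken by smaller start. Chromosomes with no gene leave the variant
#' unassigned with a warning.
#'
#' @param variants a `pp_variants` tibble.
#' @param genes a gene-interval tibble from [read_gene_intervals()].
#' @return `variants` with `gene` and `exonic` filled.
#' @export
assign_gene <- function(variants, genes) {
  warned <- character(0)
  for (i in seq_len(nrow(variants))) {
    g <- genes[genes$chrom == variants$chrom[i], ]
    if (nrow(g) == 0) {
      if (!variants$chrom[i] %in% warned) {
        rlang::warn(paste0("No genes on chromosome ", variants$chrom[i],
                           "; variants left unassigned"))
        warned <- c(warned, variants$chrom[i])
      }
      next
    }
    pos <- variants$pos[i]
    inside <- g$start <= pos & pos < g$end
    if (any(inside)) {
      gi <- g[inside, ]
      pick <- gi$gene_id[order(gi$start)][1]
      variants$gene[i] <- pick
      variants$exonic[i] <- TRUE
    } else {
      dist <- ifelse(pos < g$start, g$start - pos, pos - (g$end - 1))
      pick <- g$gene_id[order(dist, g$start)][1]
      variants$gene[i] <- pick
      variants$exonic[i] <- FALSE
    }
  }
  variants
}

#' Attach pathogenicity scores from the three score sources
#'
#' Each table is keyed by `chrom:pos:ref:alt`; variants absent from a table
#' keep a missing score (imputed at model time) and are never dropped.
#'
#' @param variants a `pp_variants` tibble.
#' @param score_tables list of up to three score tibbles
#'   (see [read_score_table()]); element `k` fills `score_k`.
#' @return `variants` with `score_1..3` filled where known.
#' @export
attach_scores <- function(variants, score_tables) {
  key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  for (k in seq_along(score_tables)) {
    tb <- score_tables[[k]]
    if (is.null(tb) || nrow(tb) == 0) next
    m <- match(key, tb$key)
    variants[[paste0("score_", k)]] <- tb$score[m]
  }
  variants
}

#' Attach minor allele frequencies
#'
#' Variants absent from the table keep a missing MAF, which downstream
#' filtering treats as rare (novel variants are the method's main target).
#'
#' @param variants a `pp_variants` tibble.
#' @param maf_table a MAF tibble from [read_maf_table()] (or NULL).
#' @return `variants` with `maf` filled where known.
#' @export
attach_maf <- function(variants, maf_table) {
  if (is.null(maf_table) || nrow(maf_table) == 0) return(variants)
  key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  variants$maf <- maf_table$maf[match(key, maf_table$key)]
  variants
}
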