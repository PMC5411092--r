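# VCF reading/splitting, gene assignment, score/MAF attachment, table readers.

write_test_vcf <- function(rows, path, samples = "S1") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, rows), path)
  path
}

test_that("read_vcf splits multi-allelic rows and classifies genotypes", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(c(
    "chr1\t100\t.\tA\tT\t.\t.\t.\tGT\t0/1",
    "chr1\t200\t.\tG\tC\t.\t.\t.\tGT\t0|1",
    "chr1\t300\t.\tT\tA\t.\t.\t.\tGT\t1/1",
    "chr1\t400\t.\tC\tG,T\t.\t.\t.\tGT\t1/2",
    "chr1\t500\t.\tA\tC\t.\t.\t.\tGT\t./.",
    "chr1\t600\t.\tG\tA,T\t.\t.\t.\tGT\t0/2"
  ), path)
  v <- read_vcf(path)
  # splitting conserves count: sum of per-row alt alleles
  expect_equal(nrow(v), 8)
  expect_equal(v$genotype[v$pos == 100], "het")
  expect_equal(v$genotype[v$pos == 200], "het") # phased dialect
  expect_equal(v$genotype[v$pos == 300], "hom")
  # 1/2 is neither het-against-ref nor hom for either single alt
  expect_equal(v$genotype[v$pos == 400], c("uncalled", "uncalled"))
  expect_equal(v$genotype[v$pos == 500], "uncalled")
  expect_equal(v$genotype[v$pos == 600], c("uncalled", "het"))
  expect_equal(v$alt[v$pos == 400], c("G", "T"))
})

test_that("read_vcf rejects multi-sample files and malformed rows", {
  multi <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf("chr1\t100\t.\tA\tT\t.\t.\t.\tGT\t0/1\t0/0", multi,
                 samples = c("S1", "S2"))
  expect_error(read_vcf(multi), "Multi-sample")

  bad <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf("chr1\tnotanumber\t.\tA\tT\t.\t.\t.\tGT\t0/1", bad)
  expect_error(suppressWarnings(read_vcf(bad)), "row 1")
})

test_that("variants round-trip through write_vcf and read_vcf", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(c(
    "chr2\t10\t.\tA\tT\t.\t.\t.\tGT\t0/1",
    "chr2\t20\t.\tGA\tG\t.\t.\t.\tGT\t1/1"
  ), path)
  v1 <- read_vcf(path)
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v1, path2)
  v2 <- read_vcf(path2)
  cols <- c("chrom", "pos", "ref", "alt", "genotype")
  expect_identical(as.data.frame(v1[cols]), as.data.frame(v2[cols]))
})

test_that("assign_gene follows containment, boundary distance and tie-breaks", {
  genes <- tibble::tibble(
    chrom = "chr1", start = c(100L, 400L), end = c(200L, 500L),
    gene_id = c("G1", "G2")
  )
  mk <- function(pos) {
    v <- tibble::tibble(chrom = "chr1", pos = pos, ref = "A", alt = "T",
                        genotype = "het", maf = NA_real_,
                        score_1 = NA_real_, score_2 = NA_real_,
                        score_3 = NA_real_, gene = NA_character_, exonic = NA)
    class(v) <- c("pp_variants", class(v))
    v
  }
  inside <- assign_gene(mk(150L), genes)
  expect_equal(inside$gene, "G1")
  expect_true(inside$exonic)
  # distance 51 to G1's last contained coordinate vs 150 to G2's start
  between <- assign_gene(mk(250L), genes)
  expect_equal(between$gene, "G1")
  expect_false(between$exonic)
  # independent brute force over the distance rule for a sweep of positions
  for (pos in c(50L, 99L, 205L, 299L, 300L, 301L, 399L, 600L)) {
    got <- assign_gene(mk(pos), genes)$gene
    d <- vapply(seq_len(nrow(genes)), function(i) {
      if (genes$start[i] <= pos && pos < genes$end[i]) return(0L)
      min(abs(pos - genes$start[i]), abs(pos - (genes$end[i] - 1L)))
    }, integer(1))
    expect_equal(got, genes$gene_id[order(d, genes$start)][1],
                 info = paste("pos", pos))
  }
  # equidistant: 300 is 101 from G1's last base (199) and 100 from G2 start;
  # 299+1/2... use a symmetric pair instead
  genes2 <- tibble::tibble(chrom = "chr1", start = c(100L, 300L),
                           end = c(200L, 400L), gene_id = c("GB", "GA"))
  tie <- assign_gene(mk(249L), genes2) # 50 from 199, 51 from 300 -> GB
  expect_equal(tie$gene, "GB")
  tie2 <- assign_gene(mk(250L), genes2) # 51 vs 50 -> GA
  expect_equal(tie2$gene, "GA")
  # containment tie: overlapping genes, smaller start wins
  genes3 <- tibble::tibble(chrom = "chr1", start = c(120L, 100L),
                           end = c(220L, 200L), gene_id = c("GX", "GY"))
  expect_equal(assign_gene(mk(150L), genes3)$gene, "GY")
  # no gene on chromosome leaves the variant unassigned with a warning
  expect_warning(out <- assign_gene(mk(10L),
                                    dplyr::mutate(genes, chrom = "chr9")),
                 "chr1")
  expect_true(is.na(out$gene))
})

test_that("attach_scores fills what is present and leaves the rest missing", {
  v <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L), ref = "A",
                      alt = "T", genotype = "het", maf = NA_real_,
                      score_1 = NA_real_, score_2 = NA_real_,
                      score_3 = NA_real_, gene = NA_character_, exonic = NA)
  tb <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                       score = 0.7, key = "chr1:100:A:T")
  out <- attach_scores(v, list(tb, tb[0, ], NULL))
  expect_equal(out$score_1, c(0.7, NA))
  expect_true(all(is.na(out$score_2)))
  expect_true(all(is.na(out$score_3)))
  expect_equal(nrow(out), 2) # never drops records
})

test_that("strict readers reject unknown columns and validate values", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tgene_id\tbogus",
               "chr1\t1\t10\tG1\tx"), p)
  expect_error(read_gene_intervals(p), "bogus")
  writeLines(c("chrom\tstart\tend\tgene_id", "chr1\t10\t10\tG1"), p)
  expect_error(read_gene_intervals(p), "start < end")
  writeLines(c("chrom\tpos\tref\talt\tmaf", "chr1\t5\tA\tT\t1.5"), p)
  expect_error(read_maf_table(p), "\\[0, 1\\]")
})

test_that("MOI labels collapse to the four feature values", {
  expect_equal(
    collapse_moi(c("Dominant", "Recessive", "Multifactorial", "Others",
                   "Sporadic", "X-linked", "Y-linked")),
    c("Dominant", "Recessive", "Other", "Other", "Other", "X-linked", "Other")
  )
  expect_error(collapse_moi("Mendelian"), "Mendelian")
})

test_that("disease and labeled-variant tables parse and validate", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "disease_id\tmoi\tphenotype_id",
    "D1\tRecessive\tP:x", "D1\tRecessive\tP:y",
    "D2\tSporadic\tP:z", "D3\tDominant\t"
  ), p)
  d <- read_disease_table(p)
  expect_equal(nrow(d), 3)
  expect_equal(d$moi, c("Recessive", "Other", "Dominant"))
  expect_equal(d$phenotypes[[1]], c("P:x", "P:y"))
  expect_length(d$phenotypes[[3]], 0)

  lv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "chrom\tpos\tref\talt\tsignificance\tdisease_id",
    "chr1\t10\tA\tT\t5\tD1",
    "chr1\t10\tA\tT\t5\tD2", # same variant, second disease: second record
    "chr1\t20\tG\tC\t2\t",
    "chr1\t30\tT\tA\t3\t"
  ), lv)
  expect_message(tab <- read_labeled_variants(lv), "significance")
  expect_equal(nrow(tab), 3)
  expect_equal(sum(tab$label == "pathogenic"), 2)
  writeLines(c("chrom\tpos\tref\talt\tsignificance\tdisease_id",
               "chr1\t10\tA\tT\t5\t"), lv)
  expect_error(read_labeled_variants(lv), "disease_id")
})
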