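test_that("toy table parses with missingness recorded", {
  path <- write_toy_table(tempfile(fileext = ".tsv"))
  ds <- read_variant_table(path)
  expect_s3_class(ds, "variant_dataset")
  expect_equal(nrow(ds$records), 3)
  expect_equal(ds$records$label,
               c("pathogenic", "neutral", "neutral"))
  expect_equal(sum(ds$features$mask), 1)
  expect_true(ds$features$mask[2, "cadd_phred"])
  expect_equal(colnames(ds$features$values), c("cadd_phred", "sift_score"))
})

test_that("identity-column and duplicate-key errors are raised", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tref\talt\taa_change\tscore",
               "ND1\tA\tG\tM1V\t1.0"), bad)
  expect_error(read_variant_table(bad), class = "apogee_format_error")

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tposition\tref\talt\taa_change",
               "ND1\t3400\tA\tG\tM1V",
               "ND1\t3400\tC\tG\tM1V"), dup)
  expect_error(read_variant_table(dup),
               class = "apogee_duplicate_variant_error")

  expect_error(read_variant_table(tempfile()), class = "apogee_format_error")
})

test_that("write/read round trip is lossless for values and missingness", {
  set.seed(101)
  n <- 100; p <- 10
  vals <- matrix(rnorm(n * p) * 10^sample(-3:3, n * p, TRUE), n, p)
  vals[sample(n * p, 40)] <- NA
  colnames(vals) <- paste0("score_", letters[1:p])
  spans <- sample(3307:4262, n)
  records <- data.frame(gene = "ND1", position = spans, ref = "A",
                        alt = "G", aa_change = "M1V",
                        label = sample(c("pathogenic", "neutral"), n, TRUE),
                        stringsAsFactors = FALSE)
  ds <- variant_dataset(records, feature_matrix(vals))
  for (dialect in c("tsv", "csv")) {
    path <- tempfile()
    write_variant_table(ds, path, dialect = dialect)
    back <- read_variant_table(path, dialect = dialect)
    expect_identical(back$features$values, ds$features$values)
    expect_identical(back$features$mask, ds$features$mask)
    expect_identical(back$records$position, ds$records$position)
    expect_identical(back$records$label, ds$records$label)
  }
})

test_that("label curation follows the MITOMAP/dbSNP rules", {
  entries <- data.frame(
    mitomap_status = c("reported", "absent", "confirmed", "reported"),
    mitomap_pathogenic = c(FALSE, NA, TRUE, NA),
    dbsnp_clinical = c("absent", "none", "absent", "pathological"),
    stringsAsFactors = FALSE)
  # 9055:G>A-style explicitly non-pathogenic MITOMAP entry -> neutral;
  # dbSNP-only benign -> neutral; confirmed disease-linked -> pathogenic
  expect_equal(assign_labels(entries),
               c("neutral", "neutral", "pathogenic", "pathogenic"))

  conflict <- data.frame(mitomap_status = "reported",
                         mitomap_pathogenic = FALSE,
                         dbsnp_clinical = "pathological")
  expect_error(assign_labels(conflict), class = "apogee_curation_error")
  orphan <- data.frame(mitomap_status = "absent",
                       mitomap_pathogenic = NA,
                       dbsnp_clinical = "absent")
  expect_error(assign_labels(orphan), class = "apogee_curation_error")
})

test_that("assign_labels is total and partition sizes sum to input size", {
  set.seed(5)
  n <- 200
  entries <- data.frame(
    mitomap_status = sample(c("confirmed", "reported", "absent"), n, TRUE),
    mitomap_pathogenic = sample(c(TRUE, FALSE, NA), n, TRUE,
                                prob = c(0.2, 0.1, 0.7)),
    dbsnp_clinical = sample(c("pathological", "none"), n, TRUE),
    stringsAsFactors = FALSE)
  # remove contradictions so the call is total
  bad <- !is.na(entries$mitomap_pathogenic) & !entries$mitomap_pathogenic &
    entries$dbsnp_clinical == "pathological"
  entries$dbsnp_clinical[bad] <- "none"
  lab <- assign_labels(entries)
  expect_equal(length(lab), n)
  expect_true(all(lab %in% c("pathogenic", "neutral")))
  expect_identical(assign_labels(entries), lab)  # deterministic
})

test_that("per-gene summaries count totals and pathogenic fractions", {
  rec <- data.frame(gene = rep("ND5", 10),
                    position = 12400:12409, ref = "A", alt = "G",
                    aa_change = "M1V",
                    label = rep(c("pathogenic", "neutral"), c(2, 8)),
                    stringsAsFactors = FALSE)
  s <- summarize_by_gene(variant_dataset(rec))
  expect_equal(s$total, 10)
  expect_equal(s$pathogenic, 2)
  expect_equal(s$pathogenic_pct, 20.0)

  empty <- variant_dataset(rec[0, ])
  expect_equal(nrow(summarize_by_gene(empty)), 0)

  # the published per-gene table's largest row: ND5, 140 variants, 28
  # pathogenic (20%)
  rec2 <- data.frame(gene = "ND5", position = sample(12337:14148, 140),
                     ref = "A", alt = "G", aa_change = "M1V",
                     label = rep(c("pathogenic", "neutral"), c(28, 112)),
                     stringsAsFactors = FALSE)
  s2 <- summarize_by_gene(variant_dataset(rec2))
  expect_equal(unlist(s2[, c("total", "pathogenic", "pathogenic_pct")]),
               c(total = 140, pathogenic = 28, pathogenic_pct = 20.0))
})

test_that("missense enumeration matches brute-force hand translation", {
  # single plus-strand toy gene: ATG GCT TGA (M, A, stop)
  genes <- data.frame(gene = "ND1", start = 1, end = 9, strand = "+",
                      codon_start = 1)
  rec <- enumerate_missense("ATGGCTTGA", genes)
  # brute-force oracle: all 27 substitutions, translated independently
  gc2 <- Biostrings::getGeneticCode("2")
  seq <- strsplit("ATGGCTTGA", "")[[1]]
  hand <- 0
  for (pos in 1:9) for (alt in setdiff(c("A", "C", "G", "T"), seq[pos])) {
    mut <- seq; mut[pos] <- alt
    i <- (pos - 1) %/% 3 + 1
    ref_aa <- gc2[[paste(seq[(3 * i - 2):(3 * i)], collapse = "")]]
    alt_aa <- gc2[[paste(mut[(3 * i - 2):(3 * i)], collapse = "")]]
    if (ref_aa != alt_aa) hand <- hand + 1
  }
  expect_equal(nrow(rec), hand)
  # every emitted record changes the amino acid
  expect_true(all(substr(rec$aa_change, 1, 1) !=
                    substring(rec$aa_change, nchar(rec$aa_change))))
})

test_that("synonymous substitutions are never emitted and order is stable", {
  # CTA -> CTG is synonymous (both Leu) under the mitochondrial code
  genes <- data.frame(gene = "CYB", start = 1, end = 3, strand = "+",
                      codon_start = 1)
  rec <- enumerate_missense("CTA", genes)
  expect_false(any(rec$position == 3 & rec$alt == "G"))
  # deterministic (gene, position, alt) ordering
  expect_identical(order(rec$gene, rec$position, rec$alt), seq_len(nrow(rec)))
  # count invariant to gene-row ordering
  genes2 <- data.frame(gene = c("CYB", "ND1"),
                       start = c(1, 4), end = c(3, 9),
                       strand = "+", codon_start = 1)
  seq2 <- "CTAATGGCT"
  expect_equal(nrow(enumerate_missense(seq2, genes2)),
               nrow(enumerate_missense(seq2, genes2[2:1, ])))
})

test_that("reverse-strand genes report plus-strand alleles", {
  # plus-strand CAT at 1..3; the minus-strand CDS is ATG (Met)
  genes <- data.frame(gene = "ND6", start = 1, end = 3, strand = "-",
                      codon_start = 1)
  rec <- enumerate_missense("CAT", genes)
  # the CDS codon's first base sits at plus-strand position 3 (ref T);
  # a minus-strand A->G change (GTG, Val) is plus-strand T>C
  expect_true(all(rec$ref[rec$position == 3] == "T"))
  m1 <- rec[rec$position == 3 & rec$alt == "C", ]
  expect_equal(m1$aa_change, "M1V")
})

test_that("frame errors and stop-handling flag behave", {
  genes <- data.frame(gene = "ND1", start = 1, end = 8, strand = "+",
                      codon_start = 1)
  expect_error(enumerate_missense("ATGGCTTG", genes),
               class = "apogee_annotation_error")
  genes3 <- data.frame(gene = "ND1", start = 1, end = 6, strand = "+",
                       codon_start = 1)
  with_stop <- enumerate_missense("ATGGCT", genes3, include_stop = TRUE)
  no_stop <- enumerate_missense("ATGGCT", genes3, include_stop = FALSE)
  expect_true(nrow(no_stop) < nrow(with_stop))
  expect_false(any(grepl("\\*", no_stop$aa_change)))
})
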