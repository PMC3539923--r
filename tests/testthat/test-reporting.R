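test_that("category distribution reports fixed categories with percentages", {
  g <- mk_coding_gene("ATGTGCGCTTAA")
  v <- dplyr::bind_rows(
    lapply(1:4, function(i) mk_snv("c", 14, "T", "C")),   # missense
    lapply(1:6, function(i) mk_snv("chrZ", i * 10, "A", "G")))  # intergenic
  ann <- annotate_variants(v, g$tx, g$genome)
  d <- category_distribution(ann)
  snv <- d[d$var_class == "snv", ]
  expect_equal(snv$n_before[snv$category == "missense"], 4L)
  expect_equal(snv$pct_before[snv$category == "missense"], 40)
  expect_equal(snv$pct_before[snv$category == "intergenic"], 60)
  expect_equal(sum(snv$pct_before), 100)
  # all nine SNV categories and four InDel categories always present
  expect_equal(sum(d$var_class == "snv"), 9L)
  expect_equal(sum(d$var_class == "indel"), 4L)

  empty <- category_distribution(ann[0, ])
  expect_true(all(empty$n_before == 0L))
  expect_true(all(empty$pct_before == 0))
})

test_that("distribution recovers the planted fixture composition", {
  fx <- std_fixture()
  rep <- run_single_case(fx$samples$case3, fx$genome, fx$transcripts,
                         known = fx$known, panel = fx$panel,
                         criteria = als_preset())
  truth <- fx$truth[fx$truth$sample_id == "case3", ]
  d <- rep$distribution
  for (cat in names(fx$spec$snv_counts)) {
    expect_equal(d$n_before[d$var_class == "snv" & d$category == cat],
                 unname(fx$spec$snv_counts[cat]),
                 info = cat)
  }
  for (cat in names(fx$spec$indel_counts)) {
    expect_equal(d$n_before[d$var_class == "indel" & d$category == cat],
                 unname(fx$spec$indel_counts[cat]),
                 info = cat)
  }
  # after-filter counts equal the retained composition
  expect_equal(sum(d$n_after), nrow(rep$retained))
})

test_that("detail tables carry the documented columns and round-trip", {
  fx <- std_fixture()
  rep <- run_single_case(fx$samples$case1, fx$genome, fx$transcripts,
                         known = fx$known, panel = fx$panel,
                         criteria = als_preset())
  snv_path <- tempfile(fileext = ".tsv")
  write_detail_table(rep$retained, "snv", snv_path, freq = rep$freq)
  back <- read_detail_table(snv_path)
  expect_identical(names(back),
                   c("rs_id", "gene_name", "transcript_id", "aa_change",
                     "snp_frequency", "mutation_type", "snp_function",
                     "damage_prediction"))
  kept_snv <- rep$retained[rep$retained$var_class == "snv", ]
  expect_equal(nrow(back), nrow(kept_snv))
  expect_identical(back$gene_name, kept_snv$gene_name)
  expect_identical(back$snp_function, kept_snv$category)
  expect_identical(back$aa_change, kept_snv$aa_change)
  expect_true(all(back$mutation_type %in% c("transition", "transversion")))
  expect_true(all(grepl("CHB:maf=", back$snp_frequency)))
  expect_true(all(is.na(back$rs_id)))  # retained candidates are novel

  indel_path <- tempfile(fileext = ".tsv")
  write_detail_table(rep$retained, "indel", indel_path)
  iback <- read_detail_table(indel_path)
  expect_identical(names(iback),
                   c("sn", "contig", "pos", "strand", "indel_seq",
                     "substitution_class", "rs_id", "support", "gene_name",
                     "region"))
  expect_identical(iback$sn, as.character(seq_len(nrow(iback))))
  kept_ind <- rep$retained[rep$retained$var_class != "snv", ]
  expect_identical(as.integer(iback$pos), kept_ind$pos)
  expect_identical(iback$substitution_class, kept_ind$var_class)
})

test_that("export bundle has a deterministic five-member layout", {
  fx <- std_fixture()
  rep <- run_single_case(fx$samples$case1, fx$genome, fx$transcripts,
                         known = fx$known, panel = fx$panel,
                         criteria = als_preset())
  out1 <- file.path(tempdir(), "b1"); out2 <- file.path(tempdir(), "b2")
  a1 <- export_bundle(rep, out1)
  expect_identical(attr(a1, "members"),
                   c("annotation_final.tsv", "annotation_intermediate.tsv",
                     "category_distribution.tsv", "criteria.cfg",
                     "input_variants.tsv"))
  a2 <- export_bundle(rep, out2)
  # member contents are byte-identical between runs
  x1 <- file.path(tempfile("u1")); x2 <- file.path(tempfile("u2"))
  utils::untar(a1, exdir = x1); utils::untar(a2, exdir = x2)
  for (m in attr(a1, "members")) {
    f1 <- list.files(x1, pattern = m, recursive = TRUE, full.names = TRUE)
    f2 <- list.files(x2, pattern = m, recursive = TRUE, full.names = TRUE)
    expect_identical(readLines(f1), readLines(f2))
  }
  # summary counts are recomputable from the bundled tables
  inter <- readr::read_tsv(
    list.files(x1, pattern = "annotation_intermediate", recursive = TRUE,
               full.names = TRUE), show_col_types = FALSE)
  final <- readr::read_tsv(
    list.files(x1, pattern = "annotation_final", recursive = TRUE,
               full.names = TRUE), show_col_types = FALSE)
  fr <- rep$filter_report
  expect_equal(nrow(inter), attr(fr, "n_before"))
  expect_equal(nrow(final), attr(fr, "n_after"))

  # a two-case run adds the shared/unique tables
  rep2 <- run_single_case(fx$samples$case2, fx$genome, fx$transcripts,
                          known = fx$known, panel = fx$panel,
                          criteria = als_preset())
  cmp <- run_two_cases(rep, rep2)
  a3 <- export_bundle(rep, file.path(tempdir(), "b3"), comparison = cmp)
  expect_true(all(c("shared_variants.tsv", "unique_a_variants.tsv",
                    "unique_b_variants.tsv") %in% attr(a3, "members")))
})

test_that("report objects support the broom-style verbs and autoplot", {
  fx <- std_fixture()
  rep <- run_single_case(fx$samples$case1, fx$genome, fx$transcripts,
                         known = fx$known, panel = fx$panel,
                         criteria = als_preset())
  g <- glance(rep)
  expect_equal(g$n_effective, nrow(fx$samples$case1))
  expect_equal(g$n_retained, nrow(rep$retained))
  td <- tidy(rep)
  expect_identical(td, rep$distribution)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
  expect_s3_class(tidy(rep$filter_report), "tbl_df")
})
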