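ann_case1 <- function() {
  fx <- std_fixture()
  run_single_case(fx$samples$case1, fx$genome, fx$transcripts,
                  known = fx$known, panel = fx$panel)
}

test_that("unset criteria are the identity filter", {
  rep <- ann_case1()
  kept <- filter_variants(rep$annotations, filter_criteria())
  expect_equal(nrow(kept), nrow(rep$annotations))
  expect_true(all(filter_report(kept)$removed == 0L))
  fr <- filter_report(kept)
  expect_equal(attr(fr, "n_before") - attr(fr, "n_after"),
               sum(fr$removed))
})

test_that("filters retain exactly the planted composition", {
  fx <- std_fixture()
  rep <- ann_case1()
  truth <- fx$truth[fx$truth$sample_id == "case1", ]

  kept <- filter_variants(rep$annotations,
                          filter_criteria(snp_novelty = "novel_only",
                                          snp_classification = "missense"))
  expected <- truth$key[(truth$var_class == "snv" &
                           truth$novelty == "novel" &
                           truth$category == "missense") |
                          truth$var_class != "snv"]
  expect_setequal(variant_key(kept), expected)

  kept2 <- filter_variants(rep$annotations,
                           filter_criteria(indel_coding_only = TRUE))
  expected2 <- truth$key[truth$var_class == "snv" |
                           truth$category != "non_coding"]
  expect_setequal(variant_key(kept2), expected2)

  # novel_or_disease also keeps the clinically associated
  kept3 <- filter_variants(rep$annotations,
                           filter_criteria(snp_novelty = "novel_or_disease"))
  expected3 <- truth$key[truth$var_class != "snv" |
                           truth$novelty %in% c("novel",
                                                "known_disease_related")]
  expect_setequal(variant_key(kept3), expected3)
})

test_that("criteria are conjunctive, monotone and order-consistent", {
  rep <- ann_case1()
  fx <- std_fixture()
  freq <- rep$freq
  loose <- filter_variants(rep$annotations,
                           filter_criteria(snp_novelty = "novel_only"))
  tight <- filter_variants(rep$annotations,
                           filter_criteria(snp_novelty = "novel_only",
                                           snp_zygosity = "het",
                                           snp_classification =
                                             c("missense", "nonsense")))
  expect_true(all(variant_key(tight) %in% variant_key(loose)))

  # applying criteria jointly equals applying them in two passes
  two_pass <- filter_variants(
    filter_variants(rep$annotations,
                    filter_criteria(snp_novelty = "novel_only")),
    filter_criteria(snp_classification = c("missense", "nonsense")))
  joint <- filter_variants(rep$annotations,
                           filter_criteria(snp_novelty = "novel_only",
                                           snp_classification =
                                             c("missense", "nonsense")))
  expect_setequal(variant_key(two_pass), variant_key(joint))
})

test_that("zygosity criteria treat unknown zygosity as not assessable", {
  g <- mk_coding_gene("ATGTGCGCTTAA")
  v <- mk_snv("c", 14, "T", "C")
  v$zygosity <- "unknown"
  ann <- annotate_variants(v, g$tx, g$genome)
  expect_equal(nrow(filter_variants(ann,
                                    filter_criteria(snp_zygosity = "het"))),
               0L)
  expect_equal(nrow(filter_variants(
    ann, filter_criteria(snp_zygosity = "het",
                         unknown_zygosity_passes = TRUE))), 1L)
})

test_that("criteria referencing unattached data fail before filtering", {
  rep <- ann_case1()
  expect_error(filter_variants(rep$annotations,
                               filter_criteria(snp_freq_population = "CHB")),
               class = "exomesieve_config_error")
  expect_error(filter_variants(rep$annotations,
                               filter_criteria(snp_max_score = 0.05)),
               class = "exomesieve_config_error")
  expect_error(filter_criteria(snp_mutation_type = "bogus"),
               class = "exomesieve_config_error")
})

test_that("the ALS preset has the published configuration and round-trips", {
  p <- als_preset()
  expect_equal(p$snp_novelty, "novel_only")
  expect_equal(p$snp_freq_population, "CHB")
  expect_equal(p$snp_freq_alpha, 0.05)
  expect_equal(p$snp_zygosity, "het")
  expect_setequal(p$snp_classification,
                  c("missense", "nonsense", "splice_site"))
  expect_equal(p$indel_novelty, "novel_only")
  expect_true(p$indel_coding_only)
  expect_equal(p$indel_zygosity, "het")

  path <- tempfile(fileext = ".cfg")
  write_criteria(p, path)
  expect_equal(read_criteria(path), p)
})

test_that("the preset never retains a homozygous variant", {
  fx <- std_fixture()
  rep <- run_single_case(fx$samples$case1, fx$genome, fx$transcripts,
                         known = fx$known, panel = fx$panel,
                         criteria = als_preset())
  expect_false(any(rep$retained$zygosity == "hom"))
})

test_that("deleterious-score filtering keeps damaging variants only", {
  g <- mk_coding_gene("ATGTGCGCTTAA")
  v <- dplyr::bind_rows(mk_snv("c", 14, "T", "C"),
                        mk_snv("c", 16, "C", "A"))
  scores <- tibble::tibble(contig = "c", pos = c(14L, 16L),
                           ref_allele = c("T", "C"),
                           alt_allele = c("C", "A"),
                           score = c(0.8, 0.01))
  ann <- annotate_variants(v, g$tx, g$genome, scores = scores)
  kept <- filter_variants(ann, filter_criteria(snp_max_score = 0.05))
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$pos, 16L)
})
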