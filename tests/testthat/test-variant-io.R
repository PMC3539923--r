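vcf_header <- c("##fileformat=VCFv4.2",
                paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", "s1", sep = "\t"))

vcf_line <- function(...) paste(..., sep = "\t")

test_that("read_variants parses VCF SNVs, indels and genotypes", {
  path <- write_tempfile(c(
    vcf_header,
    vcf_line("chr1", 101, ".", "A", "G", ".", ".", ".", "GT:DP", "0/1:33"),
    vcf_line("chr1", 201, ".", "AT", "A", ".", ".", ".", "GT", "1/1"),
    vcf_line("chr1", 301, ".", "A", "AGG", ".", ".", "DP=12", "GT", "0|1"),
    vcf_line("chr1", 401, ".", "A", "G,T", ".", ".", ".", "GT", "1/2")
  ), ".vcf")
  v <- read_variants(path, "vcf", "s1")
  expect_equal(nrow(v), 5L)
  # SNV
  expect_equal(row_vals(v, 1, c("pos", "ref_allele", "alt_allele",
                                "var_class", "zygosity", "support")),
               list(pos = 101L, ref_allele = "A", alt_allele = "G",
                    var_class = "snv", zygosity = "het", support = 33L))
  # anchored deletion becomes a pure deletion of T at 202
  expect_equal(row_vals(v, 2, c("pos", "ref_allele", "alt_allele",
                                "var_class", "zygosity")),
               list(pos = 202L, ref_allele = "T", alt_allele = "",
                    var_class = "deletion", zygosity = "hom"))
  # anchored insertion: GG inserted before 302; DP read from INFO
  expect_equal(row_vals(v, 3, c("pos", "ref_allele", "alt_allele",
                                "var_class", "zygosity", "support")),
               list(pos = 302L, ref_allele = "", alt_allele = "GG",
                    var_class = "insertion", zygosity = "het",
                    support = 12L))
  # multi-allelic row split, one het record per alternate allele
  expect_equal(v$alt_allele[4:5], c("G", "T"))
  expect_equal(v$zygosity[4:5], c("het", "het"))
})

test_that("malformed lines are counted, never fatal", {
  good <- vcf_line("chr1", 100 + 1:8, ".", "A", "C", ".", ".", ".",
                   "GT", "0/1")
  path <- write_tempfile(c(vcf_header, good[1:4], "garbage line",
                           vcf_line("chr1", "x", ".", "A", "C", ".", ".",
                                    "."),
                           good[5:8]), ".vcf")
  v <- read_variants(path, "vcf", "s1")
  s <- parse_summary(v)
  expect_equal(as.list(s), list(n_input = 10L, n_unavailable = 2L,
                                n_effective = 8L))
  expect_equal(s$n_input, s$n_unavailable + s$n_effective)
  expect_length(attr(v, "bad_lines"), 2L)
})

test_that("pileup dialect decodes IUPAC consensus and indel alleles", {
  path <- write_tempfile(c(
    paste("chr1", 50, "A", "R", 40, 40, 30, 21, sep = "\t"),  # het A/G
    paste("chr1", 60, "A", "G", 40, 40, 30, 18, sep = "\t"),  # hom G
    paste("chr1", 70, "A", "S", 40, 40, 30, 9, sep = "\t"),   # het C + G
    paste("chr1", 80, "A", "A", 40, 40, 30, 9, sep = "\t"),   # no variant
    paste("chr1", 90, "*", "+AG/+AG", 40, 40, 30, 11, sep = "\t"),
    paste("chr1", 95, "*", "-t/*", 40, 40, 30, 12, sep = "\t")
  ), ".pileup")
  v <- read_variants(path, "pileup", "s1")
  expect_equal(parse_summary(v)$n_unavailable, 1L)  # the reference call
  expect_equal(v$alt_allele[v$pos == 50], "G")
  expect_equal(v$zygosity[v$pos == 50], "het")
  expect_equal(v$zygosity[v$pos == 60], "hom")
  expect_setequal(v$alt_allele[v$pos == 70], c("C", "G"))
  ins <- v[v$var_class == "insertion", ]
  expect_equal(row_vals(ins, 1, c("pos", "alt_allele", "zygosity",
                                  "support")),
               list(pos = 91L, alt_allele = "AG", zygosity = "hom",
                    support = 11L))
  del <- v[v$var_class == "deletion", ]
  expect_equal(row_vals(del, 1, c("pos", "ref_allele", "zygosity")),
               list(pos = 96L, ref_allele = "T", zygosity = "het"))
})

test_that("soapsnp dialect reads the 17-column consensus layout", {
  mk <- function(pos, ref, cons, depth) {
    paste(c("chr2", pos, ref, cons, 40, cons, 30, 5, 6, "N", 0, 0, 0,
            depth, 1.0, 40, 1), collapse = "\t")
  }
  path <- write_tempfile(c(mk(10, "C", "Y", 25), mk(20, "T", "T", 30),
                           "short\tline"), ".soap")
  v <- read_variants(path, "soapsnp", "s2")
  expect_equal(parse_summary(v)$n_effective, 1L)
  expect_equal(row_vals(v, 1, c("contig", "pos", "ref_allele",
                                "alt_allele", "zygosity", "support")),
               list(contig = "chr2", pos = 10L, ref_allele = "C",
                    alt_allele = "T", zygosity = "het", support = 25L))
})

test_that("indel normalization left-aligns through repeat runs", {
  #          1234567890123
  g <- mk_genome(c = "CCGTAAAAAGTCC")
  # deleting the last A of the run (pos 9) equals deleting the first (pos 5)
  v <- normalize_indel(mk_indel("c", 9, ref = "A"), g)
  expect_equal(v$pos, 5L)
  # idempotent
  expect_identical(normalize_indel(v, g), v)
  # insertion with no adjacent repeat does not move
  vi <- normalize_indel(mk_indel("c", 3, alt = "CG"), g)
  expect_equal(vi$pos, 3L)
  # a deletion disagreeing with the reference errors
  expect_error(normalize_indel(mk_indel("c", 9, ref = "G"), g),
               class = "exomesieve_ref_mismatch")
})

test_that("records normalize identically iff their haplotypes agree", {
  set.seed(42)
  for (rep in 1:6) {
    w <- paste(sample(c("A", "A", "C", "G", "T", "T"), 50, replace = TRUE),
               collapse = "")
    g <- mk_genome(c = w)
    recs <- list()
    for (pos in 2:47) {
      for (L in 1:2) {
        recs <- c(recs, list(mk_indel("c", pos,
                                      ref = substring(w, pos,
                                                      pos + L - 1L))))
      }
      recs <- c(recs, list(mk_indel("c", pos, alt = "A")))
    }
    recs <- dplyr::bind_rows(recs)
    haplos <- vapply(seq_len(nrow(recs)), function(i) {
      apply_edit(w, recs$pos[i], recs$ref_allele[i], recs$alt_allele[i])
    }, character(1))
    norm <- normalize_indel(recs, g)
    keys <- variant_key(norm)
    # same haplotype <=> same normalized key
    expect_identical(duplicated(haplos), duplicated(keys))
    expect_equal(length(unique(haplos)), length(unique(keys)))
    split_keys <- split(keys, haplos)
    expect_true(all(vapply(split_keys,
                           function(k) length(unique(k)) == 1L,
                           logical(1))))
  }
})

test_that("VCF writer and reader round-trip fixture records exactly", {
  fx <- std_fixture()
  v1 <- fx$samples$case2
  path <- tempfile(fileext = ".vcf")
  write_variants_vcf(v1, path, genome = fx$genome)
  v2 <- read_variants(path, "vcf", "case2")
  expect_equal(parse_summary(v2)$n_unavailable, 0L)
  m <- match(variant_key(v1), variant_key(v2))
  expect_false(anyNA(m))
  expect_identical(v2$zygosity[m], v1$zygosity)
  expect_identical(v2$support[m], v1$support)
  expect_identical(v2$var_class[m], v1$var_class)
})
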