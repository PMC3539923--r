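test_that("read_fasta loads, uppercases and validates records", {
  fa <- write_tempfile(c(">chr1", "ACGT"), ".fa")
  expect_equal(unclass(read_fasta(fa))[["chr1"]], "ACGT")

  fa2 <- write_tempfile(c(">c", "acgt"), ".fa")
  expect_equal(unclass(read_fasta(fa2))[["c"]], "ACGT")

  dup <- write_tempfile(c(">a", "ACGT", ">a", "GGCC"), ".fa")
  expect_error(read_fasta(dup), class = "exomesieve_parse_error")

  bad <- write_tempfile(c(">a", "ACGU"), ".fa")
  expect_error(read_fasta(bad), class = "exomesieve_parse_error")
})

test_that("read_gene_models parses and validates refGene rows", {
  # CDS length (200-150) + (352-300) = 102, a clean multiple of 3
  row_ok <- paste("tx1", "chr1", "+", 100, 400, 150, 352, 2,
                  "100,300,", "200,400,", "G1", sep = "\t")
  tx <- read_gene_models(write_tempfile(row_ok))
  expect_equal(nrow(tx), 1L)
  expect_equal(tx$n_exons, 2L)
  expect_equal(tx$exon_starts[[1]], c(100L, 300L))
  expect_true(tx$coding)
  expect_true(tx$cds_ok)

  # non-coding row: cdsStart == cdsEnd
  row_nc <- paste("tx2", "chr1", "+", 100, 400, 250, 250, 2,
                  "100,300,", "200,400,", "G2", sep = "\t")
  tx_nc <- read_gene_models(write_tempfile(row_nc))
  expect_false(tx_nc$coding)

  # unsorted exon starts are skipped with a warning
  row_bad <- paste("tx3", "chr1", "+", 100, 400, 150, 350, 2,
                   "300,100,", "400,200,", "G3", sep = "\t")
  expect_warning(tx_bad <- read_gene_models(write_tempfile(row_bad)),
                 "invalid")
  expect_equal(nrow(tx_bad), 0L)

  # wrong column count is a parse error
  expect_error(read_gene_models(write_tempfile("a\tb\tc")),
               class = "exomesieve_parse_error")
})

test_that("coding transcripts with CDS length not divisible by 3 are flagged", {
  # CDS length (200-150) + (351-300) = 101, not divisible by 3
  row <- paste("txb", "chr1", "+", 100, 400, 150, 351, 2,
               "100,300,", "200,400,", "GB", sep = "\t")
  expect_warning(tx <- read_gene_models(write_tempfile(row)), "skipped")
  expect_equal(nrow(tx), 0L)
  expect_warning(tx2 <- read_gene_models(write_tempfile(row),
                                         keep_broken = TRUE), "kept")
  expect_equal(nrow(tx2), 1L)
  expect_false(tx2$cds_ok)
})

test_that("locate classifies regions of a two-exon coding transcript", {
  tx <- mk_tx(c(100L, 300L), c(200L, 400L), 150L, 350L)
  # CDS length (200-150)+(350-300) = 100 -- not a multiple of 3, but locate
  # is purely positional so that does not matter here
  loc <- locate(tx, c(120, 201, 250, 100, 101, 450))
  expect_equal(loc$region,
               c("utr5", "splice_site", "intron", "intergenic", "utr5",
                 "intergenic"))
  # first/last intronic base vs window
  expect_equal(locate(tx, 202, splice_window = 2)$region, "splice_site")
  expect_equal(locate(tx, 203, splice_window = 2)$region, "intron")
  expect_equal(locate(tx, 300, splice_window = 2)$region, "splice_site")
  expect_equal(locate(tx, 299, splice_window = 2)$region, "splice_site")
  expect_equal(locate(tx, 298, splice_window = 2)$region, "intron")
  # CDS offsets count spliced coding bases 5'->3'
  expect_equal(locate(tx, 151)$cds_offset, 0L)
  expect_equal(locate(tx, 200)$cds_offset, 49L)
  expect_equal(locate(tx, 301)$cds_offset, 50L)
  # UTR assignment follows coding orientation on the minus strand
  txm <- mk_tx(c(100L, 300L), c(200L, 400L), 150L, 350L, strand = "-")
  expect_equal(locate(txm, 120)$region, "utr3")
  expect_equal(locate(txm, 380)$region, "utr5")
  expect_equal(locate(txm, 151)$cds_offset, 99L)
  expect_equal(locate(txm, 349 + 1)$cds_offset, 0L)
})

test_that("locate matches per-base painting around fixture transcripts", {
  ref <- oracle_ref()
  for (t in c(1L, 2L, 5L, 12L)) {   # includes the nested-overlap pair
    tx <- ref$transcripts[t, ]
    lab <- oracle_paint(tx, 2L)
    pos <- seq(max(1L, tx$tx_start - 20L), tx$tx_end + 20L)
    inside <- pos - 1L >= tx$tx_start & pos - 1L < tx$tx_end
    idx <- pmin(pmax(pos - tx$tx_start, 1L), length(lab))
    expected <- ifelse(inside, lab[idx], "intergenic")
    expect_identical(locate(tx, pos)$region, expected)
  }
})

test_that("locate is strand-symmetric under contig reflection", {
  tx <- mk_tx(c(100L, 300L), c(200L, 400L), 150L, 350L)
  L <- 500L
  mirror <- mk_tx(rev(L - tx$exon_ends[[1]]), rev(L - tx$exon_starts[[1]]),
                  L - tx$cds_end, L - tx$cds_start)
  swap <- c(utr5 = "utr3", utr3 = "utr5")
  for (pos in seq(90L, 410L, by = 7L)) {
    a <- locate(tx, pos)$region
    b <- locate(mirror, L + 1L - pos)$region
    expected <- if (a %in% names(swap)) unname(swap[a]) else a
    expect_identical(b, expected)
  }
})

test_that("cds_offset_to_codon reads codons across junctions and strands", {
  g <- mk_coding_gene("ATGTGCGCTTAA")
  expect_equal(as.list(cds_offset_to_codon(g$tx, g$genome, 0))[
    c("codon", "within_codon_index", "aa_position")],
    list(codon = "ATG", within_codon_index = 0L, aa_position = 1L))

  # junction-spanning codon equals the same position of the spliced CDS
  ref <- oracle_ref()
  tx <- ref$transcripts[1, ]
  cds <- spliced_cds(tx, ref$genome)
  codons <- cds_offset_to_codon(tx, ref$genome, seq(0, nchar(cds) - 1))
  expect_identical(
    paste(codons$codon[codons$within_codon_index == 0], collapse = ""), cds)

  # minus strand: offset 0 is the reverse complement of the genomically
  # last CDS triplet
  txm <- ref$transcripts[ref$transcripts$strand == "-", ][1, ]
  ivs <- exomesieve:::tx_cds_intervals(txm)
  k <- length(ivs$end)
  tail_seq <- substring(unclass(ref$genome)[[txm$contig]],
                        ivs$end[k] - 2L, ivs$end[k])
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", tail_seq), "")[[1]]),
              collapse = "")
  expect_equal(cds_offset_to_codon(txm, ref$genome, 0)$codon, rc)

  expect_error(cds_offset_to_codon(tx, ref$genome, nchar(cds)),
               class = "exomesieve_bounds_error")
})

test_that("spliced CDS of every generated gene is a clean ORF", {
  ref <- std_fixture()
  for (t in seq_len(nrow(ref$transcripts))) {
    cds <- spliced_cds(ref$transcripts[t, ], ref$genome)
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substring(cds, 1, 3), "ATG")
    aas <- exomesieve:::translate_codons(
      substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3)))
    expect_equal(aas[length(aas)], "*")
    expect_false(any(aas[-length(aas)] == "*"))
  }
})
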