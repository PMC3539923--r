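# A small gene whose CDS is ATG TGC GCT TAA (Met-Cys-Ala-stop); the CDS
# starts at 1-based position 11 of the contig.
cys_gene <- function(strand = "+") mk_coding_gene("ATGTGCGCTTAA",
                                                  strand = strand)

test_that("classify_snv resolves codon-level categories", {
  g <- cys_gene()
  # TGC (Cys) third base C>A -> TGA: nonsense, the Cys->stop event class
  v <- classify_snv(mk_snv("c", 16, "C", "A"), g$tx, g$genome)
  expect_equal(v$category, "nonsense")
  expect_equal(v$aa_change, "p.Cys2Ter")
  expect_equal(v$codon_change, "TGC>TGA")
  # stop codon TAA first base T>C -> CAA (Gln): read-through
  v <- classify_snv(mk_snv("c", 20, "T", "C"), g$tx, g$genome)
  expect_equal(v$category, "read_through")
  expect_equal(v$aa_change, "p.Ter4Gln")
  # GCT -> GCC: wobble synonymous
  v <- classify_snv(mk_snv("c", 19, "T", "C"), g$tx, g$genome)
  expect_equal(v$category, "syn_code")
  expect_equal(v$aa_change, "p.Ala3Ala")
  # TGC -> CGC: missense Cys->Arg
  v <- classify_snv(mk_snv("c", 14, "T", "C"), g$tx, g$genome)
  expect_equal(v$category, "missense")
  expect_equal(v$aa_change, "p.Cys2Arg")
  # destroying the initiator ATG is missense flagged start_loss
  v <- classify_snv(mk_snv("c", 11, "A", "C"), g$tx, g$genome)
  expect_equal(v$category, "missense")
  expect_true(v$start_loss)
  # reference mismatch errors
  expect_error(classify_snv(mk_snv("c", 16, "G", "A"), g$tx, g$genome),
               class = "exomesieve_ref_mismatch")
})

test_that("classify_snv handles minus-strand codon arithmetic", {
  g <- cys_gene(strand = "-")
  # coding offset 3 (first base of the Cys codon) lies at the genomic
  # position mapped from the CDS end side
  cds_pos <- exomesieve:::oracle_cds_positions(g$tx)
  # genomic position of coding offset 4 (middle of TGC codon)
  gpos <- rev(cds_pos)[5] + 1L
  ref_b <- substring(unclass(g$genome)[["c"]], gpos, gpos)
  # alternate chosen so the coding-strand codon becomes TGA (nonsense):
  # coding G>A at codon position 3 means genomic C>T on the minus strand
  gpos3 <- rev(cds_pos)[6] + 1L
  ref3 <- substring(unclass(g$genome)[["c"]], gpos3, gpos3)
  v <- classify_snv(mk_snv("c", gpos3, ref3, "T"), g$tx, g$genome)
  expect_equal(v$category, "nonsense")
  expect_equal(v$aa_change, "p.Cys2Ter")
  expect_equal(v$codon_change, "TGC>TGA")
})

test_that("classify_indel applies the coding-length mod-3 rule", {
  g <- cys_gene()
  # 2 bp deletion inside the CDS: frame shift
  v <- classify_indel(mk_indel("c", 14, ref = "TG"), g$tx, g$genome)
  expect_equal(v$category, "frame_shift")
  expect_true(is.na(v$aa_change))
  # 3 bp in-frame deletion (the whole Cys codon)
  v <- classify_indel(mk_indel("c", 14, ref = "TGC"), g$tx, g$genome)
  expect_equal(v$category, "aa_deletion")
  expect_equal(v$aa_change, "p.Cys2del")
  # 3 bp insertion between two CDS bases
  v <- classify_indel(mk_indel("c", 15, alt = "AAA"), g$tx, g$genome)
  expect_equal(v$category, "aa_insertion")
  # insertion in the 5' flank (outside the transcript/CDS): non-coding
  v <- classify_indel(mk_indel("c", 3, alt = "AAAA"), g$tx, g$genome)
  expect_equal(v$category, "non_coding")
})

test_that("intronic indels are non-coding, splice-adjacent ones flagged", {
  ref <- oracle_ref()
  tx <- ref$transcripts[ref$transcripts$n_exons > 1, ][1, ]
  ee1 <- tx$exon_ends[[1]][1]
  # 4 bp insertion deep inside the first intron (outside splice windows)
  deep <- ee1 + 30L
  v <- classify_indel(mk_indel(tx$contig, deep + 1L, alt = "ACGT"),
                      tx, ref$genome)
  expect_equal(v$category, "non_coding")
  expect_false(v$splice_adjacent)
  # deletion hitting the donor dinucleotide is still non-coding but flagged
  v <- classify_indel(
    mk_indel(tx$contig, ee1 + 1L,
             ref = substring(unclass(ref$genome)[[tx$contig]],
                             ee1 + 1L, ee1 + 2L)),
    tx, ref$genome)
  expect_equal(v$category, "non_coding")
  expect_true(v$splice_adjacent)
})

test_that("annotate_variants picks the most severe representative", {
  ref <- oracle_ref()
  tx <- ref$transcripts
  # the nested pair: TX002 sits inside TX001's first intron
  nested <- tx[tx$transcript_id == "TX002", ]
  host <- tx[tx$transcript_id == "TX001", ]
  expect_true(nested$tx_start > host$exon_ends[[1]][1] &&
                nested$tx_end < host$exon_starts[[1]][2])
  # a missense variant of the nested gene beats the host's intron label
  enum <- oracle_snv_categories_all(nested, ref$genome, flank = 0)
  hit <- enum[enum$category == "missense", ][1, ]
  v <- mk_snv(nested$contig, hit$pos, hit$ref, hit$alt)
  ann <- annotate_variants(v, tx, ref$genome)
  expect_equal(ann$category, "missense")
  expect_equal(ann$transcript_id, "TX002")
  all_ann <- attr(ann, "all_annotations")
  expect_setequal(all_ann$transcript_id, c("TX001", "TX002"))
  expect_equal(all_ann$category[all_ann$transcript_id == "TX001"],
               "intron")
  # severity selection does not depend on transcript order
  ann_rev <- annotate_variants(v, tx[rev(seq_len(nrow(tx))), ], ref$genome)
  expect_equal(ann_rev$category, ann$category)
  expect_equal(ann_rev$transcript_id, ann$transcript_id)
})

test_that("representative ties break on the smaller transcript id", {
  g <- cys_gene()
  tx2 <- g$tx
  tx2$transcript_id <- "t0"
  both <- dplyr::bind_rows(g$tx, tx2)   # identical models, two ids
  ann <- annotate_variants(mk_snv("c", 14, "T", "C"), both, g$genome)
  expect_equal(ann$transcript_id, "t0")
  ann2 <- annotate_variants(mk_snv("c", 14, "T", "C"),
                            both[2:1, ], g$genome)
  expect_equal(ann2$transcript_id, "t0")
})

test_that("variants overlapping no transcript are intergenic", {
  g <- cys_gene()
  far <- mk_snv("chrZ", 1000, "A", "G")
  ann <- annotate_variants(far, g$tx, g$genome)
  expect_equal(ann$category, "intergenic")
  expect_true(is.na(ann$transcript_id))
})

test_that("novelty lookup distinguishes known and disease-related", {
  known <- tibble::tibble(
    contig = "c", pos = c(10L, 20L), ref_allele = "A", alt_allele = "G",
    var_class = "snv", rs_id = c("rs0001", "rs0002"),
    clinical = c(FALSE, TRUE))
  v <- dplyr::bind_rows(mk_snv("c", 10, "A", "G"),
                        mk_snv("c", 20, "A", "G"),
                        mk_snv("c", 30, "A", "G"),
                        mk_snv("c", 10, "A", "T"))
  nov <- lookup_known(v, known)
  expect_equal(nov$novelty,
               c("known", "known_disease_related", "novel", "novel"))
  expect_equal(nov$rs_id, c("rs0001", "rs0002", NA, NA))
  # position-only fallback matches regardless of allele
  nov2 <- lookup_known(v, known, match_alleles = FALSE)
  expect_equal(nov2$novelty[4], "known")
  # no catalogue: everything novel
  expect_equal(unique(lookup_known(v, NULL)$novelty), "novel")
})

test_that("gene_term_join is a pure de-duplicating join", {
  mapping <- data.frame(gene = c("G1", "G1", "G1", "G2", "G2"),
                        term = c("hsa001", "GO:1", "hsa001", "GO:2",
                                 "GO:2"))
  res <- gene_term_join(c("G1", "G3", "G2", NA), mapping)
  expect_setequal(res[[1]], c("hsa001", "GO:1"))
  expect_length(res[[2]], 0L)
  expect_equal(res[[3]], "GO:2")
  expect_length(res[[4]], 0L)
})
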