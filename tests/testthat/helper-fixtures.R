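# Shared fixtures, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

# The standard cohort fixture (cases, controls, trio, panel, catalogue).
std_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    .fixture_cache$fx <- generate_fixture(fixture_spec(seed = 7))
  }
  .fixture_cache$fx
}

# A gene-dense reference for exhaustive classifier-vs-oracle sweeps:
# 20 transcripts, both strands, 1-6 exons.
oracle_ref <- function() {
  if (is.null(.fixture_cache$ref)) {
    .fixture_cache$ref <- generate_reference(
      fixture_spec(seed = 11, n_genes = 20, exons_per_gene = c(1L, 6L),
                   contig_length = 60000L))
  }
  .fixture_cache$ref
}

mk_genome <- function(...) {
  structure(toupper(c(...)), class = "genome_seq")
}

mk_tx <- function(exon_starts, exon_ends, cds_start, cds_end,
                  strand = "+", contig = "c", id = "t1", gene = "g1") {
  coding <- cds_start < cds_end
  cds_len <- sum(pmin(exon_ends, cds_end) - pmax(exon_starts, cds_start))
  tibble::tibble(
    transcript_id = id, gene_name = gene, contig = contig, strand = strand,
    tx_start = exon_starts[1], tx_end = exon_ends[length(exon_ends)],
    cds_start = cds_start, cds_end = cds_end,
    n_exons = length(exon_starts),
    exon_starts = list(as.integer(exon_starts)),
    exon_ends = list(as.integer(exon_ends)),
    coding = coding, cds_ok = !coding || (cds_len > 0 && cds_len %% 3 == 0)
  )
}

# A single-exon coding gene embedded in flanking sequence; `cds` is given in
# coding orientation and laid reverse-complemented for minus strand.
mk_coding_gene <- function(cds, pre = "ACGTACGTCC", post = "GGATCCAAGG",
                           strand = "+", contig = "c") {
  genomic_cds <- if (strand == "-") {
    paste(rev(strsplit(chartr("ACGT", "TGCA", cds), "")[[1]]), collapse = "")
  } else {
    cds
  }
  seq <- paste0(pre, genomic_cds, post)
  genome <- mk_genome(c = seq)
  names(genome) <- contig
  class(genome) <- "genome_seq"
  tx <- mk_tx(exon_starts = 0L, exon_ends = nchar(seq),
              cds_start = nchar(pre), cds_end = nchar(pre) + nchar(cds),
              strand = strand, contig = contig)
  list(genome = genome, tx = tx)
}

mk_snv <- function(contig, pos, ref, alt, zygosity = "het",
                   sample_id = "s1") {
  tibble::tibble(contig = contig, pos = as.integer(pos), ref_allele = ref,
                 alt_allele = alt, var_class = "snv", zygosity = zygosity,
                 support = NA_integer_, sample_id = sample_id,
                 raw_line_no = NA_integer_)
}

mk_indel <- function(contig, pos, ref = "", alt = "", zygosity = "het",
                     sample_id = "s1") {
  tibble::tibble(contig = contig, pos = as.integer(pos), ref_allele = ref,
                 alt_allele = alt,
                 var_class = if (ref == "") "insertion" else "deletion",
                 zygosity = zygosity, support = NA_integer_,
                 sample_id = sample_id, raw_line_no = NA_integer_)
}

# Apply an internal-form edit to a sequence string (brute-force haplotype).
apply_edit <- function(seq, pos, ref, alt) {
  if (ref != "") {  # deletion of ref starting at pos
    paste0(substring(seq, 1, pos - 1),
           substring(seq, pos + nchar(ref)))
  } else {          # insertion of alt before pos
    paste0(substring(seq, 1, pos - 1), alt, substring(seq, pos))
  }
}

write_tempfile <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# One row's values as a bare named list (drops table-level attributes).
row_vals <- function(x, i, cols) {
  setNames(lapply(cols, function(cl) x[[cl]][i]), cols)
}
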