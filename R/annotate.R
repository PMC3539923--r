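AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Ter"
)

aa3 <- function(aa) unname(AA_THREE[aa])

translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

complement_base <- function(b) chartr("ACGTN", "TGCAN", b)

# Severity order used to pick one representative annotation per variant.
SEVERITY_RANK <- c(
  nonsense = 12, frame_shift = 11, read_through = 10, splice_site = 9,
  missense = 8, aa_insertion = 7, aa_deletion = 7, syn_code = 6,
  utr5 = 5, utr3 = 4, intron = 3, non_coding = 3, intergenic = 1
)

severity_rank <- function(category) {
  r <- unname(SEVERITY_RANK[category])
  r[is.na(r)] <- 2  # unresolved (e.g. CDS of a broken-CDS transcript)
  r
}

annotation_columns <- function() {
  c("transcript_id", "gene_name", "tx_strand", "region", "exon_index",
    "intron_index", "cds_offset", "category", "aa_position", "codon_change",
    "aa_change", "start_loss", "splice_adjacent", "cds_bases_affected")
}

blank_annotation_fields <- function(n) {
  tibble(
    transcript_id = rep(NA_character_, n), gene_name = NA_character_,
    tx_strand = NA_character_, region = NA_character_,
    exon_index = NA_integer_, intron_index = NA_integer_,
    cds_offset = NA_integer_, category = NA_character_,
    aa_position = NA_integer_, codon_change = NA_character_,
    aa_change = NA_character_, start_loss = NA,
    splice_adjacent = NA, cds_bases_affected = NA_integer_
  )
}

#' Classify SNVs against one transcript
#'
#' Assigns every single-nucleotide variant its functional category relative
#' to one transcript. Non-coding positions take their region label from
#' [locate()] (`intergenic`, `intron`, `splice_site`, `utr5`, `utr3`).
#' Coding positions are classified by rebuilding the affected codon in coding
#' orientation (the alternate base is complemented for minus-strand
#' transcripts) and translating with the standard nuclear genetic code:
#' same amino acid gives `syn_code`, amino acid to stop `nonsense`, stop to
#' amino acid `read_through`, and any other change `missense`. An SNV that
#' destroys the initiator ATG is reported `missense` with `start_loss = TRUE`
#' (the category set has no start-loss class). The amino-acid change is
#' reported in three-letter `p.` notation (e.g. `p.Cys146Ter`).
#'
#' @param variants Variant tibble rows with `var_class == "snv"`.
#' @param tx One transcript (one-row tibble).
#' @param genome A `genome_seq`.
#' @param splice_window Intronic bases flanking exon boundaries labelled
#'   `splice_site` (default 2).
#' @param check_ref Error if the reference base disagrees with `ref_allele`?
#' @return The input rows with annotation columns appended (`category`,
#'   `aa_change`, `codon_change`, `aa_position`, `start_loss`, ...).
#' @export
classify_snv <- function(variants, tx, genome, splice_window = 2L,
                         check_ref = TRUE) {
  if (!all(variants$var_class == "snv")) {
    abort("classify_snv expects only snv records",
          class = "exomesieve_domain_error")
  }
  tx <- tx_row(tx)
  n <- nrow(variants)
  out <- dplyr::bind_cols(variants, blank_annotation_fields(n))
  if (n == 0L) return(out)
  same <- variants$contig == tx$contig
  out$region <- ifelse(same, NA_character_, "intergenic")
  if (any(same)) {
    loc <- locate_many(tx, variants$pos[same], splice_window)
    out$region[same] <- loc$region
    out$exon_index[same] <- loc$exon_index
    out$intron_index[same] <- loc$intron_index
    out$cds_offset[same] <- loc$cds_offset
  }
  out$transcript_id <- tx$transcript_id
  out$gene_name <- tx$gene_name
  out$tx_strand <- tx$strand
  out$category <- out$region
  is_cds <- !is.na(out$region) & out$region == "cds"
  if (any(is_cds)) {
    if (check_ref) {
      obs <- substring(genome[[tx$contig]], variants$pos[is_cds],
                       variants$pos[is_cds])
      bad <- obs != variants$ref_allele[is_cds]
      if (any(bad)) {
        p1 <- variants$pos[is_cds][bad][1]
        abort(paste0("reference mismatch at ", tx$contig, ":", p1,
                     " (genome ", obs[bad][1], ", record ",
                     variants$ref_allele[is_cds][bad][1], ")"),
              class = "exomesieve_ref_mismatch")
      }
    }
    if (isTRUE(tx$cds_ok)) {
      cds <- spliced_cds(tx, genome)
      off <- out$cds_offset[is_cds]
      aa_pos <- off %/% 3L + 1L
      within <- off %% 3L
      ref_codon <- substring(cds, (aa_pos - 1L) * 3L + 1L, aa_pos * 3L)
      alt_base <- variants$alt_allele[is_cds]
      if (tx$strand == "-") alt_base <- complement_base(alt_base)
      alt_codon <- ref_codon
      substring(alt_codon, within + 1L, within + 1L) <- alt_base
      ref_aa <- translate_codons(ref_codon)
      alt_aa <- translate_codons(alt_codon)
      category <- dplyr::case_when(
        ref_aa == alt_aa ~ "syn_code",
        alt_aa == "*" ~ "nonsense",
        ref_aa == "*" ~ "read_through",
        TRUE ~ "missense"
      )
      out$category[is_cds] <- category
      out$aa_position[is_cds] <- aa_pos
      out$codon_change[is_cds] <- paste0(ref_codon, ">", alt_codon)
      out$aa_change[is_cds] <- paste0("p.", aa3(ref_aa), aa_pos, aa3(alt_aa))
      out$start_loss[is_cds] <- aa_pos == 1L & ref_codon == "ATG" &
        category != "syn_code"
    } else {
      # broken CDS: region-level annotation only
      out$category[is_cds] <- NA_character_
    }
  }
  out
}

# splice-window intronic intervals of a transcript, 0-based half-open
splice_intervals <- function(tx, splice_window = 2L) {
  tx <- tx_row(tx)
  k <- length(tx$exon_starts)
  if (k < 2L || splice_window < 1L) {
    return(list(start = integer(0), end = integer(0)))
  }
  donor_s <- tx$exon_ends[-k]
  donor_e <- pmin(donor_s + splice_window, tx$exon_starts[-1])
  acc_e <- tx$exon_starts[-1]
  acc_s <- pmax(acc_e - splice_window, tx$exon_ends[-k])
  list(start = c(donor_s, acc_s), end = c(donor_e, acc_e))
}

# Count of CDS bases strictly below 0-based coordinate x (vectorised in x).
cds_bases_below <- function(tx, x) {
  iv <- tx_cds_intervals(tx)
  tot <- rep(0L, length(x))
  for (j in seq_along(iv$start)) {
    tot <- tot + pmax(0L, pmin(x, iv$end[j]) - iv$start[j])
  }
  tot
}

#' Classify InDels against one transcript
#'
#' An indel whose affected bases intersect no CDS exon base is `non_coding`
#' (with `splice_adjacent = TRUE` when it touches an intronic splice-window
#' base). Otherwise the number of CDS bases inserted or removed decides:
#' not a multiple of 3 is `frame_shift`; an in-frame event is `aa_insertion`
#' or `aa_deletion`. An indel spanning a CDS/intron boundary is classified by
#' its CDS-intersecting portion. An insertion counts as coding when both
#' bases flanking the insertion point are CDS bases. In-frame events carry
#' the first affected amino-acid position in `aa_change`.
#'
#' @inheritParams classify_snv
#' @param variants Variant tibble rows with `var_class` of `insertion` or
#'   `deletion`, already left-normalised (see [normalize_indel()]).
#' @return The input rows with annotation columns appended.
#' @export
classify_indel <- function(variants, tx, genome, splice_window = 2L,
                           check_ref = TRUE) {
  if (!all(variants$var_class %in% c("insertion", "deletion"))) {
    abort("classify_indel expects only insertion/deletion records",
          class = "exomesieve_domain_error")
  }
  tx <- tx_row(tx)
  n <- nrow(variants)
  out <- dplyr::bind_cols(variants, blank_annotation_fields(n))
  if (n == 0L) return(out)
  out$transcript_id <- tx$transcript_id
  out$gene_name <- tx$gene_name
  out$tx_strand <- tx$strand

  p0 <- variants$pos - 1L
  is_del <- variants$var_class == "deletion"
  len <- ifelse(is_del, nchar(variants$ref_allele), nchar(variants$alt_allele))
  same <- variants$contig == tx$contig

  if (check_ref && any(is_del & same)) {
    idx <- which(is_del & same)
    for (i in idx) {
      obs <- genome_slice(genome, variants$contig[i], variants$pos[i],
                          variants$pos[i] + len[i] - 1L)
      if (obs != variants$ref_allele[i]) {
        abort(paste0("reference mismatch for deletion at ",
                     variants$contig[i], ":", variants$pos[i]),
              class = "exomesieve_ref_mismatch")
      }
    }
  }

  # CDS bases affected
  coding_tx <- tx$cds_start < tx$cds_end && isTRUE(tx$cds_ok)
  d <- rep(0L, n)
  if (coding_tx) {
    # deletions: overlap of [p0, p0+len) with the CDS intervals
    del_d <- cds_bases_below(tx, p0 + len) - cds_bases_below(tx, p0)
    # insertions: coding iff both flanking bases (p0-1 and p0) are CDS bases
    flank_ok <- (cds_bases_below(tx, p0 + 1L) - cds_bases_below(tx, p0) == 1L) &
      (cds_bases_below(tx, p0) - cds_bases_below(tx, p0 - 1L) == 1L)
    d <- ifelse(is_del, del_d, ifelse(flank_ok, len, 0L))
    d[!same] <- 0L
  }
  out$cds_bases_affected <- as.integer(d)

  # splice adjacency (intronic splice-window bases touched)
  spl <- splice_intervals(tx, splice_window)
  adj <- rep(FALSE, n)
  if (length(spl$start)) {
    iv_s <- ifelse(is_del, p0, p0 - 1L)
    iv_e <- ifelse(is_del, p0 + len, p0 + 1L)
    for (j in seq_along(spl$start)) {
      adj <- adj | (pmin(iv_e, spl$end[j]) > pmax(iv_s, spl$start[j]))
    }
    adj <- adj & same
  }
  out$splice_adjacent <- adj

  out$category <- dplyr::case_when(
    d == 0L ~ "non_coding",
    d %% 3L != 0L ~ "frame_shift",
    is_del ~ "aa_deletion",
    TRUE ~ "aa_insertion"
  )
  out$region <- ifelse(d > 0L, "cds", "non_coding")

  in_frame <- which(out$category %in% c("aa_insertion", "aa_deletion"))
  if (length(in_frame) && coding_tx) {
    cds <- spliced_cds(tx, genome)
    cds_len <- nchar(cds)
    for (i in in_frame) {
      # first affected CDS base, in coding orientation
      first_fwd <- cds_bases_below(tx, if (is_del[i]) p0[i] else p0[i] - 1L)
      last_fwd <- if (is_del[i]) {
        cds_bases_below(tx, p0[i] + len[i]) - 1L
      } else {
        first_fwd + 1L
      }
      offs <- if (tx$strand == "+") first_fwd else cds_len - 1L - last_fwd
      offs <- max(0L, min(cds_len - 1L, offs))
      aa_pos <- offs %/% 3L + 1L
      codon <- substring(cds, (aa_pos - 1L) * 3L + 1L, aa_pos * 3L)
      out$aa_position[i] <- aa_pos
      out$aa_change[i] <- paste0(
        "p.", aa3(translate_codons(codon)), aa_pos,
        if (is_del[i]) "del" else "ins"
      )
    }
  }
  out
}

#' Annotate variants against all overlapping transcripts
#'
#' Produces one annotation per (variant, overlapping transcript) pair, then
#' selects a single representative annotation per variant by a fixed severity
#' order (`nonsense > frame_shift > read_through > splice_site > missense >
#' aa_insertion = aa_deletion > syn_code > utr5 > utr3 > intron >
#' intergenic`), breaking ties by lexicographically smaller transcript id.
#' A variant overlapping no transcript gets a single `intergenic` annotation.
#' Novelty against a known-variant catalogue, externally supplied
#' deleterious scores and gene-level term joins are attached to the result.
#'
#' Records whose reference allele disagrees with the genome are dropped with
#' a warning and counted in the `n_ref_mismatch` attribute.
#'
#' @param variants Variant tibble (indels already normalised).
#' @param transcripts Transcript tibble from [read_gene_models()].
#' @param genome A `genome_seq`.
#' @param known Optional known-variant catalogue from
#'   [read_known_variants()]; fills `novelty`/`rs_id` (all `novel` when
#'   absent).
#' @param splice_window Splice-site window in intronic bases (default 2).
#' @param scores Optional tibble of externally computed deleterious scores
#'   with columns `contig`, `pos`, `ref_allele`, `alt_allele`, `score`.
#' @param gene_terms Optional two-column gene-to-term mapping (see
#'   [gene_term_join()]); terms are collapsed into a `gene_terms` column.
#' @return A tibble with one representative annotation per surviving variant
#'   (plus a `key` column). The full per-transcript table is available in
#'   `attr(, "all_annotations")` with an `is_representative` flag.
#' @export
annotate_variants <- function(variants, transcripts, genome, known = NULL,
                              splice_window = 2L, scores = NULL,
                              gene_terms = NULL) {
  variants <- as_tibble(variants)
  variants$.vid <- seq_len(nrow(variants))

  # drop reference-mismatching records up front
  ok <- rep(TRUE, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    contig <- variants$contig[i]
    if (!contig %in% names(genome)) next
    if (variants$var_class[i] == "snv") {
      ok[i] <- genome_slice(genome, contig, variants$pos[i]) ==
        variants$ref_allele[i]
    } else if (variants$var_class[i] == "deletion") {
      L <- nchar(variants$ref_allele[i])
      if (variants$pos[i] + L - 1L > nchar(genome[[contig]])) {
        ok[i] <- FALSE
      } else {
        ok[i] <- genome_slice(genome, contig, variants$pos[i],
                              variants$pos[i] + L - 1L) ==
          variants$ref_allele[i]
      }
    }
  }
  n_mismatch <- sum(!ok)
  if (n_mismatch > 0L) {
    warn(paste0("dropped ", n_mismatch,
                " record(s) with reference-allele mismatch"))
    variants <- variants[ok, , drop = FALSE]
  }

  p0 <- variants$pos - 1L
  is_del <- variants$var_class == "deletion"
  is_ins <- variants$var_class == "insertion"
  v_start <- ifelse(is_ins, p0 - 1L, p0)
  v_end <- ifelse(is_del, p0 + nchar(variants$ref_allele), p0 + 1L)

  pieces <- list()
  for (t in seq_len(nrow(transcripts))) {
    tx <- transcripts[t, ]
    hit <- variants$contig == tx$contig &
      v_start < tx$tx_end & v_end > tx$tx_start
    if (!any(hit)) next
    sub <- variants[hit, , drop = FALSE]
    snv <- sub[sub$var_class == "snv", , drop = FALSE]
    ind <- sub[sub$var_class != "snv", , drop = FALSE]
    if (nrow(snv)) {
      pieces <- c(pieces, list(classify_snv(snv, tx, genome, splice_window,
                                            check_ref = FALSE)))
    }
    if (nrow(ind)) {
      pieces <- c(pieces, list(classify_indel(ind, tx, genome, splice_window,
                                              check_ref = FALSE)))
    }
  }
  all_ann <- if (length(pieces)) bind_rows(pieces) else
    dplyr::bind_cols(variants[0, ], blank_annotation_fields(0L))

  # variants with no overlapping transcript -> single intergenic annotation
  uncovered <- setdiff(variants$.vid, all_ann$.vid)
  if (length(uncovered)) {
    sub <- variants[match(uncovered, variants$.vid), , drop = FALSE]
    blank <- dplyr::bind_cols(sub, blank_annotation_fields(nrow(sub)))
    blank$region <- "intergenic"
    blank$category <- ifelse(sub$var_class == "snv", "intergenic",
                             "non_coding")
    all_ann <- bind_rows(all_ann, blank)
  }

  all_ann$severity <- severity_rank(all_ann$category)
  all_ann <- all_ann |>
    arrange(.data$.vid, dplyr::desc(.data$severity), .data$transcript_id) |>
    group_by(.data$.vid) |>
    mutate(is_representative = row_number() == 1L) |>
    ungroup()

  rep_ann <- all_ann |> filter(.data$is_representative)
  rep_ann$key <- variant_key(rep_ann)
  all_ann$key <- variant_key(all_ann)

  # novelty
  nov <- lookup_known(rep_ann, known)
  rep_ann$novelty <- nov$novelty
  rep_ann$rs_id <- nov$rs_id

  # externally supplied deleterious scores
  if (!is.null(scores)) {
    sc <- as_tibble(scores)
    sc$key <- variant_key(sc)
    rep_ann <- left_join(rep_ann,
                         sc |> select("key", deleterious_score = "score"),
                         by = "key")
  } else {
    rep_ann$deleterious_score <- NA_real_
  }

  if (!is.null(gene_terms)) {
    terms <- gene_term_join(rep_ann$gene_name, gene_terms)
    rep_ann$gene_terms <- vapply(terms, function(x) {
      if (length(x)) paste(x, collapse = ";") else NA_character_
    }, character(1))
  }

  rep_ann <- rep_ann |> select(-".vid", -"severity", -"is_representative")
  attr(rep_ann, "all_annotations") <- all_ann |> select(-".vid")
  attr(rep_ann, "n_ref_mismatch") <- n_mismatch
  rep_ann
}

#' Read a known-variant catalogue
#'
#' Parses a VCF-shaped catalogue (e.g. a dbSNP extract) into a lookup table.
#' Records with INFO flag `CLN=1` (or a bare `CLN` flag) are marked
#' clinically associated; [lookup_known()] reports these as
#' `known_disease_related`, which the novelty filter retains alongside novel
#' variants. Anchored indels are converted to the internal representation;
#' the catalogue is assumed left-normalised (normalise it against the genome
#' with [normalize_indel()] if in doubt).
#'
#' @param path Catalogue path (VCF, gzip accepted).
#' @return A tibble with `contig`, `pos`, `ref_allele`, `alt_allele`,
#'   `var_class`, `rs_id`, `clinical`.
#' @export
read_known_variants <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) next
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) next
    alts <- toupper(strsplit(f[5], ",", fixed = TRUE)[[1]])
    clinical <- grepl("(^|;)CLN(=1)?(;|$)", f[8])
    for (alt in alts) {
      red <- reduce_alleles(pos, toupper(f[4]), alt)
      if (is.null(red)) next
      vc <- if (red$ref == "") "insertion"
            else if (red$alt == "") "deletion" else "snv"
      out <- c(out, list(tibble(
        contig = f[1], pos = red$pos, ref_allele = red$ref,
        alt_allele = red$alt, var_class = vc, rs_id = f[3],
        clinical = clinical
      )))
    }
  }
  if (length(out)) bind_rows(out) else
    tibble(contig = character(), pos = integer(), ref_allele = character(),
           alt_allele = character(), var_class = character(),
           rs_id = character(), clinical = logical())
}

#' Look up variants in a known-variant catalogue
#'
#' A variant absent from the catalogue is `novel`; present without the
#' clinical flag, `known`; present with it, `known_disease_related`.
#'
#' @param variants Variant (or annotation) tibble with normalised alleles.
#' @param known Catalogue tibble from [read_known_variants()], or `NULL`
#'   (everything novel).
#' @param match_alleles Match on exact alleles (default) or position only
#'   (for catalogues without allele detail).
#' @return A tibble with columns `novelty` and `rs_id`, one row per input.
#' @export
lookup_known <- function(variants, known = NULL, match_alleles = TRUE) {
  n <- nrow(variants)
  if (is.null(known) || nrow(known) == 0L) {
    return(tibble(novelty = rep("novel", n), rs_id = rep(NA_character_, n)))
  }
  if (match_alleles) {
    vk <- variant_key(variants)
    kk <- variant_key(known)
  } else {
    vk <- paste(variants$contig, variants$pos, sep = ":")
    kk <- paste(known$contig, known$pos, sep = ":")
  }
  m <- match(vk, kk)
  novelty <- ifelse(is.na(m), "novel",
                    ifelse(known$clinical[m], "known_disease_related",
                           "known"))
  tibble(novelty = novelty,
         rs_id = ifelse(is.na(m), NA_character_, known$rs_id[m]))
}

#' Join genes to pathway/ontology terms
#'
#' A pure join against a user-supplied two-column mapping (gene, term id),
#' e.g. KEGG pathway or Gene Ontology assignments; no enrichment statistics.
#'
#' @param genes Character vector of gene names (`NA` allowed).
#' @param mapping Two-column data frame: gene, term id. Duplicated rows are
#'   de-duplicated.
#' @return A list (one element per input gene) of character vectors of term
#'   ids; genes absent from the mapping get `character(0)`.
#' @export
gene_term_join <- function(genes, mapping) {
  mapping <- as_tibble(mapping)
  names(mapping)[1:2] <- c("gene", "term")
  mapping <- distinct(mapping, .data$gene, .data$term)
  by_gene <- split(mapping$term, mapping$gene)
  lapply(genes, function(g) {
    if (is.na(g)) character(0) else by_gene[[g]] %||% character(0)
  })
}
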