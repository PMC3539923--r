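#' Brute-force reference implementations
#'
#' These functions recompute region labels and variant categories by the
#' most literal route available — painting every base of a transcript span
#' with its label, collecting CDS bases position by position, applying an
#' edit to the spliced sequence and re-translating the whole protein — with
#' no shared code path with [locate()], [classify_snv()] or
#' [classify_indel()], which use interval and codon arithmetic instead.
#' The fixture generator uses them to certify every planted variant's
#' intended category at generation time, and the test suite uses them as
#' the independent reference the fast classifiers must agree with.
#'
#' @name oracle
#' @keywords internal
NULL

#' Paint every base of a transcript span with its region label
#'
#' @param tx One transcript row.
#' @param splice_window Intronic splice-site window in bp.
#' @return Character vector of labels for 0-based positions
#'   `tx_start .. tx_end - 1`.
#' @rdname oracle
#' @export
oracle_paint <- function(tx, splice_window = 2L) {
  tx <- tx_row(tx)
  span <- tx$tx_end - tx$tx_start
  lab <- rep("intron", span)
  at <- function(p) p - tx$tx_start + 1L  # 0-based genomic -> index
  k <- length(tx$exon_starts)
  for (i in seq_len(k)) {
    for (p in seq(tx$exon_starts[i], tx$exon_ends[i] - 1L)) {
      lab[at(p)] <- "exon"
    }
  }
  coding <- tx$cds_start < tx$cds_end
  if (coding) {
    for (i in seq_len(k)) {
      for (p in seq(tx$exon_starts[i], tx$exon_ends[i] - 1L)) {
        if (p >= tx$cds_start && p < tx$cds_end) {
          lab[at(p)] <- "cds"
        } else {
          lab[at(p)] <- if (p < tx$cds_start) {
            if (tx$strand == "+") "utr5" else "utr3"
          } else {
            if (tx$strand == "+") "utr3" else "utr5"
          }
        }
      }
    }
  } else {
    lab[lab == "exon"] <- "intron"
  }
  if (k >= 2L && splice_window >= 1L) {
    for (i in seq_len(k - 1L)) {
      donor <- seq(tx$exon_ends[i],
                   min(tx$exon_ends[i] + splice_window,
                       tx$exon_starts[i + 1L]) - 1L)
      acceptor <- seq(max(tx$exon_starts[i + 1L] - splice_window,
                          tx$exon_ends[i]),
                      tx$exon_starts[i + 1L] - 1L)
      for (p in unique(c(donor, acceptor))) {
        if (lab[at(p)] == "intron") lab[at(p)] <- "splice_site"
      }
    }
  }
  lab
}

#' @param pos 1-based genomic position(s).
#' @rdname oracle
#' @export
oracle_region <- function(tx, pos, splice_window = 2L) {
  tx <- tx_row(tx)
  lab <- oracle_paint(tx, splice_window)
  p0 <- as.integer(pos) - 1L
  out <- rep("intergenic", length(p0))
  inside <- p0 >= tx$tx_start & p0 < tx$tx_end
  out[inside] <- lab[p0[inside] - tx$tx_start + 1L]
  out
}

# 0-based genomic positions of CDS bases, ascending, collected base by base
oracle_cds_positions <- function(tx) {
  tx <- tx_row(tx)
  pos <- integer(0)
  for (i in seq_along(tx$exon_starts)) {
    for (p in seq(tx$exon_starts[i], tx$exon_ends[i] - 1L)) {
      if (p >= tx$cds_start && p < tx$cds_end) pos <- c(pos, p)
    }
  }
  pos
}

oracle_translate <- function(chars, strand) {
  if (strand == "-") {
    chars <- rev(chartr("ACGTN", "TGCAN", chars))
  }
  n_codon <- length(chars) %/% 3L
  aa <- character(n_codon)
  for (j in seq_len(n_codon)) {
    codon <- paste(chars[(3L * (j - 1L) + 1L):(3L * j)], collapse = "")
    aa[j] <- Biostrings::GENETIC_CODE[[codon]]
  }
  aa
}

#' SNV category by splice-edit-retranslate
#'
#' Rebuilds the spliced CDS base by base, applies the substitution,
#' re-translates both sequences in full and compares the protein strings.
#'
#' @param genome A `genome_seq`.
#' @param alt Alternate base.
#' @rdname oracle
#' @export
oracle_snv_category <- function(tx, genome, pos, alt, splice_window = 2L) {
  tx <- tx_row(tx)
  region <- oracle_region(tx, pos, splice_window)
  if (region != "cds") return(region)
  if (!isTRUE(tx$cds_ok)) return(NA_character_)
  cds_pos <- oracle_cds_positions(tx)
  ref_chars <- vapply(cds_pos + 1L, function(p) {
    genome_slice(genome, tx$contig, p)
  }, character(1))
  i <- match(pos - 1L, cds_pos)
  alt_chars <- ref_chars
  alt_chars[i] <- alt
  ref_aa <- oracle_translate(ref_chars, tx$strand)
  alt_aa <- oracle_translate(alt_chars, tx$strand)
  if (identical(ref_aa, alt_aa)) return("syn_code")
  j <- which(ref_aa != alt_aa)[1]
  if (alt_aa[j] == "*") return("nonsense")
  if (ref_aa[j] == "*") return("read_through")
  "missense"
}

#' InDel category by explicit CDS-base membership
#'
#' @param ref_allele,alt_allele Internal pure-indel alleles (one empty).
#' @rdname oracle
#' @export
oracle_indel_category <- function(tx, genome, pos, ref_allele, alt_allele,
                                  splice_window = 2L) {
  tx <- tx_row(tx)
  cds_pos <- if (isTRUE(tx$cds_ok)) oracle_cds_positions(tx) else integer(0)
  p0 <- pos - 1L
  if (ref_allele != "") {  # deletion
    span <- seq(p0, p0 + nchar(ref_allele) - 1L)
    d <- sum(span %in% cds_pos)
    is_del <- TRUE
  } else {                 # insertion: coding iff both flanks are CDS bases
    coding <- (p0 %in% cds_pos) && ((p0 - 1L) %in% cds_pos)
    d <- if (coding) nchar(alt_allele) else 0L
    is_del <- FALSE
  }
  if (d == 0L) return("non_coding")
  if (d %% 3L != 0L) return("frame_shift")
  if (is_del) "aa_deletion" else "aa_insertion"
}

#' Enumerate oracle SNV categories over a transcript's neighbourhood
#'
#' Computes the brute-force category of every possible SNV (all three
#' alternate bases at every position of the transcript span extended by
#' `flank` bp on each side) in one pass, sharing only the per-transcript
#' precomputation (the painted span, the collected CDS base list and the
#' reference CDS characters); every edit is still applied to the spliced
#' sequence and re-translated in full.
#'
#' @param flank Bases beyond the transcript span to enumerate.
#' @return A tibble `pos`, `ref`, `alt`, `category`.
#' @rdname oracle
#' @export
oracle_snv_categories_all <- function(tx, genome, splice_window = 2L,
                                      flank = 50L) {
  tx <- tx_row(tx)
  lab <- oracle_paint(tx, splice_window)
  cds_pos <- oracle_cds_positions(tx)
  contig_len <- nchar(genome[[tx$contig]])
  ref_chars <- if (length(cds_pos)) {
    strsplit(genome_slice(genome, tx$contig, 1L, contig_len), "")[[1]][cds_pos + 1L]
  } else {
    character(0)
  }
  ref_aa <- if (isTRUE(tx$cds_ok) && length(cds_pos)) {
    oracle_translate(ref_chars, tx$strand)
  } else {
    NULL
  }
  pos_all <- seq(max(1L, tx$tx_start + 1L - flank),
                 min(contig_len, tx$tx_end + flank))
  rows <- vector("list", length(pos_all))
  bases <- c("A", "C", "G", "T")
  contig_chars <- strsplit(genome_slice(genome, tx$contig, 1L, contig_len),
                           "")[[1]]
  for (ii in seq_along(pos_all)) {
    pos <- pos_all[ii]
    p0 <- pos - 1L
    ref <- contig_chars[pos]
    region <- if (p0 >= tx$tx_start && p0 < tx$tx_end) {
      lab[p0 - tx$tx_start + 1L]
    } else {
      "intergenic"
    }
    alts <- setdiff(bases, ref)
    if (region != "cds") {
      cat3 <- rep(region, 3L)
    } else if (is.null(ref_aa)) {
      cat3 <- rep(NA_character_, 3L)
    } else {
      i <- match(p0, cds_pos)
      cat3 <- vapply(alts, function(alt) {
        alt_chars <- ref_chars
        alt_chars[i] <- alt
        alt_aa <- oracle_translate(alt_chars, tx$strand)
        if (identical(ref_aa, alt_aa)) return("syn_code")
        j <- which(ref_aa != alt_aa)[1]
        if (alt_aa[j] == "*") return("nonsense")
        if (ref_aa[j] == "*") return("read_through")
        "missense"
      }, character(1), USE.NAMES = FALSE)
    }
    rows[[ii]] <- tibble(pos = pos, ref = ref, alt = alts,
                         category = cat3)
  }
  bind_rows(rows)
}

#' Enumerate oracle InDel categories over a transcript's neighbourhood
#'
#' Every deletion of each length in `lens` starting at every position of
#' the extended span, and every insertion of each length before every
#' position, categorised from an explicit painted CDS-base membership
#' vector.
#'
#' @param lens Indel lengths to enumerate (default 1–6 bp).
#' @return A tibble `pos`, `len`, `var_class`, `category`.
#' @rdname oracle
#' @export
oracle_indel_categories_all <- function(tx, genome, lens = 1:6,
                                        splice_window = 2L, flank = 50L) {
  tx <- tx_row(tx)
  contig_len <- nchar(genome[[tx$contig]])
  is_cds <- rep(FALSE, contig_len)  # 1-based position -> CDS base?
  is_cds[oracle_cds_positions(tx) + 1L] <- isTRUE(tx$cds_ok)
  csum <- cumsum(is_cds)
  n_cds_in <- function(lo1, hi1) {  # CDS bases among 1-based [lo1, hi1]
    lo1 <- max(lo1, 1L); hi1 <- min(hi1, contig_len)
    if (hi1 < lo1) return(0L)
    csum[hi1] - if (lo1 > 1L) csum[lo1 - 1L] else 0L
  }
  pos_all <- seq(max(2L, tx$tx_start + 1L - flank),
                 min(contig_len - max(lens), tx$tx_end + flank))
  out <- vector("list", 2L * length(lens))
  k <- 0L
  for (L in lens) {
    del_cat <- vapply(pos_all, function(pos) {
      d <- n_cds_in(pos, pos + L - 1L)
      if (d == 0L) "non_coding"
      else if (d %% 3L != 0L) "frame_shift"
      else "aa_deletion"
    }, character(1))
    ins_cat <- vapply(pos_all, function(pos) {
      coding <- pos <= contig_len && pos >= 2L &&
        is_cds[pos] && is_cds[pos - 1L]
      d <- if (coding) L else 0L
      if (d == 0L) "non_coding"
      else if (d %% 3L != 0L) "frame_shift"
      else "aa_insertion"
    }, character(1))
    k <- k + 1L
    out[[k]] <- tibble(pos = pos_all, len = L, var_class = "deletion",
                       category = del_cat)
    k <- k + 1L
    out[[k]] <- tibble(pos = pos_all, len = L, var_class = "insertion",
                       category = ins_cat)
  }
  bind_rows(out)
}

#' Representative category across all overlapping transcripts
#'
#' Applies the per-transcript oracle to every transcript the variant
#' overlaps and keeps the most severe category under the package's fixed
#' severity order.
#'
#' @param variant One-row variant tibble.
#' @param transcripts Transcript tibble.
#' @rdname oracle
#' @export
oracle_representative_category <- function(variant, transcripts, genome,
                                           splice_window = 2L) {
  v <- as.list(variant)
  p0 <- v$pos - 1L
  is_snv <- v$var_class == "snv"
  is_del <- v$var_class == "deletion"
  v_start <- if (v$var_class == "insertion") p0 - 1L else p0
  v_end <- if (is_del) p0 + nchar(v$ref_allele) else p0 + 1L
  cats <- character(0)
  for (t in seq_len(nrow(transcripts))) {
    tx <- transcripts[t, ]
    if (tx$contig != v$contig || v_start >= tx$tx_end ||
        v_end <= tx$tx_start) {
      next
    }
    cat_t <- if (is_snv) {
      oracle_snv_category(tx, genome, v$pos, v$alt_allele, splice_window)
    } else {
      oracle_indel_category(tx, genome, v$pos, v$ref_allele, v$alt_allele,
                            splice_window)
    }
    cats <- c(cats, cat_t)
  }
  cats <- cats[!is.na(cats)]
  if (length(cats) == 0L) {
    return(if (is_snv) "intergenic" else "non_coding")
  }
  cats[which.max(severity_rank(cats))]
}
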