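#' Read variant calls into a unified record table
#'
#' Parses one sample's SNV/InDel calls from one of three tabular dialects
#' into a single normalised record layout:
#'
#' * `vcf`: VCF 4.x. Multi-allelic rows are split into one record per ALT
#'   allele, each taking its zygosity from the genotype's copy number of that
#'   allele. Anchored indels (`REF=AT, ALT=A`) are converted to the internal
#'   pure-indel form (see below).
#' * `pileup`: the samtools consensus-pileup layout (10+ columns); SNVs are
#'   decoded from the IUPAC consensus base, indel lines (`*` in the reference
#'   column) from their `+SEQ`/`-SEQ` allele pair.
#' * `soapsnp`: the SOAPsnp 17-column consensus layout (SNVs only).
#'
#' Malformed lines are never fatal: they are counted as *unavailable* in the
#' parse summary (retrieve it with [parse_summary()]) and their line numbers
#' kept in the `bad_lines` attribute. Lines that describe no variant (e.g. a
#' pileup consensus equal to the reference) also count as unavailable.
#'
#' Internal representation: `pos` is the 1-based coordinate of the first
#' affected base. An insertion has `ref_allele = ""` and is placed *before*
#' `pos`; a deletion has `alt_allele = ""` and removes `nchar(ref_allele)`
#' bases starting at `pos`.
#'
#' @param path Input file (gzip accepted).
#' @param dialect One of `"vcf"`, `"pileup"`, `"soapsnp"`.
#' @param sample_id Sample identifier stored on every record.
#' @return A tibble of variant records with columns `contig`, `pos`,
#'   `ref_allele`, `alt_allele`, `var_class` (`snv`/`insertion`/`deletion`),
#'   `zygosity` (`het`/`hom`/`unknown`), `support`, `sample_id`,
#'   `raw_line_no`, plus attributes `parse_summary` and `bad_lines`.
#' @export
read_variants <- function(path, dialect = c("vcf", "pileup", "soapsnp"),
                          sample_id = "sample") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("variant file not found: ", path),
          class = "exomesieve_io_error")
  }
  lines <- readr::read_lines(path)
  recs <- switch(dialect,
    vcf = parse_vcf_lines(lines, sample_id),
    pileup = parse_pileup_lines(lines, sample_id),
    soapsnp = parse_soapsnp_lines(lines, sample_id)
  )
  out <- recs$records
  attr(out, "parse_summary") <- tibble(
    n_input = recs$n_input,
    n_unavailable = length(recs$bad_lines),
    n_effective = recs$n_input - length(recs$bad_lines)
  )
  attr(out, "bad_lines") <- recs$bad_lines
  out
}

#' Parse summary of a variant table
#'
#' @param x A tibble returned by [read_variants()].
#' @return A one-row tibble with `n_input`, `n_unavailable`, `n_effective`
#'   (counts of data lines; `n_input = n_unavailable + n_effective`).
#' @export
parse_summary <- function(x) {
  s <- attr(x, "parse_summary")
  if (is.null(s)) {
    tibble(n_input = nrow(x), n_unavailable = 0L, n_effective = nrow(x))
  } else {
    s
  }
}

empty_records <- function() {
  tibble(contig = character(), pos = integer(), ref_allele = character(),
         alt_allele = character(), var_class = character(),
         zygosity = character(), support = integer(),
         sample_id = character(), raw_line_no = integer())
}

new_record <- function(contig, pos, ref, alt, zyg, support, sample_id, line_no) {
  vc <- if (ref == "" && alt != "") "insertion"
        else if (ref != "" && alt == "") "deletion"
        else "snv"
  tibble(contig = contig, pos = as.integer(pos), ref_allele = ref,
         alt_allele = alt, var_class = vc, zygosity = zyg,
         support = as.integer(support), sample_id = sample_id,
         raw_line_no = as.integer(line_no))
}

# Reduce a VCF REF/ALT pair to internal form: trim shared suffix then shared
# prefix (advancing pos), leaving an SNV, a pure insertion or a pure deletion.
# Returns NULL for unsupported complex (MNV) alleles.
reduce_alleles <- function(pos, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substring(ref, nchar(ref)) == substring(alt, nchar(alt))) {
    ref <- substring(ref, 1L, nchar(ref) - 1L)
    alt <- substring(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substring(ref, 1L, 1L) == substring(alt, 1L, 1L)) {
    ref <- substring(ref, 2L); alt <- substring(alt, 2L)
    pos <- pos + 1L
  }
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == 1L && na == 1L && ref != alt) {
    return(list(pos = pos, ref = ref, alt = alt))
  }
  if (nr == 1L && na > 1L && substring(alt, 1L, 1L) == ref) {
    return(list(pos = pos + 1L, ref = "", alt = substring(alt, 2L)))
  }
  if (nr > 1L && na == 1L && substring(ref, 1L, 1L) == alt) {
    return(list(pos = pos + 1L, ref = substring(ref, 2L), alt = ""))
  }
  NULL
}

parse_vcf_lines <- function(lines, sample_id) {
  is_data <- !grepl("^#", lines) & nzchar(lines)
  data_idx <- which(is_data)
  bad <- integer(0)
  out <- vector("list", length(data_idx))
  for (j in seq_along(data_idx)) {
    i <- data_idx[j]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    rec <- vcf_row_records(f, sample_id, i)
    if (is.null(rec)) bad <- c(bad, i) else out[[j]] <- rec
  }
  records <- if (length(data_idx)) bind_rows(out) else empty_records()
  list(records = records, n_input = length(data_idx), bad_lines = bad)
}

vcf_row_records <- function(f, sample_id, line_no) {
  if (length(f) < 8L) return(NULL)
  pos <- suppressWarnings(as.integer(f[2]))
  ref <- toupper(f[4])
  alts <- toupper(strsplit(f[5], ",", fixed = TRUE)[[1]])
  if (is.na(pos) || pos < 1L || !grepl("^[ACGTN]+$", ref) ||
      length(alts) == 0L || !all(grepl("^[ACGTN]+$", alts))) {
    return(NULL)
  }
  gt_alleles <- NULL
  support <- NA_integer_
  if (length(f) >= 10L) {
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    smp <- strsplit(f[10], ":", fixed = TRUE)[[1]]
    gi <- match("GT", fmt)
    if (!is.na(gi) && gi <= length(smp)) {
      gt_alleles <- strsplit(smp[gi], "[/|]")[[1]]
    }
    di <- match("DP", fmt)
    if (!is.na(di) && di <= length(smp)) {
      support <- suppressWarnings(as.integer(smp[di]))
    }
  }
  if (is.na(support)) {
    m <- regmatches(f[8], regexpr("(?:^|;)DP=([0-9]+)", f[8]))
    if (length(m)) support <- as.integer(sub(".*DP=", "", m))
  }
  recs <- list()
  for (ai in seq_along(alts)) {
    red <- reduce_alleles(pos, ref, alts[ai])
    if (is.null(red)) return(NULL)
    zyg <- "unknown"
    if (!is.null(gt_alleles)) {
      copies <- sum(gt_alleles == as.character(ai))
      zyg <- if (copies == 2L) "hom" else if (copies == 1L) "het" else "unknown"
    }
    recs[[ai]] <- new_record(f[1], red$pos, red$ref, red$alt, zyg, support,
                             sample_id, line_no)
  }
  bind_rows(recs)
}

IUPAC_HET <- list(M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
                  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"))

# Decode a consensus base against the reference base into 0, 1 or 2 records.
decode_consensus <- function(contig, pos, ref, cons, support, sample_id,
                             line_no) {
  ref <- toupper(ref); cons <- toupper(cons)
  if (!grepl("^[ACGT]$", ref)) return(NULL)
  if (cons %in% c("A", "C", "G", "T")) {
    if (cons == ref) return(NULL)  # no variant on this line
    return(new_record(contig, pos, ref, cons, "hom", support, sample_id,
                      line_no))
  }
  pair <- IUPAC_HET[[cons]]
  if (is.null(pair)) return(NULL)
  alts <- setdiff(pair, ref)
  if (length(alts) == 0L) return(NULL)
  bind_rows(lapply(alts, function(a) {
    new_record(contig, pos, ref, a, "het", support, sample_id, line_no)
  }))
}

parse_pileup_lines <- function(lines, sample_id) {
  is_data <- !grepl("^#", lines) & nzchar(lines)
  data_idx <- which(is_data)
  bad <- integer(0)
  out <- list()
  for (i in data_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    rec <- NULL
    if (length(f) >= 8L) {
      pos <- suppressWarnings(as.integer(f[2]))
      support <- suppressWarnings(as.integer(f[8]))
      if (!is.na(pos)) {
        if (f[3] == "*") {
          rec <- pileup_indel_records(f[1], pos, f[4], support, sample_id, i)
        } else {
          rec <- decode_consensus(f[1], pos, f[3], f[4], support, sample_id, i)
        }
      }
    }
    if (is.null(rec) || nrow(rec) == 0L) bad <- c(bad, i) else out <- c(out, list(rec))
  }
  records <- if (length(out)) bind_rows(out) else empty_records()
  list(records = records, n_input = length(data_idx), bad_lines = bad)
}

# Indel pileup: the position column is the base *before* the event; the
# consensus column holds two /-separated alleles, each "*" (reference),
# "+SEQ" (insertion) or "-SEQ" (deletion).
pileup_indel_records <- function(contig, pos, allele_field, support,
                                 sample_id, line_no) {
  alleles <- strsplit(allele_field, "/", fixed = TRUE)[[1]]
  if (length(alleles) != 2L) return(NULL)
  events <- unique(alleles[alleles != "*"])
  if (length(events) == 0L) return(NULL)
  recs <- lapply(events, function(ev) {
    op <- substring(ev, 1L, 1L)
    seq <- toupper(substring(ev, 2L))
    if (!grepl("^[ACGTN]+$", seq)) return(NULL)
    zyg <- if (sum(alleles == ev) == 2L) "hom" else "het"
    if (op == "+") {
      new_record(contig, pos + 1L, "", seq, zyg, support, sample_id, line_no)
    } else if (op == "-") {
      new_record(contig, pos + 1L, seq, "", zyg, support, sample_id, line_no)
    } else {
      NULL
    }
  })
  if (any(vapply(recs, is.null, logical(1)))) return(NULL)
  bind_rows(recs)
}

parse_soapsnp_lines <- function(lines, sample_id) {
  is_data <- !grepl("^#", lines) & nzchar(lines)
  data_idx <- which(is_data)
  bad <- integer(0)
  out <- list()
  for (i in data_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    rec <- NULL
    if (length(f) == 17L) {
      pos <- suppressWarnings(as.integer(f[2]))
      support <- suppressWarnings(as.integer(f[14]))
      if (!is.na(pos)) {
        rec <- decode_consensus(f[1], pos, f[3], f[4], support, sample_id, i)
      }
    }
    if (is.null(rec) || nrow(rec) == 0L) bad <- c(bad, i) else out <- c(out, list(rec))
  }
  records <- if (length(out)) bind_rows(out) else empty_records()
  list(records = records, n_input = length(data_idx), bad_lines = bad)
}

#' Left-align and minimise indel records
#'
#' Shifts each insertion/deletion as far left as possible while leaving the
#' edited haplotype unchanged (the standard left-alignment used to give every
#' indel a canonical coordinate, so that identical edits from different
#' callers or representations compare equal). SNVs pass through untouched.
#' The operation is idempotent.
#'
#' @param variants A variant tibble (see [read_variants()]).
#' @param genome A `genome_seq` from [read_fasta()].
#' @return The variant tibble with indel `pos`/alleles normalised.
#' @export
normalize_indel <- function(variants, genome) {
  if (nrow(variants) == 0L) return(variants)
  for (i in seq_len(nrow(variants))) {
    vc <- variants$var_class[i]
    if (!vc %in% c("insertion", "deletion")) next
    contig <- variants$contig[i]
    if (!contig %in% names(genome)) next
    pos <- variants$pos[i]
    seq <- if (vc == "deletion") variants$ref_allele[i] else variants$alt_allele[i]
    L <- nchar(seq)
    if (vc == "deletion") {
      obs <- genome_slice(genome, contig, pos, pos + L - 1L)
      if (obs != seq) {
        abort(paste0("deletion allele disagrees with reference at ", contig,
                     ":", pos, " (", seq, " vs ", obs, ")"),
              class = "exomesieve_ref_mismatch")
      }
    }
    while (pos > 1L &&
           genome_slice(genome, contig, pos - 1L) == substring(seq, L, L)) {
      seq <- paste0(genome_slice(genome, contig, pos - 1L),
                    substring(seq, 1L, L - 1L))
      pos <- pos - 1L
    }
    variants$pos[i] <- pos
    if (vc == "deletion") variants$ref_allele[i] <- seq
    else variants$alt_allele[i] <- seq
  }
  variants
}

#' Write variant records as VCF
#'
#' Writes records in VCF 4.2 with the conventional anchored representation
#' for indels (the base before the event is prepended to both alleles). When
#' an annotation table is supplied, per-variant results are carried in INFO
#' keys `EA_FUNC` (category), `EA_GENE`, `EA_AAC` (amino-acid change),
#' `EA_NOVEL` (novelty) and `EA_MAFP` (population test p-values).
#'
#' @param variants Variant tibble (internal representation).
#' @param path Output path; a `.gz` suffix gzip-compresses.
#' @param genome `genome_seq`, required when indels are present (anchor bases).
#' @param annotations Optional representative annotation tibble from
#'   [annotate_variants()], matched by variant key.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path, genome = NULL,
                               annotations = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=EA_FUNC,Number=1,Type=String,Description=\"Functional category\">",
    "##INFO=<ID=EA_GENE,Number=1,Type=String,Description=\"Gene name\">",
    "##INFO=<ID=EA_AAC,Number=1,Type=String,Description=\"Amino-acid change\">",
    "##INFO=<ID=EA_NOVEL,Number=1,Type=String,Description=\"Novelty\">",
    "##INFO=<ID=EA_MAFP,Number=1,Type=String,Description=\"Population MAF test p-values\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT",
          if (nrow(variants) > 0L && !is.na(variants$sample_id[1])) {
            variants$sample_id[1]
          } else "sample",
          sep = "\t")
  )
  ann_by_key <- NULL
  if (!is.null(annotations)) {
    ann_by_key <- annotations
    ann_by_key$.__key <- variant_key(annotations)
  }
  body <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$var_class == "snv") {
      pos <- v$pos; ref <- v$ref_allele; alt <- v$alt_allele
    } else {
      if (is.null(genome)) {
        abort("genome required to write indels (anchor base)",
              class = "exomesieve_domain_error")
      }
      if (v$pos < 2L) {
        abort("cannot anchor an indel at position 1",
              class = "exomesieve_domain_error")
      }
      anchor <- genome_slice(genome, v$contig, v$pos - 1L)
      pos <- v$pos - 1L
      if (v$var_class == "insertion") {
        ref <- anchor; alt <- paste0(anchor, v$alt_allele)
      } else {
        ref <- paste0(anchor, v$ref_allele); alt <- anchor
      }
    }
    info <- if (!is.na(v$support)) paste0("DP=", v$support) else "."
    if (!is.null(ann_by_key)) {
      a <- ann_by_key[ann_by_key$.__key == variant_key(v), ]
      if (nrow(a) >= 1L) {
        a <- a[1, ]
        tags <- c(
          paste0("EA_FUNC=", a$category %||% "."),
          if (!is.na(a$gene_name)) paste0("EA_GENE=", a$gene_name),
          if (!is.na(a$aa_change)) paste0("EA_AAC=", a$aa_change),
          if (!is.null(a$novelty) && !is.na(a$novelty))
            paste0("EA_NOVEL=", a$novelty),
          if (!is.null(a$maf_p) && !is.na(a$maf_p))
            paste0("EA_MAFP=", a$maf_p)
        )
        info <- paste(c(if (info != ".") info, tags), collapse = ";")
      }
    }
    gt <- switch(v$zygosity, het = "0/1", hom = "1/1", "./.")
    fmt <- if (!is.na(v$support)) {
      c("GT:DP", paste0(gt, ":", v$support))
    } else {
      c("GT", gt)
    }
    body[i] <- paste(v$contig, pos, ".", ref, alt, ".", ".", info,
                     fmt[1], fmt[2], sep = "\t")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
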