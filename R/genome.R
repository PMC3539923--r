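#' Read a reference genome from FASTA
#'
#' Loads every record of a (possibly gzip-compressed) FASTA file into a named
#' set of uppercase nucleotide strings. Soft-masked (lowercase) bases are
#' accepted and normalised to uppercase; any letter outside `A/C/G/T/N` is a
#' parse error, as is a duplicated or empty contig.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of contig sequences with class
#'   `"genome_seq"`. Names are the first whitespace-delimited token of each
#'   FASTA header.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' g <- read_fasta(fa)
#' g[["chr1"]]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "exomesieve_io_error")
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) {
      abort(paste0("malformed FASTA in ", path, ": ", conditionMessage(e)),
            class = "exomesieve_parse_error")
    },
    # readDNAStringSet only warns on invalid sequence letters; treat that
    # as the parse error it is
    warning = function(w) {
      abort(paste0("malformed FASTA in ", path, ": ", conditionMessage(w)),
            class = "exomesieve_parse_error")
    }
  )
  nm <- sub("\\s.*$", "", names(seqs))
  if (any(nm == "")) {
    abort("FASTA record with empty header name", class = "exomesieve_parse_error")
  }
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate contig name in FASTA: ",
                 nm[duplicated(nm)][1]),
          class = "exomesieve_parse_error")
  }
  x <- toupper(as.character(seqs))
  names(x) <- nm
  if (any(nchar(x) == 0L)) {
    abort(paste0("empty contig in FASTA: ", nm[nchar(x) == 0L][1]),
          class = "exomesieve_parse_error")
  }
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(paste0("non-nucleotide characters in contig ", nm[bad][1]),
          class = "exomesieve_parse_error")
  }
  structure(x, class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("<genome_seq> ", length(x), " contig(s): ",
      paste0(names(x), " (", nchar(unclass(x)), " bp)", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# 1-based inclusive slice with bounds checking
genome_slice <- function(genome, contig, start, end = start) {
  if (!contig %in% names(genome)) {
    abort(paste0("contig not in genome: ", contig),
          class = "exomesieve_bounds_error")
  }
  len <- nchar(genome[[contig]])
  if (any(start < 1L) || any(end > len) || any(end < start)) {
    abort(paste0("position out of bounds on ", contig, " (length ", len, ")"),
          class = "exomesieve_bounds_error")
  }
  substring(genome[[contig]], start, end)
}

# reverse complement of one or more nucleotide strings
revcomp <- function(x) {
  vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Read gene models from a UCSC refGene-style flat table
#'
#' Parses a tab-separated table with columns `name, chrom, strand, txStart,
#' txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds, name2` (the
#' refGene dump layout minus the leading `bin` column; a 16-column dump with
#' `bin` is detected and accepted). Coordinates are 0-based half-open as in
#' UCSC dumps and are kept that way internally; all user-facing coordinates
#' elsewhere in the package are 1-based.
#'
#' Structural validation is applied per row: exons must be sorted, ascending
#' and non-overlapping, with `txStart <= cdsStart <= cdsEnd <= txEnd`. Rows
#' failing these checks are skipped with a warning. Coding transcripts whose
#' spliced CDS length is not a multiple of 3 are skipped by default (their
#' protein-level annotation would be meaningless); set `keep_broken = TRUE`
#' to keep them with `cds_ok = FALSE`, in which case they receive region-level
#' annotation only.
#'
#' @param path Path to the tab-separated table. `#`-prefixed lines are ignored.
#' @param keep_broken Keep transcripts whose CDS length is not divisible by 3?
#' @return A tibble with one row per transcript: `transcript_id`, `gene_name`,
#'   `contig`, `strand`, `tx_start`, `tx_end`, `cds_start`, `cds_end`
#'   (0-based half-open), `n_exons`, list-columns `exon_starts`/`exon_ends`,
#'   and logicals `coding` and `cds_ok`.
#' @export
read_gene_models <- function(path, keep_broken = FALSE) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_transcripts())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (!all(ncol %in% c(11L, 16L))) {
    abort(paste0("gene model line ", which(!ncol %in% c(11L, 16L))[1],
                 " has ", ncol[!ncol %in% c(11L, 16L)][1],
                 " columns (expected 11 or 16)"),
          class = "exomesieve_parse_error")
  }
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) == 16L) f <- f[2:12]  # drop bin, keep through name2
    es <- suppressWarnings(as.integer(strsplit(f[9], ",", fixed = TRUE)[[1]]))
    ee <- suppressWarnings(as.integer(strsplit(f[10], ",", fixed = TRUE)[[1]]))
    tibble(
      transcript_id = f[1], contig = f[2], strand = f[3],
      tx_start = suppressWarnings(as.integer(f[4])),
      tx_end = suppressWarnings(as.integer(f[5])),
      cds_start = suppressWarnings(as.integer(f[6])),
      cds_end = suppressWarnings(as.integer(f[7])),
      n_exons = suppressWarnings(as.integer(f[8])),
      exon_starts = list(es), exon_ends = list(ee),
      gene_name = f[11], line = i
    )
  })
  tx <- bind_rows(rows)
  keep <- rep(TRUE, nrow(tx))
  reasons <- character(0)
  for (i in seq_len(nrow(tx))) {
    es <- tx$exon_starts[[i]]; ee <- tx$exon_ends[[i]]
    bad <- anyNA(c(tx$tx_start[i], tx$tx_end[i], tx$cds_start[i],
                   tx$cds_end[i], tx$n_exons[i], es, ee)) ||
      tx$n_exons[i] != length(es) || length(es) != length(ee) ||
      any(ee <= es) ||
      (length(es) > 1 && (is.unsorted(es, strictly = TRUE) ||
                          any(es[-1] < ee[-length(ee)]))) ||
      !(tx$strand[i] %in% c("+", "-")) ||
      !(tx$tx_start[i] <= tx$cds_start[i] &&
        tx$cds_start[i] <= tx$cds_end[i] &&
        tx$cds_end[i] <= tx$tx_end[i]) ||
      es[1] != tx$tx_start[i] || ee[length(ee)] != tx$tx_end[i]
    if (bad) {
      keep[i] <- FALSE
      reasons <- c(reasons, paste0(tx$transcript_id[i], " (line ", tx$line[i],
                                   "): invalid structure"))
    }
  }
  if (length(reasons)) {
    warn(paste0("skipped ", length(reasons), " invalid gene model row(s): ",
                paste(head(reasons, 5), collapse = "; ")))
  }
  tx <- tx[keep, , drop = FALSE]
  tx$coding <- tx$cds_start < tx$cds_end
  cds_len <- vapply(seq_len(nrow(tx)), function(i) {
    tx_cds_length(as.list(tx[i, ]))
  }, integer(1))
  tx$cds_ok <- !tx$coding | (cds_len > 0L & cds_len %% 3L == 0L)
  broken <- tx$coding & !tx$cds_ok
  if (any(broken)) {
    msg <- paste0(sum(broken), " coding transcript(s) with CDS length not a ",
                  "multiple of 3: ", paste(head(tx$transcript_id[broken], 5),
                                           collapse = ", "))
    if (keep_broken) {
      warn(paste0(msg, " (kept with cds_ok = FALSE; region-level ",
                  "annotation only)"))
    } else {
      warn(paste0(msg, " (skipped)"))
      tx <- tx[!broken, , drop = FALSE]
    }
  }
  tx$line <- NULL
  tx[, c("transcript_id", "gene_name", "contig", "strand", "tx_start",
         "tx_end", "cds_start", "cds_end", "n_exons", "exon_starts",
         "exon_ends", "coding", "cds_ok")]
}

empty_transcripts <- function() {
  tibble(
    transcript_id = character(), gene_name = character(), contig = character(),
    strand = character(), tx_start = integer(), tx_end = integer(),
    cds_start = integer(), cds_end = integer(), n_exons = integer(),
    exon_starts = list(), exon_ends = list(),
    coding = logical(), cds_ok = logical()
  )
}

#' Read gene models from a BED12 file
#'
#' Maps the 12-column BED layout (chrom, chromStart, chromEnd, name, score,
#' strand, thickStart, thickEnd, itemRgb, blockCount, blockSizes,
#' blockStarts) onto the same transcript tibble as [read_gene_models()],
#' using `thickStart`/`thickEnd` as the CDS bounds.
#'
#' @inheritParams read_gene_models
#' @return A transcript tibble; see [read_gene_models()].
#' @export
read_bed12 <- function(path, keep_broken = FALSE) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 12L)) {
    abort("BED12 requires exactly 12 columns", class = "exomesieve_parse_error")
  }
  ref_lines <- vapply(fields, function(f) {
    start <- as.integer(f[2])
    sizes <- as.integer(strsplit(f[11], ",")[[1]])
    offs <- as.integer(strsplit(f[12], ",")[[1]])
    es <- start + offs
    ee <- es + sizes
    paste(f[4], f[1], f[6], f[2], f[3], f[7], f[8], length(sizes),
          paste0(paste(es, collapse = ","), ","),
          paste0(paste(ee, collapse = ","), ","),
          f[4], sep = "\t")
  }, character(1))
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(ref_lines, tmp)
  read_gene_models(tmp, keep_broken = keep_broken)
}

# Accept a one-row tibble or a plain list describing a transcript.
tx_row <- function(tx) {
  if (is.data.frame(tx)) {
    stopifnot(nrow(tx) == 1L)
    tx <- as.list(tx)
  }
  if (is.list(tx$exon_starts)) tx$exon_starts <- tx$exon_starts[[1]]
  if (is.list(tx$exon_ends)) tx$exon_ends <- tx$exon_ends[[1]]
  tx
}

# Exon-CDS intersection intervals, 0-based half-open, genomic order.
tx_cds_intervals <- function(tx) {
  tx <- tx_row(tx)
  s <- pmax(tx$exon_starts, tx$cds_start)
  e <- pmin(tx$exon_ends, tx$cds_end)
  keep <- e > s
  list(start = s[keep], end = e[keep])
}

tx_cds_length <- function(tx) {
  iv <- tx_cds_intervals(tx)
  as.integer(sum(iv$end - iv$start))
}

#' Spliced coding sequence of a transcript
#'
#' Concatenates the exon-CDS intersection in genomic order and
#' reverse-complements for minus-strand transcripts, yielding the CDS 5'->3'
#' in coding orientation.
#'
#' @param tx One transcript (a one-row tibble from [read_gene_models()]).
#' @param genome A `genome_seq` from [read_fasta()].
#' @return A single nucleotide string.
#' @export
spliced_cds <- function(tx, genome) {
  tx <- tx_row(tx)
  iv <- tx_cds_intervals(tx)
  if (length(iv$start) == 0L) return("")
  pieces <- genome_slice(genome, tx$contig, iv$start + 1L, iv$end)
  cds <- paste(pieces, collapse = "")
  if (tx$strand == "-") cds <- revcomp(cds) else cds
}

# Vectorised region lookup. pos is 1-based; returns list of parallel vectors.
# Convention: splice_site labels intronic bases only (within splice_window of
# an exon boundary); exonic bases keep their exonic label. Exonic bases of
# non-coding transcripts are labelled intron (the category set has no
# non-coding-exon class).
locate_many <- function(tx, pos, splice_window = 2L) {
  tx <- tx_row(tx)
  p <- as.integer(pos) - 1L
  n <- length(p)
  es <- tx$exon_starts; ee <- tx$exon_ends
  region <- rep("intergenic", n)
  exon_index <- rep(NA_integer_, n)
  intron_index <- rep(NA_integer_, n)
  cds_offset <- rep(NA_integer_, n)

  inside <- p >= tx$tx_start & p < tx$tx_end
  idx <- findInterval(p, es)
  in_exon <- inside & idx >= 1L & p < ee[pmax(idx, 1L)]
  in_intron <- inside & !in_exon

  coding <- tx$cds_start < tx$cds_end
  if (any(in_exon)) {
    exon_index[in_exon] <- idx[in_exon]
    if (coding) {
      cs <- pmax(es, tx$cds_start); ce <- pmin(ee, tx$cds_end)
      olap <- pmax(0L, ce - cs)
      cum_before <- cumsum(c(0L, olap))
      cds_len <- sum(olap)
      in_cds <- in_exon & p >= tx$cds_start & p < tx$cds_end
      if (any(in_cds)) {
        fwd <- cum_before[idx[in_cds]] + (p[in_cds] - cs[idx[in_cds]])
        cds_offset[in_cds] <- if (tx$strand == "+") fwd else cds_len - 1L - fwd
        region[in_cds] <- "cds"
      }
      left <- in_exon & p < tx$cds_start
      right <- in_exon & p >= tx$cds_end
      region[left] <- if (tx$strand == "+") "utr5" else "utr3"
      region[right] <- if (tx$strand == "+") "utr3" else "utr5"
    } else {
      region[in_exon] <- "intron"
    }
  }
  if (any(in_intron)) {
    ii <- idx[in_intron]
    intron_index[in_intron] <- ii
    dl <- p[in_intron] - ee[ii]               # 0 at first intronic base
    dr <- es[pmin(ii + 1L, length(es))] - p[in_intron]  # 1 at last intronic base
    spl <- dl < splice_window | dr <= splice_window
    region[in_intron] <- ifelse(spl, "splice_site", "intron")
  }
  list(region = region, exon_index = exon_index,
       intron_index = intron_index, cds_offset = cds_offset)
}

#' Locate genomic positions relative to a transcript
#'
#' Classifies each 1-based genomic position into a transcript region:
#' `intergenic` (outside the transcript span), `intron`, `splice_site`
#' (intronic bases within `splice_window` of an exon boundary; exonic effects
#' take precedence so the categories stay disjoint), `utr5`/`utr3` (assigned
#' in coding orientation, so the 5' UTR of a minus-strand transcript is at
#' the genomic right), or `cds` with the 0-based offset into the spliced CDS.
#'
#' @param tx One transcript (one-row tibble from [read_gene_models()]).
#' @param pos Vector of 1-based genomic positions.
#' @param splice_window Number of intronic bases flanking each exon boundary
#'   to call `splice_site`. Default 2 (the canonical GT/AG dinucleotides).
#' @return A tibble with columns `pos`, `region`, `exon_index`,
#'   `intron_index`, `cds_offset`.
#' @examples
#' tx <- tibble::tibble(
#'   transcript_id = "t1", gene_name = "g1", contig = "c", strand = "+",
#'   tx_start = 100L, tx_end = 400L, cds_start = 150L, cds_end = 350L,
#'   n_exons = 2L, exon_starts = list(c(100L, 300L)),
#'   exon_ends = list(c(200L, 400L)), coding = TRUE, cds_ok = TRUE)
#' locate(tx, c(120, 201, 250))
#' @export
locate <- function(tx, pos, splice_window = 2L) {
  loc <- locate_many(tx, pos, splice_window)
  tibble(pos = as.integer(pos), region = loc$region,
         exon_index = loc$exon_index, intron_index = loc$intron_index,
         cds_offset = loc$cds_offset)
}

#' Codon at a CDS offset
#'
#' Returns the codon covering each 0-based offset into the spliced CDS of a
#' coding transcript, read across exon junctions and reverse-complemented for
#' minus-strand transcripts so the codon is always in coding orientation.
#'
#' @inheritParams spliced_cds
#' @param cds_offset Vector of 0-based offsets into the spliced CDS.
#' @return A tibble with columns `cds_offset`, `codon` (3-mer),
#'   `within_codon_index` (0..2) and `aa_position` (1-based).
#' @export
cds_offset_to_codon <- function(tx, genome, cds_offset) {
  tx <- tx_row(tx)
  if (!(tx$cds_start < tx$cds_end)) {
    abort("transcript is non-coding", class = "exomesieve_domain_error")
  }
  cds <- spliced_cds(tx, genome)
  off <- as.integer(cds_offset)
  if (any(off < 0L) || any(off >= nchar(cds))) {
    abort(paste0("cds_offset out of range [0, ", nchar(cds), ")"),
          class = "exomesieve_bounds_error")
  }
  aa_pos <- off %/% 3L + 1L
  tibble(
    cds_offset = off,
    codon = substring(cds, (aa_pos - 1L) * 3L + 1L, aa_pos * 3L),
    within_codon_index = off %% 3L,
    aa_position = aa_pos
  )
}
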