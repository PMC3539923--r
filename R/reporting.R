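SNV_CATEGORIES <- c("intergenic", "utr3", "intron", "syn_code", "nonsense",
                    "splice_site", "utr5", "read_through", "missense")
INDEL_CATEGORIES <- c("aa_insertion", "non_coding", "frame_shift",
                      "aa_deletion")

#' Category distribution before and after filtering
#'
#' Counts and percentages per functional category, separately for SNVs and
#' InDels, over the fixed category lists (zero rows included so the table
#' shape is constant). Percentages are within each variant class and state;
#' an empty input yields all-zero percentages.
#'
#' @param before Representative annotation tibble before filtering.
#' @param after Representative annotation tibble after filtering (default:
#'   same as `before`, i.e. no filtering applied).
#' @return A tibble `var_class`, `category`, `n_before`, `pct_before`,
#'   `n_after`, `pct_after`.
#' @export
category_distribution <- function(before, after = NULL) {
  if (is.null(after)) after <- before
  count_state <- function(x, classes, cats, cls) {
    x <- x[x$var_class %in% classes, , drop = FALSE]
    n <- vapply(cats, function(cat) sum(x$category == cat, na.rm = TRUE),
                integer(1))
    tot <- sum(n)
    tibble(var_class = cls, category = cats, n = unname(n),
           pct = if (tot > 0) 100 * unname(n) / tot else rep(0, length(n)))
  }
  mk <- function(x) {
    bind_rows(
      count_state(x, "snv", SNV_CATEGORIES, "snv"),
      count_state(x, c("insertion", "deletion"), INDEL_CATEGORIES, "indel")
    )
  }
  b <- mk(before); a <- mk(after)
  tibble(var_class = b$var_class, category = b$category,
         n_before = b$n, pct_before = b$pct,
         n_after = a$n, pct_after = a$pct)
}

snv_detail_columns <- c("rs_id", "gene_name", "transcript_id", "aa_change",
                        "snp_frequency", "mutation_type", "snp_function",
                        "damage_prediction")
indel_detail_columns <- c("sn", "contig", "pos", "strand", "indel_seq",
                          "substitution_class", "rs_id", "support",
                          "gene_name", "region")

#' Write the per-variant detail table
#'
#' Emits the fixed column set for each variant class, in output order, with
#' missing values rendered as `.`:
#'
#' * SNVs: dbSNP rs id, gene name, transcript id, amino-acid change,
#'   SNP frequency (per-population panel MAF and test p-value, as
#'   `POP:maf=..,p=..` pairs), mutation type (transition/transversion),
#'   SNP function (category), damage prediction (the externally supplied
#'   deleterious score).
#' * InDels: serial number (from 1 in output order), chromosome
#'   coordinates, mutated strand (the representative transcript's strand —
#'   variant calls themselves are unstranded), InDel sequence, substitution
#'   class (insertion/deletion), dbSNP id, support frequency (read depth),
#'   gene name, region of occurrence.
#'
#' @param annotations Representative annotation tibble (filtered or not).
#' @param kind `"snv"` or `"indel"`; rows of the other class are ignored.
#' @param path Output TSV path; `.gz` compresses.
#' @param freq Optional frequency-test tibble from
#'   [test_all_populations()], rendered into the SNP frequency column.
#' @return `path`, invisibly.
#' @export
write_detail_table <- function(annotations, kind = c("snv", "indel"), path,
                               freq = NULL) {
  kind <- match.arg(kind)
  dot <- function(x) {
    x <- as.character(x)
    ifelse(is.na(x) | x == "", ".", x)
  }
  if (kind == "snv") {
    x <- annotations[annotations$var_class == "snv", , drop = FALSE]
    freq_col <- rep(NA_character_, nrow(x))
    if (!is.null(freq) && nrow(x)) {
      keys <- variant_key(x)
      f <- freq[!freq$absent, , drop = FALSE]
      if (nrow(f)) {
        rendered <- f |>
          mutate(txt = sprintf("%s:maf=%.4g,p=%.4g", .data$population,
                               .data$panel_maf, .data$p_value)) |>
          group_by(.data$key) |>
          summarise(txt = paste(.data$txt, collapse = ";"),
                    .groups = "drop")
        freq_col <- rendered$txt[match(keys, rendered$key)]
      }
    }
    out <- tibble(
      rs_id = dot(x$rs_id %||% NA),
      gene_name = dot(x$gene_name),
      transcript_id = dot(x$transcript_id),
      aa_change = dot(x$aa_change),
      snp_frequency = dot(freq_col),
      mutation_type = dot(mutation_type_snv(x$ref_allele, x$alt_allele)),
      snp_function = dot(x$category),
      damage_prediction = dot(x$deleterious_score %||% NA)
    )
  } else {
    x <- annotations[annotations$var_class %in% c("insertion", "deletion"),
                     , drop = FALSE]
    out <- tibble(
      sn = seq_len(nrow(x)),
      contig = dot(x$contig),
      pos = x$pos,
      strand = dot(x$tx_strand),
      indel_seq = dot(ifelse(x$var_class == "insertion", x$alt_allele,
                             x$ref_allele)),
      substitution_class = dot(x$var_class),
      rs_id = dot(x$rs_id %||% NA),
      support = dot(x$support),
      gene_name = dot(x$gene_name),
      region = dot(x$category)
    )
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_detail_table
#' @export
read_detail_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  na = ".", col_types = readr::cols(.default = "c"))
}

#' Export a gzip-compressed result bundle
#'
#' Collects a run's artefacts into a `.tar.gz` archive with a deterministic
#' member listing: the echo of the effective input records, the intermediate
#' (pre-filter) annotation table, the final (retained) detail table, the
#' category distribution and the criteria echo — plus, for cohort runs,
#' shared/unique comparison tables.
#'
#' @param report An `exomesieve_report` from [run_single_case()].
#' @param out_dir Output directory (created if needed).
#' @param name Basename for the archive.
#' @param comparison Optional `exomesieve_comparison` from a two-case run;
#'   adds shared/unique member tables.
#' @return The archive path, with the sorted member listing in
#'   `attr(, "members")`.
#' @export
export_bundle <- function(report, out_dir, name = "exomesieve_results",
                          comparison = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- file.path(tempfile("bundle"), name)
  dir.create(stage, recursive = TRUE)
  drop_listcols <- function(x) {
    x[, !vapply(x, is.list, logical(1)), drop = FALSE]
  }
  readr::write_tsv(drop_listcols(report$variants),
                   file.path(stage, "input_variants.tsv"), progress = FALSE)
  readr::write_tsv(drop_listcols(report$annotations),
                   file.path(stage, "annotation_intermediate.tsv"),
                   progress = FALSE)
  readr::write_tsv(drop_listcols(report$retained),
                   file.path(stage, "annotation_final.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$distribution,
                   file.path(stage, "category_distribution.tsv"),
                   progress = FALSE)
  write_criteria(report$criteria, file.path(stage, "criteria.cfg"))
  if (!is.null(comparison)) {
    readr::write_tsv(drop_listcols(comparison$shared),
                     file.path(stage, "shared_variants.tsv"),
                     progress = FALSE)
    readr::write_tsv(drop_listcols(comparison$unique_a),
                     file.path(stage, "unique_a_variants.tsv"),
                     progress = FALSE)
    readr::write_tsv(drop_listcols(comparison$unique_b),
                     file.path(stage, "unique_b_variants.tsv"),
                     progress = FALSE)
  }
  members <- sort(list.files(stage))
  archive <- file.path(normalizePath(out_dir), paste0(name, ".tar.gz"))
  old <- setwd(dirname(stage))
  on.exit(setwd(old), add = TRUE)
  utils::tar(archive, files = file.path(name, members),
             compression = "gzip", tar = "internal")
  setwd(old)
  unlink(dirname(stage), recursive = TRUE)
  attr(archive, "members") <- members
  archive
}

#' Plot the category distribution
#'
#' Bar chart of category percentages before and after filtering, faceted by
#' variant class.
#'
#' @param distribution A tibble from [category_distribution()].
#' @return A ggplot object.
#' @export
plot_category_distribution <- function(distribution) {
  long <- distribution |>
    tidyr::pivot_longer(c("pct_before", "pct_after"),
                        names_to = "state", values_to = "pct",
                        names_prefix = "pct_") |>
    mutate(state = factor(.data$state, levels = c("before", "after")))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$category, y = .data$pct,
                               fill = .data$state)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~var_class, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "% of variants", fill = "filtering") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
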