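#' Declarative filter criteria
#'
#' Builds the configuration object driving [filter_variants()]. Criteria
#' left at their defaults pass everything; set criteria are combined
#' conjunctively (a variant must pass every set criterion). The SNV criteria
#' are applied in the order: novelty, population-frequency difference,
#' mutation type (transition/transversion plus zygosity), classification,
#' protein impact; the InDel criteria in the order: novelty, coding region,
#' mutation type (insertion/deletion plus zygosity), impact subcategory.
#'
#' @param snp_novelty `"any"`, `"novel_or_disease"` (novel plus known
#'   disease-related) or `"novel_only"`.
#' @param snp_freq_population Require a significant allele-frequency
#'   difference in this population code, or `"ALL"` for every population;
#'   `NULL` disables the criterion.
#' @param snp_freq_alpha Significance level for the frequency test.
#' @param snp_mutation_type Subset of `c("transition", "transversion")`.
#' @param snp_zygosity Subset of `c("het", "hom")`.
#' @param snp_classification Subset of the SNV categories to retain.
#' @param snp_max_score Retain SNVs with externally supplied deleterious
#'   score `<=` this threshold (damaging); requires scores to be attached.
#' @param indel_novelty As `snp_novelty`, for indels.
#' @param indel_coding_only Retain only coding-region indels (category other
#'   than `non_coding`)?
#' @param indel_mutation_type Subset of `c("insertion", "deletion")`.
#' @param indel_zygosity Subset of `c("het", "hom")`.
#' @param indel_impact Subset of
#'   `c("frame_shift", "aa_insertion", "aa_deletion")`.
#' @param unknown_zygosity_passes Should records with unknown zygosity pass
#'   a zygosity criterion? Default `FALSE` (not assessable fails).
#' @return An object of class `exomesieve_criteria`.
#' @export
filter_criteria <- function(snp_novelty = c("any", "novel_or_disease",
                                            "novel_only"),
                            snp_freq_population = NULL,
                            snp_freq_alpha = 0.05,
                            snp_mutation_type = NULL,
                            snp_zygosity = NULL,
                            snp_classification = NULL,
                            snp_max_score = NULL,
                            indel_novelty = c("any", "novel_or_disease",
                                              "novel_only"),
                            indel_coding_only = FALSE,
                            indel_mutation_type = NULL,
                            indel_zygosity = NULL,
                            indel_impact = NULL,
                            unknown_zygosity_passes = FALSE) {
  snp_novelty <- match.arg(snp_novelty)
  indel_novelty <- match.arg(indel_novelty)
  check_subset <- function(x, allowed, what) {
    if (!is.null(x)) {
      if (length(x) == 0L || !all(x %in% allowed)) {
        abort(paste0(what, " must be a non-empty subset of {",
                     paste(allowed, collapse = ", "), "}"),
              class = "exomesieve_config_error")
      }
    }
    x
  }
  structure(list(
    snp_novelty = snp_novelty,
    snp_freq_population = snp_freq_population,
    snp_freq_alpha = snp_freq_alpha,
    snp_mutation_type = check_subset(snp_mutation_type,
                                     c("transition", "transversion"),
                                     "snp_mutation_type"),
    snp_zygosity = check_subset(snp_zygosity, c("het", "hom"),
                                "snp_zygosity"),
    snp_classification = check_subset(
      snp_classification,
      c("intergenic", "intron", "utr5", "utr3", "splice_site", "syn_code",
        "missense", "nonsense", "read_through"),
      "snp_classification"),
    snp_max_score = snp_max_score,
    indel_novelty = indel_novelty,
    indel_coding_only = isTRUE(indel_coding_only),
    indel_mutation_type = check_subset(indel_mutation_type,
                                       c("insertion", "deletion"),
                                       "indel_mutation_type"),
    indel_zygosity = check_subset(indel_zygosity, c("het", "hom"),
                                  "indel_zygosity"),
    indel_impact = check_subset(indel_impact,
                                c("frame_shift", "aa_insertion",
                                  "aa_deletion"),
                                "indel_impact"),
    unknown_zygosity_passes = isTRUE(unknown_zygosity_passes)
  ), class = "exomesieve_criteria")
}

#' @export
print.exomesieve_criteria <- function(x, ...) {
  cat("<exomesieve_criteria>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.null(v)) v <- "(unset)"
    cat("  ", nm, ": ", paste(v, collapse = ","), "\n", sep = "")
  }
  invisible(x)
}

#' The published ALS exome filter preset
#'
#' The candidate-selection configuration used in the familial ALS analysis:
#' novel missense/nonsense/splice-site SNVs and novel coding-region indels,
#' heterozygous only (homozygous sites filtered out), with SNV allele
#' frequencies required to differ significantly from the CHB panel
#' population at alpha 0.05.
#'
#' @return An `exomesieve_criteria` object.
#' @export
als_preset <- function() {
  filter_criteria(
    snp_novelty = "novel_only",
    snp_freq_population = "CHB",
    snp_freq_alpha = 0.05,
    snp_zygosity = "het",
    snp_classification = c("missense", "nonsense", "splice_site"),
    indel_novelty = "novel_only",
    indel_coding_only = TRUE,
    indel_zygosity = "het"
  )
}

#' Serialise filter criteria to a flat config file
#'
#' Writes `key=value` lines (multi-valued criteria comma-separated, unset
#' criteria omitted). [read_criteria()] reads them back; the round trip is
#' exact.
#'
#' @param criteria An `exomesieve_criteria` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_criteria <- function(criteria, path) {
  lines <- character(0)
  for (nm in names(criteria)) {
    v <- criteria[[nm]]
    if (is.null(v)) next
    lines <- c(lines, paste0(nm, "=", paste(v, collapse = ",")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_criteria
#' @export
read_criteria <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  args <- list()
  for (p in kv) {
    key <- p[1]
    val <- strsplit(paste(p[-1], collapse = "="), ",", fixed = TRUE)[[1]]
    args[[key]] <- switch(
      key,
      snp_freq_alpha = as.numeric(val),
      snp_max_score = as.numeric(val),
      indel_coding_only = as.logical(val),
      unknown_zygosity_passes = as.logical(val),
      val
    )
  }
  do.call(filter_criteria, args)
}

mutation_type_snv <- function(ref, alt) {
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  ifelse(unname(transitions[ref]) == alt, "transition", "transversion")
}

novelty_pass <- function(novelty, rule) {
  switch(rule,
         any = rep(TRUE, length(novelty)),
         novel_or_disease = novelty %in% c("novel", "known_disease_related"),
         novel_only = novelty == "novel")
}

zygosity_pass <- function(zygosity, allowed, unknown_passes) {
  ifelse(zygosity == "unknown", unknown_passes, zygosity %in% allowed)
}

#' Apply filter criteria to annotated variants
#'
#' Evaluates the set criteria sequentially in their listed order so each
#' criterion's removal tally is attributable (the retained set itself is
#' order-independent: criteria are conjunctive). A criterion referencing a
#' quantity that was never attached (frequency results, deleterious scores)
#' is a configuration error raised before any filtering.
#'
#' @param annotated Representative annotation tibble from
#'   [annotate_variants()] (needs `category`, `novelty`, `zygosity`).
#' @param criteria An `exomesieve_criteria` object.
#' @param freq Optional long frequency-test tibble from
#'   [test_all_populations()], required when `snp_freq_population` is set.
#' @return The retained annotation tibble, with the tally as
#'   `attr(, "filter_report")` (also retrievable with [filter_report()]).
#' @export
filter_variants <- function(annotated, criteria, freq = NULL) {
  stopifnot(inherits(criteria, "exomesieve_criteria"))
  if (!is.null(criteria$snp_freq_population) && is.null(freq)) {
    abort("snp_freq_population is set but no frequency results supplied",
          class = "exomesieve_config_error")
  }
  if (!is.null(criteria$snp_max_score) &&
      (!"deleterious_score" %in% names(annotated) ||
       all(is.na(annotated$deleterious_score)))) {
    abort("snp_max_score is set but no deleterious scores were attached",
          class = "exomesieve_config_error")
  }
  x <- annotated
  x$.__key <- variant_key(x)
  is_snv <- x$var_class == "snv"
  uzp <- criteria$unknown_zygosity_passes

  freq_pass <- NULL
  if (!is.null(criteria$snp_freq_population)) {
    f <- freq
    if (criteria$snp_freq_population != "ALL") {
      f <- f[f$population == criteria$snp_freq_population, , drop = FALSE]
      if (nrow(f) == 0L) {
        abort(paste0("population ", criteria$snp_freq_population,
                     " absent from frequency results"),
              class = "exomesieve_config_error")
      }
    }
    agg <- f |> group_by(.data$key) |>
      summarise(pass = all(.data$significant), .groups = "drop")
    freq_pass <- setNames(agg$pass, agg$key)
  }

  steps <- list(
    snp_1_novelty = function(v) {
      !is_snv | novelty_pass(v$novelty, criteria$snp_novelty)
    },
    snp_2_frequency = function(v) {
      if (is.null(freq_pass)) return(rep(TRUE, nrow(v)))
      p <- freq_pass[v$.__key]
      p[is.na(p)] <- TRUE  # untested sites: frequency unexplained, retained
      !is_snv | p
    },
    snp_3_mutation_type = function(v) {
      pass <- rep(TRUE, nrow(v))
      if (!is.null(criteria$snp_mutation_type)) {
        mt <- mutation_type_snv(v$ref_allele, v$alt_allele)
        pass <- pass & (mt %in% criteria$snp_mutation_type)
      }
      if (!is.null(criteria$snp_zygosity)) {
        pass <- pass & zygosity_pass(v$zygosity, criteria$snp_zygosity, uzp)
      }
      !is_snv | pass
    },
    snp_4_classification = function(v) {
      if (is.null(criteria$snp_classification)) return(rep(TRUE, nrow(v)))
      !is_snv | (v$category %in% criteria$snp_classification)
    },
    snp_5_impact = function(v) {
      if (is.null(criteria$snp_max_score)) return(rep(TRUE, nrow(v)))
      !is_snv | (!is.na(v$deleterious_score) &
                   v$deleterious_score <= criteria$snp_max_score)
    },
    indel_1_novelty = function(v) {
      is_snv | novelty_pass(v$novelty, criteria$indel_novelty)
    },
    indel_2_coding = function(v) {
      if (!criteria$indel_coding_only) return(rep(TRUE, nrow(v)))
      is_snv | (v$category != "non_coding")
    },
    indel_3_mutation_type = function(v) {
      pass <- rep(TRUE, nrow(v))
      if (!is.null(criteria$indel_mutation_type)) {
        pass <- pass & (v$var_class %in% criteria$indel_mutation_type)
      }
      if (!is.null(criteria$indel_zygosity)) {
        pass <- pass & zygosity_pass(v$zygosity, criteria$indel_zygosity, uzp)
      }
      is_snv | pass
    },
    indel_4_impact = function(v) {
      if (is.null(criteria$indel_impact)) return(rep(TRUE, nrow(v)))
      is_snv | (v$category %in% criteria$indel_impact)
    }
  )

  n_before <- nrow(x)
  keep <- rep(TRUE, n_before)
  removed <- integer(0)
  for (nm in names(steps)) {
    pass <- steps[[nm]](x)
    newly <- keep & !pass
    removed[nm] <- sum(newly)
    keep <- keep & pass
  }
  retained <- x[keep, , drop = FALSE]
  retained$.__key <- NULL
  report <- tibble(criterion = names(removed), removed = unname(removed))
  attr(report, "n_before") <- n_before
  attr(report, "n_after") <- nrow(retained)
  class(report) <- c("exomesieve_filter_report", class(report))
  attr(retained, "filter_report") <- report
  retained
}

#' Retrieve the per-criterion filter tally
#'
#' @param x The retained tibble returned by [filter_variants()].
#' @return A tibble of per-criterion removal counts with `n_before` /
#'   `n_after` attributes.
#' @export
filter_report <- function(x) {
  attr(x, "filter_report")
}

#' @export
print.exomesieve_filter_report <- function(x, ...) {
  cat("<filter report> ", attr(x, "n_before"), " -> ", attr(x, "n_after"),
      " variant(s)\n", sep = "")
  print(as_tibble(x))
  invisible(x)
}

#' @export
tidy.exomesieve_filter_report <- function(x, ...) {
  as_tibble(x)
}
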