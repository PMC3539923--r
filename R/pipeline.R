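#' Run the single-case pipeline on one sample
#'
#' The full per-sample workflow: left-normalise indels, annotate every
#' variant against the gene models (representative annotation per variant),
#' attach novelty from the known-variant catalogue, test SNV allele
#' frequencies against the population panel, apply the filter criteria and
#' tabulate the category distribution before/after.
#'
#' @param variants A variant tibble from [read_variants()].
#' @param genome A `genome_seq` from [read_fasta()].
#' @param transcripts Gene models from [read_gene_models()].
#' @param known Optional known-variant catalogue
#'   ([read_known_variants()]).
#' @param panel Optional population panel ([read_panel()]).
#' @param criteria Filter criteria (default: pass everything).
#' @param splice_window Splice-site window (intronic bp, default 2).
#' @param scores,gene_terms Passed to [annotate_variants()].
#' @param absent_significant Policy for panel-absent sites (see
#'   [test_all_populations()]).
#' @return An `exomesieve_report`: a list with `sample_id`, `variants`
#'   (effective records), `parse_summary`, `annotations` (representative,
#'   pre-filter), `freq`, `retained`, `filter_report`, `distribution`,
#'   `criteria`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
run_single_case <- function(variants, genome, transcripts, known = NULL,
                            panel = NULL, criteria = filter_criteria(),
                            splice_window = 2L, scores = NULL,
                            gene_terms = NULL, absent_significant = TRUE) {
  psum <- parse_summary(variants)
  variants <- normalize_indel(variants, genome)
  ann <- annotate_variants(variants, transcripts, genome, known = known,
                           splice_window = splice_window, scores = scores,
                           gene_terms = gene_terms)
  freq <- NULL
  if (!is.null(panel)) {
    freq <- test_all_populations(ann, panel,
                                 alpha = criteria$snp_freq_alpha %||% 0.05,
                                 absent_significant = absent_significant)
  }
  retained <- filter_variants(ann, criteria, freq = freq)
  structure(list(
    sample_id = variants$sample_id[1] %||% NA_character_,
    variants = variants,
    parse_summary = psum,
    annotations = ann,
    freq = freq,
    retained = retained,
    filter_report = filter_report(retained),
    distribution = category_distribution(ann, retained),
    criteria = criteria
  ), class = "exomesieve_report")
}

#' @export
print.exomesieve_report <- function(x, ...) {
  g <- glance(x)
  cat("<exomesieve_report> sample ", x$sample_id, ": ",
      g$n_effective, " effective, ", g$n_retained,
      " retained after filtering\n", sep = "")
  invisible(x)
}

#' @export
glance.exomesieve_report <- function(x, ...) {
  tibble(
    sample_id = x$sample_id,
    n_input = x$parse_summary$n_input,
    n_unavailable = x$parse_summary$n_unavailable,
    n_effective = x$parse_summary$n_effective,
    n_annotated = nrow(x$annotations),
    n_retained = nrow(x$retained),
    n_retained_snv = sum(x$retained$var_class == "snv"),
    n_retained_indel = sum(x$retained$var_class != "snv")
  )
}

#' @export
tidy.exomesieve_report <- function(x, ...) {
  x$distribution
}

#' @export
autoplot.exomesieve_report <- function(object, ...) {
  plot_category_distribution(object$distribution)
}

#' Two-case comparison of filtered candidate sets
#'
#' @param report_a,report_b `exomesieve_report` objects from
#'   [run_single_case()].
#' @return An `exomesieve_comparison` (see [shared_and_unique()]).
#' @export
run_two_cases <- function(report_a, report_b) {
  shared_and_unique(report_a$retained, report_b$retained)
}

#' Multiple-case candidate selection
#'
#' Variants shared by at least `k` filtered case samples and absent from
#' every control sample's effective call set.
#'
#' @param case_reports List of `exomesieve_report` objects (cases).
#' @param k Minimum number of cases sharing a candidate (`>= 2`).
#' @param control_reports Optional list of reports (or raw variant tibbles)
#'   whose variants exclude candidates.
#' @param position_only See [shared_by_k()].
#' @return A candidate tibble (see [shared_by_k()]).
#' @export
run_multiple_cases <- function(case_reports, k, control_reports = list(),
                               position_only = FALSE) {
  cases <- lapply(case_reports, function(r) {
    if (inherits(r, "exomesieve_report")) r$retained else r
  })
  controls <- lapply(control_reports, function(r) {
    if (inherits(r, "exomesieve_report")) r$variants else r
  })
  shared_by_k(cases, k, controls, position_only = position_only)
}

#' Trio Mendelian candidate selection
#'
#' Builds the trio genotype table over the union of the three samples'
#' calls (a site absent from a member's call set is taken as `hom_ref` by
#' default) and applies the inheritance model. When a filtered child report
#' is given, candidates are additionally restricted to the child's retained
#' set.
#'
#' @param child Child `exomesieve_report` or variant tibble.
#' @param father,mother Parent variant tibbles (raw effective calls).
#' @param model Inheritance model (see [trio_filter()]).
#' @param absent,drop_missing See [genotypes_from_variants()] and
#'   [trio_filter()].
#' @return The passing rows of the trio genotype table.
#' @export
run_trio <- function(child, father, mother,
                     model = c("de_novo", "recessive_hom",
                               "dominant_inherited"),
                     absent = c("hom_ref", "missing"), drop_missing = TRUE) {
  model <- match.arg(model)
  absent <- match.arg(absent)
  child_vars <- if (inherits(child, "exomesieve_report")) child$variants
                else child
  gt <- trio_genotypes(child_vars, father, mother, absent = absent)
  hits <- trio_filter(gt, model, drop_missing = drop_missing)
  if (inherits(child, "exomesieve_report")) {
    hits <- hits[hits$key %in% variant_key(child$retained), , drop = FALSE]
  }
  hits
}
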