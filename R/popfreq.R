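#' Read a population allele-count panel
#'
#' The panel is a tab-separated table with columns `contig`, `pos`, `ref`,
#' `alt` followed by one `<POP>_ref`, `<POP>_alt` pair of allele counts per
#' population (e.g. `YRI_ref  YRI_alt  JPT_ref ...`); the header row names
#' the populations.
#'
#' @param path Panel path (gzip accepted).
#' @return A tibble with a `populations` attribute (character vector of
#'   population codes).
#' @export
read_panel <- function(path) {
  panel <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  base_cols <- c("contig", "pos", "ref", "alt")
  if (!all(base_cols %in% names(panel))) {
    abort("panel must have columns contig, pos, ref, alt",
          class = "exomesieve_parse_error")
  }
  count_cols <- setdiff(names(panel), base_cols)
  pops <- unique(sub("_(ref|alt)$", "", count_cols))
  missing <- setdiff(c(paste0(pops, "_ref"), paste0(pops, "_alt")), count_cols)
  if (length(missing)) {
    abort(paste0("panel missing count column(s): ",
                 paste(missing, collapse = ", ")),
          class = "exomesieve_parse_error")
  }
  attr(panel, "populations") <- pops
  panel
}

panel_populations <- function(panel) {
  attr(panel, "populations") %||%
    unique(sub("_(ref|alt)$", "",
               setdiff(names(panel), c("contig", "pos", "ref", "alt"))))
}

#' Minor allele frequency from allele counts
#'
#' @param ref_count,alt_count Non-negative allele counts (vectorised).
#' @return `min(ref, alt) / (ref + alt)`, a fraction in `[0, 0.5]`.
#' @export
minor_allele_frequency <- function(ref_count, alt_count) {
  tot <- ref_count + alt_count
  if (any(tot <= 0)) {
    abort("undefined MAF: zero total allele count",
          class = "exomesieve_domain_error")
  }
  pmin(ref_count, alt_count) / tot
}

#' Chi-square test of sample alleles against panel allele counts
#'
#' Builds the 2x2 allele-count contingency table
#' `[[sample_ref, sample_alt], [panel_ref, panel_alt]]` and computes the
#' Pearson chi-square statistic (1 df, no continuity correction by default)
#' via the closed form `N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, with the
#' p-value from the chi-square survival function. `significant` is
#' `p_value < alpha`. When any expected cell falls below `min_expected` the
#' `low_count` flag is set (the chi-square approximation is crude there —
#' unavoidably so with two sample alleles); with `low_count_fails = TRUE`
#' such tests are additionally forced non-significant.
#'
#' @param sample_alt Alternate-allele copies carried by the sample (0, 1, 2).
#' @param panel_ref,panel_alt Panel allele counts (vectorised).
#' @param sample_total Total sample alleles (default 2, a diploid genotype).
#' @param alpha Significance level (default 0.05).
#' @param correct Apply the Yates continuity correction?
#' @param min_expected Expected-cell threshold for the `low_count` flag.
#' @param low_count_fails Force `significant = FALSE` when `low_count`?
#' @return A tibble with `panel_maf`, `chi2`, `p_value`, `significant`,
#'   `low_count`.
#' @export
chi_square_allele_test <- function(sample_alt, panel_ref, panel_alt,
                                   sample_total = 2L, alpha = 0.05,
                                   correct = FALSE, min_expected = 1,
                                   low_count_fails = FALSE) {
  if (any(panel_ref + panel_alt <= 0)) {
    abort("panel total allele count must be positive",
          class = "exomesieve_domain_error")
  }
  a <- as.numeric(sample_total - sample_alt)   # sample ref alleles
  b <- as.numeric(sample_alt)
  c_ <- as.numeric(panel_ref)
  d <- as.numeric(panel_alt)
  n <- a + b + c_ + d
  num <- abs(a * d - b * c_)
  if (correct) num <- pmax(0, num - n / 2)
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  chi2 <- ifelse(denom == 0, 0, n * num^2 / denom)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  min_exp <- pmin((a + b) * (a + c_), (a + b) * (b + d),
                  (c_ + d) * (a + c_), (c_ + d) * (b + d)) / n
  low <- min_exp < min_expected
  sig <- p < alpha
  if (low_count_fails) sig <- sig & !low
  tibble(panel_maf = minor_allele_frequency(panel_ref, panel_alt),
         chi2 = chi2, p_value = p, significant = sig, low_count = low)
}

#' Test sample variants against every panel population
#'
#' For each SNV and each population with the site present in the panel
#' (matching contig, position and alleles), tests the sample's two alleles
#' against the panel allele counts with [chi_square_allele_test()]. Sites
#' absent from the panel are returned with `absent = TRUE` and `significant`
#' set by the absent-site policy (default `TRUE`: an unexplained frequency
#' counts as different). Zygosity maps to alternate-allele copies
#' (`het` = 1, `hom` = 2); records with unknown zygosity are also treated
#' by the absent-site policy.
#'
#' @param variants Variant/annotation tibble (SNVs are tested; other records
#'   are returned absent).
#' @param panel Panel tibble from [read_panel()].
#' @param alpha Significance level.
#' @param populations Restrict to these population codes (default: all in
#'   the panel).
#' @param absent_significant Policy for sites absent from the panel.
#' @inheritParams chi_square_allele_test
#' @return A long tibble: `key`, `population`, `panel_maf`, `chi2`,
#'   `p_value`, `significant`, `low_count`, `absent` — one row per
#'   (variant, population).
#' @export
test_all_populations <- function(variants, panel, alpha = 0.05,
                                 populations = NULL,
                                 absent_significant = TRUE,
                                 correct = FALSE, min_expected = 1,
                                 low_count_fails = FALSE) {
  pops <- populations %||% panel_populations(panel)
  keys <- variant_key(variants)
  pk <- paste(panel$contig, panel$pos, panel$ref, panel$alt, sep = ":")
  m <- match(keys, pk)
  alt_copies <- dplyr::case_when(
    variants$zygosity == "het" ~ 1L,
    variants$zygosity == "hom" ~ 2L,
    TRUE ~ NA_integer_
  )
  out <- list()
  for (p in pops) {
    pr <- panel[[paste0(p, "_ref")]][m]
    pa <- panel[[paste0(p, "_alt")]][m]
    absent <- is.na(m) | is.na(alt_copies) | variants$var_class != "snv" |
      is.na(pr) | (pr + pa) <= 0
    res <- tibble(
      key = keys, population = p,
      panel_maf = NA_real_, chi2 = NA_real_, p_value = NA_real_,
      significant = absent_significant, low_count = FALSE, absent = absent
    )
    if (any(!absent)) {
      t <- chi_square_allele_test(alt_copies[!absent], pr[!absent],
                                  pa[!absent], alpha = alpha,
                                  correct = correct,
                                  min_expected = min_expected,
                                  low_count_fails = low_count_fails)
      res$panel_maf[!absent] <- t$panel_maf
      res$chi2[!absent] <- t$chi2
      res$p_value[!absent] <- t$p_value
      res$significant[!absent] <- t$significant
      res$low_count[!absent] <- t$low_count
    }
    out <- c(out, list(res))
  }
  bind_rows(out)
}
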