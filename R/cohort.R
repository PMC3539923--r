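#' Canonical variant key
#'
#' The unit of identity for cross-sample comparison: contig, 1-based
#' position and normalised alleles joined as `contig:pos:ref:alt`, with `-`
#' standing for the empty allele of a pure insertion/deletion. Two records
#' get the same key iff they describe the same normalised edit.
#'
#' @param x A variant or annotation tibble (columns `contig`, `pos`,
#'   `ref_allele`, `alt_allele`).
#' @return A character vector of keys.
#' @export
variant_key <- function(x) {
  r <- ifelse(x$ref_allele == "", "-", x$ref_allele)
  a <- ifelse(x$alt_allele == "", "-", x$alt_allele)
  paste(x$contig, x$pos, r, a, sep = ":")
}

dedup_by_key <- function(x, label) {
  k <- variant_key(x)
  if (anyDuplicated(k)) {
    warn(paste0("duplicate variant keys in ", label, "; de-duplicated"))
    x <- x[!duplicated(k), , drop = FALSE]
  }
  x
}

#' Shared and unique variants between two samples
#'
#' Partitions the union of two samples' variant sets (keyed by
#' [variant_key()]) into shared, unique-to-a and unique-to-b, with
#' percentages relative to each sample's effective variant count.
#'
#' @param a,b Variant/annotation tibbles for the two samples.
#' @return A list of class `exomesieve_comparison`: tibbles `shared` (rows
#'   from `a`), `unique_a`, `unique_b`, and a two-row `summary` tibble with
#'   per-sample shared/unique counts and percentages.
#' @export
shared_and_unique <- function(a, b) {
  a <- dedup_by_key(a, "sample a")
  b <- dedup_by_key(b, "sample b")
  ka <- variant_key(a); kb <- variant_key(b)
  shared_keys <- intersect(ka, kb)
  res <- list(
    shared = a[ka %in% shared_keys, , drop = FALSE],
    unique_a = a[!ka %in% shared_keys, , drop = FALSE],
    unique_b = b[!kb %in% shared_keys, , drop = FALSE],
    summary = tibble(
      sample = c("a", "b"),
      n_effective = c(length(ka), length(kb)),
      n_shared = length(shared_keys),
      n_unique = c(sum(!ka %in% shared_keys), sum(!kb %in% shared_keys)),
      pct_shared = ifelse(c(length(ka), length(kb)) > 0,
                          100 * length(shared_keys) /
                            c(length(ka), length(kb)), 0),
      pct_unique = ifelse(c(length(ka), length(kb)) > 0,
                          100 * c(sum(!ka %in% shared_keys),
                                  sum(!kb %in% shared_keys)) /
                            c(length(ka), length(kb)), 0)
    )
  )
  structure(res, class = "exomesieve_comparison")
}

#' @export
print.exomesieve_comparison <- function(x, ...) {
  cat("<two-case comparison>\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.exomesieve_comparison <- function(x, ...) {
  x$summary
}

#' Variants shared by at least k case samples, minus controls
#'
#' Keys present in at least `k` of the case sets (k must be at least two)
#' and absent from every control set are reported as candidates. With
#' `position_only = TRUE` matching ignores alleles and uses `contig:pos`.
#'
#' @param cases List of variant/annotation tibbles (one per case sample).
#' @param k Minimum number of case samples sharing a variant (`>= 2`).
#' @param controls Optional list of control variant tibbles.
#' @param position_only Match on position alone instead of full alleles?
#' @return A tibble of candidate keys with `n_cases` (how many case samples
#'   carry each) plus the variant columns from the first carrying case.
#' @export
shared_by_k <- function(cases, k, controls = list(), position_only = FALSE) {
  if (k < 2L) {
    abort("k must be a minimum of two", class = "exomesieve_config_error")
  }
  if (k > length(cases)) {
    abort("k exceeds the number of case samples",
          class = "exomesieve_config_error")
  }
  keyfun <- if (position_only) {
    function(x) paste(x$contig, x$pos, sep = ":")
  } else {
    variant_key
  }
  case_keys <- lapply(cases, function(x) unique(keyfun(x)))
  counts <- table(unlist(case_keys))
  cand <- names(counts)[counts >= k]
  if (length(controls)) {
    control_keys <- unique(unlist(lapply(controls, keyfun)))
    cand <- setdiff(cand, control_keys)
  }
  rows <- list()
  for (key in cand) {
    for (i in seq_along(cases)) {
      kk <- keyfun(cases[[i]])
      hit <- which(kk == key)
      if (length(hit)) {
        r <- cases[[i]][hit[1], , drop = FALSE]
        r$key <- key
        r$n_cases <- as.integer(counts[[key]])
        rows <- c(rows, list(r))
        break
      }
    }
  }
  if (length(rows)) {
    out <- bind_rows(rows)
    arrange(out, .data$contig, .data$pos)
  } else {
    tibble(contig = character(), pos = integer(), key = character(),
           n_cases = integer())
  }
}

#' Genotype map from one sample's variant calls
#'
#' Converts a variant tibble into per-key genotypes for Mendelian filtering:
#' `het` records map to `het`, `hom` to `hom_alt`, unknown zygosity to
#' `missing`. Keys in `universe` absent from the sample become `hom_ref`
#' when the site is assumed callable (the default for exome call sets,
#' which omit reference-matching sites) or `missing` otherwise.
#'
#' @param variants One sample's variant tibble.
#' @param universe Character vector of keys to cover (default: the sample's
#'   own keys).
#' @param absent Genotype for covered keys not called in this sample:
#'   `"hom_ref"` (default) or `"missing"`.
#' @return A tibble `key`, `genotype`.
#' @export
genotypes_from_variants <- function(variants, universe = NULL,
                                    absent = c("hom_ref", "missing")) {
  absent <- match.arg(absent)
  keys <- variant_key(variants)
  gt <- dplyr::case_when(
    variants$zygosity == "het" ~ "het",
    variants$zygosity == "hom" ~ "hom_alt",
    TRUE ~ "missing"
  )
  gt <- setNames(gt, keys)
  gt <- gt[!duplicated(keys)]
  universe <- universe %||% names(gt)
  out_gt <- gt[universe]
  out_gt[is.na(out_gt)] <- absent
  tibble(key = universe, genotype = unname(out_gt))
}

trio_model_pass <- function(child, father, mother, model) {
  carries <- function(g) g %in% c("het", "hom_alt")
  switch(model,
    de_novo = carries(child) & father == "hom_ref" & mother == "hom_ref",
    recessive_hom = child == "hom_alt" & father == "het" & mother == "het",
    dominant_inherited = carries(child) & (carries(father) | carries(mother)),
    abort(paste0("unknown trio model: ", model),
          class = "exomesieve_config_error")
  )
}

#' Mendelian trio filtering
#'
#' Selects variant keys whose genotypes in a child-father-mother trio
#' segregate according to an inheritance model:
#'
#' * `de_novo`: child carries the allele (`het` or `hom_alt`), both parents
#'   `hom_ref`;
#' * `recessive_hom`: child `hom_alt`, both parents `het` carriers;
#' * `dominant_inherited`: child carries the allele and at least one parent
#'   carries it.
#'
#' Keys with a `missing` genotype in any trio member are dropped when
#' `drop_missing = TRUE` (the default) or retained whenever some assignment
#' of the missing genotypes satisfies the model otherwise.
#'
#' @param genotypes A tibble with columns `key`, `child`, `father`,
#'   `mother`, each genotype one of `hom_ref`, `het`, `hom_alt`, `missing`
#'   (build per-sample maps with [genotypes_from_variants()]).
#' @param model One of `"de_novo"`, `"recessive_hom"`,
#'   `"dominant_inherited"`.
#' @param drop_missing Drop keys with any missing genotype?
#' @return The rows of `genotypes` passing the model.
#' @export
trio_filter <- function(genotypes, model = c("de_novo", "recessive_hom",
                                             "dominant_inherited"),
                        drop_missing = TRUE) {
  model <- match.arg(model)
  g <- as_tibble(genotypes)
  req <- c("key", "child", "father", "mother")
  if (!all(req %in% names(g))) {
    abort("genotypes must have columns key, child, father, mother",
          class = "exomesieve_config_error")
  }
  any_missing <- g$child == "missing" | g$father == "missing" |
    g$mother == "missing"
  if (drop_missing) {
    pass <- !any_missing &
      trio_model_pass(g$child, g$father, g$mother, model)
  } else {
    # a missing genotype acts as a wildcard
    states <- c("hom_ref", "het", "hom_alt")
    pass <- logical(nrow(g))
    for (i in seq_len(nrow(g))) {
      cs <- if (g$child[i] == "missing") states else g$child[i]
      fs <- if (g$father[i] == "missing") states else g$father[i]
      ms <- if (g$mother[i] == "missing") states else g$mother[i]
      grid <- expand.grid(c = cs, f = fs, m = ms,
                          stringsAsFactors = FALSE)
      pass[i] <- any(trio_model_pass(grid$c, grid$f, grid$m, model))
    }
  }
  g[pass, , drop = FALSE]
}

#' Assemble a trio genotype table from three samples' calls
#'
#' @param child,father,mother Variant tibbles for the three samples.
#' @param absent Genotype assumed for sites called in one member but not
#'   another (see [genotypes_from_variants()]).
#' @return A tibble `key`, `child`, `father`, `mother` over the union of
#'   the three samples' keys.
#' @export
trio_genotypes <- function(child, father, mother,
                           absent = c("hom_ref", "missing")) {
  absent <- match.arg(absent)
  universe <- sort(unique(c(variant_key(child), variant_key(father),
                            variant_key(mother))))
  tibble(
    key = universe,
    child = genotypes_from_variants(child, universe, absent)$genotype,
    father = genotypes_from_variants(father, universe, absent)$genotype,
    mother = genotypes_from_variants(mother, universe, absent)$genotype
  )
}
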