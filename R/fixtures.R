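#' Specification for a synthetic exome fixture
#'
#' Describes a fully synthetic study: a random genome with constructed gene
#' models (every CDS starts ATG, ends with a stop, has length divisible by
#' 3 and no internal stop), per-sample variant sets planted per category
#' with oracle-certified labels, a known-variant catalogue, a population
#' allele-count panel with planted frequency-divergent sites, and a cohort
#' layout (cases sharing a candidate set, controls, an optional trio with a
#' planted de novo and a planted recessive variant). The same spec and seed
#' always reproduce byte-identical outputs.
#'
#' @param seed Integer seed; the single source of all fixture randomness.
#' @param n_contigs,contig_length Genome shape.
#' @param n_genes Number of genes (>= 4 also plants one overlapping gene
#'   pair: a compact gene inside a long intron of another).
#' @param exons_per_gene Inclusive range of exon counts.
#' @param snv_counts Named per-category SNV counts planted per case sample.
#' @param indel_counts Named per-category InDel counts per case sample.
#' @param n_cases,n_controls Cohort sizes.
#' @param include_trio Add child/father/mother samples with planted
#'   Mendelian variants?
#' @param panel_populations,panel_total Population codes and per-population
#'   total allele count.
#' @param alpha Significance level the divergent panel sites are planted to
#'   beat.
#' @return A list of class `exomesieve_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_contigs = 2L, contig_length = 50000L,
                         n_genes = 8L, exons_per_gene = c(2L, 4L),
                         snv_counts = c(intergenic = 20, intron = 30,
                                        utr5 = 8, utr3 = 10,
                                        splice_site = 8, syn_code = 20,
                                        missense = 30, nonsense = 8,
                                        read_through = 4),
                         indel_counts = c(non_coding = 12, frame_shift = 10,
                                          aa_insertion = 6,
                                          aa_deletion = 6),
                         n_cases = 3L, n_controls = 2L, include_trio = TRUE,
                         panel_populations = c("YRI", "JPT", "CHB", "CEU"),
                         panel_total = 200L, alpha = 0.05) {
  spec <- list(
    seed = as.integer(seed), n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length),
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    snv_counts = snv_counts, indel_counts = indel_counts,
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    include_trio = isTRUE(include_trio),
    panel_populations = panel_populations,
    panel_total = as.integer(panel_total), alpha = alpha,
    # cohort plan: candidate variants shared by every case
    als_snv_candidates = c(missense = 3, nonsense = 2, splice_site = 1),
    als_indel_candidates = c(frame_shift = 1, aa_deletion = 1),
    n_shared_known = 4L,       # known variants shared by every case
    n_control_excluded = 2L,   # shared by every case AND present in controls
    n_shared_two = 3L,         # shared by exactly the first two cases
    control_scale = 0.4,       # control decoy load relative to a case
    n_trio_background = 12L
  )
  if (spec$n_genes < 1L || spec$n_contigs < 1L) {
    abort("need at least one gene and one contig",
          class = "exomesieve_config_error")
  }
  if (any(spec$als_snv_candidates >
          spec$snv_counts[names(spec$als_snv_candidates)], na.rm = TRUE)) {
    abort("snv_counts too small for the planted candidate set",
          class = "exomesieve_config_error")
  }
  structure(spec, class = "exomesieve_fixture_spec")
}

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE)[
  !grepl("N", names(Biostrings::GENETIC_CODE))],
  c("TAA", "TAG", "TGA"))
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generate the reference genome and gene models of a fixture
#'
#' Builds random contigs, places genes along them (alternating strands,
#' one compact gene nested inside a long intron of the first gene when
#' `n_genes >= 4`), and overwrites each gene's CDS bases with a constructed
#' coding sequence: ATG, random sense codons, one stop.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `genome` (a `genome_seq`) and `transcripts` (the
#'   gene-model tibble).
#' @export
generate_reference <- function(spec) {
  withr::with_seed(spec$seed, generate_reference_impl(spec))
}

generate_reference_impl <- function(spec) {
  bases <- c("A", "C", "G", "T")
  contigs <- paste0("chr", seq_len(spec$n_contigs))
  chars <- lapply(contigs, function(x) {
    sample(bases, spec$contig_length, replace = TRUE)
  })
  names(chars) <- contigs

  make_gene <- function(id, contig, strand, start, n_exons,
                        long_intron1 = FALSE, compact = FALSE) {
    exon_lens <- if (compact) {
      sample(90:140, n_exons, replace = TRUE)
    } else if (n_exons == 1L) {
      sample(150:240, 1L)
    } else {
      sample(80:150, n_exons, replace = TRUE)
    }
    intron_lens <- if (n_exons > 1L) {
      sample(80:200, n_exons - 1L, replace = TRUE)
    } else {
      integer(0)
    }
    if (long_intron1 && n_exons > 1L) intron_lens[1] <- 2000L
    es <- integer(n_exons); ee <- integer(n_exons)
    cur <- start
    for (i in seq_len(n_exons)) {
      es[i] <- cur
      ee[i] <- cur + exon_lens[i]
      cur <- ee[i] + if (i < n_exons) intron_lens[i] else 0L
    }
    u5 <- sample(15:30, 1L)
    u3 <- sample(15:30, 1L)
    cds_start <- es[1] + u5
    cds_end <- ee[n_exons] - u3
    cds_len <- sum(pmin(ee, cds_end) - pmax(es, cds_start))
    cds_end <- cds_end - cds_len %% 3L
    cds_len <- cds_len - cds_len %% 3L
    if (cds_len < 30L || cds_start >= cds_end) {
      abort("infeasible gene geometry (CDS too short)",
            class = "exomesieve_config_error")
    }
    tibble(
      transcript_id = sprintf("TX%03d", id),
      gene_name = sprintf("GENE%02d", id),
      contig = contig, strand = strand,
      tx_start = es[1], tx_end = ee[n_exons],
      cds_start = cds_start, cds_end = cds_end,
      n_exons = n_exons, exon_starts = list(es), exon_ends = list(ee),
      coding = TRUE, cds_ok = TRUE
    )
  }

  genes <- list()
  cursor <- setNames(rep(500L, spec$n_contigs), contigs)
  nest_pair <- spec$n_genes >= 4L
  g <- 1L
  while (g <= spec$n_genes) {
    contig <- contigs[(g - 1L) %% spec$n_contigs + 1L]
    strand <- if (g %% 2L == 1L) "+" else "-"
    n_exons <- sample(seq(spec$exons_per_gene[1], spec$exons_per_gene[2]),
                      1L)
    if (nest_pair && g == 1L) {
      host <- make_gene(g, contig, strand, cursor[contig],
                        max(n_exons, 2L), long_intron1 = TRUE)
      genes[[g]] <- host
      # nested gene inside the 2 kb intron, opposite strand
      intron_lo <- host$exon_ends[[1]][1]
      nested <- make_gene(g + 1L, contig, "-", intron_lo + 200L, 2L,
                          compact = TRUE)
      if (nested$tx_end >= host$exon_starts[[1]][2] - 50L) {
        abort("infeasible nested gene geometry",
              class = "exomesieve_config_error")
      }
      genes[[g + 1L]] <- nested
      cursor[contig] <- host$tx_end + sample(400:800, 1L)
      g <- g + 2L
    } else {
      genes[[g]] <- make_gene(g, contig, strand, cursor[contig], n_exons)
      cursor[contig] <- genes[[g]]$tx_end + sample(400:800, 1L)
      g <- g + 1L
    }
    last <- genes[[length(genes)]]
    if (last$tx_end + 200L > spec$contig_length) {
      abort("contig_length too small for n_genes",
            class = "exomesieve_config_error")
    }
  }
  transcripts <- bind_rows(genes)

  # overwrite CDS bases with a constructed coding sequence
  for (t in seq_len(nrow(transcripts))) {
    tx <- tx_row(transcripts[t, ])
    cds_pos <- oracle_cds_positions(tx)
    n_codon <- length(cds_pos) %/% 3L
    cds_str <- paste0("ATG",
                      paste(sample(SENSE_CODONS, n_codon - 2L,
                                   replace = TRUE), collapse = ""),
                      sample(STOP_CODONS, 1L))
    genomic <- if (tx$strand == "+") cds_str else revcomp(cds_str)
    chars[[tx$contig]][cds_pos + 1L] <- strsplit(genomic, "")[[1]]
  }

  genome <- vapply(chars, paste, character(1), collapse = "")
  list(genome = structure(genome, class = "genome_seq"),
       transcripts = transcripts)
}

REGION_RANK <- c(intergenic = 1, intron = 3, utr3 = 4, utr5 = 5,
                 splice_site = 9, exon = 99, cds = 99)

# Per-contig map of the highest-severity region label at every base, and
# per-transcript rank vectors (for cross-transcript severity checks).
build_region_maps <- function(genome, transcripts, splice_window = 2L) {
  maps <- list()
  for (contig in names(genome)) {
    len <- nchar(genome[[contig]])
    label <- rep("intergenic", len)
    rank <- rep(1, len)
    tx_ranks <- list()
    for (t in seq_len(nrow(transcripts))) {
      tx <- tx_row(transcripts[t, ])
      if (tx$contig != contig) next
      lab <- oracle_paint(tx, splice_window)
      r <- unname(REGION_RANK[lab])
      idx <- seq(tx$tx_start + 1L, tx$tx_end)
      tr <- rep(0, len)
      tr[idx] <- r
      tx_ranks[[tx$transcript_id]] <- tr
      upd <- tr[idx] > rank[idx]
      label[idx][upd] <- lab[upd]
      rank[idx][upd] <- tr[idx][upd]
    }
    maps[[contig]] <- list(label = label, rank = rank, tx_ranks = tx_ranks)
  }
  maps
}

#' Plant per-sample variant sets with oracle-certified truth labels
#'
#' Chooses a position and alleles for every requested category such that
#' the brute-force oracle assigns exactly that category to the variant's
#' representative annotation (cross-transcript severity included), assigns
#' novelty, zygosity and panel-divergence attributes, lays out the cohort
#' (shared candidate set in every case, pairwise-shared variants,
#' control-excluded variants, trio plants), and derives the expected filter
#' fate of every record from its attributes alone.
#'
#' @param spec A [fixture_spec()].
#' @param ref Output of [generate_reference()].
#' @return A list with `samples` (named list of variant tibbles), `roles`,
#'   `truth` (one row per planted record per sample), `known` (catalogue
#'   tibble), `cohort` (shared/excluded key sets) and `trio_truth`.
#' @export
plant_variants <- function(spec, ref) {
  withr::with_seed(spec$seed + 1L, plant_variants_impl(spec, ref))
}

plant_variants_impl <- function(spec, ref) {
  genome <- ref$genome
  transcripts <- ref$transcripts
  maps <- build_region_maps(genome, transcripts)
  bases <- c("A", "C", "G", "T")

  # --- candidate pools -----------------------------------------------------
  coding_cats <- c("syn_code", "missense", "nonsense", "read_through")
  pool_coding <- list()
  for (t in seq_len(nrow(transcripts))) {
    tx <- transcripts[t, ]
    cat_tbl <- oracle_snv_categories_all(tx, genome, flank = 0L)
    cat_tbl <- cat_tbl[cat_tbl$category %in% coding_cats, , drop = FALSE]
    if (nrow(cat_tbl) == 0L) next
    m <- maps[[tx$contig]]
    other <- rep(0, nchar(genome[[tx$contig]]))
    for (id in names(m$tx_ranks)) {
      if (id != tx$transcript_id) other <- pmax(other, m$tx_ranks[[id]])
    }
    keep <- severity_rank(cat_tbl$category) > other[cat_tbl$pos]
    cat_tbl <- cat_tbl[keep, , drop = FALSE]
    cat_tbl$contig <- tx$contig
    pool_coding[[length(pool_coding) + 1L]] <- cat_tbl
  }
  pool_coding <- bind_rows(pool_coding)
  pool_coding <- pool_coding[sample(nrow(pool_coding)), ]

  region_positions <- function(contig, label) {
    which(maps[[contig]]$label == label)
  }

  used_pos <- new.env(parent = emptyenv())
  mark_used <- function(contig, pos, len = 1L) {
    for (p in seq(pos, pos + len - 1L)) {
      assign(paste0(contig, ":", p), TRUE, envir = used_pos)
    }
  }
  is_used <- function(contig, pos, len = 1L) {
    any(vapply(seq(pos, pos + len - 1L), function(p) {
      exists(paste0(contig, ":", p), envir = used_pos)
    }, logical(1)))
  }

  draw_snv <- function(category) {
    if (category %in% coding_cats) {
      idx <- which(pool_coding$category == category)
      for (i in idx) {
        if (is_used(pool_coding$contig[i], pool_coding$pos[i])) next
        row <- pool_coding[i, ]
        pool_coding <<- pool_coding[-i, , drop = FALSE]
        mark_used(row$contig, row$pos)
        return(list(contig = row$contig, pos = row$pos, ref = row$ref,
                    alt = row$alt, var_class = "snv", category = category))
      }
      abort(paste0("no site available for category ", category),
            class = "exomesieve_config_error")
    } else {
      for (try in 1:500) {
        contig <- sample(names(genome), 1L)
        cand <- region_positions(contig, category)
        if (length(cand) == 0L) next
        pos <- sample(cand, 1L)
        if (is_used(contig, pos)) next
        ref_b <- genome_slice(genome, contig, pos)
        mark_used(contig, pos)
        return(list(contig = contig, pos = pos, ref = ref_b,
                    alt = sample(setdiff(bases, ref_b), 1L),
                    var_class = "snv", category = category))
      }
      abort(paste0("no site available for category ", category),
            class = "exomesieve_config_error")
    }
  }

  draw_indel <- function(category) {
    coding <- category %in% c("frame_shift", "aa_insertion", "aa_deletion")
    for (try in 1:500) {
      if (coding) {
        L <- switch(category, frame_shift = sample(c(1L, 2L, 4L), 1L), 3L)
        vc <- switch(category,
                     frame_shift = sample(c("insertion", "deletion"), 1L),
                     aa_insertion = "insertion", aa_deletion = "deletion")
        ctx <- transcripts[sample(nrow(transcripts), 1L), ]
        iv <- tx_cds_intervals(ctx)
        ok <- which(iv$end - iv$start >= L + 8L)
        if (length(ok) == 0L) next
        j <- sample(rep(ok, 2L), 1L)  # rep() guards length-1 sample()
        pos <- sample((iv$start[j] + 4L):(iv$end[j] - L - 4L), 1L) + 1L
        contig <- ctx$contig
      } else {
        L <- sample(1:4, 1L)
        vc <- sample(c("insertion", "deletion"), 1L)
        contig <- sample(names(genome), 1L)
        cand <- region_positions(contig, sample(c("intron", "intergenic"),
                                                1L))
        cand <- cand[cand > 10L & cand < nchar(genome[[contig]]) - 10L]
        if (length(cand) == 0L) next
        pos <- sample(cand, 1L)
      }
      if (is_used(contig, max(1L, pos - 2L), L + 4L)) next
      rec <- tibble(
        contig = contig, pos = as.integer(pos),
        ref_allele = if (vc == "deletion") {
          genome_slice(genome, contig, pos, pos + L - 1L)
        } else "",
        alt_allele = if (vc == "insertion") {
          paste(sample(bases, L, replace = TRUE), collapse = "")
        } else "",
        var_class = vc, zygosity = "het", support = NA_integer_,
        sample_id = "tmp", raw_line_no = NA_integer_
      )
      rec <- normalize_indel(rec, genome)
      if (is_used(contig, max(1L, rec$pos - 2L), L + 4L)) next
      got <- oracle_representative_category(rec, transcripts, genome)
      if (got != category) next
      mark_used(contig, max(1L, rec$pos - 2L), L + 4L)
      return(list(contig = rec$contig, pos = rec$pos,
                  ref = rec$ref_allele, alt = rec$alt_allele,
                  var_class = vc, category = category))
    }
    abort(paste0("no site available for indel category ", category),
          class = "exomesieve_config_error")
  }

  # --- plant records -------------------------------------------------------
  rs_counter <- 0L
  known_rows <- list()
  add_known <- function(site, clinical) {
    rs_counter <<- rs_counter + 1L
    known_rows[[length(known_rows) + 1L]] <<- tibble(
      contig = site$contig, pos = site$pos, ref_allele = site$ref,
      alt_allele = site$alt, var_class = site$var_class,
      rs_id = sprintf("rs%06d", rs_counter), clinical = clinical
    )
    sprintf("rs%06d", rs_counter)
  }

  plant <- function(category, novelty, zygosity, divergent, in_panel) {
    site <- if (category %in% names(spec$snv_counts)) draw_snv(category)
            else draw_indel(category)
    rs <- NA_character_
    if (novelty == "known") rs <- add_known(site, FALSE)
    if (novelty == "known_disease_related") rs <- add_known(site, TRUE)
    tibble(
      contig = site$contig, pos = site$pos, ref_allele = site$ref,
      alt_allele = site$alt, var_class = site$var_class,
      category = category, novelty = novelty, rs_id = rs,
      zygosity = zygosity, support = sample(15:60, 1L),
      in_panel = in_panel && site$var_class == "snv",
      chb_divergent = divergent && site$var_class == "snv"
    )
  }

  rand_novelty <- function(n) {
    sample(c("novel", "known", "known_disease_related"), n, replace = TRUE,
           prob = c(0.35, 0.58, 0.07))
  }
  rand_zyg <- function(n) {
    sample(c("het", "hom"), n, replace = TRUE, prob = c(0.65, 0.35))
  }

  # candidate set shared by every case: novel, het, CHB-divergent
  cand_rows <- list()
  for (cat in names(spec$als_snv_candidates)) {
    for (i in seq_len(spec$als_snv_candidates[[cat]])) {
      cand_rows <- c(cand_rows, list(
        plant(cat, "novel", "het", divergent = TRUE, in_panel = TRUE)))
    }
  }
  for (cat in names(spec$als_indel_candidates)) {
    for (i in seq_len(spec$als_indel_candidates[[cat]])) {
      cand_rows <- c(cand_rows, list(
        plant(cat, "novel", "het", divergent = FALSE, in_panel = FALSE)))
    }
  }
  candidates <- bind_rows(cand_rows)

  shared_known <- bind_rows(lapply(seq_len(spec$n_shared_known), function(i) {
    plant(sample(c("intron", "syn_code"), 1L), "known", "het",
          divergent = FALSE, in_panel = TRUE)
  }))
  control_excluded <- bind_rows(lapply(seq_len(spec$n_control_excluded),
                                       function(i) {
    plant("missense", "known", "het", divergent = FALSE, in_panel = TRUE)
  }))
  shared_two <- bind_rows(lapply(seq_len(spec$n_shared_two), function(i) {
    plant(sample(c("utr3", "intron", "syn_code"), 1L), "known", "het",
          divergent = FALSE, in_panel = TRUE)
  }))

  shared_all <- bind_rows(candidates, shared_known, control_excluded)

  # per-case unique decoys fill the remaining per-category quota
  shared_tally <- function(x) table(factor(
    x$category, levels = c(names(spec$snv_counts),
                           names(spec$indel_counts))))
  base_quota <- c(spec$snv_counts, spec$indel_counts)
  case_samples <- list()
  case_truth <- list()
  for (ci in seq_len(spec$n_cases)) {
    sid <- paste0("case", ci)
    shared_here <- if (ci <= 2L) bind_rows(shared_all, shared_two)
                   else shared_all
    quota <- base_quota - as.integer(shared_tally(shared_here))
    if (any(quota < 0)) {
      abort("per-category counts too small for the shared plan",
            class = "exomesieve_config_error")
    }
    uniq <- list()
    for (cat in names(quota)) {
      k <- quota[[cat]]
      if (k <= 0) next
      nov <- rand_novelty(k); zyg <- rand_zyg(k)
      for (i in seq_len(k)) {
        uniq <- c(uniq, list(plant(cat, nov[i], zyg[i], divergent = FALSE,
                                   in_panel = TRUE)))
      }
    }
    recs <- bind_rows(c(list(shared_here), uniq))
    recs$sample_id <- sid
    case_truth[[sid]] <- recs
    case_samples[[sid]] <- recs
  }

  # controls: the control-excluded keys plus their own decoys
  control_samples <- list()
  control_truth <- list()
  for (ci in seq_len(spec$n_controls)) {
    sid <- paste0("control", ci)
    quota <- floor(base_quota * spec$control_scale)
    uniq <- list()
    for (cat in names(quota)) {
      k <- quota[[cat]]
      if (k <= 0) next
      nov <- rand_novelty(k); zyg <- rand_zyg(k)
      for (i in seq_len(k)) {
        uniq <- c(uniq, list(plant(cat, nov[i], zyg[i], divergent = FALSE,
                                   in_panel = FALSE)))
      }
    }
    recs <- bind_rows(c(list(control_excluded), uniq))
    recs$sample_id <- sid
    control_truth[[sid]] <- recs
    control_samples[[sid]] <- recs
  }

  # trio: planted de novo (A), recessive (B), inheritance decoys, background
  trio_samples <- NULL
  trio_truth <- NULL
  if (spec$include_trio) {
    A <- plant("missense", "novel", "het", FALSE, FALSE)   # de novo
    B <- plant("missense", "novel", "hom", FALSE, FALSE)   # recessive
    C <- plant("intron", "known", "het", FALSE, FALSE)     # inherited (F)
    D <- plant("syn_code", "known", "het", FALSE, FALSE)   # inherited (M)
    E <- plant("missense", "known", "hom", FALSE, FALSE)   # hom, one carrier
    F_ <- plant("intron", "known", "het", FALSE, FALSE)    # parents only
    bg <- bind_rows(lapply(seq_len(spec$n_trio_background), function(i) {
      plant(sample(c("intron", "syn_code", "utr5"), 1L), "known", "het",
            FALSE, FALSE)
    }))
    with_zyg <- function(x, z) { x$zygosity <- z; x }
    child <- bind_rows(A, B, C, D, E, bg)
    father <- bind_rows(with_zyg(B, "het"), C, with_zyg(E, "het"), F_, bg)
    mother <- bind_rows(with_zyg(B, "het"), D, F_, bg)
    trio_plan <- list(child = child, father = father, mother = mother)
    trio_samples <- list()
    trio_t <- list()
    for (sid in names(trio_plan)) {
      recs <- trio_plan[[sid]]
      recs$sample_id <- sid
      trio_samples[[sid]] <- recs
      trio_t[[sid]] <- recs
    }
    gt_of <- function(x, key) {
      i <- match(key, variant_key(x))
      if (is.na(i)) "hom_ref"
      else if (x$zygosity[i] == "hom") "hom_alt"
      else "het"
    }
    all_keys <- sort(unique(unlist(lapply(trio_plan, variant_key))))
    trio_truth <- bind_rows(lapply(all_keys, function(k) {
      cg <- gt_of(trio_plan$child, k)
      fg <- gt_of(trio_plan$father, k)
      mg <- gt_of(trio_plan$mother, k)
      carries <- function(g) g %in% c("het", "hom_alt")
      tibble(
        key = k, child = cg, father = fg, mother = mg,
        expect_de_novo = carries(cg) && fg == "hom_ref" && mg == "hom_ref",
        expect_recessive = cg == "hom_alt" && fg == "het" && mg == "het",
        expect_dominant = carries(cg) && (carries(fg) || carries(mg))
      )
    }))
    case_truth <- c(case_truth, trio_t)
    case_samples <- c(case_samples, trio_samples)
  }

  samples_raw <- c(case_samples, control_samples)
  truth <- bind_rows(c(case_truth, control_truth))
  truth$key <- variant_key(truth)
  truth$als_retained <- ifelse(
    truth$var_class == "snv",
    truth$novelty == "novel" & truth$zygosity == "het" &
      truth$category %in% c("missense", "nonsense", "splice_site") &
      (truth$chb_divergent | !truth$in_panel),
    truth$novelty == "novel" & truth$zygosity == "het" &
      truth$category != "non_coding"
  )

  roles <- c(setNames(rep("case", spec$n_cases),
                      paste0("case", seq_len(spec$n_cases))),
             if (spec$include_trio) {
               c(child = "child", father = "father", mother = "mother")
             },
             setNames(rep("control", spec$n_controls),
                      paste0("control", seq_len(spec$n_controls))))

  # catalogue decoys at untouched positions
  decoys <- list()
  for (i in seq_len(30L)) {
    contig <- sample(names(genome), 1L)
    cand <- which(maps[[contig]]$label %in% c("intergenic", "intron"))
    pos <- sample(cand, 1L)
    if (is_used(contig, pos)) next
    mark_used(contig, pos)
    ref_b <- genome_slice(genome, contig, pos)
    site <- list(contig = contig, pos = pos, ref = ref_b,
                 alt = sample(setdiff(bases, ref_b), 1L),
                 var_class = "snv")
    add_known(site, FALSE)
  }

  known <- bind_rows(known_rows)
  known <- known[!duplicated(variant_key(known)), , drop = FALSE]
  known <- arrange(known, .data$contig, .data$pos)

  to_records <- function(x) {
    out <- x |>
      select("contig", "pos", "ref_allele", "alt_allele", "var_class",
             "zygosity", "support", "sample_id") |>
      arrange(.data$contig, .data$pos)
    out$raw_line_no <- seq_len(nrow(out))
    out
  }
  samples <- lapply(samples_raw, to_records)

  list(
    samples = samples, roles = roles, truth = truth, known = known,
    cohort = list(
      shared_all_keys = sort(variant_key(shared_all)),
      candidate_keys = sort(variant_key(candidates)),
      control_excluded_keys = sort(variant_key(control_excluded)),
      shared_two_keys = sort(variant_key(shared_two))
    ),
    trio_truth = trio_truth
  )
}

#' Generate the population allele-count panel of a fixture
#'
#' Every planted in-panel SNV gets per-population allele counts: sites
#' planted as CHB-divergent get counts whose 2x2 chi-square against the
#' carrying sample's two alleles is significant at `spec$alpha` in CHB (and
#' matching counts elsewhere); non-divergent sites get counts exactly
#' matching the sample allele frequency (chi-square 0). Each planted site
#' is verified at generation time by calling [chi_square_allele_test()].
#'
#' @param spec A [fixture_spec()].
#' @param planted Output of [plant_variants()].
#' @return A wide panel tibble (see [read_panel()]).
#' @export
generate_panel <- function(spec, planted) {
  withr::with_seed(spec$seed + 2L, generate_panel_impl(spec, planted))
}

generate_panel_impl <- function(spec, planted) {
  truth <- planted$truth
  sites <- truth[truth$in_panel & truth$var_class == "snv", , drop = FALSE]
  sites <- sites[!duplicated(sites$key), , drop = FALSE]
  tot <- spec$panel_total
  half <- tot %/% 2L
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    counts <- list()
    for (p in spec$panel_populations) {
      if (s$chb_divergent && p == "CHB") {
        cnt <- c(tot, 0L)              # panel carries no alternate allele
      } else if (s$zygosity == "hom") {
        cnt <- c(0L, tot)              # matches a hom-alt carrier exactly
      } else {
        cnt <- c(half, tot - half)     # matches a het carrier exactly
      }
      counts[[paste0(p, "_ref")]] <- cnt[1]
      counts[[paste0(p, "_alt")]] <- cnt[2]
    }
    rows[[i]] <- tibble(contig = s$contig, pos = s$pos, ref = s$ref_allele,
                        alt = s$alt_allele, !!!counts)
    # generation-time self-check of the planted significance
    alt_copies <- if (s$zygosity == "hom") 2L else 1L
    chb <- chi_square_allele_test(alt_copies, counts$CHB_ref,
                                  counts$CHB_alt, alpha = spec$alpha)
    if (chb$significant != s$chb_divergent) {
      abort("planted panel site failed its significance self-check",
            class = "exomesieve_config_error")
    }
  }
  panel <- bind_rows(rows)
  panel <- arrange(panel, .data$contig, .data$pos)
  attr(panel, "populations") <- spec$panel_populations
  panel
}

#' Generate a complete synthetic fixture
#'
#' Runs [generate_reference()], [plant_variants()] and [generate_panel()]
#' for one spec and bundles the results.
#'
#' @param spec A [fixture_spec()].
#' @return A list of class `exomesieve_fixture`: `spec`, `genome`,
#'   `transcripts`, `samples`, `roles`, `truth`, `known`, `panel`,
#'   `cohort`, `trio_truth`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  ref <- generate_reference(spec)
  planted <- plant_variants(spec, ref)
  panel <- generate_panel(spec, planted)
  structure(c(list(spec = spec, genome = ref$genome,
                   transcripts = ref$transcripts, panel = panel),
              planted),
            class = "exomesieve_fixture")
}

#' Write a fixture to disk in the formats the pipeline consumes
#'
#' Emits `reference.fa`, `genes.refgene.tsv`, `known.vcf`, `panel.tsv`,
#' one VCF per sample, `manifest.tsv` (sample_id, role, path) and
#' `truth_table.tsv`.
#'
#' @param fx An `exomesieve_fixture`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  fa <- file.path(dir, "reference.fa")
  con <- file(fa, "w")
  for (contig in names(fx$genome)) {
    writeLines(paste0(">", contig), con)
    seq <- fx$genome[[contig]]
    starts <- seq.int(1L, nchar(seq), by = 60L)
    writeLines(substring(seq, starts, pmin(starts + 59L, nchar(seq))), con)
  }
  close(con)
  paths$reference <- fa

  gm <- file.path(dir, "genes.refgene.tsv")
  tx <- fx$transcripts
  lines <- vapply(seq_len(nrow(tx)), function(i) {
    paste(tx$transcript_id[i], tx$contig[i], tx$strand[i], tx$tx_start[i],
          tx$tx_end[i], tx$cds_start[i], tx$cds_end[i], tx$n_exons[i],
          paste0(paste(tx$exon_starts[[i]], collapse = ","), ","),
          paste0(paste(tx$exon_ends[[i]], collapse = ","), ","),
          tx$gene_name[i], sep = "\t")
  }, character(1))
  writeLines(lines, gm)
  paths$gene_models <- gm

  kv <- file.path(dir, "known.vcf")
  k <- fx$known
  klines <- c("##fileformat=VCFv4.2",
              paste0("##INFO=<ID=CLN,Number=0,Type=Flag,",
                     "Description=\"Clinically associated\">"),
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", sep = "\t"))
  for (i in seq_len(nrow(k))) {
    if (k$var_class[i] == "snv") {
      pos <- k$pos[i]; ref <- k$ref_allele[i]; alt <- k$alt_allele[i]
    } else {
      anchor <- genome_slice(fx$genome, k$contig[i], k$pos[i] - 1L)
      pos <- k$pos[i] - 1L
      if (k$var_class[i] == "insertion") {
        ref <- anchor; alt <- paste0(anchor, k$alt_allele[i])
      } else {
        ref <- paste0(anchor, k$ref_allele[i]); alt <- anchor
      }
    }
    klines <- c(klines, paste(k$contig[i], pos, k$rs_id[i], ref, alt, ".",
                              ".", if (k$clinical[i]) "CLN=1" else ".",
                              sep = "\t"))
  }
  writeLines(klines, kv)
  paths$known <- kv

  pn <- file.path(dir, "panel.tsv")
  readr::write_tsv(fx$panel, pn, progress = FALSE)
  paths$panel <- pn

  manifest <- list()
  for (sid in names(fx$samples)) {
    vp <- file.path(dir, paste0(sid, ".vcf"))
    write_variants_vcf(fx$samples[[sid]], vp, genome = fx$genome)
    paths[[sid]] <- vp
    manifest[[sid]] <- tibble(sample_id = sid, role = fx$roles[[sid]],
                              path = basename(vp))
  }
  mf <- file.path(dir, "manifest.tsv")
  readr::write_tsv(bind_rows(manifest), mf, progress = FALSE)
  paths$manifest <- mf

  tt <- file.path(dir, "truth_table.tsv")
  readr::write_tsv(fx$truth, tt, progress = FALSE)
  paths$truth <- tt

  invisible(paths)
}
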