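---
title: "Variant annotation, filtering and cohort selection with exomesieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant annotation, filtering and cohort selection with exomesieve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

exomesieve prioritises candidate disease-related variants from exome
sequencing call sets. A run takes one or more per-sample variant lists
(VCF, samtools consensus pileup, or SOAPsnp tabular), a reference genome,
UCSC refGene-style gene models, a known-variant catalogue and a population
allele-count panel, and produces annotated, filtered candidate tables plus
cross-sample comparisons. This vignette explains the underlying model, the
parameters that matter, and the design decisions taken where the problem
statement left choices open.

## The annotation model

Every variant is located relative to every transcript it overlaps.
Internally all transcript coordinates are 0-based half-open (the refGene
convention); every user-facing coordinate is 1-based (the VCF convention).

Positions are painted into six regions: `intergenic` (outside the
transcript span), `intron`, `splice_site`, `utr5`/`utr3` (assigned in
coding orientation, so the 5' UTR of a minus-strand transcript lies at the
genomic right), and `cds`. Three choices here were genuinely open:

* **Splice window.** A splice site is not defined in the underlying
  description; we take the canonical donor/acceptor dinucleotides and
  default `splice_window = 2` intronic bases on each side of every
  exon/intron boundary. The window is configurable.
* **Exonic precedence.** A coding base that is also within the splice
  window of a boundary is classified `cds`, never `splice_site`:
  `splice_site` refers to intronic bases only. This keeps the nine SNV
  output categories disjoint, so category counts partition the variants.
* **Non-coding transcripts.** The category set has no "non-coding exon"
  class; exonic bases of a transcript without a CDS are labelled `intron`.

For a coding-region SNV the affected codon is rebuilt from the spliced CDS
(read across exon junctions, reverse-complemented for minus-strand
transcripts), the alternate base is substituted strand-adjusted, and both
codons are translated with the standard nuclear genetic code. The category
follows from the amino-acid comparison: `syn_code` (unchanged, including a
stop codon replaced by another stop), `nonsense` (amino acid to stop),
`read_through` (stop to amino acid), `missense` otherwise. Changes are
reported in three-letter `p.` notation, e.g. `p.Cys146Ter`. Two edge
policies: an SNV destroying the initiator ATG is reported `missense` with
a `start_loss = TRUE` flag (the taxonomy has no start-loss class), and
transcripts whose annotated CDS length is not a multiple of 3 — real
refGene dumps contain them — are skipped by default, or kept with
region-level annotation only (`keep_broken = TRUE`), because silently
translating a broken frame is worse than refusing to.

InDels have four categories. An indel whose affected bases intersect no
CDS base is `non_coding` (flagged `splice_adjacent` when it touches a
splice-window base, so the signal is preserved without inventing a fifth
category). Otherwise the number of CDS bases added or removed drives the
frame rule: not a multiple of 3 is `frame_shift`, in-frame events are
`aa_insertion`/`aa_deletion`. An indel spanning a CDS/intron boundary is
classified by its CDS-intersecting portion, which is the reading most
consistent with a "located in the coding region" criterion. An insertion
counts as coding when both bases flanking the insertion point are CDS
bases.

A variant overlapping several transcripts is annotated against all of
them; one representative is chosen by a fixed severity order —

```
nonsense > frame_shift > read_through > splice_site > missense >
aa_insertion = aa_deletion > syn_code > utr5 > utr3 > intron > intergenic
```

— with ties broken by lexicographically smaller transcript id, which makes
the choice deterministic and independent of input order.

## Novelty and the known-variant catalogue

Variants are matched against a catalogue (a dbSNP-style VCF) by normalised
position and alleles; a position-only fallback exists for catalogues
without allele detail. Absent variants are `novel`; present ones are
`known`, or `known_disease_related` when the record carries the
clinically-associated flag (INFO key `CLN`). The novelty filter retains
disease-related known variants alongside novel ones under the
`novel_or_disease` setting, reflecting that a clinically flagged variant
is a finding, not noise. Indel matching uses left-aligned minimal
representations on both sides: every indel is shifted left while the
edited haplotype is unchanged, so identical edits from different callers
compare equal. Normalisation is idempotent and haplotype-preserving.

## Population-frequency testing

For each SNV and each panel population the sample's two alleles are
tabulated against the panel allele counts in a 2x2 table
`[[sample_ref, sample_alt], [panel_ref, panel_alt]]` and tested with the
Pearson chi-square (1 df, no continuity correction by default; Yates
available), computed in closed form as
`N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`. `significant` is defined as
`p < alpha`, with `alpha = 0.05` by default.

What exactly should be tabulated was an open choice; testing the single
sample's two alleles is the smallest faithful reading, and a pooled mode
(summing alleles across case samples) can be built from the same
primitive. With only two sample alleles the chi-square approximation is
crude: whenever an expected cell falls below `min_expected` (default 1)
the result carries a `low_count` flag. The flag is advisory — significance
remains defined by the p-value, because with a diploid sample the minimum
expected cell is below 1 for essentially every unbalanced panel, and a
hard veto would make the test vacuous; users who want the conservative
behaviour set `low_count_fails = TRUE`. Sites absent from the panel are
treated as significant by default (`absent_significant = TRUE`): an
unexplained frequency should not silently pass a frequency filter.

## Filtering

Filter criteria are declarative and conjunctive. SNV criteria apply in the
order: novelty; frequency difference (in a named population or all);
mutation type (transition/transversion, and zygosity); classification
(category subset); protein impact (an externally supplied deleterious
score at most a threshold — impact prediction itself, e.g. SIFT, is an
external method and its scores are accepted as a side table). InDel
criteria: novelty; coding region; mutation type (insertion/deletion, and
zygosity); impact subcategory. The per-criterion removal tally follows
this order; the retained set itself is order-independent. Records with
unknown zygosity fail zygosity criteria by default ("not assessable"
rather than silently kept), configurable. `als_preset()` encodes the
published familial-ALS configuration: novel-only, heterozygous,
missense/nonsense/splice-site SNVs diverging from the CHB panel at 0.05,
plus novel heterozygous coding InDels.

## Cohort analyses

The unit of cross-sample identity is the normalised variant key
(contig, position, alleles) — the two-case and multiple-case analyses
count shared variant *sites*, with gene-level aggregation left to
reporting; a position-only mode exists. `shared_by_k()` keeps keys present
in at least *k* case samples (k at least 2) and subtracts every control
key. Trio filtering implements three explicit Mendelian models rather
than one opaque switch: `de_novo` (child carries, parents homozygous
reference), `recessive_hom` (child homozygous alternate, both parents
heterozygous carriers) and `dominant_inherited` (child carries, at least
one parent carries). Compound heterozygotes require phase and are out of
scope. A site absent from one member's call set is taken as homozygous
reference by default, since exome call sets omit reference-matching sites;
`absent = "missing"` documents the risk and drops such sites under the
default strictness.

## The synthetic-data generator

`generate_fixture()` builds a complete toy study from one seed, and every
random draw flows through that seed, so the same spec reproduces
byte-identical files. Defaults: 2 contigs of 50 kb; 8 genes (2–4 exons,
both strands, one compact gene nested inside a 2 kb intron of another, so
overlap handling is always exercised); about 170 variants per case sample
across all SNV and InDel categories; a catalogue with known and
clinically flagged entries plus decoys; a 4-population panel
(YRI/JPT/CHB/CEU) of 200 alleles per population; 3 cases sharing a planted
candidate set, 2 controls, and a trio with a planted de novo and a planted
recessive variant. Every CDS is constructed as ATG, random sense codons,
one stop. Panel counts are planted exactly: matching sites reproduce the
carrier's allele frequency (chi-square 0), divergent sites carry no
alternate allele in CHB, and each site's significance is verified at
generation time.

Planted truth labels are certified by a brute-force oracle that shares no
code path with the fast classifiers: it paints every base of a transcript
span individually, collects CDS bases one by one, applies each edit to the
spliced sequence and re-translates the whole protein. The test suite uses
the same oracle as the independent reference for exhaustive sweeps (every
possible SNV — three alternates at every position of 20 transcript spans
±50 bp — and every 1–6 bp indel at every position), for chi-square
equivalence against `stats::chisq.test` on 1,000 random tables, for the
64-entry trio genotype truth table, and for cohort algebra on 200 random
cohorts. These problem sizes keep the whole suite around two minutes while
leaving no category or boundary unexercised.

The generator emulates the *structure* of an exome study, not its
population genetics: no linkage disequilibrium, no realistic mutation-rate
or allele-frequency spectrum, no sequencing error or read-level data, and
contigs far smaller than chromosomes. Passing tests therefore demonstrate
the correctness of coordinate arithmetic, classification, testing,
filtering and set algebra — not calibration of the chi-square test on real
population structure, nor performance at whole-exome scale (though the
classifiers are vectorised and annotate hundreds of thousands of variants
per minute).

## Known limitations

Single nuclear genetic code only; multi-nucleotide substitutions are
counted as unavailable rather than decomposed; no structural variants; no
phasing; HGVS cDNA (`c.`) notation is not produced; the pileup and
SOAPsnp parsers implement the contemporaneous de facto column layouts by
position and are isolated behind the dialect switch so corrections stay
local.
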