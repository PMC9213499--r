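---
title: "Methods: segregation filtering, consequence annotation and the two-locus coat-colour model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segregation filtering, consequence annotation and the two-locus coat-colour model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minkseg)
```

## The analysis in one paragraph

A Mendelian coat-colour trait is mapped by sequencing one animal expressing
the homozygous form against a panel of animals of other colours, keeping
variants that are homozygous-alternate and adequately covered in the case
but never carried by any control, restricting to protein-coding exons and
splice sites, and prioritising genes plausibly involved in pigmentation.
The candidate's case/control allele distribution is then confirmed on a
larger genotyped cohort with an odds-ratio test, and — because the Black
crystal COPA allele interacts epistatically with the Hedlund white MITF
allele — the genotype–phenotype fit is checked under a two-locus rule set
rather than a single-locus one.

## Segregation filter

### Model and assumptions

The filter treats the trait as fully penetrant and the causal variant as
codominant with a homozygous case: every case sample must be `hom_alt`,
and any het or hom-alt call in a control disqualifies the site. This is
exact for a single sequenced case and generalises conservatively to
multi-case designs. The filter is site-wise: no linkage, haplotype or
genotype-likelihood information is used.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `min_case_depth` | 3 | minimum reads covering each case call; "coverage greater than 2" read as a strict inequality, so depth 2 fails |
| `require_case_hom_alt` | `TRUE` | homozygous-alternate case calls only; `FALSE` switches to a carrier (dominant) model |
| `control_disallowed` | `{het, hom_alt}` | control genotype states that disqualify a site |
| `treat_missing_control_as` | `pass` | a missing control call leaves a site eligible; the selection criterion names only observed het/hom states, and a no-call carries no evidence of carriage. Set `fail` for a stricter reanalysis |
| `control_min_depth` | 0 | the depth requirement applies to cases only by default; whether the original depth filter also applied to controls is not determinable, so it is a switch (controls below the threshold are treated as missing) |
| `splice_window` | 2 | intronic bases from an exon boundary kept by stage 2 and called donor/acceptor by the annotator — the canonical GT/AG dinucleotide; annotation-tool defaults vary and are larger, but 2 bp is the defensible core |

Case `hom_ref` sites are never candidates: "homozygous" means homozygous
for the non-reference allele, since the discovery design genotypes the
case against the reference assembly.

Stage 3's severity order (stop > splice > missense > synonymous >
non-coding) is conventional; ties preserve input order, making the ranking
deterministic.

## Consequence annotation

Coding positions are numbered 1..CDS-length from the start-codon A in
transcript orientation; codon index is `⌊(c−1)/3⌋+1`. Intronic positions
are written relative to the nearest exon boundary (`+d` donor side, `−d`
acceptor side, donor preferred on ties — only relevant for odd-length
introns). For minus-strand transcripts the genomic alleles are
reverse-complemented into cDNA space before codon lookup; this is why the
COPA worked example reads G>A genomically but `c.478C>T` in transcript
space. The standard nuclear genetic code is used (these are nuclear
genes), amino acids are reported three-letter (`Arg`, `Cys`, `Ter`), and
UTR positions are categorised but not given `c.−`/`c.*` numbering, which
no downstream step needs. Indels are rejected explicitly: the filter lets
them through, the annotator flags them `unsupported`, because the
annotation model (single-base codon substitution) does not apply.

If a variant's stated reference allele disagrees with the transcript
sequence the annotator warns and trusts the transcript — the transcript is
the coordinate authority.

## Association statistics

The allele table counts two alleles per diploid animal per group. When any
cell is zero the Haldane–Anscombe correction adds 0.5 to **all four**
cells; tables without an empty cell are used unmodified (an unconditional
correction would perturb non-degenerate tables for no reason). The odds
ratio is the cross-product of the (possibly corrected) cells; inference is
Wald on the log scale.

Two numerical conventions matter:

* **Critical value.** `wald_interval()` defaults to the two-decimal normal
  quantile (1.96 at 95%), the value summary tables in this literature are
  computed with; the exact quantile is available via `z_crit`. At the
  reference table the two choices differ only in the third significant
  figure of the upper bound (3825.1 vs 3824.9).
* **Reporting precision.** `format_association()` rounds OR to 3
  significant figures, CI bounds to 2 decimals and p to 2 significant
  figures; full precision is kept in the result object.

The grouping decision for the reference cohort: all 17 animals with a
Black-crystal-spectrum phenotype (both the white-hat carriers and the
completely white double-genotype animals) are cases, the 34 other-colour
animals controls. This is the only grouping under which the allele table
(21, 13, 0, 68) and all four reported statistics are mutually consistent,
and it is the biologically natural one — every case carries at least one
Cr allele.

Fisher's exact test (hypergeometric summation of tables at fixed margins
with probability ≤ the observed) is provided as a labelled alternative;
it is *not* the test the reference values derive from.

## Two-locus epistasis model

Alleles: COPA C (wild-type) / T (Cr); MITF G (wild-type) / A (h). The
default rule set:

| COPA | MITF | class |
|---|---|---|
| CC | GG | standard |
| CC | GA | ventral_spotting |
| CC | AA | hedlund_white_deaf |
| CT | GG | white_hat |
| CT | GA | completely_white |
| CT | AA | completely_white *(extrapolated)* |
| TT | GG / GA | completely_white |
| TT | AA | completely_white *(extrapolated)* |

Eyes are dark in every class of this model; hearing is impaired only in
MITF h/h homozygotes — the double heterozygote is completely white *with
normal hearing*, which is the phenotypic signature of the epistatic class.
Genotype pairs never observed in genotyped cohorts, (CT, AA) and (TT, AA),
are mapped to completely_white on the rationale that full depigmentation
from either locus dominates, and carry an `extrapolated` flag so they are
never mistaken for observation-backed rules. Cr/Cr animals are collapsed
to completely_white even though young homozygotes can retain sparse
pigmented points; genotyped cohorts record them as completely white.

Crosses treat the loci as unlinked (they reside on different chromosomes
in carnivores); a recombination fraction below 0.5 can be supplied, in
which case the parental phase is taken as written.

## Synthetic data: what it emulates and what it does not

`generate_cohort()` emulates the *downstream product* of a whole-genome
discovery cohort: a multi-sample genotype matrix with one planted causal
variant perfectly concordant with case status (full penetrance), background
variants with independent Hardy–Weinberg genotypes, Poisson per-call
depths, and uniformly random missing calls. Defaults are the discovery
design: 1 case, 8 controls, 200 background variants at alternate-allele
frequency 0.2, mean depth 8× (within the 5–40× range typical of such
cohorts), missing rate 2%. Causal-site case calls are never masked and
their depth is drawn from the Poisson truncated at `min_case_depth`,
because the premise of a planted-signal experiment is that the signal was
called — untruncated depths would conflate caller dropout with filter
behaviour.

Not emulated: linkage disequilibrium (the filter is site-wise, so LD adds
nothing testable), sequencing error or genotype-likelihood noise,
population structure, and read-level data. A passing test suite therefore
demonstrates the *logic* of the funnel, not robustness to miscalled
genotypes in real cohorts.

`generate_transcript()` builds a random CDS (ATG start, sense internal
codons, one terminal stop) satisfying user-pinned codons — e.g. CGC at
residue 160, which makes the c.478 C>T / p.Arg160Cys example realisable by
construction — and embeds it with GT/AG introns and flanks on either
strand. Generated transcripts always pass model validation, and identical
spec + seed give byte-identical GFF3/FASTA.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive end-to-end (VCF/GFF3 convention);
  there is no internal 0-based representation to convert.
* Missing DP is depth 0, which fails any positive depth threshold —
  conservative, since the filter is about *observed* coverage.
* Multi-allelic records decompose before filtering; a `1/2` genotype is
  het with respect to each alternate.
* An empty group in the allele table is an error for the odds ratio (the
  estimate is undefined), while an all-zero allele-of-interest column is a
  warning (the table is valid, the association merely absent).
* `fisher_exact()` uses the customary `1 + 1e-7` relative tolerance when
  collecting tables as extreme as the observed one.
* Zero cases or zero controls make the segregation filter undefined and
  raise immediately rather than returning an empty result.

## Problem sizes used by the checks

The shipped tests and the acceptance script use: 100 random 50×6 matrices
for filter/oracle equivalence; 20 seeded default cohorts (201 variants × 9
samples) for planted-variant recovery; 50 cohorts for the closed-form
unique-recovery bound; exhaustive per-base enumeration of toy transcripts
(≤ 1.2 kb contigs) for coordinate bijection and translation consistency;
10,000 offspring per simulated cross; and all 2×2 tables with margins ≤ 15
for the Fisher cross-check. These sizes give stable 4σ statistical margins
while keeping a full run in well under a minute.

## Known limitations

* The annotator handles SNVs against single-transcript models only: no
  indels, no multi-transcript consequence ranking, no damage prediction.
* The funnel's absolute candidate counts on real genomes depend on the
  cohort and caller upstream of the VCF; the package reproduces the
  funnel's *structure* and its behaviour on synthetic truth, not any
  particular count.
* The phenotype rule set is a classifier over two loci; coat colours
  driven by other loci must be collapsed by the label map (everything
  wild-type at COPA/MITF maps to `standard`).
* VCF parsing accepts any caller's 4.x output with GT (and optionally DP)
  fields; filtering provenance (raw vs hard-filtered call sets) is the
  caller's concern, upstream of this package.
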