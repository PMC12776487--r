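---
title: "Prioritising rare variants in trio and dyad exome studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritising rare variants in trio and dyad exome studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triofunnel)
```

## The problem

Syndromic congenital malformations -- here, orofacial clefts co-occurring
with limb anomalies -- are typically studied in small case-parent trios
(proband plus both parents) and case-mother dyads, sequenced at the exome.
Each family yields tens of thousands of coding variants; the analytical
task is to funnel these down to a handful of plausible candidates and to
say, for each survivor, how it segregates in its family. triofunnel
implements that funnel as a reusable, fully testable pipeline over
annotated variant tables: a staged filter cascade, a Mendelian inheritance
classifier, hub-gene ranking on a protein-interaction network, and
over-representation analysis of the surviving gene list. Because the real
patient data behind such studies is controlled-access, the package also
ships a cohort simulator with planted ground truth, so every stage can be
validated end to end without any download.

## The filter cascade

Stages are applied in a fixed order, and each variant carries a complete
per-stage decision trace (`pass` / `fail` / `not_applicable`):

1. **Consequence class.** Only protein-altering classes survive: missense,
   frameshift, stop-gained/lost, start-gained/lost, and splice-region
   variants. Synonymous and other classes fail.
2. **Rarity.** The minor allele frequency is aggregated over three
   population databases (1000 Genomes, ESP, gnomAD) by taking the maximum
   of the *present* values -- the most conservative choice when databases
   disagree, and one the underlying study protocol leaves open. The
   variant passes iff that maximum is *strictly* below `maf_threshold`
   (default 0.01; a variant at exactly 0.01 fails). A variant absent from
   all three databases is novel and passes: absence of frequency evidence
   is not evidence of commonness, and novel variants are exactly the ones
   such studies aim to keep.
3. **Class-specific pathogenicity gate.**
   - *Missense*: a consensus vote over a fixed panel of eleven binarised
     in-silico predictors (ClinPred, MetaRNN, BayesDel_addAF, REVEL, CADD,
     AlphaMissense, MutPred2, Polyphen-2, MutationAssessor,
     MutationTaster, SIFT). The variant passes with at least
     `consensus_min = 6` pathogenic votes -- a strict majority of the
     11-tool panel. A missing verdict counts toward the denominator but
     never the numerator, because the majority is defined against the
     fixed panel size, not against however many tools happened to return
     a call.
   - *Stop/start gain-loss*: gated on the CADD phred score,
     `cadd_min = 20` by default -- the conventional "top 1% most
     deleterious" cutoff. The protocol this package operationalises names
     the tool but no cutoff, so the value is a package default and fully
     config-exposed.
   - *Splice region*: gated on the SpliceAI delta score,
     `splice_min = 0.5`, again the community-standard operating point and
     config-exposed. A missing score fails either gate: a variant whose
     only claim to pathogenicity is unscored has no evidence to stand on.
   - *Frameshift and in-frame indels* bypass the gate: the predictor panel
     and CADD gating are defined for substitutions, and frameshifts are
     presumed damaging by mechanism.
4. **Gene-panel tier.** An optional list of phenotype-associated genes
   annotates survivors as `known_phenotype_gene` or `other`. This stage
   *never* discards: candidate lists in this field retain genes with no
   prior phenotype association, and the tier exists to rank, not to
   exclude.

The rarity filter is applied to every class, including splice-region
variants, before their gate -- the cascade is a funnel, not a set of
parallel filters.

## Inheritance classification

The classifier is a closed decision table over the proband/mother/father
zygosity triple, parent presence, affected status, and chromosome. The
conventions, chosen conservatively:

- **De novo requires positive evidence**: both parents present with
  non-missing `hom_ref` calls. Any missing parental genotype demotes the
  call to `unknown_missing_parent` -- a dyad can never assert de novo
  status, however suggestive.
- A heterozygous proband with exactly one carrier parent is dominant
  inheritance: `ad_inherited_affected_parent` when the carrier parent is
  affected, `ad_incomplete_penetrance` when not. When *both* parents
  carry the allele (possible for less-rare alleles) the same dominant
  sub-modes apply with `carrier_parent = "both"` -- the table must be
  total, and dominance does not care which parent transmitted.
- A homozygous proband with two carrier parents is `ar_homozygous`; with
  two `hom_ref` parents it is `de_novo_homozygous_flagged` -- two
  independent de novo hits at one site are implausible, so the pattern is
  preserved but annotated (`possible hemizygosity/CNV or genotyping
  artefact`) rather than silently called de novo. Real call sets do print
  this combination.
- A homozygous proband with one `hom_ref` parent is
  `mendelian_inconsistent`, even when the other parent is absent: a
  `hom_ref` parent cannot have transmitted the allele regardless of
  anyone else. (With a het proband, the analogous single `hom_ref` parent
  merely yields `unknown_missing_parent` -- the allele may have come from
  the missing side.)
- On the X chromosome, an XY proband is hemizygous: a het call is
  `mendelian_inconsistent`; `hom_alt` with a carrier mother is
  `x_linked`, and with a present `hom_ref` mother is `de_novo` (the
  father's X is not transmitted to a son, so the mother alone decides).
  XX probands follow the autosomal table.
- `tolerate_miscall = TRUE` relaxes the inconsistency verdicts by one
  parental miscall: the `hom_ref` x carrier case under a homozygous
  proband becomes `ar_homozygous` with an explanatory note. The default
  is zero tolerance.

Compound heterozygotes are paired per gene among the proband's het
variants: a pair qualifies iff one variant is carried by the mother only
and the other by the father only (trans by parental origin); same-parent
pairs are excluded as cis. With an absent parent phase cannot be
established, so pairs are emitted with a phase-unknown note -- never
asserted -- except pairs both carried by the single available parent,
which are suppressed as presumed cis. This parsimony rule can in
principle suppress a true trans pair whose second variant the missing
parent also carried, a deliberate trade of sensitivity for not reporting
pairs the data actively suggests are cis.

## Network hubs and enrichment

The survivors' genes form the node set of an undirected weighted
protein-interaction graph; edges at or above a confidence threshold
(default 0.150 -- the permissive exploratory setting appropriate when the
default 0.4 cutoff leaves a near-empty network over a small candidate
list) are retained, and *every queried gene stays a node*, connected or
not, so network statistics are reported against the full candidate list.
Mean degree is `2|E|/|N|`. Hubs are ranked by maximal clique centrality:

$$\mathrm{MCC}(v) = \sum_{C \in M(v)} (|C| - 1)!$$

over the maximal cliques containing `v`, with isolated nodes scoring 1
(the standard CytoHubba singleton convention, which the source protocol
does not state but which keeps every node rankable). Ties are broken by
degree, then alphabetically -- the underlying study lists six top hubs in
one place and seven in another without a rule, so the ranking here is
simply deterministic and `k` is the caller's choice.

Over-representation uses the one-sided hypergeometric upper tail
$P(X \ge k)$ for an overlap of `k` between query and set, equivalent to a
one-sided Fisher exact test, with Benjamini--Hochberg correction. The
published analysis this mirrors used g:Profiler's proprietary g:SCS
correction; BH is the transparent standard replacement, so published
adjusted p-values are illustrative, not reproducible targets. Sets with
zero overlap are not tested (they carry no information and inflate the
correction burden), and the universe defaults to the union of the
collection's genes, extendable with a custom background.

## The simulator, and what passing tests mean

`simulate_cohort()` emulates the *structure* of a small trio/dyad exome
study: per-family annotated variant tables and Mendelian-consistent trio
genotypes with patterns planted at known truth. Defaults mirror the
study design the package operationalises: nine families with a 2/9 dyad
fraction, and one planted de novo candidate per family, the modal pattern
in such cohorts. Background variants draw their population MAF from a
mixture of a point mass at 0 (weight 0.2) and a log-uniform on
[1e-5, 0.5] -- a crude but analytically tractable stand-in for the
heavy-tailed site frequency spectrum, chosen so the expected
rarity-filter pass rate has a closed form the tests verify. Predictor
support is simulated directly as a vote count (6--11 for planted, 0--5
for background) with the voting tools drawn at random; simulating
per-tool raw scores would add structure nothing downstream consumes.
The population MAF is deliberately decoupled from the within-family
sampling frequency used to draw parental genotypes (clamped to
[0.01, 0.5], with sites resampled until some member carries the allele,
as in a real per-family call set). Consanguinity is emulated only as an
inbreeding coefficient in the parental genotype draw. Dyads are
generated as full trios with the father dropped afterwards, so the truth
table retains what the classifier could not see. Genotype error replaces
each observed call, with configured probability, by one of the other two
states uniformly -- applied last, after planting and dropping.

What the simulator does *not* model: linkage and haplotype structure,
read-level evidence, sequencing-error profiles, mosaicism, pedigree
loops. Passing recovery tests therefore demonstrates the correctness of
the decision logic under clean and uniformly noised genotypes, not
robustness to the correlated artefacts of real sequencing.

`evaluate_recovery()` scores calls against expectation, where the
expected label is obtained by classifying the *true* genotypes under the
observed parent availability -- recovery of a correctly demoted dyad
de novo counts as success, and nothing is scored against an
unachievable label.

## Numerical and validation choices

- Thresholds are compared with `>=` at the gates and `<` at rarity,
  exactly as documented; boundary behaviour (6/11 vote, MAF 0.01, edge
  score 0.150) is pinned by tests.
- Exact hypergeometric tests are discrete: their attainable size is below
  the nominal level. The null-calibration study in the test suite uses a
  universe of 10,000 genes, queries of 200 and four disjoint sets of
  sizes 100/200/500/800, where the analytic attainable size averages
  about 0.047 -- close enough to nominal that 2000 replicates resolve
  miscalibration; with small sets the same check would trivially pass at
  a size far below 0.05 and demonstrate nothing.
- Validation problem sizes: the clique/MCC oracle sweeps 200 random
  graphs of up to 10 nodes against exhaustive subset search; the
  segregation table is enumerated exhaustively (genotype triples x
  affected patterns x parent presence); recovery uses 50-family cohorts,
  once clean and twenty times under 1% genotype error, with the
  Mendelian-inconsistency rate checked against its exact expectation
  under the error kernel.
- All randomness in a simulation flows from the single config seed;
  identical configs produce byte-identical files.

## Known limitations

- The classifier is per-variant (plus per-gene pairing); it does not
  jointly model multiple variants, genotype likelihoods, or population
  priors, and will not detect mosaicism.
- The eleven predictor verdicts are consumed pre-binarised; the package
  deliberately does not re-threshold raw scores, because per-tool cutoffs
  are not part of its contract.
- The packaged nine-family fixture transcribes a published variant table;
  fields that table does not print (indel ref/alt alleles, per-database
  MAFs, the identity of the five interaction edges) are synthetic
  placeholders consistent with the published filtering outcome, and the
  edge list is named and documented as synthetic. Network *geometry*
  (13 nodes, 5 edges, mean degree 0.769) is preserved exactly; edge
  identities and hence hub identities are not reproduction targets.
- Phenotype granularity is out of scope: "affected" is a boolean, and
  variable expressivity is represented simply as affected = TRUE.
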