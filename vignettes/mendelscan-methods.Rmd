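---
title: "Cloning a monogenic recessive gene from a biparental cross: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cloning a monogenic recessive gene from a biparental cross: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mendelscan)
```

mendelscan implements an integrated strategy for cloning the gene behind a
monogenic, fully penetrant recessive trait segregating in a biparental plant
cross: confirm the inheritance mode, localise the locus by per-variant
association over a resequenced F2, narrow to a physical target interval,
screen the interval variants against a diversity panel and a bulked-segregant
(BSA) pool, assign the surviving candidates to genes, and reconstruct the
molecular consequence of the causal lesion. This vignette explains each
model, the tunable parameters, what the simulator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## Segregation tests

Inheritance-mode confirmation uses the Pearson goodness-of-fit statistic
with no continuity correction,

$$\chi^2 = \sum_i \frac{(O_i - E_i)^2}{E_i}, \qquad
  E_i = n\,\frac{r_i}{\sum_j r_j},$$

against the 3:1 (F2) and 1:1 (backcross) expectations, at $\alpha = 0.05$
with $k - 1$ degrees of freedom (critical value 3.84 for two classes). The
uncorrected statistic is deliberate: it is the form whose two-decimal
rounding reproduces the classical published inheritance tables this package
is validated against, whereas the Yates-corrected statistic does not.
`classify_inheritance()` applies the full checklist — uniformly
normal-phenotype F1s, backcross fitting 1:1, F2 fitting 3:1 — and names
whichever condition fails. Note that the checklist runs two tests at
$\alpha = 0.05$, so on simulated data it returns "not consistent" for
roughly one replicate in ten even when the trait really is monogenic
recessive; that is the test's nominal type-I behaviour, not a defect.

## Association scan

The default per-variant statistic is the genotypic contingency chi-square on
the 2 (phenotype) × k (observed genotype class) table with $df = k - 1$,
computed vectorised across all variants; missing genotypes are dropped
variant-wise and never imputed (the simplest defensible rule, and imputation
would blur exactly the recombinant signal the scan needs). A general linear
model route (`method = "glm"`), the one-way F-test of the binary phenotype
on genotype-class indicators, is provided for parity with mainstream
GWAS-style tooling; the chi-square is the default because it is exactly
reproducible and oracle-checkable: for a phenotype that is a deterministic
function of genotype the statistic equals the number of non-missing samples.
No multiple-testing correction is applied — peak selection uses the raw
minimum, mirroring field practice for single-locus traits. P-values are
floored at the smallest positive double so they remain in $(0, 1]$.

## Peak selection and the target interval

A fully penetrant recessive trait makes the scan's top end degenerate:
every marker whose homozygous-alternate class coincides exactly with the
mutant-phenotype set separates the phenotypes perfectly and attains
$\chi^2 = n$. These perfect separators form a single linkage block around
the causal site — the block of markers with no informative recombinant —
and their p-values differ only through per-marker call counts, which is
noise. `define_interval()` therefore treats the perfect separators as one
candidate set and places the peak at the marker closest to the block's
coordinate midpoint (on the modal chromosome); this is the posterior-median
choice under the flat likelihood the block implies. When no perfect
separator exists (noisy or quantitative-leaning phenotypes), the ordinary
lowest-p rule applies, with deterministic (chromosome, position)
tie-breaking.

The target interval is the peak ± 200 kb (the `flank_bp` default), with
endpoints reported as the positions of the outermost scanned variants inside
the flank — intervals are marker-bounded, as in the interval naming
convention `C29_6522236`–`C29_6918901`. All coordinates are VCF-style
1-based inclusive.

### The localisation limit

With $n$ F2 individuals, only about $n$ meioses constrain the boundary of
the perfect-separation block (two gametes per mutant individual plus the
non-mutant gamete of each heterozygote). Each side of the block therefore
extends approximately $\mathrm{Exp}(100/n)$ centimorgans beyond the causal
site. At $n = 130$ that is ~0.77 cM per side — roughly 200 kb at the
simulated 3.7 cM/Mb — so a fixed ±200 kb flank around *any* point estimate
inside the block misses the causal variant in a sizeable minority of
replicates (the acceptance script measures the end-to-end recovery rate;
about one run in five fails at this stage under the default design). This
is an information limit of the design, not of the estimator: no peak rule
can do better than the block centre, and only a wider flank or a larger
population raises the recovery rate. The downstream screens are verified
separately and recover and top-rank the causal variant essentially always
once the interval contains it.

## Dual variant screening

Two orthogonal filters then shrink the interval:

* **Germplasm panel** (`panel_screen()`): a fully penetrant recessive causal
  allele cannot be homozygous in any normal-phenotype accession, and if the
  mutation is private to the mutant line it cannot be present at all. The
  default rule (`"no-allele"`) retains variants with zero panel carriers;
  `"no-homozygote"` tolerates heterozygous carriers, since those are
  biologically possible for a recessive allele segregating in the wider
  germplasm. Missing panel calls are tracked as missing and never counted
  as evidence of absence.
* **BSA pool** (`pool_screen()`): in a pool of recessive individuals the
  causal region is fixed for the mutant allele, so retained variants must
  have read depth ≥ 10 and alternate-read fraction ≥ 0.95. The fraction
  threshold sits below 1 to tolerate sequencing error; the depth threshold
  marks shallower sites "unevaluable" — excluded but flagged distinctly,
  not treated as discordant.

The candidate set is the intersection, ranked by association p-value.
`assign_to_genes()` classifies each candidate against gene models with
priority exon > intron > 5'-flanking > 3'-flanking > intergenic; flanks
extend 10 kb and are strand-aware (a 5' flank lies upstream of the
transcription start on the gene's own strand). The nominated gene is the
one hosting the plurality of candidates, ties broken by the member with the
lowest p.

## Consequence engine

`gene_model()` represents a gene 5'→3' on its coding strand with 1-based
exon intervals and a CDS start; introns are the gaps, expected to carry GT
donors and AG acceptors. `apply_gene_variant()` replaces an arbitrary span
(deletion, insertion or indel-substitution) and recomputes the structure.
The key policy concerns a replacement that destroys a splice donor: by
default the affected intron is **retained** into the mature transcript up to
its intact acceptor (the upstream exon, the intron remainder and the
downstream exon merge). Retention is the default because it is the
mechanism that lets intronic sequence enter the reading frame and create a
frameshift a fixed distance after the lesion — the signature this engine is
designed to reconstruct; `splice_policy = "cryptic-gt"` instead re-splices
at the first GT at or downstream of the lost donor, falling back to
retention with a warning when none exists. Deletions swallowing an entire
intron, or hitting an acceptor whose donor is intact, are refused rather
than guessed at.

Translation runs from the CDS start to the first in-frame stop
(standard code, via Biostrings), reporting the stop codon identity, the
stop residue (protein length + 1) and the ORF length $3(\mathrm{aa} + 1)$.
`diff_proteins()` locates the first altered residue and the contiguous
substituted run and classifies the event as truncating, elongating or
length-preserving; `domain_overlap()` marks each protein domain intact,
disrupted (first difference or premature stop inside the span) or lost
(entirely beyond the mutant protein's end). `alternative_splice_isoforms()`
models a shifted donor/acceptor a few nucleotides from the canonical one: a
3-nt shift inside the CDS changes the protein by exactly one residue, any
non-multiple-of-3 shift is flagged as a frameshift.

The packaged `splice_loss_fixture()` is a fully synthetic six-exon gene
engineered so that a 20-nt → 6-nt replacement spanning exon 2's end and
intron 2's donor yields a 440-residue wild protein, a frameshift at CDS
position 883 (codon 295), a five-residue substituted run, a premature TAA
at residue 300, a 900-nt mutant ORF (299 residues) and a disrupted
MYB-like domain at residues 271–323. Only these engineered positions are
fixed; all filler sequence is seeded-random. It is a structural stand-in
built in code, not any real gene sequence.

## The simulator

`simulate_f2()` generates the mapping population: two fully inbred parents
opposite at every variant, each F2 receiving one recombinant gamete per F1
parent, with crossovers between adjacent markers at the Haldane
recombination fraction $r = (1 - e^{-2d/100})/2$ for map distance $d$ cM
(no interference — the standard neutral choice, and the one with a closed
form the tests can verify against). Physical position maps linearly onto
the genetic map. The phenotype is recessive iff homozygous mutant at the
causal variant, thinned by `penetrance`.

Defaults mirror the modelled study design: 130 mapping F2 on 13
chromosomes, an 822-accession panel, a 50-individual pool drawn from a
separate 1231-individual test F2 (a 130-individual F2 yields only ~32
recessives, so the pool must come from the larger validation population).
Values the design leaves open were fixed once at realistic levels:
27 Mb chromosomes (a 354 Mb genome over 13 chromosomes), 100 cM per
chromosome, 200 variants per chromosome, 2% genotype missingness, 1% panel
missingness, a 0.3 panel background-sharing fraction, and 30× mean pool
depth. Marker density is deliberately far below a real resequencing
experiment — the methods consume genetic structure, not marker count, and
the localisation behaviour above is density-independent.

What the simulator does **not** emulate: read-level data and sequencing
error (pool counts are Poisson/binomial draws from true pooled
frequencies), linkage disequilibrium and population structure within the
germplasm panel (accessions are independent draws), recombination
interference and heterogeneous recombination landscapes, genotyping-error
modes other than missingness, and multi-locus or partially penetrant trait
architectures beyond a single penetrance parameter. Passing tests therefore
demonstrate correctness of the statistical machinery and the screening
logic under idealised inputs, not robustness to every artefact of real
resequencing data.

## Pipeline, determinism and problem sizes

`run_pipeline()` executes the stages in study order — inheritance,
QC (call count ≥ 100, minor-allele frequency ≥ 0.1, both inclusive),
association, interval, dual screen, gene nomination, consequence — and
produces a summary carrying the configuration hash and seed; every stage
derives its random stream from the master seed, so a fixed seed reproduces
every output byte for byte. Stage failures halt the run with the stage
name and cause. The consequence stage runs on the packaged splice-loss
fixture, mirroring a study flow in which gene-structure analysis operates
on cloned sequence rather than on the simulated marker genome.

Test and acceptance workloads use scaled problem sizes chosen as the
package's own balance of precision against runtime: 100 replicate pipelines
for recovery rates, 10,000 multinomial replicates for the segregation
test's type-I error, populations of 2,000–10,000 for distributional checks,
and the default 130/822/50 study geometry everywhere the design itself is
being exercised.

## Known limitations

* The ±200 kb interval around any peak estimator misses the causal variant
  in roughly one default-sized replicate in five (see "The localisation
  limit"); the package reports "no candidate" rather than a wrong candidate
  in almost all such runs.
* Panel screening assumes panel accessions are phenotyped correctly; a
  mislabelled curly-leaf accession would eliminate the true candidate.
* The consequence engine handles one event per gene and refuses
  rearrangements that remove entire introns or orphan an acceptor.
* Association offers no kinship or structure correction; it targets
  biparental crosses, not diversity panels.
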