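---
title: "Methods: genome-to-metabolite inference for the tryptophan indole pathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-to-metabolite inference for the tryptophan indole pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indolepath)
```

## The model

`indolepath` answers one question per strain: *which indole derivatives of
tryptophan can this organism produce, judging from its proteome alone?* The
model has two parts.

First, a fixed metabolic network: a directed acyclic graph rooted at
tryptophan whose ten nodes are the pathway metabolites (IPYA, ILA, IA, IPA,
IAM, TA, IAAld, IAA, IAld) and whose ten edges are reactions, each carrying
an *enzyme requirement* — a disjunction of conjunctions over the 14 enzyme
families of the registry. The IPYA→ILA reaction is satisfied by either of
two dehydrogenases (`fldH | LDH`); the ILA→IA reaction needs the complete
dehydratase cluster (`fldA & fldBC & fldI`). The enzyme that converts IAA
to IAld is not known, so that edge carries an unsatisfiable requirement and
IAld is excluded from the predictable set — the model can represent the
metabolite but will never claim genomic evidence for it.

Second, a completeness rule: a strain is predicted to produce a metabolite
if and only if some directed path from tryptophan to that metabolite has
every edge requirement satisfied by the strain's detected enzyme set. This
is computed as breadth-first reachability over satisfied edges, and it is
provably monotone: adding enzymes can only add predictions. The test suite
checks the reachability implementation against an independent
path-enumeration oracle on all $2^{14}$ subsets of the registry.

The key modelling assumptions, made explicit:

* **Presence suffices.** One passing homolog of each required family makes
  a reaction available; expression, regulation and kinetics are outside the
  model. Predictions are therefore statements about capacity, not yield.
* **Families, not genes.** HdhD (D-2-hydroxyacid dehydrogenase) shares its
  partial EC class with fldH and acts as an indole-3-lactate dehydrogenase;
  by default its homologs count toward the fldH family
  (`hdhd_as_fldh = TRUE`). The dehydratase alpha/beta subunits are treated
  as the single family fldBC.
* **The reference set defines the search.** Any curated set of reference
  proteins per family can be loaded (`load_reference_db()`); the registry
  does not restrict LDH references to the D-type enzymes, which is a
  deliberate openness — curators can narrow the set if they wish.

## Homology detection

Each strain protein is aligned against every reference sequence with an
affine-gap Smith–Waterman aligner (Gotoh three-state recursion, written in
C++). A hit passes iff it clears all four thresholds *inclusively*:
identity ≥ 30 %, E ≤ 10⁻³, query cover ≥ 70 %, subject cover ≥ 70 % — the
same filter a DIAMOND/BLASTP search would apply with the corresponding
flags, which is why `import_external_hits()` can substitute an external
tabular search and re-filter it identically.

Definitions that the thresholds depend on, fixed here because different
tools vary:

* **Identity denominator** is the number of alignment columns *including
  gaps*, matching the common BLAST `pident` convention.
* **Coverage** is the aligned span (end − start + 1) divided by the full
  sequence length, on the query and the subject respectively, with spans
  taken from the local-alignment traceback.
* **Gap model**: a gap of length $k$ costs open + $k$·extend, the BLAST
  convention; with the BLOSUM62 open 11 / extend 1 defaults a one-residue
  gap costs 12. Note that classic textbook worked examples often use a
  linear gap penalty; the same sequence pair can score differently under
  the two conventions (the well-known `HEAGAWGHEE`/`PAWHEAE` BLOSUM50
  instance scores 28 with a linear penalty of 8 but 25 under the affine
  10/1 scheme used here — the package's regression tests pin the affine
  value, computed by an independent brute-force dynamic program).
* **E-values** come from the Karlin–Altschul formula
  $E = K m n e^{-\lambda S}$ with the standard published gapped parameters
  for BLOSUM62 11/1 ($\lambda = 0.267$, $K = 0.041$). These are carried in
  the scoring configuration, not hard-coded.
* **Determinism**: traceback ties prefer diagonal over up over left, and
  the best local cell is the first strict maximum in row-major order, so
  repeated runs are byte-identical.
* **Best hit** per (strain, family) is selected by bitscore, ties broken
  by higher identity, then lexicographic subject and query ids. The
  best-hit *criterion* is not dictated by the biology; bitscore-first is
  the convention of every major search tool and is recorded here as the
  package's choice.

Composition-based score adjustment and the seed heuristics of production
search tools are deliberately not reproduced: proteome-scale inputs here
are desk-sized, and full dynamic programming is exact. The cost is
quadratic per pair; a 148-strain cohort with ~25 proteins per strain
against 16 references annotates in a few minutes on one CPU.

## From predictions to species tables and concordance

Species-level summaries report, per species and metabolite, the percentage
of strains predicted as producers, rounded **half away from zero** to one
decimal (base R's `round()` is round-half-even, which would turn 12.25
into 12.2 where 12.3 is wanted); integers print without the decimal
(`"100"`, `"6.7"` style). Species with zero strains are rejected rather
than reported as 0.

Concordance against measured concentrations uses a detection threshold of
0 ng/mL by default — any positive quantified concentration counts as
production, since reported concentration ranges start at 0 and no limit of
quantification is stated; the threshold is configurable. Because IPYA is
the only upstream precursor of ILA but too transient to quantify, observed
ILA sets the IPYA phenotype (measured-by-inference); a flag
(`include_ipya_in_accuracy`) controls whether this inferred phenotype
enters the accuracy denominators, since a headline accuracy could
reasonably be quoted either way. Unmeasured metabolites (IAAld in the
default measured set, IAld always) are excluded from denominators, never
imputed. Two overall accuracies are reported — the unweighted mean of
per-metabolite accuracies and the pooled accuracy over all evaluated
cells — because "average accuracy" is ambiguous between them; the
per-metabolite mean is the headline figure.

## Association statistics

Spearman's ρ is the Pearson correlation of mid-ranks. For n ≤ 9 the
two-sided p-value is an exact permutation probability over all $n!$
permutations (valid under ties); otherwise the usual t-approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ is used. Benjamini–Hochberg q-values are
computed over the full family of enzyme × metabolite pairs in one run;
pairs with a constant vector (a family absent from every strain, say) have
no defined rank correlation and are excluded from the family rather than
given a pseudo-value. An association is *reported* when |ρ| > 0.3 strictly
and q < α (default α = 0.05, configurable — no α is dictated by the
application). The absolute value matters: negative associations (an
amidase count anticorrelated with an aldehyde concentration, for example)
are as reportable as positive ones. Under a null simulation at n = 148 the
reported-association rate stays below α; the screen on |ρ| makes it nearly
zero, which the acceptance suite verifies.

Mann–Whitney U (two-sided) compares within-species metabolite levels
between isolation sources: U is the smaller rank-sum statistic, the
p-value exact by enumeration when $n_a + n_b \le 12$ without ties, and a
tie- and continuity-corrected normal approximation otherwise (the behavior
of `wilcox.test`, which backs the computation; the exact regime is checked
against full enumeration in the tests).

## Homolog clustering

The full phylogenomic treatment of enzyme homologs (multiple alignment,
model-selected maximum likelihood, bootstrap) is out of scope. What the
downstream conclusion actually consumes is *cluster membership*: do the
homologs of one species form their own groups, far from everyone else's?
The package therefore computes pairwise global-alignment distances
(1 − identity/100), builds a neighbor-joining tree (classical Saitou–Nei
with the Q criterion; ties broken by the lowest index pair; negative
branch lengths clamped to zero with the deficit moved to the sibling so
path lengths are preserved), and enumerates *species-exclusive clades*:
maximal leaf sets induced by an internal edge, of size ≥ 2, whose members
all carry one species label. "Independently clustered" is a visual
judgment on a published tree; monophyly of same-species leaves is the
operationalization chosen here. Branch supports are not computed — the
report says "no support" rather than pretending. An externally built
newick tree can be supplied to the clade detector via the command-line
wrapper. NJ correctness is tested by exact recovery (zero Robinson–Foulds
distance, path-length error < 10⁻⁹) of random additive 5–8 leaf trees.

## The synthetic data generator

No sequence accessions or raw measurement tables are distributed with the
study this package operationalizes, so the package ships a generator that
reproduces the *statistical structure* the analysis assumes, and the
reference database itself is a synthetic stand-in
(`synthetic_reference_db()`: deterministic random proteins per family,
two for ArAT and LDH to mimic multi-entry families).

* **Proteomes**: each strain receives full-length homologs of its
  configured enzyme families, mutated to a target global identity
  (default 60 %, tolerance ± 2 points, with a 2 % indel rate), hidden
  among random decoys (default 20 per strain, 250–400 residues, drawn
  from Robinson–Robinson background frequencies). The 60 % default sits
  comfortably above the 30 % detection threshold while far from exact
  copies — the regime where real cross-species homologs live; 40 %
  targets are exercised in tests as the harder case.
* **The default cohort** (`default_cohort_spec()`) mirrors the published
  panel: 148 strains over 13 species with the published strain counts,
  every species except *L. curvatus* carrying ArAT + an ILA dehydrogenase
  + amiE + ALD, species-specific TMO and IPD complements, no TDC and no
  dehydratase cluster anywhere.
* **Concentrations**: genotype-positive cells draw lognormal values
  parameterized by arithmetic mean and CV (defaults 100 ng/mL, CV 0.5;
  the *L. salivarius* ILA mean is set to 1907 ng/mL in the default spec,
  an order of magnitude above the rest, as observed). The lognormal is
  chosen because concentrations are strictly positive and right-skewed;
  zeros arise only through false-negative dropouts (probability
  configurable, default 0) or the detection floor. Genotype-discordant
  phenotypes — tryptamine in one species, indoleacrylate in another —
  are *injected* deliberately to emulate the cases where fermentation
  finds what the genome cannot explain.

What the generator does **not** emulate: real homologs share domain
architecture and conserved motifs, not uniformly random divergence;
real decoy proteomes contain paralogs and low-complexity regions that
stress a search far harder than i.i.d. decoys; real concentration tables
have batch effects and correlated metabolites. Passing the recovery tests
therefore shows the pipeline is *correct under its own assumptions* —
thresholds applied as specified, predictions consistent with the network,
accuracies counted right — not that the thresholds themselves are optimal
for any particular genus.

Everything is seeded: per-strain and per-cell child seeds are derived
arithmetically (no iteration-order dependence), the session RNG state is
saved and restored, and identical seeds give byte-identical outputs across
runs, which the test suite asserts.

## Numerical and scale choices

Test problem sizes were chosen to finish in minutes while still probing
the claims at cohort scale: exhaustive aligner-versus-oracle comparison on
sequences up to length 8 over a reduced alphabet (where the brute-force
oracle is affordable), the full $2^{14}$ enzyme-subset sweep for the
prediction rule, one complete 148-strain cohort for end-to-end recovery,
1000 replicates for the null calibration of the association screen, and
15 random trees for NJ recovery. The acceptance script regenerates its
five species-table percentages in about a minute.

Degenerate inputs are rejected early with named errors: empty sequences or
FASTA records, residues outside the 20-letter + X alphabet, self-loop or
cyclic network edges, enzymes missing from the registry, constant vectors
in correlation, non-symmetric distance matrices, strains missing from the
species map, negative concentrations.

## Known limitations

* Predictions are capacity claims; a strain with the genes may still not
  ferment the metabolite (the IAM case: genomically widespread, never
  observed in broth), and a strain without known genes may produce it
  (tryptamine, indoleacrylate) — which is exactly what the concordance
  module is for.
* The built-in aligner is exact but quadratic; for genuinely large
  proteome collections, run DIAMOND externally and import the tabular
  output.
* The NJ stand-in resolves cluster membership, not branch support;
  conclusions that need support values require an external ML tree,
  which the clade detector accepts.
* The synthetic reference database carries no biochemical information;
  swap in curated references via `load_reference_db()` for real use.
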