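---
title: "Methods: diagnostic SNP panels and their validation in oryzaQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnostic SNP panels and their validation in oryzaQC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`oryzaQC` selects and validates small panels of taxon-diagnostic biallelic
SNPs for quality-control genotyping of an *Oryza* genebank collection
spanning four species and two *O. sativa* subspecies. This vignette
documents the statistical model behind each stage, the tunable parameters
and their defaults, the synthetic world used for testing, and the design
decisions taken where the problem left the design open.

## Genotypes and marker statistics

Genotypes are stored as allele dosages: the count (0/1/2) of a locus's
second listed allele, with `NA` for missing calls. All statistics are
symmetric under relabelling (`d -> 2 - d`), so the orientation is pure
bookkeeping. From the non-missing calls at a locus with alternate-allele
frequency $p$:

* gene diversity (expected heterozygosity) $H_e = 1 - p^2 - (1-p)^2$;
* polymorphism information content
  $\mathrm{PIC} = H_e - 2 p^2 (1-p)^2$ (the Botstein measure; for a
  biallelic locus its maximum is 0.375 at $p = 0.5$);
* observed heterozygosity = fraction of dosage-1 calls among non-missing;
* missing rate = fraction of `NA` calls over all samples.

The quality filter keeps a locus iff MAF $\ge 0.05$, PIC $\ge 0.18$,
heterozygosity $\le 0.09$ and missingness $\le 0.24$. The removal rules
are quoted as strict inequalities, so boundary values are kept; rejected
loci are annotated with the *first* failing rule in the fixed order MAF,
PIC, heterozygosity, missingness (membership itself is conjunctive and
order-free). A locus with no calls at all fails the MAF rule, since its
allele frequencies are undefined.

## Diagnostic scoring

A *group contrast* opposes a target taxon set to a complement ("complex")
set; its universe is their union and may be a proper subset of all taxa
(the wild-vs-cultivated African contrast G1 involves only those two taxa;
the package ships six default contrasts G1–G6). For a locus, the
*diagnostic allele* is the collection-wide minor allele when that allele
is the majority state within the target group, otherwise the allele most
enriched in the target relative to the complex, with ties broken toward
the minor allele. These species are predominantly inbred, so the expected
state is the homozygous diagnostic allele in target taxa and the opposite
homozygote in complex taxa.

Per-taxon *concordance* is the fraction of that taxon's accessions (among
non-missing calls) carrying the expected state. Two conservative choices:
heterozygous calls always count as mismatches (observed heterozygosity in
these taxa is 0–1%, so a heterozygote is more likely a scoring artefact or
an off-type than a true intermediate state), and missing calls are removed
from the denominator rather than counted as failures (the study kept a
highly diagnostic marker with 21% missing data, so missingness evidently
did not disqualify). A marker passes a contrast when **every** universe
taxon's concordance strictly exceeds the threshold (default 0.97 — chosen
because KASP plate mismatches among positive controls can reach ~3%).

### Jointly-diagnostic pairs

When no singleton passes a contrast (the G1 situation), pairs of
candidate loci are scored on their two-locus expected haplotype. An
accession agrees with a pair when its matches are at least as many as its
mismatches over the pair's non-missing loci; accessions missing both loci
are excluded. The "ties count as agreement" rule is deliberate: it makes
one clean call outvote one missing or discordant call, which is exactly
how a two-marker assay rescues a high-missing partner, and it reproduces
the behaviour that two markers individually below threshold can jointly
assign a group. Pairs that still fail the threshold are reported *flagged*
rather than suppressed (the study retained its best pair at 92% wild-side
concordance). The search space is restricted to loci whose minimum
singleton concordance reaches a floor (default 0.85) to keep the
quadratic search small and to avoid pairing junk.

### Panel assembly, classification, minimal panels

The panel takes every contrast's passing singletons plus the best flagged
pair for contrasts with none. Expected homozygous states per taxon come
from the contrast definition inside a contrast's universe; taxa outside a
restricted contrast's universe get their empirical modal homozygote
(design decision: the data say what, e.g., *O. sativa* carries at a
wild-vs-cultivated African marker; no assumption is needed).

An accession is classified to the taxon minimizing haplotype mismatches
over its non-missing panel loci. Ties are broken alphabetically but
reported (`tie`), and an accession whose runner-up taxon is within one
mismatch is flagged `intermediate`; both flags mean "re-genotype or
inspect", which is the correct genebank action. With no non-missing panel
loci the accession is `unclassifiable`.

Minimal panels use greedy set cover over taxon pairs: repeatedly keep the
marker separating the most not-yet-covered pairs (ties broken by higher
mean concordance, then lexicographic id) until every pair is covered by
`redundancy` markers (default 2) where available. Optimal set cover is
NP-hard; the tests verify greedy against exhaustive search on small
instances, and the reduced panel is always checked to classify every
accession identically to the full panel. A flagged joint pair travels as a
unit — its two loci are only meaningful together.

## Validation battery

**Distances.** The AMOVA distance is squared Euclidean on dosages over
pairwise-complete loci, rescaled by $L / L_{obs}(i,j)$ so all entries sit
on the scale of $L$ loci; these inbred taxa are treated as haploid-like
dosage vectors, which is what a PhiPT-style analysis (suppressing
within-individual variance) amounts to. A binary presence coding is
available as an alternative policy. Trees use $1 - \mathrm{IBS}$ (mean
shared-allele fraction), which is bounded and robust to missingness; the
square root of the squared-Euclidean matrix is available.

**AMOVA / PhiPT.** One level, $k$ groups, $N$ samples:
$SS_{tot} = \frac{1}{N}\sum_{i<j} d^2_{ij}$,
$SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d^2_{ij}$,
$SS_{among}$ by subtraction; $df = (k-1, N-k)$;
$n_0 = (N - \sum_g n_g^2/N)/(k-1)$; $\sigma^2_W = MS_{within}$,
$\sigma^2_A = \max(0, (MS_{among} - MS_{within})/n_0)$ (clamping keeps
$\Phi_{PT} = \sigma^2_A / (\sigma^2_A + \sigma^2_W)$ in $[0,1]$). The
permutation p-value shuffles group labels and uses the
$(1 + \#\{\Phi^{perm} \ge \Phi^{obs}\})/(n_{perm}+1)$ estimator, which can
never return 0 with finite permutations; 999 permutations by default.
Pairwise $\Phi_{PT}$ applies the same machinery to every pair of groups.

**PCA.** Eigendecomposition of mean-imputed, centered dosages (no
scaling). Mean imputation is deterministic and standard for genotype PCA;
a constant matrix yields zero eigenvalues rather than an error.

**NJ.** Standard Saitou–Nei agglomeration with the Studier–Keppler
update, written here rather than delegated so that the distance policies
and branch-length clamping are explicit; the test suite proves topological
identity with `ape::nj` on random matrices and exact recovery of additive
metrics. A negative branch-length estimate at a join is clamped to zero
with the length moved to its sibling, preserving path lengths. Bootstrap
support resamples loci with replacement (default 200 replicates) and
scores each internal edge of the reference tree by the percentage of
replicates containing the same leaf bipartition; supports are written as
internal node labels in newick.

**DAPC-style K selection.** PCA, then k-means (multi-start, seeded) on the
retained PCs for $K = 1..K_{max}$ (default 20);
$\mathrm{BIC}(K) = n \ln(WSS_K/n) + K \ln n$, the convention used by the
common find-clusters implementations — an approximation, since the cited
tools do not print their internal formula. Mean silhouette width on the PC
coordinates is computed for $K \ge 2$ as a cross-check; when the two
criteria disagree the BIC choice wins and the disagreement is reported
(on strongly hierarchical collections silhouette often prefers the
coarsest split, e.g. African vs Asian, while BIC resolves all five
groups). PCs retained: the smallest number explaining $\ge 90\%$ of
variance, capped at $n - K_{max} - 1$; the cited study does not state its
retention, so it is explicit and configurable here. Discriminant axes come
from the eigen-decomposition of $W^{-1}B$ on the chosen clustering, and
membership probabilities are a softmax of negative squared discriminant
distances scaled by the mean within-cluster spread.

## The synthetic world

`simulate_collection()` emulates the validation study's structure: five
taxa of 88/169/69/178/121 accessions; 65 diagnostic loci planted across
the six contrasts as 4/28/16/9/7/1 plus 93 background loci (158 total);
per-locus missingness uniform on 0–11% with one designated high-missing
G1 locus at 21%; heterozygotes injected independently per call at 0.5%;
background allele frequencies uniform on 0.05–0.5 and *shared across
taxa* (no drift model — the object under test is the diagnostic
structure, not neutral divergence); allele orientation randomized per
locus so minor-allele logic is exercised; everything seeded.

Noise at planted loci is i.i.d. per call: an accession carries its
group's expected homozygote with probability `fixation` (default 0.99),
else the opposite homozygote. The G1 contrast is special: seven planted
"hybrid" accessions, labelled wild *O. barthii* but carrying the
cultivated haplotype at all G1 loci, are the *sole* source of G1
discordance (realized wild-side fixation $(88-7)/88 \approx 0.92$,
matching the configured 0.93 level); with `n_hybrids = 0` G1 reverts to
i.i.d. flips. This follows the study's account, where 100% of
*O. glaberrima* and 92% of *O. barthii* showed the contrasting
haplotypes and the missing 8% were exactly the seven suspected
intermediates.

What the generator does **not** emulate: linkage/LD, within-taxon neutral
diversity at diagnostic loci, genotyping-intensity (cluster-plot)
artefacts, or error processes correlated across loci other than the
hybrids. Consequently a green test establishes that the *machinery*
recovers planted structure under the stated noise — not that real KASP
data will behave identically.

### What the stated noise level implies

Two stochastic facts about this world are worth stating plainly, because
they bound what the test suite can honestly assert:

* With 1% flips plus 0.5% heterozygotes, per-taxon discordance averages
  ~1.5% against the strict 3% margin of the 97% rule. For the smallest
  group (69 accessions, minus missing calls) a *single* extra mismatch
  can cross the margin, so each planted locus passes all five taxa with
  probability well below 1, and full recall of all planted loci is
  essentially impossible — mirroring the study itself, which retained
  only 36 of its 65 diagnostic SNPs at this rule. The suite therefore
  asserts *precision* (background loci never pass; every selected marker
  sits in its planted contrast) as a hard property, and full recall only
  in the noiseless limit.
* Strict monophyly of all five taxa in a 625-tip NJ tree fails for the
  same reason: a few accessions with one or two erroneous calls at
  contrast loci attach to the backbone between clusters. Cluster
  *recovery* (DAPC K = 5, classification agreement) is robust; strict
  monophyly is asserted only on low-noise or constructed fixtures.

## Numerical and interface choices

* Missing sentinel is `NA` throughout; the writers emit the token `NA`.
* Dosage and hapmap-like dialects round-trip exactly; the calls dialect
  infers allele pairs alphabetically from the data, so a column where
  only one allele was observed reads back as the reference homozygote
  (orientation is unknowable without metadata; all statistics are
  orientation-invariant).
* Scaled test configurations (`scale_config`) round group sizes and locus
  counts but never let a contrast that had a marker pair drop below two
  loci, so pair search and taxon-pair separation stay exercisable.
* k-means failures at infeasible K (fewer distinct points than centers)
  yield `NA` BIC entries rather than errors; a zero within-cluster sum of
  squares maps to $-\infty$ BIC, so a perfect clustering at the smallest
  such K wins.
* Permutation, bootstrap, sampling and k-means seeds are explicit
  arguments everywhere; the pipeline derives per-stage seeds from one
  master seed and records them in its manifest.

## Known limitations

* One AMOVA level only (no region/population/individual nesting).
* No probabilistic admixture model: hybrids are detected by haplotype
  mismatch and flagged, not quantified.
* The NJ tree is exactly neighbor joining — no likelihood refinement.
* The BIC constant and the cited tools' internal distance conventions are
  approximations by necessity; both the distance policy and the cluster
  criteria are configurable and reported side by side.
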