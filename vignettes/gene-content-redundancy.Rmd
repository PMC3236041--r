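---
title: "Quantifying gene-content redundancy with entropy and the broken stick"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene-content redundancy with entropy and the broken stick}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogent)
```

## The problem

When the protein-coding genes of a genome are assigned to functional
categories (COGs, Pfam families, KO groups, ...), the *shape* of the
resulting category-size distribution is informative on its own. A genome in
which most categories hold a single gene is functionally "even"; a genome in
which a few categories — transposases, integrases, resolvases — hold
hundreds of near-identical copies is redundant, which is typical of genomes
heavily colonised by mobile elements. `cogent` quantifies this with Shannon
entropy against two reference points, calls out the categories driving the
unevenness, and ships the desk-scale companions of that analysis: homolog
Venn partitioning of proteomes, HSP-based genome-to-genome similarity
ratios, genome summary statistics, and synthetic-data generators that make
the whole pipeline testable against known ground truth.

## The model

Let a genome have $N$ genes assigned to $S$ distinct categories with counts
$c_1, \dots, c_S$ and relative frequencies $p_i = c_i / N$.

**Observed entropy.** $H = -\sum_i p_i \ln p_i$ (natural log throughout; all
entropies are in nats).

**Maximum entropy.** $H_{\max} = \ln N$, the entropy of the maximally even
arrangement in which every category holds exactly one gene. Note the
denominator counts *items* (genes), not categories: with one gene per
category, $S = N$ and $H = \ln N$. Evenness is $H / H_{\max}$ and the first
redundancy index is

$$R_{\max} = 1 - H / H_{\max} \in [0, 1).$$

**Chance-expected entropy.** Perfect evenness is not a realistic null: even
random assignment of genes to categories produces unequal sizes. The
broken-stick distribution — break a unit interval at $S - 1$ uniform random
points and sort the pieces — gives the expected rank-ordered proportions

$$p_i^{bs} = \frac{1}{S} \sum_{k=i}^{S} \frac{1}{k},$$

and its entropy $H_{exp}$ (computed here from the exact summed proportions,
not the large-$S$ asymptotic $\ln S - (1 - \gamma)$) is the entropy expected
by chance for $S$ categories. The second redundancy index,

$$R_{exp} = 1 - H / H_{exp},$$

is negative when the genome is *more* even than a random broken stick. For
a worked case with $N = 2022$ genes in $S = 1300$ categories and observed
$H = 6.912$:

```{r indices}
r <- redundancy_indices(H = 6.912, N = 2022, S = 1300)
round(100 * c(r_max = r$redundancy_max, r_exp = r$redundancy_exp), 2)
```

**Over-representation.** Sorting observed frequencies in decreasing order
and overlaying the broken-stick curve, the category at rank $i$ is called
over-represented when its observed frequency strictly exceeds $p_i^{bs}$.
The comparison is rank-positional: tied categories keep their stable rank
(ties broken by category id, so results are deterministic) and each is
compared against the expectation of its own rank. Equality is not flagged —
a conservative reading of "larger than". Rationale for the strictness: with
counts of one gene per category the tail ranks sit exactly on the
$1/S$-vs-$p_S$ boundary, and flagging them would brand a perfectly even
genome as enriched.

```{r overrep}
prof <- abundance_profile(c(X = 10, Y = 3, Z = 2, W = 1))
over_represented(prof)
```

## Counting policy for multi-category genes

Export tables list one row per gene-category hit, so a gene annotated into
two COGs appears twice. `build_profile()` makes the policy explicit:
`per_pair` (default) counts each distinct gene-category pair as one item, so
$N$ counts memberships; `first_only` keeps a gene's first listed category,
so $N$ counts genes. Published gene totals rarely state which convention
produced them, hence both are first-class and tested. Genes with no
category assignment never enter the table and are excluded from all entropy
computations.

## Homolog sharing and the three-way Venn

`homologs()` performs all-vs-all Smith–Waterman local alignment
(BLOSUM62, affine gaps 11/1, via `Biostrings::pairwiseAlignment`) and
applies two conjunctive filters: E-value at most $10^{-5}$ and percent
identity at least 30, the standard thresholds for phylogenetic-profiler
style comparisons. E-values use the Karlin–Altschul formula
$E = K m n e^{-\lambda s}$ with the published gapped BLOSUM62 constants
($\lambda = 0.267$, $K = 0.041$) so the package needs no external search
engine; the constants are configurable through `homology_params()`. Identity
is computed over alignment columns including gaps (the BLAST convention).
`venn3()` classifies every gene of each proteome by which of the other two
proteomes contain a homolog of it. Counting is deliberately gene-level and
per-genome — homology is not transitive, so a symmetric family-level diagram
would need a clustering step that is out of scope here; the per-genome
region counts always sum to the proteome size, which the tests enforce.

This is a desk-scale implementation: all-vs-all dynamic programming is
quadratic in proteome size and is meant for the synthetic fixtures and
small gene sets, not for 13,000-protein genomes.

## Genome-to-genome distances

`find_hsps()` is an ungapped seed-and-extend finder: exact `word_size`-mer
seeds (default 11) are extended on their diagonal with +1/−1 scoring until
the running score drops `xdrop` (default 20) below its maximum, then trimmed
back to the maximal-scoring extent. Because ungapped extension decomposes
into independent prefix and suffix sums, the trimmed segment is exactly the
maximum-score segment containing the seed, which is what the brute-force
enumeration oracle in the test suite verifies. Seeds inside an HSP already
found on their diagonal are skipped; contained duplicates are collapsed;
HSPs shorter than `min_length` (default 50 bp) are dropped. The finder is
forward-strand by default, with `both_strands = TRUE` unioning hits against
the reverse complement of the second genome.

`ggdc_formulas()` then reports the three classical genome-pair ratios:
coverage $f_1 = $ HSP length / total length, within-HSP identity
$f_2 = $ identities / HSP length, and whole-genome identity
$f_3 = $ identities / total length, with total length the arithmetic mean of
the two genome lengths. Overlapping HSPs are merged before summing: HSPs
are visited in order of decreasing identities, each contributes only its
novel covered bases (averaged over the two genomes), and its identity count
is prorated by the trimmed fraction. This prevents double counting and
makes $f_3 = f_1 f_2$ an exact algebraic identity, asserted to $10^{-9}$ in
the tests. An empty HSP set reports $f_1 = f_2 = f_3 = 0$ with an explicit
`no_hsps` flag rather than a 0/0. Multi-contig inputs are concatenated with
100-base `N` spacers; `N` never matches, so no HSP crosses a contig
boundary, and the ratio denominators use the true summed contig lengths.

Real whole-genome comparisons additionally involve gapped alignment and a
particular search parameterisation; reproducing published multi-Mb values
is therefore out of scope, and the finder is validated against planted
ground truth instead.

## What the simulators emulate

* `simulate_cog_table()` draws category counts under five models
  (uniform, broken-stick, geometric, Dirichlet, transposon burst) and
  expands them into an assignment table. The burst model plants `n_burst`
  mobile-element-like families absorbing a fixed mass fraction (default
  0.3) on top of a Dirichlet baseline — the situation of a
  transposase-riddled genome whose largest COG holds hundreds of genes.
  Default sizes in the tests mirror a real comparison of three genomes
  with roughly 2,000–6,700 categorised genes over 1,300–1,731 categories.
* `simulate_proteomes()` plants core, pairwise and unique gene families
  across up to three proteomes. `within_family_identity` is the target
  *pairwise* identity: members are mutated from a common ancestor at rate
  $1 - \sqrt{q}$, so two members match at a site with probability $q$ plus
  a small coincidental-match term ($\approx r^2/19$, under 0.005 for
  $q \ge 0.5$). The substitution primitive itself always replaces a residue
  with a *different* one, so a single mutated copy has identity exactly
  $1 - \text{rate}$ to its template in expectation.
* `simulate_genome_pair()` builds two independent random backgrounds at a
  configurable G+C content and copies planted segments from genome A into
  genome B with substitutions at rate $1 - q$ (copy-vs-source identity is
  exactly $q$ in expectation). Placement distributes the free space as
  random gaps, so segments never overlap; truth manifests record 0-based
  half-open intervals on both genomes. Forward strand only: the ratio
  formulas are strand-agnostic, so strand simulation adds nothing the
  statistics would see.

What the simulators do **not** emulate: indels and codon structure (point
substitutions only), repeat-induced self-similarity within one genome,
length variation within gene families, and annotation noise in the
assignment tables. Passing tests therefore demonstrate correctness of the
statistics and the recovery machinery on clean planted signal, not
robustness to real annotation pipelines.

## Numerical and design choices

* Natural logarithms everywhere; published redundancy percentages only
  reproduce with $H_{\max} = \ln N$ (items, not categories), so that
  definition is used even though $\ln S$ is the more common evenness
  denominator.
* $H_{exp}$ uses the exact broken-stick proportions. At the published
  3-decimal precision the exact and asymptotic values agree; exactness is
  preferred because it costs one `cumsum`.
* Ranking ties: stable sort by count descending then category id
  ascending. Deterministic output matters more than any particular tie
  order.
* Degenerate inputs: a single category gives $H = 0$ and redundancy 1; a
  profile with one gene per category gives redundancy exactly 0; empty
  count vectors, zero counts, non-positive genome lengths and word sizes
  below 8 (seed explosion) are rejected with informative errors.
* Reported percentages are rounded to two decimals in printed output only;
  all stored values keep full precision.
* Problem sizes in the test suite (10 kb genome pairs, proteomes of tens
  of sequences, 100–200 simulation replicates) are chosen so the full
  suite exercises every stage in a couple of minutes on one core while
  keeping every stochastic check far from its decision boundary.
* Default seed is 42 for every generator config; all randomness flows
  through R's RNG, so a seed fixes every output byte.

## Known limitations

* The all-vs-all aligner and the HSP finder are quadratic; they are
  correctness references for desk-scale data, not production search tools.
* E-values rely on fixed Karlin–Altschul constants rather than per-query
  estimation; they are accurate enough for thresholding at $10^{-5}$ on
  desk-scale databases but are not BLAST-identical.
* Venn counting is directional and gene-level; a symmetric family-level
  mode (requiring orthology clustering) is deliberately absent.
* The deviation of $H_{exp}(S)$ from the asymptote $\ln S - (1-\gamma)$
  is about $0.012$ nats at $S = 100$ and falls below $0.01$ only from
  $S \approx 120$; code comparing the exact and asymptotic forms near
  $S = 100$ should use the exact one.
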