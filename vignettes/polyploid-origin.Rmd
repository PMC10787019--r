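---
title: "Diagnosing polyploid origin from K-mer profiles and smudge analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing polyploid origin from K-mer profiles and smudge analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrasig)
```

## The problem

A tetraploid genome can arise by doubling within one species
(auto-tetraploidy: four haplotypes per homologous group, all recently
diverged from one ancestor) or by hybridization of two diverged species
(allo-tetraploidy: two subgenomes, each contributing two haplotypes).
Given a fully haplotype-resolved assembly, the two scenarios leave
opposite signatures in repeat space: chromosome- and group-specific
repeat families are shared by all four haplotypes of a group in an
autopolyploid, but partitioned by subgenome in an allopolyploid.
`tetrasig` implements three complementary diagnostics:

1. **Chromosome-enriched K-mer clustering** — canonical 13-mers that are
   globally abundant and concentrated on few chromosomes are selected;
   chromosomes are clustered by their abundance profiles over these
   markers. Auto-polyploidy predicts that each homologous group forms one
   clade (monophyly of all four haplotypes); allo-polyploidy predicts
   clustering by subgenome.
2. **Smudge analysis of heterozygous K-mer pairs** — pairs of read
   K-mers differing at exactly one (the middle) position represent the
   two alleles of a heterozygous site. Plotting total pair coverage
   $T = \mathrm{cov}_A + \mathrm{cov}_B$ against the minor fraction
   $f = \mathrm{cov}_B / T$ concentrates pairs at $(n c,\; b/n)$, where
   $c$ is the 1x (haploid) coverage, $n$ the total copy number and $b$
   the minor-allele copy number. A highly heterozygous auto-tetraploid is
   dominated by the AAAB smudge $(4c, 1/4)$; a diploid by AB $(2c, 1/2)$;
   an allo-tetraploid with diverged subgenomes by AABB $(4c, 1/2)$.
3. Supporting stages used by the same study design: a six-rule **SNP
   hard-filter cascade** with per-rule accounting, and a **tandem
   gene-cluster caller** (≥ 3 consecutive family genes, inter-gene
   distance ≤ 0.8 Mb).

Everything is exercisable on synthetic genomes, reads and call sets
generated in-package, so the full analysis is testable offline.

## Chromosome-enriched K-mers

K-mers are counted canonically (lexicographic minimum of a window and its
reverse complement; odd $k$ avoids self-complementary palindromes;
windows containing `N` are skipped). A K-mer is *chromosome-enriched*
when

1. its genome-wide count is at least `min_global`, and
2. its abundance on its best chromosome is at least `fold` (default 2)
   times a baseline over the remaining chromosomes.

Two baselines are provided because the defining literature is ambiguous:

* `max_other` — the maximum over all other chromosomes. This is the
  strictest reading: the K-mer must be effectively private to a single
  chromosome. It is the `select_enriched()` default.
* `mean_other` — the mean over all other chromosomes. This admits repeat
  families shared by a *few* chromosomes far above the genomic
  background.

For the polyploid-origin question the distinction is not cosmetic: in an
auto-tetraploid the informative repeat families are shared by all four
haplotypes of a group, so under `max_other` their fold is ≈ 1 and the
marker set is empty. The end-to-end pipeline
(`run_tetrasig_pipeline()`) therefore uses `mean_other`, and the package
treats `max_other` as the conservative single-chromosome screen. Both
modes are verified against an exhaustive brute-force scan in the test
suite.

`min_global = 1000` is calibrated to a multi-gigabase assembly; it
scales roughly with the copy number of the discriminating repeat
families. For the 600-kb simulated genomes (150 repeat copies per
chromosome, four haplotypes) the acceptance runs use `min_global = 100`.

Abundances are length-normalized by default (`count / (L - k + 1)`),
with `normalize = "raw"` reproducing the similar-length-chromosome
reading of the original method.

## Clustering and the verdict

Chromosome profiles over the enriched K-mers are compared by Bray-Curtis
dissimilarity (standard for non-negative abundance profiles; Jaccard on
presence/absence and $1 - \rho_{Spearman}$ are available — note the
latter ranges over $[0, 2]$) and clustered by UPGMA (average linkage).
Leaves are sorted lexicographically before clustering so distance ties
break deterministically.

A homologous group is *monophyletic* when some clade's leaf set equals
exactly that group's chromosomes. The score $S$ is the fraction of
monophyletic groups, and the verdict is

* `auto` when $S \ge$ `auto_threshold` (default 1.0 — every group must
  co-cluster, the strict reading of the observed signature; a documented
  relaxation to 0.75 is available for noisy genomes);
* otherwise `allo` when cutting the tree into two clusters splits at
  least `auto_threshold` of the groups into two equal halves (the
  candidate subgenomes);
* otherwise `ambiguous`.

Significance of $S$ is assessed by permuting group labels over leaves
(group sizes preserved, seeded). With two groups of four among eight
leaves there are only $\binom{8}{4}/2 = 35$ distinct splits, so the
smallest achievable p-value is $1/35$; the test suite checks the
Monte-Carlo estimate against exhaustive enumeration.

## Smudge analysis

Read K-mers (default $k = 21$, the method's convention) with counts in
$[L, U]$ (defaults 10 and 1000: above the sequencing-error band, below
the repeat band) are grouped by their middle-masked,
orientation-canonicalized sequence; families of exactly two members
become heterozygous pairs. The dominant member is the higher-count
K-mer; ties take the lexicographically smaller K-mer as dominant with
$f = 0.5$.

**Coverage estimation.** The 1x coverage $\hat{c}$ maximizes the
fraction of pairs lying within relative tolerance `tol` (default 0.2) of
some pattern point $(n \hat{c}, b/n)$, $n \le 8$, with each captured
pair weighted by $1/n$ of its best pattern. The parsimony weight is a
deliberate design choice: the unweighted fraction is degenerate, because
any $\hat{c}/m$ explains the same pairs at $m$-fold inflated copy
number, and "smaller candidate wins ties" would then collapse to the
grid minimum. Under the weighted objective, pure diploid data at
$(2c_0, 1/2)$ yields $\hat{c} = c_0$ (pattern AB), not $c_0/2$ (AABB).
Remaining exact ties still go to the smaller candidate. Note that with
150-bp reads the K-mer coverage is $(150 - k + 1)/150 \approx 0.87$ of
the per-haplotype base coverage; $\hat{c}$ estimates the former.

**Assignment.** Each pair goes to the pattern minimizing
$\max\!\big(|T - n\hat{c}|/(n\hat{c}),\; |f - b/n|/(b/n)\big)$, and is
left unassigned when that minimum exceeds `tol`. Proportions are
reported over *all* tested pairs, so they sum to at most 1.

**Known limitation.** At ~25x per-haplotype coverage the AAAB smudge is
broad relative to the `tol = 0.2` window on $f$ (which admits only
$f \in [0.2, 0.3]$): Poisson noise alone leaves ~30% of true AAAB pairs
unassigned or mis-binned, and each heterozygous site yields an exact
$(3c, c)$ pair only when all three non-focal haplotypes are clean across
the 21-base window ($\approx (1 - d)^{63}$). Consequently the simulated
auto-tetraploid's AAAB share of *tested* pairs plateaus near 0.4 even
with error-free reads; the dominant pattern is nevertheless recovered
robustly, and a diploid simulation yields a clear AB majority. The
corresponding acceptance expectation (> 0.5) is left failing rather than
loosened; higher coverage or a coarser tolerance would clear it, but
both are fixed parts of the stated test world.

## The synthetic world

`simulate_polyploid_genome()` emulates exactly the structure the
diagnostics assume, with substitutions only (no indels — K-mer
expectations stay analytic):

* **auto / diploid**: per group, one random ancestor (50 kb default)
  receives a group-private 200-bp repeat motif at 150 random
  non-overlapping offsets; 4 (or 2) haplotypes are drawn by mutating the
  ancestor at `d_hap` (default 0.005, i.e. ~1% haplotype-haplotype
  divergence — a placeholder for the unpublished real value, exposed as
  configuration).
* **allo**: per group, two subgenome ancestors diverged at `d_sub`
  (default 0.05) each carry a subgenome-private repeat family shared
  across *all* chromosomes of that subgenome; two haplotypes per
  subgenome at `d_hap`.

Mutation applies uniformly, including repeat copies (realistic decay of
repeat identity); repeat placement is uniform random rather than tandem
(enrichment depends on density, not arrangement). Reads have uniform
start positions, equal strand probability, i.i.d. substitution errors,
and `round(coverage * L / read_len)` reads per chromosome; the default
read length of 150 bp matches a contemporary short-read run. Everything
is deterministic given the seed.

What a green test does *not* establish: real genomes have indels,
structural variation, nested and diverged repeat hierarchies, uneven
coverage and base-quality structure; the simulator's clean separation of
"group-private repeat vs background" is the easiest possible instance of
the enrichment problem. The tests establish correctness of the
machinery, not power on hard genomes.

`simulate_vcf()` generates a primary and a secondary call set, a repeat
mask and a per-record truth table (first failing rule in cascade order),
with controlled fractions of each defect, so the filter cascade can be
checked against an independent predicate oracle.

## Variant filter cascade

Rules in order: (1) two-pipeline intersection on (chrom, pos, ref,
ALT-set); (2) site depth outside [5, 1000] — depth is `INFO/DP`, else
the sum of `FORMAT/DP` (the GATK convention; the defining study does not
say which field it used), with depth-unknown records failing
conservatively under a separate reason code; (3) not biallelic;
(4) missing-genotype rate > 40% (`./.` counted missing, per site across
all samples); (5) inside the repeat mask (BED, 0-based half-open,
converted to 1-based positions); (6) closer than 5 bp (`|Δpos| ≤ 4`,
the literal reading of "less than 5 bp") to *any* other record of the
input set — both members of a close pair are removed, and records
failing earlier rules still count as neighbors. Each record is removed
at its first failing rule, so the per-rule counts partition the input
exactly; the surviving set is invariant to rule order.

## Gene clusters

`find_clusters()` chains family genes in coordinate order while the gap
(default: `next start − previous end − 1`, floored at 0 for overlaps;
start-to-start available since the source criterion is ambiguous) stays
≤ 0.8 Mb, and emits maximal chains of ≥ 3. "Adjacent" is read as
consecutive *family* members — intervening non-family genes are allowed,
since a 0.8-Mb distance criterion is meaningless under strict adjacency;
a `strict_adjacency` flag provides the narrow reading. Strand is
ignored. Equivalence with a window-enumeration oracle, maximality and
disjointness are property-tested on 200 random fixtures.

## Worked example

```{r example, eval = FALSE}
g <- simulate_polyploid_genome(sim_config("auto", seed = 1))
res <- run_tetrasig_pipeline(g, min_global = 100, seed = 1)
res$call
#> ploidy_call: verdict = auto | S = 1.000 | permutation p = 0.001 (n = 1000)

reads <- simulate_reads(g, coverage = 25, seed = 1)
smudge <- run_smudge_pipeline(reads)
smudge$report
#> smudge_report: c_hat = 22.5 | 1497 pairs tested | 305 unassigned
#>   AAAB        594  (39.7%)  <- dominant
#>   AAB         326  (21.8%)
#>   AB          124  (8.3%)
#>   AAAAB        66  (4.4%)
#>   AABB         28  (1.9%)
```

## Numerical choices

* Argmax chromosome ties break to the lexicographically smallest id;
  distance ties in UPGMA break by pre-sorted labels; estimator ties go
  to the smaller coverage.
* `fold` achieved is `Inf` when the baseline is zero (K-mer absent from
  all other chromosomes).
* Degenerate inputs raise errors rather than guessing: single-chromosome
  enrichment, empty marker sets, all-zero profile rows, unlabeled
  leaves, groups of size 1, `L ≥ U`, fewer than 100 pairs for coverage
  estimation.
* Reports embed the resolved run parameters; identical inputs, seeds and
  configuration reproduce byte-identical outputs.
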