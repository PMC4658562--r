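---
title: "Comparative molecular evolution of subterranean rodent lineages: models and methods"
author: "burrowevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative molecular evolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`burrowevol` implements, as one tested pipeline, the comparative analyses
used to characterise molecular adaptation in a subterranean rodent lineage
(the plateau zokor) against its relatives: one-to-one ortholog preparation,
per-branch dN/dS estimation with outlier and saturation filtering, the
branch-site positive-selection test with Bayes empirical Bayes (BEB) site
posteriors, GO-category acceleration testing, marginal ancestral
reconstruction with parallel/convergent substitution detection, and the
interpretation layer (GO enrichment, tissue-specificity of expression, PPI
sub-networks). Because the original transcriptome data are not required
here, a first-class synthetic-data module generates every input with known
ground truth; all quantitative claims about the pipeline are made by the
test suite and the acceptance script, which recompute them from these
simulations.

# The codon substitution model

All rate and selection inference rests on the standard codon model over the
61 sense codons. The instantaneous rate from codon $i$ to codon $j$ is

$$
q_{ij} \;=\;
\begin{cases}
0 & \text{more than one nucleotide differs}\\
\pi_j & \text{synonymous transversion}\\
\kappa \pi_j & \text{synonymous transition}\\
\omega \pi_j & \text{nonsynonymous transversion}\\
\kappa \omega \pi_j & \text{nonsynonymous transition,}
\end{cases}
$$

with $\kappa$ the transition/transversion rate ratio, $\omega = d_N/d_S$,
and $\pi$ the codon frequencies. $Q$ is scaled so one unit of time equals
one expected substitution per codon; branch lengths are therefore expected
substitutions **per codon** throughout (a rodent terminal branch at 50–90
My is then of order 0.2–0.8, not the per-nucleotide 0.05–0.3 one sees on
nucleotide trees — an easy unit trap). Likelihoods use Felsenstein pruning
over site patterns, with gapped or ambiguous codons entering as missing
data (a flat tip partial, the `cleandata = 0` convention). Codon
frequencies default to F3x4 (positional nucleotide frequencies estimated
from each alignment), with F1x4, uniform, or user-supplied vectors
available.

Two parameterisations are exposed through `log_likelihood()` and the
fitting functions:

* **Free-ratio**: one independent $\omega$ per branch
  (`fit_free_ratio()`). After fitting, each branch length is decomposed
  into $d_N$ and $d_S$ through the expected synonymous and nonsynonymous
  substitution flows of the fitted $Q$, with site counts taken from the
  neutral ($\omega = 1$) mutational opportunity; the transition/transversion
  substitution count ratio per branch comes from the same flows, which is
  what the saturation diagnostic plots against $d_S$. With this
  decomposition $d_N/d_S$ equals the fitted $\omega$ exactly, so the two
  views are consistent by construction.
* **Branch-site model A** (`fit_branch_site()`): four site classes with
  proportions $(p_0, p_1, p_{2a}, p_{2b})$,
  $p_{2a} = (1-p_0-p_1)\,p_0/(p_0+p_1)$ and $p_{2b}$ analogously. Classes
  0 and 2a use $\omega_0 \in (0,1)$ on background branches; classes 1 and
  2b use 1; on the designated foreground branch classes 2a/2b use
  $\omega_2 \ge 1$ (fixed at 1 under the null). The site likelihood is the
  class mixture; the LRT statistic $2\Delta\ell$ is referred to
  $\chi^2_1$ by default. The 50:50 mixture of $\chi^2_0$ and $\chi^2_1$ is
  available (`mixture = TRUE`) but is not the default, because the
  $\chi^2_1$ reference is the conservative, conventional choice when plain
  LRT p-values are reported.

## Optimisation strategy

All fits run bounded L-BFGS-B on log/logit-transformed parameters with
forward-difference gradients that share the base evaluation, and fixed,
deterministic starting points — repeated fits are bit-for-bit identical.
The free-ratio fit starts from a single-ratio fit that is itself started
from three $\omega$ values (0.1, 1, 2). For the branch-site fits the
expensive part of the calibration and power studies is the 200+ repeated
datasets, so the design differs deliberately:

1. a single-ratio prefit estimates $\kappa$ and branch lengths once per
   gene;
2. background branch lengths are then held fixed on a mutational time
   scale, while the **foreground branch's effective time remains a free
   parameter in both the null and the alternative fits**, alongside
   $\kappa$ and the mixture parameters;
3. the alternative fit uses two deterministic $\omega_2$ starts (2 and 8).

Keeping the foreground time free makes the foreground branch an exact
reparameterisation of the fully scaled model and — crucially — makes the
null parameter space a genuine subset of the alternative's, so the LRT
keeps one degree of freedom. On simulated data this scheme reproduces the
p-values of a full joint fit (all branch lengths free, exact class-mixture
rate scaling) to within ~0.005 while being an order of magnitude faster;
the class-likelihood memoisation it enables (class likelihoods do not
depend on the class proportions once times are fixed) is what makes the
200-replicate null calibration practical on one CPU.

## BEB site posteriors

`beb_site_posteriors()` integrates the per-site posterior probability of
the selected classes (2a ∪ 2b) over a uniform discrete prior grid, with
$\kappa$ and branch lengths fixed at their MLEs: $(p_0, p_1)$ on a
10×10 lattice restricted to the simplex, $\omega_0$ on 10 points in
$(0,1)$, and $\omega_2$ on 10 points in $(1, 11)$. On data with no
variation every class likelihood is equal, so the posterior collapses to
the prior class-2 mass of the grid — a property the acceptance suite
checks exactly.

# Lineage rates and category acceleration

Genes with $d_N/d_S > 4$ on either focal branch are removed (strict
inequality: 4.0 is kept), then genes with $d_S > 1$ on either focal branch
(1.0 kept), the latter motivated by the loss of linearity between the
transition/transversion ratio and $d_S$ beyond saturation; the filter
order does not matter and the suite checks commutativity. Lineage means
are compared with an unpaired two-sided Wilcoxon rank-sum test (exact
enumeration when both groups have ≤ 12 untied values, normal approximation
with continuity and tie correction otherwise); a paired signed-rank option
exists since the same genes underlie both lineages, but rank-sum is the
default to match the conventional reporting of this comparison.

The GO acceleration test concatenates the trimmed alignments of every
category with **more than 20** member genes into a category supergene,
refits the free-ratio model, and converts each lineage's branch length
into an expected nonsynonymous substitution count (flow proportion ×
length × codons). With category counts $a$ (lineage A) and $b$ (lineage
B), and $p_0$ the genome-wide A-share of nonsynonymous substitutions, the
one-sided binomial tail $P(X \ge a \mid n = a + b, p_0)$ tests
"accelerated on A", and symmetrically for B; counts are rounded to
integers and the pre-rounding values are kept in the output. This binomial
formulation is a reconstruction — the procedure it follows is cited
second-hand in the literature rather than printed in full — and a
mean-per-gene-$\omega$ alternative is deliberately out of scope. Genes
whose $\omega$ is undefined ($d_S = 0$) are excluded from lineage means
but still enter concatenations, where estimability is restored.

# Ortholog preparation

* `find_longest_orf()` scans all six frames of a transcript (assembled
  transcripts are unoriented, so both strands are searched) for
  start-to-stop ORFs, requiring ≥ 120 nt **including** the stop codon, and
  breaks ties deterministically (lowest frame, then 5'-most start).
* `best_reciprocal_hits()` implements the BRH criterion at E ≤ 1e-5 with a
  deterministic best-hit tie-break: e-value, then bit score, then
  alignment length, then subject id. Without a fixed tie-break the pair
  set is not well-defined.
* `trim_codon_blocks()` is a simplified codon-mode block filter in the
  spirit of the classic alignment cleaners: gap-containing codon columns
  are removed, runs of more than one non-conserved column are removed, and
  surviving blocks shorter than six codons are dropped. "Conserved" means
  the majority codon is shared by at least half the taxa — an explicit
  simplification, not a bit-compatible reimplementation of the original
  tool's similarity classes. The rules are applied to a fixpoint, which
  (unlike a single pass) makes trimming idempotent, a property the suite
  tests.
* The post-trim length filter removes alignments shorter than 10 nt,
  applied literally in nucleotides even though 10 is not a codon multiple.
* `extract_fourfold_sites()` takes third positions of gap-free codon
  columns whose first two nucleotides are identical across all taxa and
  define a fourfold-degenerate family — the strict convention for
  neutral-site supermatrices.
* Coordinates are 0-based internally and 1-based in all emitted tables.

# Ancestral reconstruction and parallel substitutions

`marginal_ancestral_reconstruction()` computes marginal posteriors at every
internal node and site by an up/down pruning pass under a reversible
amino-acid model, after re-estimating branch lengths by ML under that
model. The default process is the uniform (Poisson-type) exchangeability
with equal frequencies; any symmetric 20×20 exchangeability and frequency
vector can be supplied. The uniform default is a deliberate design choice:
it keeps the star-tree closed-form oracles exact and the planted-site
recovery tests interpretable, and none of the downstream classification
logic depends on which empirical matrix is used — but reconstructions of
real proteins should supply an empirical matrix, and results near the
posterior cutoff can shift with that choice (a known limitation).

Substitution events are called on a branch when the best-supported states
at its two ends differ and every reconstructed (internal) endpoint has
posterior probability **strictly greater than** 0.9 (0.90 exactly is
suppressed). The cutoff is applied at both ends of internal–internal
branches by default, with a single-end (ancestral-only) mode available,
since the printed rule names only "the reconstructed ancestral site".
For a focal branch pair, a site with events on both branches is
*parallel* if the two events share both ancestral and derived residues,
*convergent* if the ancestral residues differ but the derived match, and
*divergent* otherwise — the standard ancestral-state convention, which is
also what makes a zero-convergent / many-parallel split on two closely
related rodent lineages expected: sister-ish lineages usually start from
the same ancestral residue. Sites with a gap in a focal-adjacent taxon are
excluded because the derived state is undefined.

# Interpretation layer

GO enrichment is a one-sided hypergeometric upper tail per term with ≥ 1
candidate, BH-adjusted across the tested terms, against a user-supplied
background universe (no live database access; the backgrounds ship with
the run, making results reproducible). Tissue-specific highest expression
assigns a gene to a tissue iff its $\log_2(\text{FPKM}+1)$ there strictly
exceeds `fold` times that of every other tissue; the fold ladder defaults
to 1.5 / 3 / 4.5, the internally consistent set (the alternative printed
ladder ending in 4 appears to be a typo in the source material and the
figure-consistent 4.5 is used; assignments are monotone in the fold, which
the suite checks). PPI sub-networks are the connected components of the
graph induced by the seed genes plus their direct interactors — the
first-neighbour convention of the usual network platforms — retaining
components with more than 5 nodes, and reporting nodes with degree
strictly above 100 annotated by PSG/PEG membership.

# The synthetic-data module

Simulation uses exact CTMC sampling along each branch (exponential waiting
times from the rate matrix), never endpoint sampling from the transition
matrix, so that every realised substitution is recorded in an event log.
The event log is the test oracle: replaying it from the root must
reproduce every tip sequence exactly, an $\omega = 0$ simulation must
contain only synonymous events, and planted parallel sites must be
recovered exactly when true ancestral states are injected. Codon
frequencies default to uniform over the 61 sense codons, which keeps
closed-form expectations (e.g. the transition/transversion event ratio
against the rate-matrix flows) exact.

The study conditions are the generator defaults: the six-taxon rodent
phylogeny of `study_tree()` with branch lengths in substitutions per codon
(zokor 0.25, rat 0.40, kangaroo rat 0.55, guinea pig 0.45, naked mole-rat
0.38, human 0.75, plus internal branches), $\kappa = 2$, and per-branch
$\omega$ defaults of 0.09 on the zokor branch versus 0.136 on the rat
branch — the purifying-selection contrast the rate comparison is designed
to detect. Branch-site simulations use mixture-consistent rate scaling so
that a branch length means expected substitutions per codon averaged over
site classes.

What the generator does **not** emulate: alignment error and assembly
artefacts (alignments are simulated, never realigned), expression count
noise beyond independent FPKM draws (no replicate structure, no
library-size effects), GO-term dependency structure (terms are sampled
independently except the planted ones), and any correlation between a
gene's selection history and its network degree. Passing tests therefore
demonstrate correctness of the inference machinery under the model's own
assumptions, not robustness to real-data violations of them.

# Problem sizes and numerical choices

The validation studies run at deliberately chosen sizes: likelihood
oracles on 3–4 taxa × ≤ 10 codons (exhaustive enumeration is exact there);
free-ratio recovery on 30 genes × 500 codons; branch-site null calibration
on 200 simulated genes × 300 codons and power on 20 genes with
$\omega_2 = 5$ on 30% of sites; convergence oracles on 50 genes; and the
end-to-end determinism check on an 8-gene bundle (the `analysis/` scripts
run the 12-gene default). Optimiser tolerances are
`factr = 1e9` (≈ 2×10⁻⁴ absolute in log-likelihood at these data sizes),
loosened to 1e10 for the single-ratio prefit whose role is only to set
branch lengths; parameter bounds are wide ($\omega \in [10^{-4}, 50]$,
branch lengths in $[10^{-6}, 20]$). Degenerate inputs are handled
explicitly: alignments with no variation return a flagged record with
undefined $\omega$ rather than a spurious fit, and zero-length branches
yield $d_S = 0$ with $\omega$ flagged undefined.

# Known limitations

* The branch-site test's power at the default study conditions is
  moderate; model A has a well-known near-identifiability between "a
  selected site class on the foreground" and "a longer foreground branch
  with a larger neutral class", and individual datasets can place the
  global optimum in the latter mode. The acceptance suite measures the
  realised rejection rates rather than assuming them.
* No numerical equivalence with existing codon-model binaries is claimed;
  contracts are checked against enumeration oracles and closed forms
  instead.
* The headline counts of the motivating study (ortholog totals, numbers of
  selected and parallel genes, network sizes) depend on its deposited
  transcriptome and archived annotation releases and are out of scope; the
  pipeline reproduces the *procedures* with measurable operating
  characteristics, not those numbers.
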