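---
title: "Methods: structure-conditioned evolutionary rate contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-conditioned evolutionary rate contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ifacevol` contrasts evolutionary rates between structurally defined
residue classes of a multi-subunit complex. This vignette records the
models, the numerical choices, and the design decisions behind them, in
enough detail that a maintainer could re-derive every component.

## Residue classification

A residue's distance to another residue is the minimum Euclidean distance
over all heavy-atom pairs; hydrogens are discarded at parse time and
alternate locations are resolved to the highest-occupancy conformer (ties
broken by record order). A residue of chain X is a **contact** when some
residue of a different polypeptide chain lies closer than a cutoff,
default 4 Å — the upper limit of weak (hydrogen-bond/van der Waals)
interactions. Hetero groups (hemes, lipids, metals) never count as
partners: contacts are defined between polypeptides only. Contact
residues split by the genome of origin of their partners: any
nuclear-encoded partner puts the residue in the inter-genome class
(`MT_NU_CONTACT`), otherwise it is intra-genome (`MT_MT_CONTACT`). The
"any nuclear partner wins" precedence is a deliberate reading of the
mixed-partner case: the inter-genome class is the one whose coevolutionary
interpretation is at stake, so it absorbs residues with both kinds of
partner.

Noncontact residues split by solvent exposure. Accessible surface area is
computed with the Shrake–Rupley method: each heavy atom carries a sphere
of radius r(vdW) + r(probe) sampled at `sphere_points` quasi-uniform
(golden-spiral) test points, and the accessible fraction is the fraction
of points not inside any other atom's inflated sphere. Defaults: probe
1.4 Å (water), 960 points (≈ 0.3% area resolution per atom), element
radii C 1.70, N 1.55, O 1.52, S 1.80 Å. Per-residue ASA is the sum over
the residue's atoms, computed twice: on the isolated chain (ASA₁) and in
the full complex (ASA₂). Because both computations use the same point
set and the complex only adds blockers, ASA₂ ≤ ASA₁ holds exactly, so
ΔASA = ASA₁ − ASA₂ is nonnegative by construction; values below −10⁻⁶ Å²
would indicate mismatched inputs and are an error.

A noncontact residue is **buried** when its relative in-complex exposure,
ASA₂ divided by a per-residue-type theoretical maximum (Tien-style
Gly-X-Gly values; 200 Å² for unknown types), falls below
`exposure_threshold`, default 0.05 — a standard buried/exposed cut in the
structural-bioinformatics literature; the source analysis did not state
its threshold, so it is configurable. Exposed noncontact residues carry
an **interface** flag, true iff ΔASA > 0: complexation shadows part of
their surface even though no atom comes within contact range.

## Codon sorting

Alignment columns inherit residue classes through a reference taxon: the
k-th reference-ungapped codon column maps to residue number
`first_residue_number + k − 1` of the reference chain. Columns where the
reference is gapped cannot be structurally labelled and are excluded from
every class (reported as `UNMAPPED`). Codons containing gap characters
are treated as fully gapped; codons with ambiguity codes, and internal
stop codons under the configured genetic code, are masked (reported, not
fatal). The default code is the vertebrate mitochondrial table (60 sense
codons; stops TAA, TAG, AGA, AGG), the appropriate state space for
mtDNA-encoded genes; the universal code is available per alignment.

## Pairwise divergence and ΣdN

The evolvability summary of a codon subset is ΣdN: the sum over all
unordered sequence pairs of dN, the number of nonsynonymous substitutions
per nonsynonymous site. Two counting estimators are provided:

* `ng86` — classical Nei–Gojobori. Each codon position contributes one
  site, apportioned synonymous/nonsynonymous by the fraction of possible
  single-nucleotide changes of each kind (changes to stops excluded from
  the denominator); per-pair site totals average the two sequences.
  Differences at codons differing at d > 1 positions are averaged over
  the d! minimal mutational pathways, excluding pathways through stop
  codons (if all are blocked — possible only for some multi-hit pairs —
  all pathways are used). Proportions are corrected with the
  Jukes–Cantor transform d = −(3/4)·ln(1 − 4p/3); p ≥ 3/4 is reported as
  saturated (dN undefined).
* `yn00` (default) — a κ-weighted variant in the spirit of Yang &
  Nielsen's pairwise method: site fractions and pathway weights are
  weighted by the transition/transversion rate ratio κ (transitions
  κ-fold more likely), which corrects the classical estimator's known
  bias when transitions dominate. κ is estimated once per alignment by a
  Kimura-2-parameter fit to third codon positions pooled over all pairs
  (third positions are predominantly synonymous), with fallback κ = 2
  under saturation. An alignment-level κ — rather than per-pair — keeps
  the codon-pair lookup tables shared across pairs and, crucially, across
  the thousands of resampling replicates of the empirical null, so the
  null and the observed statistic use identical machinery. This variant
  keeps the Jukes–Cantor correction; it is not the full iterative YN00
  estimator, and `ng86` remains available as the hand-checkable tier.

Pairs with undefined dN are dropped from ΣdN and counted. A codon-column
bootstrap (default 200 replicates) supplies a standard error; the
estimator behind published ΣdN standard errors is not documented
anywhere we know of, so the bootstrap is this package's choice. The
interaction ratio between two classes is R = ΣdN(a)/ΣdN(b); R > 1 means
faster nonsynonymous evolution in class a.

Implementation note: per-pair, per-column difference and site counts are
precomputed once per alignment, making ΣdN of any column subset a row
sum. This is what keeps 10⁴-replicate nulls cheap.

## Empirical null

To ask whether a class of m codons is exceptionally conserved or variable
within its chain, the chain's alignment is resampled: B times (default
10⁴), m distinct columns are drawn uniformly without replacement and ΣdN
computed on the induced sub-alignment. The observed ΣdN is located in
this distribution with add-one tail fractions, lower tail
p = (1 + #{draws ≤ observed})/(B + 1) and the analogous upper tail — so
no finite run reports p = 0, and under a truly random subset p is
uniform on (0, 1] up to 1/(B+1) discreteness (verified by a
Kolmogorov–Smirnov check in the test suite). The tail must be chosen
explicitly: lower for conservation claims, upper for variability claims.

## Codon-model maximum likelihood

The substitution model is GY94-style: states are the sense codons,
instantaneous rates are zero for multi-nucleotide changes and otherwise
proportional to the target codon's equilibrium frequency π(j), times κ
for transitions and ω for nonsynonymous changes. Frequencies are F3×4:
products of empirical per-position nucleotide frequencies renormalised
over sense codons. The generator is reversible, so transition matrices
come from the symmetrised eigendecomposition (π^½ Q π^−½), one
decomposition per (κ, ω) reused across branches; exp(Qt) rows sum to 1
to 10⁻¹⁰ over the working range of t. Likelihoods use Felsenstein
pruning with pattern compression; gapped/masked tip codons are fully
ambiguous (partial likelihood 1 over all states); per-pattern log
rescaling guards against underflow on large trees. Branch lengths are
expected nucleotide substitutions per codon (generator scaled so
−Σπᵢqᵢᵢ = 1) with a 10⁻⁸ lower bound to keep exp(Qt) well conditioned.

Fits, all by bounded quasi-Newton (`nlminb`) on log-transformed
parameters with ω ∈ [10⁻⁴, 99] and κ ∈ [0.01, 100]:

* **M0**: branch lengths, κ and a single ω, jointly. Fitted lengths are
  cached and reused downstream ("fixed branch lengths"), the standard
  workaround when taxa are many.
* **Fixed-sites**: one ω per predefined partition, κ shared, branch
  lengths fixed. Each partition's generator is normalised to one
  substitution per codon: partitions share the branch-length scale and
  differ in the synonymous/nonsynonymous composition of change. This is
  also the simulator's default convention, making recovery exact in
  distribution. Per-partition standard errors come from the curvature of
  the profile log-likelihood in log ω.
* **M1a/M2a**: site-class mixtures, M1a = {ω₀ < 1, ω₁ = 1}, M2a adds
  {ω₂ > 1}. Mixing proportions are profiled out by an EM inner loop (no
  pruning inside), so the outer optimisation runs over (κ, ω₀[, ω₂])
  only; M2a uses multiple starts for ω₂. Unlike the fixed-sites case,
  mixture classes share a **common** rate scale c = Σ pₖ μₖ re-estimated
  alongside the proportions — sites with higher ω genuinely evolve
  faster. With per-class normalisation the ω > 1 class is nearly
  unidentifiable (the signal reduces to composition alone); this was
  measured directly during development and is why the two conventions
  coexist, each matching its fitting context, selectable in the
  simulator via `scale=`. The LRT statistic is 2(lnL₂ₐ − lnL₁ₐ) floored
  at 0, referred to χ² with 2 df — conservative at the boundary, which
  is the usual convention.

## Per-branch dN

Per-branch nonsynonymous divergence uses conditional expected labelled
Markov jump counts under the fitted model: with the spectral
decomposition, the integral J(t) = ∫₀ᵗ e^{Qs} L e^{Q(t−s)} ds (L = the
nonsynonymous off-diagonal part of Q) has a closed form, and combining
outside (preorder) and inside (postorder) partial likelihoods gives each
branch's expected number of nonsynonymous substitutions given the tip
data. Division by the partition's nonsynonymous site count — 3 × codons
× the nonsynonymous fraction of neutral mutational flux under the fitted
(κ, π) — yields dN per branch, and the per-branch difference
dN(Mt–nu) − dN(Mt–mt) summarises which contact class outpaces the other
across lineages. This is an expectation-based apportioning, not a
739-parameter free-ratio refit; the two need not agree numerically,
though both answer the same qualitative question.

## Synthetic data and what passing tests show

The generator plants ground truth at every level:

* **Toy complexes**: chains are strands of single-heavy-atom residues
  9 Å apart on lines 40 Å apart. Contact pairs are placed exactly 3.5 Å
  apart in chain-specific "lanes" offset in z, so designed pairs — and
  only they — fall under the 4 Å rule; interface pairs sit at 5.5 Å
  (no contact, but inside the ASA-shadowing range ≈ 6.6 Å, so ΔASA > 0);
  buried residues are enclosed by a 12-atom icosahedral shell of radius
  3 Å carried by a same-chain scaffold residue (the shell covers every
  direction within the cap angle that blocks a 1.4 Å probe, so the
  enclosed ASA is exactly zero); a pseudo-heme sits at a fixed offset.
  Geometric realism is irrelevant to the classifier's contracts, which
  are metric, not chemical: what matters is that the planted truth is
  geometrically exact, and the layout guarantees it.
* **Trees**: random topologies with i.i.d. exponential branch lengths;
  an unrooted binary tree over n tips has 2n − 3 branches.
* **Alignments**: exact matrix-exponential sampling down the tree,
  per-column independence, partition-specific ω, no stop codons by
  construction of the state space.
* **ΔΔG tables**: normal draws with class-dependent mean/sd.

Synthetic data lacks indels and alignment error, among-site rate
variation beyond the planted ω structure, codon usage heterogeneity along
the sequence, and real protein geometry. Passing tests therefore show the
estimators are correct and calibrated under their own model assumptions —
not that those assumptions hold for any particular real complex.

Default study conditions used by the test suite and acceptance script,
chosen once as desk-scale versions of a realistic analysis: fixed-sites
recovery at planted ω = 0.05/0.5 with 6 taxa × 600 codons × 20
replicates; LRT calibration with 6 taxa × 200 codons × 20 nearly-neutral
replicates; null-uniformity over 200 datasets of 5 taxa × 60 columns
with B = 499; the pipeline presets use 8 taxa ("small": 2 mt + 2 nuclear
chains of 30 residues) and 24 taxa ("paperlike": 3 mt + 10 nuclear
chains of 40 residues). The planted class ω map (Mt–mt 0.05 < buried 0.1
< Mt–nu 0.3 < exposed 0.6) encodes the ordering the method is designed
to detect — strongest constraint on intra-genome contacts, weakest on the
free surface.

## Known limitations

* The `yn00` tier approximates, and does not reproduce, the full
  iterative Yang–Nielsen pairwise estimator.
* Fixed-sites fits share κ across partitions and fix branch lengths;
  partition-specific rates beyond ω are not modelled.
* Per-branch dN is expectation-based (see above).
* mmCIF input, alignment construction, tree search, ΔΔG computation and
  structure repair are out of scope; ΔΔG tables are consumed as given.
* On very large complexes the O(n²) pairwise distance and neighbour
  searches are adequate but not optimal; they are exact.
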