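---
title: "Dating molecular structure: methods behind riboclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating molecular structure: methods behind riboclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboclock)
library(dplyr)
```

## The idea

Ribosomal RNA is a three-dimensional arrangement of helices, and those
helices did not appear all at once: the molecule grew by accretion, with new
substructures grafted onto an older core. riboclock implements a comparative
pipeline that turns this premise into relative ages. The units of comparison
are not sequences but *substructures* — helical stems (S), hairpin loops (H),
bulge/interior loops (B) and unpaired segments (U) — whose lengths, measured
across many organisms, become ordered multistate phylogenetic characters. A
tree built from these characters, with substructures as the operational taxa,
places ancient elements near the root and recent ones near the tips. The same
logic applied to a census of protein-domain superfamily abundances across
proteomes dates protein domains, so RNA and protein timelines can be laid
side by side.

## Character coding

Each homologous substructure slot (e.g. `h44.S1`, the stem of helix 44)
yields one character per molecule. Lengths map directly to a 64-symbol
ordered alphabet — digits, upper-case letters, lower-case letters, `@`, `&`
— with `0` the minimum and `&` the maximum state. Lengths at or above the
last index saturate at `&` (`encode_length()`); the saturation point is a
knob (`cap_at`) because the one-off ambiguity between "64 states" and a
0-based length scale admits two readings, and saturating at index 63 keeps
the map total and monotone.

Character matrices come in two orientations: molecules as rows (the natural
census layout) and its exact transpose with substructures as rows, which is
what tree building consumes. `build_matrix()` produces either; the two are
verified transposes of one another.

**Polarization.** Trees of substructures are rooted not by an outgroup (none
exists) but by declaring the direction of character change. The package's
default, `max_ancestral`, treats the largest observed state of each character
as ancestral. This follows the canalization premise: evolved RNA tends
toward conformational order, so long, stable, ordered stems are attributes
of old substructures. The direction is deliberately configurable
(`min_ancestral`, `fixed`) because it is a hypothesis, not a theorem; the
synthetic generator exposes an `invert` mode so either polarity can be
exercised against planted truth.

## Parsimony machinery

Characters are linearly ordered (Wagner parsimony): a change between states
`i` and `j` costs `|i − j|`. Tree length is computed by Sankoff dynamic
programming; because the cost is an absolute difference, the per-node
min-plus step collapses to a two-pass distance transform, making scoring
linear in the number of states. The C++ kernel scores a 30-taxon,
50-character matrix in well under a millisecond, which is what makes branch
swapping affordable. Correctness is pinned by an enumeration oracle (all
internal-state assignments, trees up to 6 leaves) and cross-checked against
an independent implementation (phangorn's `sankoff`) in the test suite.

The heuristic search is classical: stepwise addition (each taxon inserted at
the cheapest branch; ties to the first branch in enumeration order) followed
by tree-bisection-reconnection (TBR) swapping with first-improvement
acceptance, iterated to a local optimum. All distinct equally parsimonious
topologies found at convergence are retained up to a cap (default 1000,
reported when hit). Single-start searches on noisy random matrices
occasionally stop one step short of the global optimum — the expected
behaviour of hill climbing — so the search also offers random-addition
restarts (`addition = "random"`, `n_starts`), which recover the exhaustive
optimum on every 7-taxon random matrix in the acceptance suite. The
"simple" input-order addition sequence is the default because the planted
signal in realistic inputs is strong and the analysis is then fully
deterministic without a seed.

Fit statistics follow the standard definitions: `CI = Σmin/L`,
`RI = (Σmax − L)/(Σmax − Σmin)`, `HI = 1 − CI`, where per-character minima
are state ranges and maxima are star-tree (median) costs; `g1` is the
small-sample-corrected skewness (Sokal–Rohlf, via `e1071::skewness(type =
2)`) of tree lengths over uniformly random topologies (default 1000; the
pipeline uses 200 to keep runs fast). Bootstrap pseudoreplicates resample
characters with replacement as integer weights — the weighted Sankoff avoids
rebuilding matrices — and supports are clade percentages on the
majority-rule consensus.

**Rooting.** An unrooted most-parsimonious tree is rooted Lundberg-style:
a hypothetical ancestor carrying every character's ancestral state is
attached to each branch in turn, the cheapest attachment point becomes the
root, and the ancestor leaf is pruned. Ties (e.g. constant matrices) break
deterministically toward the first branch in postorder and are reported.

## The node-distance clock

For a rooted tree, a leaf's `nd` is the number of internal nodes strictly
between root and leaf, normalized by the maximum over leaves: the most
ancestral taxon that branches at the root has `nd = 0`, the most deeply
nested has `nd = 1`. `nd` is a proxy for relative time on strongly
imbalanced (accretion-driven) trees; the package therefore also provides the
imbalance statistics used to check that premise — mean root-to-tip internal
node count (`n_bar`, root counted) and cherry count — together with
Monte-Carlo nulls under the Yule (uniform-speciation) and uniform-topology
models. Note the two conventions: `nd` excludes the root from its count (so
basal leaves sit at 0), while `n_bar` includes it; both are unit-tested.
On an arbitrary tree the *minimum* `nd` is 0 only when some leaf branches
directly at the root; accretion-style trees are pectinate and always have
such a leaf, which is why the 0 endpoint is stated for them.

Timelines date annotations off the chronology: contacts (tRNA arms,
r-proteins, A-minor interactions, functional centres) take the `nd` of the
helix they reference; intersubunit bridges take the `nd` of their acceptor
element by default, or the younger partner under `bridge_rule = "max"` —
both readings of "first acceptor element" are exposed because the phrase is
ambiguous. Heat-map colour tables bin ages at 0.01 into a 101-entry
blue-to-red ramp; the table, not the particular colours, is the contract.

## Protein-domain ages

Genomic abundance `g` of a domain superfamily in a proteome spans orders of
magnitude, so it is gap-coded to 21 states with
`round(20·ln(g+1)/ln(g_max+1))`, `g_max` being that proteome's maximum
abundance (each proteome scales independently; a whole-table option exists).
The analytic form follows the census convention of this analysis family and
satisfies every stated constraint (a round function, a 0–20 range,
per-proteome `g_max`); rounding is half-up and pinned by test, and a linear
alternative sits behind `method = "linear"`. Polarization is fixed at `K`
(state 20) ancestral: superfamilies that are abundant and widespread are
taken as ancient. The domain chronology (`nd_P`) is then the same
search–root–count pipeline run on the domain-rows matrix.

Two rules connect domains to proteins. A multi-domain protein takes the age
of its *youngest* domain (largest `nd_P`) — a fusion cannot predate its
newest part; if the domain *combination's* own age postdates every
constituent, that is flagged (`combination_postdates`) rather than
substituted, following the worked two-domain case in which the combination
age falls between the constituent ages and the youngest domain still wins.
Second, early rRNA and r-protein ages co-vary linearly, so
`interpolate_protein_age()` fits ordinary least squares on early-era pairs
(defaults `nd ≤ 0.35`, `nd_P ≤ 0.2`, both overridable) and maps queries
through the line in either direction. The OLS path is verified against
closed-form hand calculations; the regression printed for the original
supplementary pairs is not recomputed here because those pairs are not
distributed in machine-readable form.

## Structural similarity screen

To ask whether a ribozyme substructure resembles an (ancestral) rRNA helix,
both are converted to ordered forests (P nodes for pairs, B nodes for
unpaired bases) and aligned with a structure-only local similarity: P–P
matches +10, B–B matches +1, every inserted or deleted node −5, P–B
substitution disallowed, score floored at 0. The optimum is taken over all
pairs of closed subforests — a Smith–Waterman pass over every pair of
sibling windows, with subtree pairs scored by global alignment of their
children. Deleting a node without deleting its subtree (the full
tree-alignment promotion move) is not implemented; the simplification is
immaterial to the screen because significance is judged on a Z-score, where
the score scale cancels — the suite verifies Z is invariant under affine
rescaling of all weights.

The null model shuffles the target sequence 1,000 times preserving exact
dinucleotide counts (Altschul–Erickson Eulerian-walk shuffle, endpoints
fixed; its output set equals the brute-force arrangement set on 6-mers),
refolds each shuffle, and realigns against the raw query (aligning against
the *refolded* query is available by passing a refolded structure). The
default refolding engine is Nussinov base-pair maximization over
Watson–Crick + GU pairs with a minimum hairpin of 3 and deterministic
leftmost traceback, verified against structure enumeration up to length 12;
a thermodynamic folder can be supplied via `folder =` if one is installed.
Similarity is significant at `Z ≥ 3.0`. The threshold itself is the
contract; confidence-level phrasings attached to it elsewhere are
inconsistent and are not reproduced.

## Synthetic data

Because the original alignments and census are not distributable inputs, the
generators are first-class, tested code and define the study conditions:

* `simulate_accretion()` — 30 molecules × 20 universal helices by default.
  A Yule guide tree is grown; each helix has a birth rank, a baseline stem
  length decreasing linearly with rank from 24 bp down to 4 bp (hairpins
  start at 4 nt), and segment lengths drift ±1 per branch with probability
  `drift_prob × (0.25 + 0.75·rank/H)` (default `drift_prob = 0.1`), so old
  helices are long and quiet, young ones short and noisy. `drift_prob = 0`
  is the degenerate control (constant matrix, warned). Values were chosen
  once as plausible rRNA-helix scales; they are not fitted to anything.
* `simulate_census()` — 50 proteomes × 30 domains by default. Domain ages
  are uniform on \[0, 1\]; presence probability is
  `plogis(−2 + 2.5·β·age)` and abundance when present is
  `1 + Poisson(exp(α + β·age))` with `α = 1`, `β = 2`. The presence slope is
  deliberately proportional to `β` so that `β = 0` removes *all* recoverable
  age signal, making it a true negative control.

What the generators do **not** emulate: real nucleotide composition,
alignment error, non-universal (lineage-specific) helices, covarying
characters, or the heavy-tailed abundance distributions of real proteomes.
Passing recovery tests therefore demonstrates that the pipeline inverts its
own generative premise — longer/older, abundant/older — not that real rRNA
data would behave as cleanly.

Recovery is measured as the Spearman correlation between planted birth
ranks and recovered `nd`/`nd_P`, summarised as the median over 20 seeds
(accretion) and 10 seeds (census); problem sizes in the test and acceptance
scripts (7-taxon exhaustive comparisons, 1,000-shuffle screens,
10,000-replicate Yule tests) were sized so the whole suite runs comfortably
on a single CPU.

## Numerical and degenerate-input choices

* Ordered costs are integer `|i − j|`; all DP is exact integer arithmetic.
* Stepwise addition, TBR acceptance and ancestor attachment all break ties
  toward the first candidate in a fixed enumeration order, so every search
  is deterministic given its seed (or without one, for input-order
  addition).
* Missing states (`?`) contribute flat zero cost vectors.
* Gaps `-` contribute 0 to segment lengths; parsing accepts hairpins of any
  size (`min_hairpin = 0`) so that hand-written toys are legal, while the
  folder enforces the biological minimum of 3.
* Pseudoknot brackets (`[]`, `{}`) parse, are stored separately, delimit
  helix regions during decomposition, and are refused by the forest
  aligner.
* Interior loops contribute one B segment per strand pass (the two-B
  convention); segments are listed by 5' start.
* An all-equal-depth tree yields `nd = 0` everywhere with a warning; zero
  null variance makes Z undefined (flagged, not significant); constant
  census matrices warn of degeneracy.

## Known limitations

* TBR from a single start can stall one step above the optimum on
  adversarial random matrices; use restarts where exactness matters.
* The forest aligner omits node-promotion moves (see above).
* `nd` is a node-count clock: it assumes roughly uniform lineage-splitting
  and says nothing about absolute time.
* The gap-coding transform is only approximately scale-free: multiplying a
  proteome's abundances by 3 can move small-abundance characters by two
  bins (tested); the linear variant is exactly scale-invariant but loses
  resolution at the abundant end.

## A worked run

```{r example, eval = FALSE}
sim <- simulate_accretion(seed = 11)
chron <- helix_ages(sim$lengths, seed = 11)
head(chron, 3)
cor(inner_join(chron, sim$truth, by = c(id = "helix")) |>
      select(nd, birth_rank), method = "spearman")
autoplot(chron)
```

The same pattern drives `domain_ages()` for the census and
`zscore_screen()`/`screen_matrix()` for ribozyme comparisons; see the README
for a complete worked example with its printed output.
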