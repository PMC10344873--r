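---
title: "Ensemble-based scanning of interface mutations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble-based scanning of interface mutations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kstarscan)
```

## The problem

Missense mutations at the binding interface of a macromolecular complex can
abolish complex formation, and for tumour suppressors such as p16 or p53
loss of a protein-protein or protein-DNA interaction is itself an oncogenic
mechanism. `kstarscan` implements a desk-scale protocol that (i) scores
every allowed point mutation at an interface by the change it causes in an
ensemble-based binding score, (ii) classifies mutations as
binding-disrupting, (iii) ranks residue positions into mutational hotspots,
and (iv) estimates, from mutational signatures, how likely each
amino-acid mutation is to arise in a given cancer type. The two axes —
"does it disrupt binding" and "how readily is it generated in patients" —
together prioritise mutations likely to become clinically relevant.

## The K* binding score

For a complex `C` formed from partners `A` and `B`, each state is modelled
as a thermodynamic ensemble over discrete side-chain conformations
(rotamers) of the flexible residues, all other atoms rigid. With partition
functions

$$Z = \sum_{c \,\in\, \text{conformations}} e^{-E(c)/RT},$$

the binding score is

$$\log_{10} K^* \;=\; \log_{10} Z_C \;-\; \log_{10} Z_A \;-\;
\log_{10} Z_B ,$$

an ensemble analogue of the association constant. A mutation's effect is
the difference of its score and the wildtype score *from the same run*
(same conformation spaces, same energies):

$$\Delta K^* = \log_{10} K^*_{\text{mut}} - \log_{10} K^*_{\text{wt}}.$$

Mutations whose score drops by more than 3 log10 units (`delta <= -3`,
closed boundary; the cutoff is a `triage_config()` parameter) are called
disruptive. When every conformation of the mutant complex is sterically
impossible the complex ensemble carries no Boltzmann mass, no finite
difference exists, and the mutation is reported with the sentinel `"X"`
(complete disruption) — always counted as disruptive.

### Bounded partition functions

Exhaustive enumeration is exponential in the number of flexible positions,
so partition functions are computed with provable bounds: conformations
are enumerated best-first by an admissible lower bound on their energy
(assigned singles-and-pairs plus, for each unassigned position, the
minimum achievable single-plus-pair contribution). The enumerated mass is
a lower bound on `Z`; adding `(remaining count) * exp(-f_min/RT)` — with
`f_min` the smallest admissible bound over the frontier — gives an upper
bound. Enumeration stops when `(upper - lower) <= epsilon * upper`, so the
exact `Z` always lies in `[lower, upper]` with relative gap at most
`epsilon`. The protocol default is `epsilon = 0.03`. Ties in the
enumeration order are broken by lexicographic choice index, making results
deterministic.

The score combines the bounds conservatively: the complex contributes its
lower bound and the unbound partners their upper bounds, so disruption
calls err toward caution. How the reference tool for such designs combines
its internal bounds is not documented at this level; the conservative
combination is this package's own choice. No stability (unfolded-state)
threshold is applied anywhere.

### Energy model

The pairwise energy is a deliberately simple heavy-atom potential:
Lennard-Jones 12-6 with Lorentz-Berthelot combining
(`r_min = r_i + r_j`, `eps = sqrt(eps_i eps_j)`) plus Coulomb with a
distance-dependent dielectric `eps(r) = 4r`; parameters come from a
hand-built united-atom template table shipped as plain text. Atom pairs
closer than `0.6 (r_i + r_j)` contribute a flat `+1000` kcal/mol
(clash cap), which keeps Boltzmann weights finite (effectively zero) and
gives the complete-disruption rule a deterministic trigger: a complex
whose best conformation is clash-capped has `log10 Z` far below the
`-300` zero-mass floor. Pairs bonded 1-2 or 1-3 within a residue are
excluded; inter-residue pairs are always counted (constant intra-chain
terms cancel exactly in the K* ratio). The decomposition into template,
single and pairwise energies is exact by construction, and the test suite
verifies matrix-based energies against a direct all-atom sum to
`1e-9` kcal/mol.

This potential is *not* a molecular-mechanics force field: no solvation,
no hydrogens, no parameter fidelity to AMBER-class force fields. It is the
package's own stand-in physics — any pairwise-decomposable potential
supports the protocol's logic (bounds, scores, triage), which is what this
package is about. Externally computed energies can be injected through the
documented TSV interchange (`read_energy_matrix()`).

### Flexibility model

Mutable residues are flexible, everything else rigid. Side chains are
rebuilt from ideal internal coordinates (a small embedded z-matrix table)
at the chi angles of a compact embedded rotamer library (1-3 rotamers per
amino acid; glycine and alanine have the single trivial rotamer).
Continuous side-chain minimisation is deliberately approximated by these
discrete rotamers: enumeration stays exact and desk-scale, at the cost of
a coarser ensemble. Histidine is modelled as three distinct template/charge
sets — N-delta protonated (H1), N-epsilon protonated (H2), doubly
protonated (H3) — each scored separately; a histidine mutation is called
disruptive only if all three variants disrupt. Nucleic-acid partners are
always rigid, and mutations are protein-side only.

## Interface detection and trimming

The interface is defined as every residue with a heavy atom within 5.0
Angstrom (closed boundary) of the opposite partner; the contact cutoff is
configurable since a numerical definition of "the interaction interface"
is a modelling choice. Around the interface a 12 Angstrom retention
shell is kept: exactly the residues with a heavy atom within the shell
radius of an interface residue. Distance boundaries are closed for
determinism; interface residues are always retained, and trimming is
idempotent.

## Relative probabilities of mutation formation

Mutational signatures assign probabilities to the 96 pyrimidine-centred
trinucleotide substitution classes; a cancer type weights the signatures
by their contribution to its mutational burden (weights are renormalised
to sum to 1 — only *relative* probabilities are meaningful here). A single
base exchange is scored by collapsing its context onto the pyrimidine
strand and mixing the catalog values with the cancer weights.

An amino-acid mutation is scored over all codon substitution paths of at
most two base exchanges. Double exchanges are scored as the sum over both
substitution orders of the product of the stepwise probabilities, the
second step evaluated in the context left behind by the first (contexts
are computed on the raw gene sequence, so adjacent-base effects cross
codon boundaries). This order-symmetric product rule is this package's
reconstruction of the published approach, which delegates the formula to
earlier work; it reduces to the single-step formula when one step is
certain, and the test suite checks its order symmetry and its closed-form
values under a uniform catalog. Mutations reachable only by substituting
all three codon bases are excluded as extremely unlikely
(`excluded_triple`) and carry no number. Codon `i` of the supplied coding
sequence is taken to correspond to author residue number `i` of the
scanned chain. For targets observed across most cancer types (the p53
situation) the probability stage is simply skipped and ranking falls back
to the score differences.

## Triage, hotspots, prioritisation

- **Disruption**: every variant value at or below the cutoff (default
  `-3`), or complete disruption. Lowering the cutoff can only remove
  disruptive calls (verified as a property test).
- **Hotspots**: positions ranked by their count of disruptive mutations,
  ties broken by ascending residue number; the top three are reported by
  default.
- **Prioritisation**: disruptive mutations at hotspot positions, ordered
  by relative probability (descending) or, without a cancer type, by score
  difference (ascending, complete disruptions first).
- **Heatmap**: a targets-by-positions matrix (histidine expanded to
  H1-H3) with the wildtype cells marked `wt` and triple-excluded cells
  marked distinctly.

Whether hotspot counting should use all predicted mutations or only the
disruptive ones is ambiguous in prose descriptions of such protocols; this
package counts disruptive calls only, i.e. positions are ranked by
confirmed disrupting mutations.

"Investigated alone or in pairs" can mean batched flexibility or double
mutants; both single-site scans and an optional two-site simultaneous mode
(`pair_mode`, exactly two mutable sites, outputs labelled
`"mut1+mut2"`) are provided.

## The synthetic data generator

Real inputs (curated PDB complexes, signature catalogs, tumour-type
weights) are external resources; the package ships deterministic
generators instead, and they define the conditions under which the test
suite and the acceptance analysis run:

- `make_toy_complex()`: two short facing peptide chains, residues spaced
  6 Angstrom along the chain (far enough apart that the toy has no
  spurious intra-chain clashes; these are independent residues, not a
  covalently modelled chain), mirrored so the closest heavy-atom pair sits
  at exactly the recipe's `interface_gap` (default 4 Angstrom — in
  contact under the 5 Angstrom criterion). Coordinates carry a seeded
  jitter of a few thousandths of an Angstrom; output is byte-reproducible
  per seed. Ground truth (interface membership by construction, engineered
  perturbations) is recorded alongside.
- Engineered disruptions are injected as known energy offsets on the
  mutant complex (the energy-matrix interface), not by editing
  coordinates, so recovery tests have exact ground truth.
- `make_uniform_catalog()` / `make_random_catalog()`: one uniform
  signature (all classes 1/96) for closed-form oracles, or normalised
  random signatures; `make_toy_gene()`: stop-free random coding sequence
  with single-base flanks.
- `random_energy_matrix()`: synthetic conformation spaces (default 4
  positions x 4 rotamers, energies N(0, 2 kcal/mol)) used to validate the
  bounded estimator against exhaustive enumeration.

What passing tests on these fixtures shows: the bound guarantees, the
exactness of the energy decomposition, the determinism of the pipeline and
the correctness of the combinatorial and probabilistic rules. What it does
not show: predictive accuracy on real complexes, which depends on a real
force field, real rotamer statistics and prepared structures — all outside
this package's physics.

## Numerical choices

- Temperature 298.15 K (configurable); `R = 0.0019872` kcal/(mol K).
- All Boltzmann masses accumulated in natural-log space (log-sum-exp);
  per-conformation energies in `[-100, +1000]` kcal/mol neither overflow
  nor underflow (property-tested).
- Zero-mass floor `log10 Z < -300` (double-precision scale) triggers the
  complete-disruption status.
- Alternate locations resolve to the highest occupancy, ties by altloc
  letter; hydrogens in the input are discarded (united-atom model);
  author residue numbering with insertion codes is kept throughout.
- Problem sizes in the test and acceptance runs: toy dimers of 3-4
  residues per chain, conformation spaces up to 4 positions x 4 rotamers
  (256 conformations), 100 random spaces for the bracketing property,
  8-codon toy genes scanned over all 19 targets per position. These sizes
  make every exhaustive oracle exact while keeping the default suite fast.

## Known limitations

- The stand-in potential ranks toy perturbations faithfully but has no
  claim to thermodynamic accuracy on real proteins.
- No backbone flexibility, no >2-site designs, no DNA mutations, no
  provable pruning (dead-end elimination) before enumeration — spaces are
  expected to be desk-scale.
- Protonation states are fixed template choices, not predicted.
- The probability model scores only substitutions (no indels) and assumes
  signature catalogs and weights are given, not fitted.
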