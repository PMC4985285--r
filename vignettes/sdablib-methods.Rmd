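---
title: "Models and methods behind sdablib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sdablib}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdablib)
```

This vignette is the package's own account of its science: the models it
implements, the defaults it commits to and why, what the synthetic-data
generator does and does not emulate, and the numerical choices a
maintainer would want written down. It states no empirical result that the
test suite or the acceptance script does not itself compute.

## The scaffold model

A single-domain antibody is modelled as seven contiguous segments,
FR1–CDR1–FR2–CDR2–FR3–CDR3–FR4, on scaffold-local, 1-based sequential
numbering. We deliberately do not commit to Kabat or IMGT numbering: the
hallmark positions the package protects (42, 49, 50, 52 in framework 2,
and Q103) are defined on the scaffold's own coordinates, and a user with a
differently numbered scaffold can supply a position alias through a custom
region map. Region maps store 1-based inclusive coordinates; conversion to
half-open slicing happens internally.

The packaged `baseline_scaffold()` is a **synthetic stand-in**, not a
published sequence. Its framework lengths are realistic for a VHH
(FR1 = 25, FR2 = 20, FR3 = 44, FR4 = 11 aa; 126 aa total with a
12-residue CDR3), it carries the canonical cysteine pair (positions 22 and
89) and llama-type framework-2 hallmarks F42/E49/R50/G52 plus Q103.
Two constraints fixed the map: hallmark Q103 must sit inside a framework
region (we place it at the last position of FR3), and FR4 must be long
enough (11 aa = 33 nt) to act as a usable alignment anchor during QC.
Together with the fixed CDR1/CDR2 length of 7 these force the 126-aa
total; a shorter map would either push Q103 into CDR3 or shrink FR4 below
anchor-worthy length.

Humanization is a substitution rule set applied to framework positions
only. The default rule set performs exactly seven substitutions and
protects five additional divergent framework positions; because the true
identity of such substitutions is scaffold-specific, the default is a
package convention and the rule set is fully user-configurable. Hallmark
positions are *always* protected, and the invariant is re-validated after
every `humanize()` call. Consensus derivation takes the per-column modal
residue with ties broken alphabetically by one-letter code — documented,
deterministic, and verified in the tests against a brute-force counter.

## Diversity design

Each CDR position carries a categorical distribution over the 20 canonical
amino acids (sum to 1 within 1e-9; banned residues exactly 0). The default
design follows the stated rules of rational single-domain library design
rather than any particular published frequency table (those exist only as
figures, not numbers):

* **CDR1/CDR2** (7 positions each) use a natural-repertoire-shaped profile
  (S/G/Y/T-rich, the composition typical of camelid loops).
* **CDR3** uses near-uniform profiles and a uniform length mixture over
  {9, 12, 15, 18} aa. The observed mixture of a real run can be supplied
  instead.
* **Cysteine is banned** at every CDR position.
* **Hydrophobic mass** on {F, I, L, V, W, M} is capped at 0.15 per
  position by proportional down-scaling followed by renormalization. The
  set and cap are configuration — the authors' exact values are not
  printed anywhere — and 0.15 was chosen once as a value that markedly
  reduces aggregation-prone composition while leaving all six residues
  available.

Profiles become DNA through **trinucleotide codon mixes**: one preferred
*E. coli* codon per residue, so the translated distribution of the mix
equals the designed profile exactly (asserted to 1e-12) and stop codons
are structurally impossible. A degenerate `nnk_codon_mix()` is provided
purely for comparison; it is explicitly allowed to violate the no-stop and
no-Cys guarantees, which is the point of the comparison.

Sequence-space sizes are computed in exact arbitrary-precision integer
arithmetic (a small internal base-10^4 big-integer, since support sizes
are at most 20 — no GMP dependency) and verified against exhaustive
enumeration on toy designs. Collision (redundancy) probabilities use the
exact birthday product `1 − prod(1 − i/N)` evaluated stably as
`-expm1(sum(log1p(-i/N)))`; the test suite checks it against an
independent double-double (≈32 significant digits) product oracle.

## The synthetic-data generator: a stated world

`generate_library()` draws clones i.i.d. from the design and realizes DNA
through the codon assignment. The defect machinery injects the four
classes observed in synthetic library construction:

* `in_frame_stop` — one sense codon replaced by a random stop codon;
* `frameshift` — exactly one base deleted;
* `missing_region` — the CDR1 span, or the CDR1-through-CDR2 span
  (including the intervening FR2), excised; the two variants are chosen
  50/50;
* `empty` — the insert replaced by a fixed synthetic stuffer standing in
  for a ccdB-style suicide-gene placeholder (no scaffold anchors).

Defect positions are uniform within an eligible span that **excludes the
FR1 and FR4 anchors**. This is a deliberate soundness choice: it keeps
every defect class verifiable from the emitted DNA alone by an independent
translate-and-align oracle, which the tests exploit (a stop codon that
destroyed an anchor would be indistinguishable from a missing anchor).

`make_sanger_fixture()` emulates the Sanger-scale QC of a library build:
315 clones, 13 defective. Only the total of 13 is an external fact; the
per-class split (4 stop / 4 frameshift / 3 missing region / 2 empty) is a
fixture convention chosen to exercise every class. The fixture is pinned
to a seed and byte-identical across runs.

Read emission supports strand flipping, substitutions and indels at
configurable rates. It does **not** model homopolymer-length errors (the
signature error mode of semiconductor sequencing), PCR chimeras, or
quality-score structure: a green QC test therefore establishes correctness
of the annotation/classification logic under generic noise, not platform
realism. Sequencing depth is a free parameter throughout — the generator
takes whatever read count the caller requests.

Cytometry events are two-channel log-normal mixtures with truth labels;
panning is multiplicative per-round enrichment with renormalization.
Both are intentionally minimal: enough structure to validate the assay
statistics (median ratios are recovered within quantile sampling error;
dominance crosses 0.5 at the closed-form geometric-growth round), nothing
more.

## Sequencing QC

Annotation anchors each read to the scaffold's framework DNA on either
strand. Anchor search runs in three tiers, cheapest first: exact
fixed-string match; a substitution-only Hamming scan; and an
indel-tolerant alignment. The middle tier exists because indel-tolerant
matchers may return an indel-shortened range even when a pure-substitution
alignment exists, which would corrupt CDR boundaries; the Hamming tier
pins the anchor width (and hence the CDR spans) whenever the read carries
only substitutions.

The per-anchor edit tolerance defaults to `max(2, ceiling(0.08 * anchor
length))`. A fixed tolerance of 2 edits was considered and rejected: at a
realistic 1% per-base error rate a 132-nt FR3 anchor accumulates more
than 2 errors in ~14% of reads, which would cap CDR recovery far below
the ≥99% the package aims for; scaling with anchor length keeps long
anchors findable and short anchors specific. The tolerance remains a
user-settable argument.

Defect classification follows a committed precedence order (the taxonomy
itself has no inherent order): **empty** (no anchors at all) →
**frameshift** (FR1-to-FR4 spacing not a multiple of 3) →
**missing_region** (spacing a whole number of codons short of every
designed length) → **in_frame_stop** (stop codon in frame between the
anchors) → **ok** (all spans present with designed lengths). Contradictory
evidence yields `unclassified`, never a silent ok, and the class counts
always partition the read set.

Unique-clone collapsing defaults to the protein level — "independent
binders" are sequence-distinct antibodies, and synonymous DNA variants
should merge — with DNA- and CDR3-level grouping available. Design-versus-
observed frequency comparisons are reported as per-position
total-variation distance rather than chi-square p-values: the distance is
symmetric, bounded in [0, 1], needs no multiple-testing machinery, and is
directly checkable against `0.5 * sum(|p − q|)`.

## Kinetics

The simulator evaluates the piecewise closed form of the 1:1 Langmuir
model across the single-cycle schedule, carrying the bound level across
phase boundaries; the test suite requires agreement with an independent
RK4 integration of `dR/dt = kon·C·(Rmax − R) − koff·R` to within 1e-6 RU.
Default sampling is 1 Hz. Bulk refractive-index steps are modelled as
per-injection additive constants during association only, zero by default,
and cancel under reference subtraction — they carry no off-rate
information. An optional bulk term can be floated in the fit
(`fit_bulk = TRUE`), off by default since published single-cycle fits do
not document one.

Fitting runs in log-parameter space because the rates span orders of
magnitude (kon ~ 10^4–10^6 1/(M·s), koff ~ 10^-5–10^-3 1/s). Initial
values come from a documented heuristic: koff from the log-linear slope of
the terminal dissociation, Rmax from three times the response span, kon
from the initial association slope divided by `C·Rmax`. The primary
optimizer is `nls(algorithm = "port")`; on failure the same objective is
polished by Nelder–Mead then BFGS, and non-convergence raises an error
with diagnostics rather than returning a best-so-far. Every fit carries
the invariant `kon·KD = koff` to 1e-12 relative. Mass-transport limitation
is not modelled — the target model is pure 1:1 Langmuir.

## Assay statistics

Knockdown is the ratio of **medians** (not means) of GFP fluorescence in
the transfected versus untransfected gates, as a percentage; medians use
the midpoint convention on even counts, making the statistic scale-free in
GFP. The mCherry gating threshold is a required argument — there is no
universal value. Differential ELISA calls require both a floor (minimum
absolute signal) and a fold-ratio threshold (default 2); both are
configuration, since "differential in favor of" is a rule shape, not a
number. Replicate-level significance testing is out of scope.

## What a green test establishes

The tests prove internal consistency of a stated world: designed mixtures
are recovered by QC within multinomial bands, defect truth labels are
recovered perfectly at zero noise, kinetic parameters are recovered to
<1% from noiseless traces and KD to <10% median error at 1 RU of noise.
They cannot establish anything about wet-lab quantities — actual library
sizes, real defect spectra, binding constants of real antibodies — which
enter only as worked examples on printed rate constants.

## Known limitations

* The baseline scaffold and humanization rules are synthetic conventions,
  not published sequences; users with real scaffolds must supply them.
* Anchor-based annotation assumes the frameworks are approximately intact;
  heavily corrupted reads fall into `unclassified` rather than being
  rescued by global alignment.
* The read simulator's error model is substitution/indel only.
* Exact big-integer arithmetic covers products of factors ≤ 20 and sums,
  which is all the design space calculation needs; it is not a general
  bignum library.
* `fit_1to1` fits a single analyte series; heterogeneous-ligand or
  bivalent models, and multi-cycle protocols with regeneration, are out of
  scope.
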