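---
title: "Open modification search and PTM mapping with h1ptm: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Open modification search and PTM mapping with h1ptm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h1ptm)
```

## The problem

Linker histones (H1) are among the most heavily modified proteins in the
cell. Mapping their post-translational modifications (PTMs) by bottom-up
mass spectrometry means digesting the protein with several proteases,
fragmenting each peptide (HCD), and reading two signals from every spectrum:
the *precursor delta mass* — the difference between the observed neutral
peptide mass and the theoretical unmodified mass — and the *fragment
ladder*, which places that delta on a specific residue. h1ptm implements
this chain as small, separately tested stages, and ships a synthetic-data
generator so that the whole pipeline can be validated against planted
ground truth without any instrument files.

## Mass conventions

All peptide and fragment arithmetic is monoisotopic, computed from isotope
masses stored to at least 7 decimals (C = 12 exactly, H = 1.0078250,
N = 14.0030740, O = 15.9949146, P = 30.9737616, S = 31.9720707; proton
1.0072765 for m/z). This precision is required: the methylpyrroline
composition C₆H₇NO must evaluate to 109.052764 Da at 6 decimals. Intact
protein work instead uses average (abundance-weighted) masses, matching the
linear-mode MALDI-TOF measurements it emulates; the two scales are never
mixed. Residue masses are derived from elemental compositions rather than
stored as numbers, which guarantees the monoisotopic < average invariant
and keeps the two tables consistent by construction.

Isopeptide amino-acid adducts (K, KV, KH) are modelled as sums of *residue*
masses with no terminal water — a branch attached through the lysine
side-chain amine, consistent with their interpretation as remnants of a
branched polypeptide.

## Digestion

Four proteases are supported with deterministic rules: trypsin (C-terminal
to K/R), Arg-C (C-terminal to R), thermolysin (N-terminal to L, I, A, F, V,
M) and pepsin (C-terminal to F/L). Two choices deserve comment:

* The "not before proline" (Keil) suppression is applied for trypsin and
  Arg-C. It is the standard search-engine behaviour, and it is exposed as a
  flag (`keil = FALSE` restores naive cleavage).
* Pepsin genuinely cleaves only *preferentially* at F/L. A probabilistic
  digest is not reproducible, so the rule is implemented strictly; users who
  need broader specificity can digest with several rule sets and pool.

Coordinates are 1-based and *Met-inclusive*: mature H1 chains lack the
initiator methionine, but published site labels (K70, K89, T59, ...) count
it, so position 1 is reserved for the absent Met and the mature chain starts
at 2. Keeping a single frame everywhere removes a whole class of off-by-one
errors; `digest()`, `classify_site()`, the maps and the motif finder all
speak this frame.

## Fragmentation

Only b, y and internal (b-type, doubly cleaved) ions are generated — the
series actually observed in HCD spectra of these peptides; a/c/z ions are
deliberately absent. The full-length b_n acylium ion is included. Internal
ions are generated for peptides of at least 5 residues with spans capped at
12 residues to bound the combinatorics. Neutral-loss channels (H₃PO₄, HPO₃)
are attached only to phospho-bearing fragments; the 63.96 Da loss observed
from phosphoglycerol-bearing b ions is carried as a channel labelled
*unassigned* — its mass matches SO₂ to 0.002 Da, but it could not be
attributed to any part of a phosphoglycerol group, so no assignment is
claimed.

Fragment correctness rests on a conservation identity — for singly charged
ions of an n-mer, b_i + y_(n−i) − 2·m_proton equals the neutral peptide
mass — which the test suite checks for randomly modified random peptides.

## Spectrum matching

MGF is the only spectrum format (a strict, line-number-reporting parser and
a lossless writer). Matching is greedy nearest-match under a dual
tolerance: ppm (default 10) capped by an absolute window (default 0.01 Da,
the working accuracy of the emulating instrument), whichever is tighter at
that m/z. Ties go to the smaller |error|, then the lower observed m/z, and
each observed peak is used at most once.

## Open search and localization

For each spectrum the delta is computed against every digest peptide;
candidates inside the delta window are ranked by a fast count of b/y ladder
masses (unshifted or delta-shifted) found in the spectrum, and the winner is
fully annotated with *both* hypotheses per fragment. Localization brackets
the site: unshifted b ions push it right, shifted b ions cap it, y ions act
symmetrically, shifted internal ions shrink the interval, and unshifted
internal ions trim its edges. A fragment matched in both its shifted and
unshifted form marks the ladder contradictory: the result is flagged
ambiguous with the maximal interval — never an exception, and never a
silently guessed site. A site is reported only when the interval collapses
to a single residue, which by construction requires a shifted/unshifted
bracketing pair on each side unless the site is terminal.

One degeneracy needs explicit handling. When the delta equals a residue
mass — exactly the situation for the K/KV/KH adducts on lysine-rich
sequences — a shifted b_i coincides with the unshifted b_(i+1) whenever
residue i+1 is that residue, and a single observed peak cannot arbitrate
between the two hypotheses. Such aliased hypothesis pairs are masked before
matching: neither votes in the bracket. The cost is honest — localization
of a lysine adduct flanked by further lysines widens to an interval — and
the alternative (letting an arbitrary tie-break decide) produces false
contradictions. This is also why site-exact recovery of planted adducts is
not expected to be perfect even with complete ladders.

The refined modification mass is the unweighted mean of per-ion shifts over
matched fragments with m/z ≤ 800 Da (falling back to all ions when none
qualify). The cutoff value is a package choice: resolution increases toward
low m/z, the preference is qualitative, and 800 Da keeps several ions in
the average for typical tryptic peptides. A weighted mean was considered
and rejected as implying an error model the data do not support.

Registry matching reports *all* candidates within tolerance (default
0.01 Da) whose target set contains the localized residue, sorted by |error|
— no winner-takes-all, since near-isobaric pairs (dimethyl vs formyl,
0.036 Da apart) are exactly the cases a reader needs to see ranked.

## Composition enumeration

For deltas that match no known modification, `enumerate_compositions()`
searches CHNO (CHNOPS by flag) exhaustively within a tolerance window. The
plausibility filters are: integer RDBE ≥ 0 (half-integer RDBE means an
odd-electron/radical composition, excluded unless `allow_radical = TRUE`),
H ≤ 2C + 2 + N, O/C ≤ 1.2, N/C ≤ 1.3 (ratio caps applied when C > 0), and
N ≤ 3 by default — compositions with four or more nitrogens are treated as
unrealistic at these masses. Hydrogen counts are solved from the mass
remainder rather than looped, which makes the search effectively
instantaneous; the test suite proves equivalence against a naive
quadruple-loop oracle.

Two documented caveats:

* Reproducing C₈H₁₄NO₂ as the top candidate for the 156.1016 Da shift
  requires `allow_radical = TRUE` (its RDBE is 2.5) and `n_max = 4` to also
  see the arginine-residue composition C₆H₁₂N₄O. Standard isotope masses
  place C₈H₁₄NO₂ about 0.0009 Da from 156.1016, not 0.0003 Da.
* For 84.020 Da a naive CHNO search does return a candidate within ~0.001
  Da (C₄H₄O₂, RDBE 3); the original analysis nevertheless reported no
  plausible assignment, presumably applying chemical criteria beyond these
  filters. The package reports what its documented filters admit.

## Intact-mass assignment

`match_intact()` compares deconvoluted masses against candidate variants at
a relative tolerance of 0.2% (linear-mode accuracy); this window also
absorbs the ±42 Da ambiguity of an (un)acetylated N-terminus, which the
measurement cannot resolve. Satellite peaks (e.g. ~190 Da above a main
peak) are forwarded to `suggest_mod_combinations()`, which enumerates
multisets of up to 3 registry deltas.

## The synthetic-data generator

`sim_config()` fixes the emulated study conditions: Gaussian m/z error with
`ppm_sigma = 3` (Orbitrap-like MS/MS accuracy), fragment peak dropout 0.1,
10 uniform noise peaks per spectrum at the 10th percentile of signal
intensity, tryptic digestion with one missed cleavage, peptide lengths
6–30, precursor charges 2+ (70%) and 3+ (30%), singly charged fragment
ladders. Proteins are built to the H1 architecture — an acidic Ser/Thr-rich
N-terminal domain starting with serine, a ~70-residue globular core, and a
lysine-rich C-tail (30% K) with embedded S/TPxK motifs — with the initiator
Met removed and Met-inclusive numbering. Modification sites are drawn
respecting residue targets at about 3 expected sites per 100 residues.
Intensities follow a rank-based exponential decay with no physical meaning;
nothing downstream uses intensity for inference, mirroring the mass-centric
procedure the package implements.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: chromatographic behaviour and co-isolation/chimeric
spectra, intensity structure and detector saturation, deamidation-scale
artefacts, incomplete/nonspecific cleavage, multiply modified peptides
(spectra are emitted only for peptides carrying exactly one planted site,
so every spectrum has a single ground-truth record), and modified residues
blocking protease cleavage.

Determinism: identical configuration and seed give byte-identical FASTA and
MGF output; all randomness flows through the single seed.

## Validation summary

The test suite asserts, among others: digestion equals a brute-force
substring oracle on random sequences; composition enumeration equals a
quadruple-loop oracle; b/y complementarity holds to 1e-9 Da; on noiseless
synthetic data the pipeline recovers 100% of planted modifications with
exact masses and sites; at 3 ppm / 10% dropout (fixed seed, 6 proteins,
~25 modified spectra) recovery — top-1 registry identification *and*
site-exact localization — is at least 90%; and the bundled synthetic
variant stand-ins reproduce their target intact masses within 0.2%. The
problem sizes (4–6 proteins for end-to-end runs, 70 proteins for the
error-distribution check) are chosen so the whole suite runs in well under
a minute on a single core while keeping the statistical checks
well-powered.

## Known limitations

* The delta-mass search assigns one global delta per spectrum; peptides
  carrying two different modifications are outside the model.
* No probabilistic localization score and no target–decoy FDR: evidence is
  reported as ion counts and intervals, and thresholds are the analyst's.
* Strict cleavage rules for pepsin/thermolysin are an idealization.
* The bundled variant sequences are synthetic stand-ins: tests against them
  validate mass arithmetic and assignment plumbing, not database identity.
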