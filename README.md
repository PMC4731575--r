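# h1ptm

Discovery and mapping of post-translational modifications (PTMs) on
lysine-rich proteins, modelled on the bottom-up proteomics workflow used to
characterize the linker histones (H1) of *Arabidopsis thaliana*. The package
is aimed at proteomics analysts who want a transparent, fully testable
re-implementation of an open (delta-mass) modification search: from in-silico
multi-protease digestion through HCD fragment annotation to site-localized
modification maps — exercised end-to-end on synthetic, ground-truthed
spectra rather than vendor raw files.

## What it computes

For a peptide assigned to a spectrum, the **precursor delta mass**

    Δ = (m/z_prec − m_proton) · z − M_peptide

is read as the total modification mass. The site is then bracketed from the
fragment ladder: every matched unshifted b_i pushes the site to the right of
i, every b_i carrying the full Δ caps it at i, symmetrically for y ions, and
internal (doubly cleaved) ions shrink the interval further. The modification
mass is refined as the arithmetic mean of per-ion shifts over fragments with
m/z ≤ 800 (Orbitrap resolution increases as m/z decreases, so low-mass ions
are preferred), then matched against a registry of histone PTMs —
phospho (HPO₃, +79.96633), acetyl (C₂H₂O, +42.01056), methyl/dimethyl,
formyl (distinguished from dimethyl by their 0.036 Da gap), crotonyl,
propionyl, methylpyrroline (C₆H₇NO, +109.052764), phosphoglycerol
(C₃H₇O₅P), isopeptide amino-acid adducts (K, KV, KH — sums of residue
masses), and bare-mass unknowns.

Unknown deltas are handed to an exhaustive CHNO(PS) composition search with
chemical plausibility filters: integer ring-and-double-bond equivalents
RDBE = C − H/2 + N/2 + 1 ≥ 0 (half-integer = radical, excluded by default),
H ≤ 2C + 2 + N, O/C ≤ 1.2, N/C ≤ 1.3, and at most 3 nitrogen atoms.
Intact (linear-mode MALDI-like) masses use average masses and are assigned
to sequence variants, with satellite peaks explained as combinations of
registry modifications.

## Worked example

Simulate a small H1-like study (3 proteins, modifications planted at known
sites, 3 ppm mass error, 10% peak dropout), run the open search, and build
the modification map:

```r
library(h1ptm)

cfg <- sim_config(seed = 3, n_proteins = 3)
sim <- simulate_study(cfg)
res <- discover_ptms(sim$spectra, sim$proteins, registry = cfg$registry,
                     protease = cfg$protease, max_missed = cfg$max_missed,
                     min_len = cfg$min_len, max_len = cfg$max_len)
rec <- evaluate_recovery(res, sim$truth)
cat("planted", rec$n_planted, "recovered", rec$n_recovered, "\n")
#> planted 16 recovered 16

build_map(res[res$site_specific & res$modified, ])
#> <modification_map> 16 modified position(s) on 3 protein(s)
#>  protein_id position residue domain         classes n_spectra
#>    SYNH1.01       99       S    GH1 phosphoglycerol         1
#>    SYNH1.01      112       S    GH1 phosphoglycerol         1
#>    SYNH1.01      133       T    CTD methylpyrroline         1
#>    ...
```

All 16 planted modifications are recovered: each spectrum's top registry hit
names the planted PTM and the localization interval collapses to the exact
planted residue (positions are Met-inclusive, i.e. the numbering counts the
absent initiator methionine as residue 1).

The composition search reproduces the key identification argument for the
109.05248 Da delta — within 0.01 Da there is no plausible CHNO alternative
to methylpyrroline:

```r
enumerate_compositions(109.05248, tol = 0.01)
#>   formula c h n o p s     mass        diff    abs_diff rdbe radical
#> 1  C6H7NO 6 7 1 1 0 0 109.0528 0.000283849 0.000283849    4   FALSE
```

A command-line front-end for digestion, composition search, intact-mass
assignment, simulation and searching lives in `inst/scripts/h1ptm-cli.R`.

## Scope notes

The bundled FASTA (`inst/extdata/synthetic_h1_variants.fasta`) contains
**synthetic** H1-like stand-in sequences constructed to the domain
architecture and intact masses of the three studied variants; they are not
database sequences. The package implements a transparent delta-mass search,
not a Mascot-style probabilistic scoring engine, and does not attempt FDR
estimation, isotope-pattern prediction or intensity modelling; see the
methods vignette (`vignettes/h1ptm-methods.Rmd`) for the full list of
assumptions and limitations.
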