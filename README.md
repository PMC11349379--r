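# xlinkfit

Cross-link distance validation and desk-scale rigid-body density fitting
for polymeric protein assemblies, with a fully synthetic two-state
benchmark generator.

## The problem

Intraflagellar-transport (IFT) trains are polymers of two multi-subunit
complexes (IFTA and IFTB) that exist in two radically different
conformations: a compact stacked polymer (two sub-polymers with ~115 Å
and ~65 Å repeats) and an extended 2-fold-symmetric polymer (~450 Å
visible repeat, one IFTA + two IFTB complexes per repeating unit).
Validating models of such assemblies against in-situ cross-linking mass
spectrometry (XL-MS), and building them by fitting rigid subcomplexes
into low-resolution cryo-ET density, both require careful multi-copy
bookkeeping that generic structure tools do not provide. `xlinkfit`
implements that computational core for R:

* **Cross-link validation.** A residue-pair cross-link `(P1, r1)–(P2, r2)`
  is mapped onto *every* copy of the proteins in the assembly; the link
  distance is the minimum Cα–Cα distance over all copy pairs,

  `d(link) = min over copies (i, j) of || Cα_i(P1, r1) − Cα_j(P2, r2) ||`,

  classified *satisfied* iff `d < 35` Å (the conventional Cα–Cα bound for
  a DSSO-linked lysine pair, strict inequality), with violated links
  rescued when an endpoint residue has prediction confidence (pLDDT)
  below 50. Two conformational states are compared link by link
  (`Δ = d_B − d_A`).
* **Burial differential.** Shrake–Rupley SASA (960 deterministic sphere
  points, 1.4 Å probe) per residue in full assembly context; residues
  accessible in one state (relative accessibility ≥ 0.25) and buried in
  the other (< 0.10) form the state-specific surface sets, clustered
  into spatial patches.
* **Rigid-body fitting.** Density simulated as per-atom Gaussians
  (σ = resolution / 2√(2 ln 2)); clustered fit libraries (80 000
  positions, 4° / 3 Å clustering, inside threshold 0.3 by default) and
  Metropolis simulated annealing over the weighted restraint score
  (connectivity 1, cross-link 30, discrete 10000, excluded volume 10,
  EM 1000; six-stage schedule 75000/1000 … 300/300), plus the
  score-histogram convergence diagnostic.
* **Synthetic truth.** `generateTwoState()` builds both polymer states
  with planted cross-links (known satisfied/violated status per state),
  planted flexible segments, exact C2 symmetry, and simulated maps, so
  every stage is tested against known ground truth.

Formats: PDB/mmCIF models (bio3d), xiFDR-style residue-pair CSV,
MRC/CCP4 maps, YAML chain maps and configs, TSV reports, ChimeraX
pseudobond files.

## Worked example

```r
library(xlinkfit)

## two-state synthetic train: 5 repeating units, 40 planted cross-links
g <- generateTwoState(syntheticSpec(seed = 1))

## validate the links on the extended state
rep <- validateCrossLinks(g$modelB, g$map, g$xlinks)
table(rep$status)
#> satisfied  violated
#>        38         2

## compare the two states link by link
cmp <- compareStates(g$modelA, g$modelB, g$map, g$map, g$xlinks)
summary(cmp$delta)

## geometry of the extended train
trainMetrics(g$modelB, g$map)[c("stoichiometry", "unitSpacing")]
#> $stoichiometry
#> [1] 2
#> $unitSpacing
#> [1] 225
contactGraph(g$modelB, g$map, cutoff = 8)$degrees
#>   unit degree
#> 1    1      2
#> 2    2      3
#> 3    3      4
#> 4    4      3
#> 5    5      2
```

38/40 links satisfied (the planted 95%), 2:1 IFTB:IFTA stoichiometry, a
225 Å repeating-unit spacing (two units per 450 Å visible repeat) and a
central repeating unit contacting four neighbours — the structural
signature of the extended train.

The same stages run from the shell:

```sh
inst/scripts/xlinkfit synth    --out run/synth --seed 1
inst/scripts/xlinkfit validate --out run/val \
    --model run/synth/modelB.cif --chainmap run/synth/chainmap.yaml \
    --xlinks run/synth/xlinks.csv --threshold 35 --plddt-cutoff 50
```

Each run writes its effective config (`config.used.yaml`) and a log next
to its outputs.

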