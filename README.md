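# rexdmd

Replica-exchange discrete molecular dynamics for helical propensity
profiling of intrinsically disordered proteins.

Intrinsically disordered proteins (IDPs) have no stable fold, yet many carry
*pre-structured motifs* (PreSMos): short stretches that transiently form
alpha-helix in the unbound state and frequently coincide with the elements
that fold upon binding a partner. `rexdmd` is a self-contained toolkit for
detecting such motifs by simulation, aimed at structural bioinformaticians
who want a desk-scale, fully reproducible pipeline:

1. **Model building** — a coarse-grained four-bead chain (N, CA, C, CB;
   glycine lacks CB) built from a FASTA sequence, with covalent geometry as
   hard distance windows and a fully extended start conformation.
2. **Event-driven (discrete) dynamics** — between collisions beads fly
   ballistically; the engine advances from one shell-boundary crossing of the
   stepwise (square-well) force field to the next, resolving each with exact
   momentum/energy conservation, under an Andersen-style thermostat (heat
   exchange factor HEX). The helix-stabilising interaction is a
   sequence-weighted i&rarr;i+4 hydrogen-bond well of depth
   `hb_eps * w(aa_i) * w(aa_i+4)` gated on the bridged torsions, so only
   right-handed helical turns are rewarded.
3. **Replica exchange** — N replicas at a temperature ladder (default:
   8 rungs, 0.5246&ndash;0.6862 reduced units) with Metropolis swaps
   `p = min(1, exp[(1/T_i - 1/T_j)(E_i - E_j)])` between adjacent rungs every
   1,000 tu; frames every 200 tu, so a 1,000,000 tu production run yields
   exactly 5,000 frames per replica, regrouped by temperature for analysis.
4. **Ensemble analysis** — phi/psi torsions (IUPAC convention), per-residue
   helical propensity (fraction of frames with phi in (-100, -30) and psi in
   (-80, -5)), per-frame continuous-helix maps, Ramachandran region
   occupancies, CA radius of gyration, and density-of-states surfaces
   `DoS = -kT ln P(Rg, E)`.
5. **PreSMo calling** — regions with propensity &ge; 20% are called and
   matched against reference annotations by the boundary rule (both ends
   within &plusmn;2 residues) or significant overlap (&ge; half of the
   shorter interval).

All quantities are in reduced units (k = 1); no physical calibration of the
time or temperature scale is implied. The methods vignette
(`vignettes/methods.Rmd`) documents the model, every default parameter, and
the design decisions.

## Worked example

A reduced-length run on a 30-residue polyalanine (the full production
protocol is the same code with `total_duration = 1e6`, `swap_every = 1000`,
`save_every = 200`):

```r
library(rexdmd)

seq  <- residue_seq(strrep("A", 30), name = "polyA30")
topo <- build_topology(seq)
ff   <- compile_forcefield(topo)
conf <- minimize(build_extended(topo), ff, seed = 1)

rx <- run_rx(conf, ff, total_duration = 2000, swap_every = 100,
             save_every = 20, seed = 1)
print(rx)
#> <rx_run> 8 replicas, 2000 tu, 70 swap attempts, mean acceptance 0.714

ens  <- demux_by_temperature(rx)
prof <- propensity_profile(ens[["T0.5246"]])
round(prof$propensity[10:16], 3)
#> [1] 0.17 0.08 0.18 0.36 0.31 0.32 0.33

calls <- call_regions(prof, threshold = 0.20)
calls
#>   start end peak  mean temperature
#> 1    13  16 0.36 0.330      0.5246
#> 2    22  27 0.47 0.375      0.5246

ref <- data.frame(name = "polyA30", start = 5L, end = 26L)
match_regions(calls, ref)
#> <match_report> 1 of 1 reference regions detected (100.0%), 1 extra predictions
#>      name start end matched    rule pred_start pred_end
#> 1 polyA30     5  26    TRUE overlap         22       27
```

Reading the output: at the coldest rung the chain is partly helical (the
71% swap acceptance says the ladder is well spaced for this chain); two
regions exceed the 20% propensity threshold at this short run length, and
the synthetic reference interval 5&ndash;26 is matched through the overlap
rule by the 22&ndash;27 call. At production length the polyalanine interior
helicises much more uniformly.

A command-line wrapper over the same functions ships at `inst/cli/rexdmd`
(subcommands `run`, `analyze`, `call`, `compare`, `fixtures`); every stage
logs the seed and the configuration/force-field checksums, and re-running a
stage with the same seed reproduces byte-identical outputs.

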