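# morphoswitch

Modelling tools for a synthetic morphogen-interpretation circuit: an
*E. coli* toggle switch ("Exclusive Receiver") in which two diffusible
quorum-sensing signals — 3O-C6-HSL (**C6**, sensed by LuxR) and 3O-C12-HSL
(**C12**, sensed by LasR) — drive two mutually repressing pathways
(C6 → CFP + LacI, C12 → YFP + TetR; LacI ⊣ LasR, TetR ⊣ LuxR). The package
is for synthetic and systems biologists who want to ask, quantitatively:
*when do transient, dynamic signal gradients leave behind stable, sharp
domains of gene expression?*

The answer implemented here is the hysteresis argument: mutual inhibition
makes single cells bistable over a region of (C6, C12) space, and a lawn of
such cells exposed to transient antiparallel gradients forms a boundary
that is **stable whenever the spatial-average concentrations fall inside
the single-cell bistable region** — because diffusion carries every
position's local environment to the spatial average, and cells arrive there
with different histories.

## The model

Each cell follows six ODEs (concentrations in a.u., time in hours),

```
luxR' = b_R + a_R · K_tet^n / (K_tet^n + tetR_eff^n) − γ_R · luxR
lasR' = b_R + a_R · K_lac^n / (K_lac^n + lacI_eff^n) − γ_R · lasR
lacI' = cfp' + (γ_cfp·cfp − γ_lacI·lacI)        (shared production)
cfp'  = b_F + a_F · A6  − γ_cfp · cfp,   A6  = (luxR/luxR_ref) · c6^n/(K6^n + c6^n)
tetR', yfp' symmetrically with A12 = (lasR/lasR_ref) · c12^n/(K12^n + c12^n)
```

with `lacI_eff = lacI · K_iptg²/(K_iptg² + IPTG²)` (and likewise TetR/aTc).
On a lawn, C6 and C12 obey 1-D no-flux diffusion (Crank–Nicolson), relay
variants add a production term `k_relay · A6` to the partner signal, and
every grid point runs the cell model with its local signals.

Modules: circuit model & integrator (`derivatives`, `integrate_circuit`),
bistability analysis (`find_equilibria`, `continue_branch`,
`map_bistable_region`, `hysteresis_protocol`), spatial simulation
(`make_antiparallel_ic`, `simulate_rd`, `simulate_relay`,
`phase_trajectories`), boundary classification (`normalize_channels`,
`locate_boundary`, `classify_boundary`), inference (`promoter_activity`,
`fit_stage`, `staged_inference`), and synthetic data (`generate_plate`,
`generate_flow`, `generate_kymograph_fixture`).

## Worked example

Static vs moving expression boundaries under transient antiparallel
gradients (compare the two spatial-average conditions):

```r
library(morphoswitch)

p   <- default_params()                       # calibrated, solid-culture phase
cfg <- spatial_config(t_end = 24, iptg = 10)  # 6 mm lawn, D = 0.36 mm^2/h

run <- function(avg_c6, avg_c12) {
  ic <- make_antiparallel_ic(avg_c6, avg_c12, source_fraction = 0.25,
                             config = cfg)
  tr <- locate_boundary(normalize_channels(simulate_rd(cfg, p, ic)))
  print(tr); print(classify_boundary(tr))
}
run(200, 2000)   # averages inside the bistable region
run(20, 2000)    # averages outside
```

This prints (output from the code as shipped):

```
<morpho_boundary_trace> detected at t = 9 h, last valid t = 24 h, delta_beta = 0.0329 mm (0.5% of L)
<boundary> label = S, dominant = YFP, delta_beta = 0.5% of domain
<morpho_boundary_trace> detected at t = 4.75 h, last valid t = 22.5 h, delta_beta = 1.67 mm (27.9% of L)
<boundary> label = N, dominant = YFP, delta_beta = 27.9% of domain
```

At averages (200, 2000) nM the equal-fluorescence boundary moves only 0.5%
of the domain over 24 h — a **static** (S) boundary, below the 10% Δβ
stability criterion. At (20, 2000) nM the boundary drifts 27.9% of the
domain toward the C6 source and is gone by the end of the timelapse
(**N**, YFP dominant): the early CFP stripe near the C6 source is
overwhelmed once C12 arrives, because the homogenised environment is
monostable-YFP.

Where the single-cell bistable region lies, and why those two conditions
differ, can be checked directly:

```r
bm <- map_bistable_region(log_grid(n = 12), p, iptg = 10)
sum(bm$bistable)      # 12x12 cells with two stable states
```

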