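# fueldrops

Chemically fueled peptide–RNA coacervate droplets, as a tested R pipeline.

Membraneless organelles are liquid–liquid phase-separated droplets whose
assembly and disassembly are driven by chemical reactions. A minimal
synthetic counterpart couples complex coacervation between a short cationic
peptide and RNA (poly-U) to a carbodiimide reaction cycle: a chemical fuel
(EDC) converts the +1-charged precursor peptide into a +3-charged transient
anhydride product that coacervates with the RNA, while spontaneous
hydrolysis deactivates the product again. Droplets therefore emerge when
fuel is added and decay when it runs out. `fueldrops` implements the
quantitative analysis of that system for chemists and biophysicists working
on dissipative self-assembly and active droplets: the reaction-cycle
kinetics, their calibration, the two-phase (droplet vs dilute phase) mass
balance, phase-regime classification, and droplet micrograph statistics —
plus seeded synthetic-data generators for every input, so each estimator
can be validated against known ground truth.

## The model

Five species in a well-mixed volume, concentrations in mM, time in
minutes: fuel F (EDC), precursor P, O-acylisourea intermediate I,
anhydride product A, waste W (EDU). The rate laws are

    dF/dt = -k0 F - k1 F P
    dP/dt = -k1 F P + k3 I + k4 A
    dI/dt =  k1 F P - (k2 + k3) I
    dA/dt =  k2 I - k4 A
    dW/dt =  k0 F + (k2 + k3) I

i.e. direct fuel hydrolysis (k0), activation of the precursor by fuel
(k1), partitioning of the intermediate between anhydride formation (k2)
and futile hydrolysis (k3), and anhydride deactivation (k4). Peptide
(P + I + A) and carbodiimide (F + I + W) totals are conserved; every
integration is checked against both balances at 1e-6 relative tolerance.

Around the cycle sit the derived quantities the experiments report:
the peak product concentration and its time, the crossings of the
critical coacervation concentration (0.9 mM product), fuel/product
depletion times, turbidity lifetimes, the two-phase mass balance
(`total = outer (1 - phi) + in-droplet * phi`), the droplet-phase
cation/anion charge ratio, one-site (Wiseman) ITC binding fits, and
partition coefficients from segmented confocal micrographs.

## Worked example

```r
library(fueldrops)
k <- default_rate_constants()          # packaged calibrated constants

tc <- simulate_cycle(experiment_config(F0 = 25), k, t_end = 40)
tc
#> Reaction-cycle time course: 401 points, 0-40 min
#> Experiment: 25 mM fuel, 23 mM precursor, 4.1 mM RNA (monomer), 200 mM MES pH 5.3, 25 C
#>   peak anhydride 3.07 mM at 2.8 min

threshold_times(tc, A_crit = 0.9)      # droplet window at 25 mM fuel
#> $t_on  0.39    $t_off  17.5          # minutes

critical_concentration(7.5, k = k)     # peak product at the fuel onset
#> [1] 0.94                             # mM: the coacervation threshold
fuel_threshold_scan(k = k, A_crit = 0.9, resolution = 0.5)
#> [1] 7.5                              # mM fuel needed for droplets

rep <- run_paper_scenarios(k)          # 7.5 / 25 / 60 mM fuel end-to-end
rep$dynamic_2min
#> 58% of the product in the filtrate two minutes in, 0.89 M product
#> inside the droplets, droplet-phase charge ratio 1.01
```

So two minutes after fueling with 25 mM EDC the model mixture holds about
3 mM anhydride, of which roughly 55–60% is still outside the droplets;
concentrated into the ~0.1% droplet volume, the rest corresponds to an
in-droplet product concentration near 0.9 M and a roughly charge-balanced
coacervate (cation/anion ratio ~1).

The imaging and ITC estimators are validated against planted truth:

```r
m <- synth_micrograph(n_droplets = 22, K_true = 37, seed = 11)
r <- segment_droplets(m$frame)
partition_coefficient(m$frame, r)
#> Partition coefficient K = 35.8 (interior 1.07e+03 / background 30, 22 droplets)

fit_binding_isotherm(synth_itc(noise = noise_spec(relative = 0.02, seed = 11)))
#> One-site ITC fit: Kd = 2.79 mM, dH = -3.57 kJ/mol, n = 1.1 (c = 0.43, low c: wide intervals)
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/fueldrops` (verbs: `simulate`, `fit-kinetics`, `fit-itc`,
`phase-map`, `report`, `synth-hplc`, `synth-itc`).

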