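# ssipsolv

An R implementation of the surface site interaction point (SSIP) model of
solvation: a rule-based, spreadsheet-simple description of solvation free
energies, solvent–solvent transfer, partition coefficients and 1:1
hydrogen-bond complexation for neutral organic molecules.

## The model

A molecule is represented as a discrete multiset of interaction points.
Each H atom that can act as a hydrogen-bond donor contributes a donor site
with polarity α, and each lone pair or π-face contributes an acceptor site
with polarity β. The number of sites per atom is fixed by functional-group
rules (every alkane C–H is one α = 1.20 plus one β = 0.60; an aromatic CH
is one α = 1.40 and two β = 0.70; a six-membered aromatic ring adds two
ring-centre β sites; water is 2 × α = 2.80 and 2 × β = 4.50; and so on),
anchored so that the total SSIP concentration of a pure liquid is roughly
constant at ≈220 M.

A simple (non-polar) solvent S is described by one site pair (α_S, β_S),
two constants C_α, C_β for the solvent–solvent interactions disrupted on
solvation, and an offset C₀ relative to n-hexadecane. The free energy of
transferring one solute site into the solvent is

    Δg_S(α) = −α·β_S − C_β        (donor site)
    Δg_S(β) = −α_S·β − C_α        (acceptor site)

and the whole-molecule solvation free energy is ΔG\* = Σ Δg − C₀, with
transfer between solvents ΔG°(S1→S2) = ΔG\*(S2) − ΔG\*(S1) and
logP = −ΔG°/(RT ln 10). Polar solvents (ethers, nitriles, ketones,
alcohols) are two-domain solvents: solute sites equilibrate between
solvation by the non-polar hydrocarbon sites and by the polar functional
group, combined as site-fraction-weighted equilibrium constants. The same
site parameters give the free energy of a 1:1 H-bonded complex in a
non-polar solvent,

    ΔG° = −αβ + αβ_S + α_S β + C_α + C_β ,

which reduces to the familiar −(α − α_S)(β − β_S) + 6 form when
C_α + C_β = 6 − α_S β_S. Solvent constants are tied to the effective
concentration of solvent–solvent interactions through
C_α + C_β = −α_S β_S + RT ln[S·S].

The package ships the calibrated descriptor tables for water, eleven
non-polar solvents and four polar solvent classes (23 member solvents),
the functional-group SSIP templates, and the rmsd-minimisation machinery
used to calibrate such parameters against experimental partition data.

## Worked example

```r
library(ssipsolv)

# n-heptane has 16 C-H bonds -> 32 SSIPs
p <- build_ssip_profile("CCCCCCC", id = "n-heptane")
n_ssips(p)
#> [1] 32

transfer_free_energy(p, "hexadecane", "water")
#> n-heptane: hexadecane -> water  dG = +28.74 kJ/mol  (logP = -5.03)
```

Each C–H group costs 1.80 kJ/mol on moving from hexadecane into water
(Δg in water: −3.40 − 1.52 = −4.92; in hexadecane: −3.36 − 3.36 = −6.72),
so every 16-hydrogen alkane is predicted to pay 16 × 1.80 ≈ 28.7 kJ/mol —
the hydrophobic effect, emerging from nothing but pairwise site
interactions. Other entry points:

```r
complexation_dg(2.80, 4.50, "carbon tetrachloride")
#> 1:1 complex (alpha 2.80 + beta 4.50) in carbon tetrachloride: dG = +0.54 kJ/mol, K = 0.804 M^-1

rt_ln_ss("chloroform")   # 6.62 kJ/mol: solvent-solvent interaction term
get_solvent("ethanol")   # two-domain alcohol descriptors + site fractions

# calibration against (here: simulated) partition data
d <- simulate_partition_dataset(c(heptane = "CCCCCCC", benzene = "c1ccccc1",
                                  ethanol = "CCO", water = "O"),
                                c("hexane", "chloroform"), noise_sd = 0.5,
                                seed = 1)
fit_parameters(d, fit_spec(free = c("solvent/hexane/c_alpha",
                                    "solvent/hexane/c0"), seed = 1))
```

A thin command-line front-end is installed at
`system.file("cli", "ssip", package = "ssipsolv")`:

```sh
ssip assign "c1ccccc1"                      # 20-row SSIP table
ssip partition "CCCCCCC" --from hexadecane --to water
ssip complex --alpha 2.8 --beta 4.5 --solvent "carbon tetrachloride"
ssip fit --dataset partition.csv --free solvent/hexane/c0
```

## Scope

Neutral, mono-functional organic solutes built from the calibrated
functional groups (alkyl, alkenyl, aromatic hydrocarbon, alcohol, ether,
ketone, nitrile, alkyl chloride, water). Atom environments without a
calibrated template raise an explicit error rather than guessing.
Gas-phase and solid-phase equilibria, ionised solutes, temperature
extrapolation and perfluorocarbon *solutes* in perfluorocarbon solvents
are out of scope; see the methods vignette for the full discussion.
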