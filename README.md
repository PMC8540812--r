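# trapdensity

Estimate the most probable absolute insect population density — and its
exact statistical bounds — from the catch of a single trap.

Traps are the workhorse of pest detection, monitoring and conservation
programmes, but a raw trap count says nothing quantitative about how many
insects are actually out there: the same catch can correspond to population
densities orders of magnitude apart depending on the trap–insect system.
`trapdensity` implements a universal catch-probability model that converts
trap counts into absolute densities for any trap type (pheromone, other
chemical attractants, light), together with the fitting protocol that
estimates its parameters from release–recapture experiments. It is aimed at
entomologists, applied ecologists and pest-management analysts.

## The model

The probability that an insect located `r` meters from a trap is eventually
caught (over the converged-catch interval) is

    spTfer(r) = spTfer(0) / (1 + (r / D50)^2)   for r <= Rmax,   0 beyond,

where `spTfer(0)` is the catch probability in the immediate proximity of
the trap, `D50` the distance at which that probability is halved (the
effective attractive distance), and `Rmax` the radius of the collection
area. Integrating the curve over the collection disk links the average
catch of a uniform population of density ρ̄ (insects/m²) to the count:

    μ = 1 / ( spTfer(0) · π · D50² · ln(1 + (Rmax/D50)²) )

so the most probable density given a catch of `M` insects is `ρ̄_mp = μ·M`,
and exact (Garwood-type) chi-square bounds give, at confidence `p`,

    (μ/2)·χ²((1−p)/2; 2M)  ≤  ρ̄  ≤  (μ/2)·χ²(1−(1−p)/2; 2M+2).

Multiply by 10,000 for insects per hectare. A zero catch still carries
information: the upper bound is a detection threshold the density cannot
exceed at the stated confidence.

`spTfer(0)` and `D50` are estimated from a release–recapture distance
ladder by a two-step protocol: step 1 fits the untransformed recapture
proportions with both parameters free (retaining `spTfer(0)`); step 2
refits `D50` alone on the log-transformed proportions, giving the sparse
catches at large distances equal weight. When `spTfer(0)` was measured
empirically, only step 2 is used.

## Worked example

Ten published trap–insect systems are bundled as presets:

```r
library(trapdensity)
cm <- trap_preset("codling_moth")
cm
#> Trap-insect system : Cydia pomonella / pheromone trap
#>   spTfer(0) = 0.7
#>   D50       = 6.5 m (SEM 1)
#>   Rmax      = 260 m
#>   mu        = 0.001459 insects/m2 per caught insect (14.59 /ha)

estimate_density(3, cm)
#> Population density from a single trap catch
#>   system:     Cydia pomonella / pheromone trap
#>   catch M = 3   (confidence 0.95)
#>   mu        = 0.001459 /m2 per insect  (14.59 /ha)
#>   rho_mp    = 0.004376 /m2  (43.76 /ha)
#>   bounds    = [0.0009025, 0.01279] /m2  ([9.025, 127.9] /ha)
```

Three codling moths in one pheromone trap most probably reflect about 44
males per hectare, and with 95% confidence between about 9 and 128 per
hectare.

Fitting a simulated release–recapture experiment (truth: spTfer(0) = 0.37,
D50 = 27.3 m) recovers the parameters:

```r
set.seed(42)
truth <- trap_params(0.37, 27.3, 1600, label = "reference system")
ds <- simulate_recapture(truth, c(0,15,25,30,45,50,60,75,80,100,
                                  150,200,250,300,500), 2000)
fit_two_step(ds, rmax = 1600)
#> Catch-probability curve fit (method: two_step )
#>   spTfer(0) = 0.366
#>   D50       = 27.89 +/- 1.38 m
#>   R         = 0.998  (observed vs predicted proportions)
#>   points used: 15; excluded: 0
```

The same workflow is available from a shell via the bundled CLI
(`inst/scripts/trapdensity`): subcommands `fit`, `estimate`, `simulate`,
`validate` and `presets`, reading the CSV dialect documented in
`?read_recapture` and emitting JSON.

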