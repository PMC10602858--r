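# lesionPMF

Free-energy pathway mapping for DNA-lesion recognition by the Rad4/XPC
damage sensor.

Rad4/XPC finds UV-induced cyclobutane pyrimidine dimers (CPDs) through a
sequence of slow conformational events — association of its BHD2/BHD3
domains with DNA, flipping of the partner adenines (5′-dA, 3′-dA) out of
the duplex, and insertion of the BHD3 β-hairpin into the lesion site. Each
event is tracked by a collective variable (CV): a distance between
mass-weighted centers of mass of two atom groups (η for hairpin insertion,
γ/γ′ for 5′-dA flipping, δ for 3′-dA flipping, ξ for association). The
free-energy profile along each CV, the potential of mean force
F(x) = −kT ln ρ(x), is estimated by umbrella sampling — harmonically biased
simulations at a ladder of window centers, combined by the weighted
histogram analysis method (WHAM):

    ρ(x_b) = Σ_i n_i(x_b) / Σ_i N_i exp[(f_i − w_i(x_b))/kT]
    f_i    = −kT ln Σ_b ρ(x_b) exp(−w_i(x_b)/kT)

Comparing the PMFs of rival model states at probe CV values then orders
the events into a recognition pathway.

The package is for structural/computational biophysicists who want this
analysis chain as reusable, tested components: CV evaluation on PDB
structures, window scheduling with the two-stage (strong-equilibration /
weak-production) bias protocol, a deterministic overdamped Langevin engine
on analytic toy landscapes (the desk-scale stand-in for biased MD — real
per-window CV series plug in through the same plain-text format),
self-consistent WHAM with block-bootstrap uncertainties, PMF feature
extraction (minima, barriers, harmonic-limit crossover, plateaus, energy
gaps), GROMOS-style RMSD clustering for metastable-state identification,
and the pairwise decision logic that yields the event order.

## Worked example

Recover a planted two-minimum flipping landscape (wells at 10.4 / 14.2 Å,
barrier 3.19 kcal/mol from the metastable side, metastable well 1.1
kcal/mol above the global one) from raw biased samples:

```r
library(lesionPMF)

ls  <- makeDoubleWell(10.4, 14.2, barrier = 3.19, asymmetry = -1.1)
sch <- buildSchedule(8.5, 16.5, 0.4, kEq = 100, kProd = 10,
                     nEq = 500, nProd = 60000)
cfg <- engineConfig(dt = 0.001, sampleStride = 10, seed = 11)
ser <- runUmbrella(ls, sch, cfg)          # 21 windows, two-stage protocol
p   <- wham(ser, whamConfig(), cvName = "gamma")

(m <- findMinima(p))
#>       x        F global
#> 1 10.45 1.082883  FALSE
#> 2 14.15 0.000000   TRUE
barrierBetween(p, m$x[1], m$x[2])[c("x", "height")]
#> $x
#> [1] 12.25
#> $height
#> [1] 3.128857
```

The two minima land within 0.05 Å of the planted wells, the metastable
offset (1.08) within 0.02 kcal/mol of the planted 1.1, and the barrier
(3.13, metastable-side convention) within 2% of the planted 3.19.

The full synthetic four-event study — six umbrella runs, six WHAM
profiles, three pairwise decisions — reproduces the recognition order from
raw samples:

```r
res <- runPathway(syntheticScenario(seed = 3))
res$order
#> [1] "association"       "flip_5prime"       "flip_3prime"
#> [4] "hairpin_insertion"
res$decisions[[2]]
#> OrderingDecision [flip_5prime vs flip_3prime]: flip_5prime first
#>   (|dF| = 3.461 kcal/mol)
```

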