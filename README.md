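# tecKinetics

Transient-kinetic analysis of single-round nucleotide addition and
translocation by RNA polymerase transcription elongation complexes
(TECs).

When a TEC is rapid-mixed with an NTP substrate, the observable kinetics
(stopped-flow fluorescence of a downstream base analog, quench-flow RNA
extension) report on a short reaction cascade. `tecKinetics` models this
cascade as a four-step scheme,

```
      k_act        k_on·[NTP]       k_inc        k_tra
  I  <------>  A  <---------->  A·N  ---->  PRE  ---->  POST
      k_inact        k_off
```

where `I`/`A` are inactive and active forms of the initial TEC that
interconvert slowly, `A·N` is the TEC with NTP bound in the active site,
`PRE` is the extended but pre-translocated TEC, and `POST` is the
post-translocated TEC. Incorporation and translocation are irreversible;
because translocation is fit as a one-way step, `k_tra` is an apparent
rate equal to the sum of the forward and backward translocation rates.
The package propagates this linear scheme by matrix exponentiation and
projects the state occupancies onto three measurement modalities:

- **HCl quench** — all chemistry stops instantly; the extended-RNA
  fraction is `PRE + POST`;
- **EDTA quench (pulse-chase)** — free NTP is inactivated but NTP
  already bound partitions between incorporation and release, so the
  observable is `PRE + POST + p·A·N` with `p = k_inc/(k_inc + k_off)`;
  the HCl/EDTA contrast is what makes `k_off` identifiable;
- **6-MI fluorescence** — a fluorescent guanine analog in the downstream
  DNA is quenched by neighboring base pairs until translocation moves it
  to the duplex edge, so the signal is `offset + scale·POST`.

On top of the scheme the package provides

- weighted least-squares **global fitting** of heterogeneous datasets
  (a fluorescence concentration series plus quench-flow courses sharing
  one rate set) with log-scale parameters, analytic profiling of
  per-trace fluorescence scale/offset nuisances, and Latin-hypercube
  multi-starts;
- **chi-square profile confidence bounds**: for each rate, the parameter
  values at which the re-optimized chi-square rises a set factor
  (default 10%) above the minimum;
- **empirical phase fits**: exponential + stretched-exponential
  two-phase fits for incorporation courses, stretched-exponential fits
  with a resistant fraction for Gre-factor-facilitated RNA cleavage, and
  median reaction times `τ·(ln 2)^{1/β}`;
- **gel lane quantification**: panel-wide 8-bit scaling, band
  integration, and arrest fractions as the ratio of arrest-band counts
  to the at-and-above counts of the control-chase lane;
- seeded **synthetic-data generators** for every modality, including a
  stochastic (Gillespie) simulator of the same scheme used as an
  independent cross-check of the deterministic propagator.

## Worked example

Simulate a uridine-incorporation experiment (fluorescence traces at four
NTP concentrations plus HCl and EDTA quench courses, 2% Gaussian noise)
and recover the rates by a global fit:

```r
library(tecKinetics)

rates  <- reference_rates("UTP")
design <- experiment_design(
  fluor_conc  = c(1.25, 5, 25, 250),
  fluor_times = exp(seq(log(0.002), log(10), length.out = 150)))
dataset <- gen_ntp_dataset(rates, design,
                           noise_spec("relative", 0.02, seed = 42))

fit <- fit_global(dataset, fit_spec(restarts = 3, seed = 1))
print(fit)
#> Global four-step fit: chi-square = 701.614 (converged)
#> Four-step TEC scheme rate set
#>   k_act          0.9568019
#>   k_inact        0.1055511
#>   k_on           1.0196589
#>   k_off         68.5837122
#>   k_inc         52.0235279
#>   k_tra        207.8922717
#>   f_inactive0    0.0929432
#>   4 fluorescence trace(s) with profiled scale/offset
```

The generating values (`k_on = 1` per uM per s, `k_off = 70`/s,
`k_inc = 55`/s, `k_tra = 200`/s, 10% initial inactive fraction) are
recovered within a few percent. Profile bounds show how well each rate
is constrained by this design:

```r
profile_bounds(fit, dataset)
#> Profile bounds at 1.1 x chi-square minimum (701.614)
#>    parameter        best       lower      upper ...
#>        k_act   0.9568019   0.3845312   2.160886
#>      k_inact   0.1055511   0.0001000   0.587575   (lower bound clipped)
#>         k_on   1.0196589   0.7469809   1.486124
#>        k_off  68.5837122  38.1480144 132.922313
#>        k_inc  52.0235279  42.5697762  66.566073
#>        k_tra 207.8922717 117.9213738 661.825742
#>  f_inactive0   0.0929432   0.0607711   0.128063
```

Each interval is the range over which that rate can move — with all
other parameters re-optimized — before the chi-square exceeds the
minimum by 10%. `k_inact`'s lower bound is clipped at the search box:
the data cannot distinguish very slow re-inactivation from none, as
expected for a single-round experiment.

A command-line wrapper over the same functions is provided at
`inst/cli/teckin.R` (subcommands `synth`, `fit-global`, `profile`,
`fit-phases`, `gel-arrest`, `run`), driven by a YAML configuration.

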