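# iminoex

Base-pair opening kinetics of nucleic acids from imino-proton exchange NMR,
in vitro and in living cells.

Imino protons (guanine H1, uracil/thymine H3) exchange with water only while
their base pair is transiently open. For a pair opening at rate k_open,
closing at k_close and exchanging from the open state at k_ex,open, the
observed exchange rate is

    k_ex = k_open * k_ex,open / (k_close + k_ex,open)  <=  k_open

so k_ex is always a lower bound on k_open, and at saturating base-catalyst
concentration (EX1 regime) k_ex plateaus at k_open. `iminoex` implements the
full analysis chain around these two facts:

- **Transfer-curve fitting** — bounded nonlinear least squares of
  `I(t)/I0 = 1 - 2 k_ex/(R1w - R1a) (exp(-R1a t) - exp(-R1w t))`
  with floated amplitude, validated against a numerically integrated
  two-pool exchange system (`mcconnell_two_pool()`).
- **Relaxation-rate fits** — inversion recovery (apparent imino R1a) and
  saturation recovery (water R1w).
- **Monte-Carlo error propagation** — 50 replicate refits with Gaussian
  spectral noise; seeded, bit-reproducible.
- **Catalyst arithmetic** — Henderson–Hasselbalch speciation of Tris, the
  two-sample swap titration schedule, and the plateau / saturation-model
  routes from a titration to k_open.
- **In-cell classification** — the one-sided bound turns an in-cell k_ex
  into a verdict (`increased_in_cell` / `indeterminate`) against the in
  vitro k_open.
- **Ensemble contact screen** — sugar protons (H3′/H4′) near imino protons
  across a multi-model PDB, for ruling out NOE-relay artifacts.
- **Synthetic-study generator** — complete TSV/YAML study bundles from
  declared ground truth, so every stage is testable without spectra.

## Worked example

```r
library(iminoex)

# ground truth emulating a five-residue RNA hairpin study
truth <- ground_truth(seed = 7)
rates <- relaxation_rates(R1a = 2.0 + 3.0, R1w = 0.4)  # apparent R1a

set.seed(7)
s <- generate_transfer_series(truth, "G4", buffer = NULL)  # in-cell series
fit <- monte_carlo_kex(s, rates, n_mc = 50, seed = 7)
fit
#> Imino proton exchange fit (G4, in_cell)
#>   k_ex = 3.584 s^-1  (I0 = 1.036, rss = 0.0212, converged)
#>   Monte Carlo (n = 50): 3.553 +/- 0.36 s^-1

classify_in_cell_opening(1.2, 0.1, fit, residue = "G4")
#> G4: k_open(in vitro) = 1.2 +/- 0.1, k_ex(in cell) = 3.55 +/- 0.36 -> increased_in_cell
```

The fitted in-cell exchange rate (3.55 ± 0.36 s⁻¹; truth 3.0 s⁻¹) is a
lower bound on the in-cell opening rate; since even the bound exceeds the in
vitro opening rate (1.2 ± 0.1 s⁻¹) beyond one sd on each side, the base pair
demonstrably opens more often in the cell.

The same analysis runs as a pipeline from the shell:

```sh
Rscript inst/cli/iminoex.R simulate --out study --seed 7
Rscript inst/cli/iminoex.R fit-kex  --bundle study --out out/kex.tsv --seed 7
Rscript inst/cli/iminoex.R titrate  --kex out/kex.tsv --out out/kopen.tsv
Rscript inst/cli/iminoex.R compare  --kex out/kex.tsv --kopen out/kopen.tsv --out out/report.tsv
```

producing a per-residue report with k_open(in vitro), k_ex(in cell) and the
verdict.

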