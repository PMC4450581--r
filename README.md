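# bicm — maximum-entropy null models for binary bipartite networks

Bipartite networks — countries linked to the products they export, pollinators
to the plants they visit, species to the sites they occupy — are summarized by
a binary biadjacency matrix **M** (C rows × P columns, `m_cp ∈ {0,1}`). To say
whether any structural feature of such a matrix (co-occurrence motifs,
nestedness, degree correlations) is *surprising*, you need a null model that
preserves the features you take for granted and randomizes everything else.

This package implements the **Bipartite Configuration Model (BiCM)**: the
maximum-entropy probability distribution over all 2^(C·P) binary matrices of
the observed shape whose *expected* degree sequences on both layers match the
observed ones. Maximizing the Shannon entropy

&nbsp;&nbsp;&nbsp;&nbsp;S = − Σ_M P(M) ln P(M)

under soft degree constraints yields an exponential family in which every
link is an independent Bernoulli variable,

&nbsp;&nbsp;&nbsp;&nbsp;p_cp = x_c y_p / (1 + x_c y_p),

with one hidden variable per node (the exponentiated Lagrange multipliers).
The x, y are fixed by maximizing the likelihood of the observed matrix —
equivalently, solving the C + P moment equations Σ_p p_cp = d_c,
Σ_c p_cp = u_p. The **BiRG** (bipartite random graph), which constrains only
the total number of links (p = L/(C·P) everywhere), is included as the
coarser baseline.

On top of the fitted ensemble the package computes, analytically where
tractable and by seed-deterministic sampling otherwise:

* **degree metrics** — diversification d_c, ubiquity u_p, connectance,
  rectangularity R = |P − C|/(P + C), monopartite projections M·Mᵀ and Mᵀ·M;
* **assortativity** — per-node average nearest-neighbour degrees (ANPU/ANCD)
  with layer means, 95% CIs and normalized globalization/homogeneity indices,
  plus Newman's assortativity coefficient r over edges;
* **motifs** — Vn (n rows sharing a column) and Λn (n columns sharing a row)
  families, N_Vn = Σ_p C(u_p, n), globally or restricted to node subsets,
  with analytic expectations (elementary symmetric polynomials of the link
  probabilities), z-scores z = (N* − ⟨N⟩)/σ and similarity
  s = (N* − ⟨N⟩)/⟨N⟩ (so s/z is the ensemble coefficient of variation);
* **nestedness** — NODF (total, rows, columns), order-invariant convention;
* **fitness–complexity** — the coupled nonlinear ranking iteration, with
  rank-averaged ensemble comparisons;
* **ensemble diagnostics** — normalized Shannon entropy
  S = −(1/(C·P)) Σ_cp [p ln p + (1−p) ln(1−p)], gaussianity checks for
  sampled observables.

Everything returns tibbles (or objects with `tidy()`/`glance()`/`autoplot()`
methods) and pipes cleanly.

## Worked example

A noisy nested (triangular) 40×90 matrix, the shape that trade and
mutualistic matrices take when ordered by fitness and complexity:

```r
library(bicm)

wtw <- generate_bipartite("nested", n_rows = 40, n_cols = 90,
                          seed = 7, fill = 0.3, noise = 0.03)
glance(wtw)
#>   n_rows n_cols n_links connectance rectangularity mean_degree_rows ...
#> 1     40     90    1145       0.318          0.385             28.6

model <- fit_bicm(wtw)
model
#> # bicm: 40 x 90, loglik -872.0582, max degree residual 9.98e-09
#> #   (fixed-point, 393 iterations)

motif_report(wtw, model, list(motif_spec("V", 2), motif_spec("Lambda", 2)))
#>   family order observed expected    sd z_score similarity     cv
#> 1 V          2    10811   10946.  288.  -0.469   -0.0123  0.0263
#> 2 Lambda     2    25245   25380.  646.  -0.209   -0.00531 0.0254

rep <- observable_report(wtw, model, n_draws = 500, seed = 11)
rep$scalars
#>   observable    observed expected     sd z_score n_used
#> 1 assortativity   -0.234   -0.395 0.0137   11.8     500
#> 2 nodf_total      62.7     71.7   2.40     -3.75    500
#> 3 nodf_rows       60.2     79.3   2.73     -7.00    500
#> 4 nodf_cols       63.2     70.2   2.78     -2.54    500
#> 5 mean_anpu       18.5     22.8   0.408   -10.7     500
#> 6 mean_ancd       45.1     51.1   0.906    -6.60    500
```

Reading the output: the fitted BiCM reproduces every observed degree to
~1e-8, so any remaining discrepancy is structure *beyond* the degree
sequence. Here the motif z-scores sit well inside the ±1.65 band — V and Λ
abundances are explained by the degrees — while the scalar report shows the
flip-noise of the generator: the noisy triangle is *less* nested and less
disassortative than a typical degree-matched matrix (negative NODF z-scores,
observed r = −0.234 above the ensemble mean −0.395), exactly what
degree-uncorrelated noise should do. `autoplot(wtw, ranked = TRUE)` draws the
matrix ordered by fitness/complexity; `autoplot()` on profiles and reports
gives the observed-vs-expected panels with ±1σ/±2σ bands.

A thin CLI covers the same pipeline from the shell
(`summary | observables | fit | sample | report | generate`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli/bicm.R", package = "bicm"))')
Rscript $CLI generate --kind nested --rows 40 --cols 90 --seed 7 --out m.tsv
Rscript $CLI report --input m.tsv --n-draws 500 --seed 11 --fmt tsv --out report.tsv
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates a 151×538 heterogeneous-degree fixture from the seed, fits the
BiCM and BiRG, verifies the degree constraints, scores the V2–V4/Λ2–Λ4 motif
families and the scalar observables against the sampled ensemble (logging
the full reports to stderr), and writes the JSON summary to `--out`.
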