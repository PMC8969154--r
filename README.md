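# acylomics

An R package for the desk-side analytics of lysine-acylation studies of
metabolic enzymes — the kind of study that asks whether a sirtuin deacylase
(such as SIRT5) regulates an acyl-CoA dehydrogenase (such as GCDH, the
glutaryl-CoA dehydrogenase of lysine catabolism) through lysine
glutarylation. It bundles five analysis stages that usually live in
disconnected scripts, plus a synthetic-data module that generates every
input with known ground truth so each stage is testable end to end:

* **Coexpression screen** (`filter_nontumor`, `correlation_matrix`,
  `resample_null`, `query_top`, `enrich`): non-tumor filtering of a liver
  expression matrix, all-vs-all Pearson correlation, an empirical null from
  B = 1000 resampled "virtual gene lists" with a mean ± 2 SD gate, a top-20
  query summary, and hypergeometric gene-set over-representation with BH
  adjustment.
* **Acyl-site quantification** (`normalize_to_protein`, `impute_low`,
  `site_differential`, `map_residue`, `mod_mass`): label-free MS1 intensities
  normalized to protein abundance computed from unmodified peptides only,
  low-abundance imputation, per-site log2 fold changes with pooled-variance
  Student's t, and the joint call `log2FC > 1.8 & p <= 0.05`. Glutarylation
  adds C5H6O3 to lysine: `mod_mass(c(C=5, H=6, O=3))` = 114.0316941 Da.
* **Thermal unfolding** (`fit_two_state`, `delta_tm`): nonlinear
  least-squares fits of the two-state van't Hoff model with linear baselines
  to 20–85 °C melting curves; melting-temperature differences such as the
  −3 °C destabilization of a modified protein.
* **Assay arithmetic** (`specific_activity`, `percent_of_control`,
  `oxidation_percent`, `relative_expression`): DCPIP dye-reduction rates in
  nmol/min via Beer–Lambert, radiolabel release as percent of total label,
  and 2^−ΔΔCt qPCR quantification.
* **Metabolite differential statistics** (`group_differential`,
  `bh_adjust`): log2 fold changes, unpaired t tests, BH q-values, and
  volcano gates `q < 0.015`, `|log2FC| > 1`.

The statistical core in the field's notation: for a query gene *g* the
screen flags correlates with `r` outside `mean ± 2·sd` of coefficients
resampled from the full correlation matrix; site calls use
`t = (mean log2 B − mean log2 A) / (s_p · sqrt(2/n))` with pooled `s_p` and
`df = 2n − 2`; the unfolding model is
`signal(T) = [yN(T) + yU(T)·K(T)]/(1+K(T))` with
`K(T) = exp[−(ΔH/R)(1/T − 1/Tm)]`.

## Worked example

```r
library(acylomics)

# a liver-like cohort with a 20-gene module planted at r = 0.8 around SIRT5
sim <- gen_expression(sim_config(seed = 42, n_genes = 1000, n_samples = 200,
                                 frac_tumor = 0.25, planted_module_size = 20,
                                 planted_r = 0.8), "SIRT5")
co <- run_coexpr(sim$expr, "SIRT5",
                 gene_sets = list(planted = sim$truth$planted_gene_ids,
                                  decoy = sprintf("GENE%04d", 101:160)),
                 seed = 42)
head(co$query_result$ranked, 3)
#>    gene_id         r        r2 beyond_threshold
#> 1 GENE0972 0.8293473 0.6878169             TRUE
#> 2 GENE0992 0.8179951 0.6691160             TRUE
#> 3 GENE0854 0.8086966 0.6539903             TRUE
```

The resampled null over the 1000-gene matrix has mean 0.0010 and SD 0.0830,
so the ±2 SD gate sits at [−0.165, 0.167]; every planted gene lands in the
top 20 (recall 1.0) and the planted set dominates the enrichment table
(hypergeometric p = 2.9e−42 versus 0.71 for a decoy set).

```r
# six sites planted at log2FC = 3 among ten; n = 3 replicates
acyl <- gen_acyl_table(10, 8, c("unmod", "glut"), 3,
                       effect_log2fc = rep(3, 6), seed = 42)
res <- run_acylquant(acyl$table, c("unmod", "glut"), seed = 42)
res[res$significant %in% TRUE, c("site_residue", "log2fc", "p")]
#>   site_residue log2fc        p
#> 1           78   2.74 1.57e-03
#> 2          103   2.90 2.10e-04
#> ...                             (exactly the six planted sites)
```

```r
# a modified/unmodified melting pair mirroring a -3 degC destabilization
fmod <- fit_two_state(gen_melting_curve(52, 300, noise_sd = 0.3, seed = 1))
funm <- fit_two_state(gen_melting_curve(55, 300, noise_sd = 0.3, seed = 2))
funm
#> two-state fit: Tm = 55.32 degC, dHvH = 289 kJ/mol, rss = 7.4
delta_tm(fmod, funm)
#> [1] -3.24

specific_activity(gen_activity_trace(5, noise_sd = 0.002, seed = 3))$rate_nmol_min
#> [1] 4.986    # nmol DCPIP reduced per minute
```

## Command line

An umbrella CLI wraps the same stages (wrapper script in `inst/cli/`):

```sh
Rscript -e 'acylomics::acylomics_main()' simulate --out sim --seed 7
Rscript -e 'acylomics::acylomics_main()' coexpr --expr sim/expression.tsv \
    --meta sim/sample_meta.tsv --query SIRT5 --B 1000 --k 2 --top-n 20 --seed 7
# other subcommands: acylquant, meltfit, activity, oxidation, ddct, volcano
```

Each stage writes its artifacts plus a `manifest.json` (seed, parameters,
versions) enabling exact re-runs.

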