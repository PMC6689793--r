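# modstick

Network-based feature selection linking gene co-expression **submodules**
to a quantitative phenotype.

Classical co-expression analysis summarizes each module by its eigengene
(first principal component) and correlates that with a trait. When the
trait-relevant genes are a minority inside a module, their signal lives in
a *second or third* component and the eigengene misses it. `modstick`
implements a pipeline for paired control/stress expression designs (e.g.
shoot RNA-seq of rice accessions under salt stress, with the log2 shoot
Na+/K+ ratio as phenotype) that:

1. builds per-accession log2 fold changes `log2((stress + 1)/(control + 1))`
   after low-information filters (count quartile ratio < 1.5; > 80% of
   samples below 10 counts; fold-change interquartile spread ≤ 0.25);
2. constructs an unsigned weighted co-expression network
   `a_ij = |cor(f_i, f_j)|^4`, computes the topological overlap matrix, and
   partitions genes into modules (average linkage, static cut, minimum
   module size 25) — or imports a partition from any external tool;
3. decomposes each module by correlation PCA and uses the top three
   component scores as **virtual genes**;
4. regresses the phenotype on all virtual genes with the LASSO
   (objective `(1/2n)·RSS + λ‖β‖₁`), choosing λ by leave-one-out
   cross-validation under the one-standard-error rule;
5. tests, for every selected component, which member genes have an
   unusually large contribution (squared loading) by comparing the sorted
   contributions against the order statistics of a unit stick broken
   uniformly at random into K pieces (flat Dirichlet, 10,000 draws, 95%
   quantile) — those genes form the **submodule**;
6. provides a simulation framework (Simulations I and II) comparing the
   LASSO shrinkage-path ranking against absolute-correlation ranking by
   precision–recall AUC, with paired Wilcoxon signed-rank comparisons.

A fully synthetic data generator with planted modules, planted submodules
and known coefficients makes every stage testable without any download.

## Worked example

```r
library(modstick)

gen <- generate_dataset(synthetic_spec(seed = 7))   # 92 accessions, 3 modules,
                                                    # one 15-gene planted submodule
res <- run_pipeline(gen$dataset, gen$phenotype, pipeline_config(seed = 7))
```

```
[preprocess] 170 genes, 184 samples
[preprocess] 170 genes after low-information filter
[preprocess] 170 genes after fold-change variation filter
[network] scale-free fit R^2 = 0.014; 3 modules
[decompose] 9 virtual genes from 3 modules
[select] lambda_chosen = 0.046802 (one_se rule); 1 component(s) selected: M1.PC2
[test-genes] M1.PC2: 15 / 64 genes significant
```

The planted submodule lives on the *second* component of module 1 — the
eigengene (`M1.PC1`) carries the module's dominant pattern and is not
associated with the phenotype, while the broken-stick test on the selected
`M1.PC2` flags 15 genes:

```r
planted <- gen$truth$planted_genes[[1]]
mean(planted %in% res$significant_genes)
#> [1] 1
head(res$stick_tests[["M1.PC2"]]$table, 3)
#>   gene_id contribution rank  threshold significant correlation
#> 1  G00001   0.15048678    1 0.10723446        TRUE   0.9503124
#> 2  G00002   0.11119982    2 0.07719879        TRUE  -0.8169007
#> 3  G00003   0.08959057    3 0.06433409        TRUE   0.7332438
```

All 15 planted genes are recovered (`recall = 1`) with no false
positives. `write_results()` serializes the selection and per-gene tables
to TSV; `run_pipeline(..., out_dir =)` additionally writes a JSON run
manifest with gene counts after every stage.

A thin command-line front end over the same functions is installed at
`inst/cli/modstick.R` with `generate`, `pipeline` and `simulate`
subcommands.

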