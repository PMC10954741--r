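# cladealign

Probabilistic assignment of single-cell RNA expression profiles to
DNA-defined tumour subclones, with per-gene copy-number **dosage-effect**
inference and per-SNP **allele** assignment.

## The problem

Tumours with chromosomal instability consist of subclones carrying distinct
copy-number alterations (CNAs). scDNA-seq resolves those subclones (and
their phylogeny); scRNA-seq resolves expression phenotypes — but on
different cells, so the two modalities must be integrated computationally.
Methods that assume *every* gene's expression tracks its copy number lose
accuracy when many genes are dosage-independent. `cladealign` models that
explicitly: a per-gene Bernoulli indicator $k_g$ (with fitted probability
$p(k_g)$) states whether gene $g$ follows copy number, so copy-number
independent genes inform neither assignment nor get forced onto the wrong
clone, and $p(k_g)$ itself is the dosage-effect readout.

## The model in brief

For cell $n$ with depth $l_n$ assigned to clone $c$ with gene copy numbers
$\lambda_{gc}$:

$$X_n \sim \mathrm{Mult}(l_n, Y_n), \qquad
  y_{ng} \propto [\mu_{g0}\lambda_{gc}k_g + \mu_{g1}(1-k_g)]\,
  e^{\psi_n \cdot w_g^T},$$

with clone assignment $z_n \sim \mathrm{Cat}(\pi)$ shared, optionally, with
a binomial allele model at heterozygous SNPs:
$r_{ns} \sim \mathrm{Binom}(t_{ns}, a_s b_{sc} + (1-a_s)(1-b_{sc}))$, where
$b_{sc}$ is the clone B-allele frequency from scDNA and $a_s$ indicates
whether the scRNA reference allele is the B haplotype. Inference is
MAP/variational (Adam, learning rate 0.1, relative-ELBO convergence at
1e-5) with $z_n$ marginalized exactly; repeated restarts give a per-cell
consistency score, and cells failing the posterior (0.8) or consistency
(0.7) bar are reported `unassigned`. Given an scDNA phylogeny instead of
clone labels, the model is applied recursively from the root, summarizing
each clade's copy number by the per-gene mode and descending until the
documented stopping rules fire. See `vignette("cladealign-methods")`.

## Worked example

Simulate a benchmark dataset (3 clones, 1000 cells, 500 clone-differential
genes, 60% dosage genes), fit the model, and score it:

```r
library(cladealign)

sim <- simulate_expression(sim_config(seed = 101))
fit <- fit_clone_model(sim$expr, sim$profile, NULL,
                       inference_config(seed = 101, n_restarts = 3))
fit
#> <fit_result> 1000 cells -> 3 clones; ELBO -726811.27 after 141 iterations (converged)
#>   labels: A=334 B=306 C=293 unassigned=67

clone_accuracy(fit$clone_label, sim$truth$z)
#> [1] 0.93
top <- top_expressed_genes(sim$expr, 0.4)
auc(fit$p_k[top], sim$truth$k[top])
#> [1] 1
```

`clone_accuracy` is the fraction of cells whose label matches the simulated
truth (unassigned counts as incorrect); the AUC measures how well the
fitted dosage probability `p_k` separates genes simulated with a dosage
effect from those without, among the top-40%-expression genes. The
baseline with the dosage indicator pinned to 1 for every gene
(`fit_baseline_dosage()`) is the dosage-agnostic comparator; on the same
regime it loses 15–20 accuracy points because copy-number-independent
genes drag it toward wrong clones.

A command-line interface wraps the same functions:

```sh
Rscript exec/cladealign simulate --out-dir sim --seed 1 --n-cells 1000
Rscript exec/cladealign fit --expr sim/matrix.mtx --cn-clone sim/cn_clones.tsv --out-dir fit --seed 1
Rscript exec/cladealign evaluate --assignment fit/assignment.tsv --truth sim/truth_cells.tsv --out-dir eval
```

Subcommands `fit-tree` (Newick phylogeny or flat clone labels) and
`benchmark` (the simulation grid) are also available; `--config FILE`
points to a YAML file overriding any configuration section.

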