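# nri — Neural Reconstruction Integrity scoring

`nri` scores how faithfully an automated connectome reconstruction preserves
the *wiring* of a ground-truth circuit, rather than its voxels. Every synapse
contributes two terminals (pre- and postsynaptic); any unordered pair of
terminals on the same neuron is an **intracellular path** a signal could take
through that cell. The Neural Reconstruction Integrity metric is the f-score
over these path pairs:

    NRI = 2·TP / (2·TP + FP + FN)
    precision = TP / (TP + FP),   recall = TP / (TP + FN)

where TP are paths present in both graphs, FN true paths the reconstruction
broke (splits, deleted synapses) and FP spurious paths it created (merges,
inserted synapses). Because an intact neuron with *n* terminals carries
C(n, 2) paths, errors are weighted by the connectivity they destroy —
unlike voxel-level Rand scores, which barely move when a thin process that
carries half a neuron's synapses is cut.

The package provides the full evaluation pipeline (synapse matching → count
table → metrics), two comparison metrics (terminal-level adapted Rand index
and normalized variation of information), a synthetic cortical-network
generator, four reconstruction-error perturbation models, and a CLI.

## Worked example

The bundled toy network has four synapses: a blue axon innervating a green
dendrite three times, and a red axon innervating an orange dendrite once.
The reconstruction splits off one of green's postsynaptic terminals onto its
own fragment (4) and merges the rest of green's dendrite with orange's into
fragment 1:

```r
library(nri)
gt  <- read_synapse_table(system.file("extdata", "fig1_ground_truth.csv",
                                      package = "nri"))
rec <- read_synapse_table(system.file("extdata", "fig1_reconstruction.csv",
                                      package = "nri"),
                          role = "reconstruction")
m  <- match_synapses(gt, rec)          # capped bipartite assignment, 300 nm
ct <- build_count_table(gt, rec, m)    # sufficient statistic for all metrics
ct
#> <count_table> 4 ground-truth neurons x 4 reconstructed fragments (+ ins/del)
#>        del 1 2 3 4
#> ins      0 0 0 0 0
#> blue     0 0 3 0 0
#> green    0 2 0 0 1
#> orange   0 1 0 0 0
#> red      0 0 0 1 0

global_nri(ct)
#> NRI (f1): 0.6667   [P 0.6667, R 0.6667;  TP 4, FP 2, FN 2]

nri_by_neuron(ct, attribution = "incident")
#>   neuron tp fp fn precision    recall       nri
#> 1   blue  3  0  0 1.0000000 1.0000000 1.0000000
#> 2  green  1  2  2 0.3333333 0.3333333 0.3333333
#> 3 orange  0  2  0 0.0000000       NaN 0.0000000
#> 4    red  0  0  0 1.0000000 1.0000000 1.0000000
```

Green keeps one of its three paths (the two terminals still together on
fragment 1), loses two to the split, and gains two spurious paths to orange
from the merge — hence 0.333. The file-level wrapper `nri_compute()` runs
the same pipeline from two CSV paths and can write a JSON report and a
per-neuron CSV.

## Synthetic networks and perturbation experiments

```r
sweep <- nri_experiment(seeds = 1L, models = "split")
#  intensity   nri precision recall adapted_rand   nvi
#        0.2 0.790         1  0.653        0.992 0.145
#        0.5 0.644         1  0.475        0.988 0.232
#        0.9 0.516         1  0.347        0.985 0.289
```

Each row scores a 50-neuron generated network (`growth_config()` defaults)
against a perturbed copy of itself. Note the contrast the metric was built
to expose: heavy splitting drags the NRI to 0.52 while the adapted Rand
index stays above 0.98. Models: `delete`, `insert`, `split`, `merge`;
perturbations are also exported individually (`delete_synapses`,
`insert_synapses`, `split_neurons`, `merge_neurons`), along with per-neuron
diagnostics (`perturbation_scores`) and region-cropping preprocessing
(`crop_relabel`).

A command-line front end with `simulate`, `perturb`, `compute` and
`experiment` subcommands is installed at:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "nri.R", package = "nri"))')" \
  compute --gt gt.csv --recon recon.csv --out-json report.json
```

See `vignettes/nri-methods.Rmd` for the method details, parameter choices
and numerical conventions.

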