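# qpin

Quantum-inspired dynamics and link prediction on protein interaction
networks.

Protein–protein interaction (PPI) prediction is usually attacked with
classifiers over hand-built features or graph embeddings. qpin implements
an alternative formalism in which the interaction network itself is a
small open quantum system: proteins are finite-dimensional quantum
systems (ground/closed vs. binding-competent conformations), the network
topology enters through a swap-operator graph Laplacian, the state
evolves under a Lindblad master equation with biologically named
decoherence channels, and candidate pairs are scored by time-integrated
measurement operators with an exponential binding-memory kernel. The
package is aimed at computational biologists and quantum-information
researchers who want a fully inspectable, desk-scale implementation of
this formalism — every operator, trajectory and score is an ordinary R
object.

## The model in brief

The network Hamiltonian combines topology and conformational energetics,

$$\hat H = \gamma \Bigl[\sum_{(i,j)\in E} W_{ij}\bigl(\hat I - \hat P_{ij}\bigr)
  + \sum_i \hbar\omega_i \hat\sigma_z^{(i)}\Bigr] + \hat V,$$

with $\hat P_{ij}$ the swap operator between adjacent proteins. The
density matrix follows the GKSL master equation

$$\dot\rho = -\tfrac{i}{\hbar}[\hat H,\rho] + \sum_k \bigl(\hat L_k\rho\hat L_k^\dagger
  - \tfrac12\{\hat L_k^\dagger\hat L_k,\rho\}\bigr)$$

with per-protein dephasing ($\sigma_z$), binding relaxation ($\sigma_-$)
and thermal ($a + a^\dagger$) channels, and a pair $(i,j)$ is scored by

$$P_{ij}(t) = \mathrm{Tr}\bigl[\hat M_{ij}(t)\,\rho(t)\bigr],\qquad
  \hat M_{ij}(t) = \tfrac1N \int_0^t e^{-\lambda(t-t')}\,
  \Pi(t')\,\hat O_{\mathrm{int}}\,\Pi(t')\,dt'.$$

Alongside: von Neumann / interaction entropies, $l_1$ coherence,
cooperativity enhancement $\eta = 1 + \alpha S(A{:}B)$, modular
entanglement bounds, and a variational eigensolver (parameter-shift
gradients, Adam, coherence/sparsity-regularized loss) over
graph-structured Pauli Hamiltonians. A planted-partition generator with
correlated node features provides ground truth for evaluation at desk
scale. See the methods vignette
(`vignettes/quantum-network-scoring.Rmd`) for every modeling and
numerical choice.

## Worked example

```r
library(qpin)

net <- generate_synthetic_network(synthetic_spec(n_vertices = 24, n_modules = 3, seed = 42))
net
#> <synthetic_network: 24 vertices, 48 edges, 20 planted positives, 20 negatives>

candidates  <- rbind(net$positives, net$negatives)
predictions <- score_all_pairs(net$graph, candidates, scoring_config())
head(predictions, 4)
#> # A tibble: 4 × 6
#>   protein_a protein_b p_interaction predicted similarity strategy
#>   <chr>     <chr>             <dbl>     <int>      <dbl> <chr>
#> 1 P018      P022              0.187         0      0.908 pair
#> 2 P019      P023              0.193         0      0.938 pair
#> 3 P003      P004              0.191         0      0.931 pair
#> 4 P002      P005              0.179         0      0.872 pair

labels <- c(rep(1, nrow(net$positives)), rep(0, nrow(net$negatives)))
classification_metrics(predictions$p_interaction, labels)
#> # A tibble: 1 × 7
#>   threshold accuracy precision recall    f1   auc     n
#>       <dbl>    <dbl>     <dbl>  <dbl> <dbl> <dbl> <int>
#> 1       0.5      0.5        NA      0    NA  0.99    40
```

`p_interaction` is the normalized measurement expectation
$\mathrm{Tr}[\hat M_{ij}\rho(t)]$ at the scoring horizon: the joint
probability that both proteins are in their binding-competent
conformation, weighted by feature similarity. With the default
homogeneous physics these probabilities sit well below the 0.5 label
threshold (hence recall 0 at that cut), but they *rank* the planted
intra-module positives far above the inter-module negatives —
AUC 0.99 here. Ranking, not calibration, is the evaluation target on
these synthetic networks.

A variational ground-energy computation on a graph edge:

```r
fit <- train_vqe(
  list(pauli_term(c(P001 = "Z", P002 = "Z"))),
  build_ansatz(c("P001", "P002"), edges = data.frame(from = "P001", to = "P002")),
  training_config(max_iters = 300, seed = 1)
)
glance(fit)
#> # A tibble: 1 × 6
#>   n_params iterations energy total_loss coherence sparsity
#>      <int>      <int>  <dbl>      <dbl>     <dbl>    <dbl>
#> 1        8        300 -1.000     -1.000     0.166     14.5
```

The exact ground energy of $\sigma_z\otimes\sigma_z$ is $-1$; the solver
recovers it to below $10^{-3}$.

Fitted objects follow broom conventions (`tidy()`, `glance()`) and have
`autoplot()` methods; `evolve()` trajectories tidy into per-time
diagnostics (trace, purity, coherence, smallest eigenvalue).

## Command line

A thin CLI over the same functions ships at `inst/cli/qpin.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/qpin.R", package = "qpin"))')" \
  run --seed 3 --out-dir myrun --n-vertices 24 --n-modules 3
```

Commands: `generate`, `operators`, `simulate`, `measure`, `score`,
`train`, `run`; all support `--seed`, `--version`, `--log-level`, and the
`run` command also accepts a YAML config (`--config run.yaml`, keys as in
`run_config()`).

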