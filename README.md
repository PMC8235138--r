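# klminimax

Minimax density estimation under Kullback–Leibler loss over *data-driven*
restricted model classes, for statisticians and modelers who need
worst-case guarantees from a single, possibly small, sample rather than
average-case accuracy.

## The idea

Given n i.i.d. samples from an unknown p, the package builds a class of
models that remain plausible given the data — a confidence region for the
parameter, or the leave-one-out class in large-alphabet problems — and
returns the density q minimizing the worst-case divergence over that class:

    min_q  sup_{p ∈ P(Θr)}  D(p ‖ q),      D(p‖q) = Σ p log(p/q)

By the redundancy–capacity theorem this is a channel-capacity problem: the
minimax estimator is the mixture q_π = Σ π(θ) p_θ under the
capacity-achieving prior, and the minimal worst-case divergence is the
capacity C(Θr). Three estimators of increasing robustness are provided:

| estimator | assumption on the truth | guarantee |
|---|---|---|
| mixture minimax (`mixture_minimax`, `blahut_arimoto`) | truth in the class | worst-case divergence = C(Θr) |
| projected mixture (`constrained_capacity`) | truth in a wider class Θ | regret vs best class member ≤ F(Θ,Θr) |
| normalized maximum likelihood (`nml_finite`, `nml_gaussian_interval`) | none | constant regret Γ(Θr) = log₂ Z |

with C(Θr) ≤ F(Θ,Θr) ≤ Γ(Θr) on a common setup.

Supported classes: Gaussian-mean confidence ellipsoids (closed-form
single-sphere mixture when the whitened radius is below the critical radius
of the amplitude-constrained Gaussian channel; Blahut–Arimoto on a boundary
grid otherwise), Sison–Glaz box–simplex regions for multinomial proportions
(solved on the polytope's vertex set), and leave-one-out classes built from
MLE / add-constant (Krichevsky–Trofimov) / Simple Good–Turing base
estimators for large alphabets, aggregated by NML or a uniform mixture and
benchmarked against the count-group natural oracle. A seeded simulation
harness (`run_experiment`) reports mean, variance and worst-case divergence
or regret over replicates, and `cli_main()` exposes everything from the
shell (`inst/scripts/klminimax`).

## Worked example: a large-alphabet sample

Forty draws from a Zipf(s = 1.5) law over 1000 symbols — most of the
alphabet unseen:

```r
library(klminimax)
p   <- zipf_pmf(1000, 1.5)
cnt <- sample_generator(generator_spec("zipf", m = 1000, s = 1.5, seed = 42), 40)

gt  <- simple_good_turing(cnt)      # base estimate
cls <- loo_class(cnt, "good_turing")
cls
#> Leave-one-out class (good_turing): 13 distinct models, n = 40

nml <- loo_nml(cls)                 # NML over the class
nml
#> NML estimate: Z = 1.167736  Gamma = 0.2237137 bits

mix <- uniform_mixture(cls)
nat <- natural_oracle(p, cnt)       # lower-bound oracle knowing p
round(c(good_turing = kl_discrete(p, gt),
        loo_mixture = kl_discrete(p, mix),
        loo_nml     = kl_discrete(p, discrete_distribution(nml$estimate$probs)),
        oracle      = kl_discrete(p, nat)), 4)
#> good_turing loo_mixture     loo_nml      oracle
#>      1.0100      0.9822      0.8453      0.8304
```

All values are in bits. Γ = 0.224 bits is the worst-case regret guarantee
of the NML against the best leave-one-out model; on this draw the NML's
divergence (0.845) nearly reaches the natural oracle's lower bound (0.830),
while plain Good–Turing pays 1.010. The simulation harness repeats this
protocol over thousands of seeded replicates:

```r
gen <- generator_spec("zipf", m = 1000, s = 1.5)
cfg <- experiment_config(gen, n_grid = 40, k = 10000,
                         estimators = c("good_turing", "loo_uniform", "loo_nml"),
                         metric = "regret_vs_oracle", master_seed = 1)
run_experiment(cfg)
#>     estimator  n   mean variance worst_case ...
#>   good_turing 40 0.1121  0.00516      0.634
#>   loo_uniform 40 0.1052  0.00463      0.614
#>       loo_nml 40 0.0972  0.00381      0.505
```

The worst-case regret ordering — NML below the uniform mixture below plain
Good–Turing — is the headline effect: aggregating over the leave-one-out
class buys worst-case robustness at almost no average cost.

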