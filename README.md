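# mptbind

Multinomial-processing-tree (MPT) analysis of distractor–response binding
in negative-priming experiments: who is this for and what does it do?

When a to-be-ignored distractor reappears as the target of the next
display, responses are slower and more error-prone. The binding-and-
retrieval account attributes part of this cost to *prime-response
retrieval*: the repeated stimulus retrieves the episode it was bound into,
and the response stored in that episode intrudes. Whether a task-irrelevant
**context** stimulus joins that episode — bound directly to the response
(*binary* binding) or jointly with the distractor (*configural* binding) —
cannot be decided from reaction times. It can be decided from the
*categories* of erroneous probe responses in a four-alternative
identification task, and that categorical analysis is what this package
implements, end to end, for researchers running or simulating such
experiments.

## The model and the test battery

Probe responses in each design cell follow the baseline MPT:

```
P(correct)               = ci
P(distractor error)      = (1-ci) psc
P(prime-response error)  = (1-ci)(1-psc) prr
P(other error)           = (1-ci)(1-psc)(1-prr)
```

`ci` is the probability of correct target identification, `psc` the
conditional probability of confusing target and distractor, and `prr` the
conditional probability of re-executing the prime response — the binding
diagnostic. Models for several conditions are fitted jointly by maximum
likelihood (closed form where the restrictions are equalities, quasi-Newton
with analytic gradients otherwise), and hypotheses are likelihood-ratio
G² tests of restricted against saturated models, each with df = 1:

1. **distractor retrieval**: `prr_IR = prr_C` within a context relation;
2. **binary context binding**: `prr_C` equal between context-repeated and
   context-changed trials;
3. **configural context binding** (interaction): `prr_IR − prr_C` equal
   between context relations, via a difference-reparameterized joint model.

Effect sizes are Cohen's `w = sqrt(G²/N)`; noncentral-χ² power and
sample-size planning (`λ = N w²`) and a faithful synthetic experiment
generator complete the pipeline. See the vignette
(`vignettes/context-binding-mpt.Rmd`) for the full methods account.

## Worked example

Simulate a three-saliency experiment (576 trials per participant, 24 per
analyzed cell and saliency level) in which the context is configurally
bound at the moderate and high saliency levels, then run the battery:

```r
library(mptbind)

spec      <- design_spec("exp1", seed = 7)
design    <- build_design(spec)                     # 576 trial records
pars      <- sim_params(spec, pattern = "configural",
                        saliency_levels = c("moderate", "high"))
responses <- simulate_experiment(design, pars, n_participants = 1000,
                                 seed = 8)
agg       <- aggregate_and_filter(responses)        # error-rate > .50 rule
battery   <- run_binding_battery(agg$table)
battery
```

```
Context-binding test battery (alpha = 0.05 , raw p)

Saliency: high  -> verdict: configural_binding 
  distractor_retrieval         repeated             G2(1) = 62.83, p < .001, w = .04  *
  distractor_retrieval         changed              G2(1) = 0.23, p = .63, w < .01
  binary_context_binding       repeated_vs_changed  G2(1) = 0.32, p = .57, w < .01
  configural_context_binding   repeated_vs_changed  G2(1) = 31.60, p < .001, w = .02  *

Saliency: low  -> verdict: not_integrated 
  distractor_retrieval         repeated             G2(1) = 13.62, p < .001, w = .02  *
  distractor_retrieval         changed              G2(1) = 15.27, p < .001, w = .02  *
  binary_context_binding       repeated_vs_changed  G2(1) = 1.68, p = .19, w < .01
  configural_context_binding   repeated_vs_changed  G2(1) = 0.08, p = .77, w < .01

Saliency: moderate  -> verdict: mixed 
  distractor_retrieval         repeated             G2(1) = 35.22, p < .001, w = .03  *
  distractor_retrieval         changed              G2(1) = 6.60, p = .01, w = .01  *
  binary_context_binding       repeated_vs_changed  G2(1) = 5.74, p = .02, w = .01  *
  configural_context_binding   repeated_vs_changed  G2(1) = 7.95, p < .01, w = .01  *
```

Reading the output: at **high** saliency the planted pattern is recovered
cleanly — the retrieval effect exists only when the context repeats
(configural binding), while `prr_C` itself does not differ between context
relations (binary test flat). At **low** saliency (no planted context
effect) nothing but the plain distractor-retrieval effect fires. At
**moderate** saliency the configural test is correctly significant, but the
binary test also lands at p = .02 — a borderline false positive (its Holm-
adjusted p is .0497), so the verdict is `mixed` at this seed: verdicts
inherit the error rates of their constituent tests. Power planning for such
effects:

```r
req <- required_trials(w = 0.03, alpha = 0.05, target_power = 0.80)
req$planning_n                    # 8721 trials
required_participants(req$planning_n, 96)   # 91 participants
round(chi2_power(10176, 0.03), 2)           # 0.86 achieved at the realized N
```

Observed data can be ingested with `read_frequency_table()` (CSV schema:
`condition, trial_type, context_relation, saliency, n_correct,
n_distractor_error, n_prime_response_error, n_other_error`), and a thin
command-line wrapper is provided in `inst/cli/mptbind.R`
(`simulate`, `fit`, `test`, `power` subcommands).

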