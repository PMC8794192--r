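# iterlang

Iterated-learning transmission chains for artificial mini-languages:
simulation, morphological-complexity metrics, and condition-by-generation
trend analysis.

## The problem

Languages with many adult (hence often imperfect) learners tend to be
morphologically simpler. One experimental handle on this claim is iterated
learning: a designed "generation-0" language is taught to a learner, the
learner's reproduction is taught to the next learner, and so on down a
transmission chain. If some generations learn under reduced exposure,
redundant morphology — *overspecification* — should erode faster.

`iterlang` is for researchers in language evolution and cultural-transmission
modelling who want that whole pipeline as tested, reusable code: generate
structurally isomorphic initial languages, simulate chains of perfect or
imperfect learners, score every language for complexity and every
transmission for fidelity, and fit the trajectory models that detect
condition differences.

The design space is the classic 16-cell meaning space: 2 agents (a round and
a square animal) × 2 numbers × 4 events. Generation-0 languages share one
template — noun = CVC stem (+ plural consonant), verb = event consonant +
agent vowel — so the agent is marked twice per sentence (noun stem and verb
ending), a minimal model of gender agreement and the redundancy whose fate
the simulation tracks. Chains come in three conditions: **N**ormal (all
long-exposure learners), **T**emporarily interrupted (short-exposure at
generations 2–4) and **P**ermanently interrupted (short-exposure from
generation 2 on).

## The statistics

* **Type-token ratio (TTR)** — distinct word forms / total word tokens, the
  operationalization of lexicogrammatical diversity. Computed over the whole
  language (`ttr`), per part of speech (`ttr_pos`), and at morpheme level:
  `ttr_ending` averages within-event TTRs of verb-final letters (isolating
  agent/number marking; 0.25 = no marking, 0.5 = full double marking) and
  `ttr_stem` averages within-agent TTRs of verb-initial letters (isolating
  lexical distinctions).
* **Transmission fidelity** — 1 minus the mean normalized Levenshtein
  distance between same-meaning sentences of an input and an output language
  (`transmission_fidelity`).
* **Shannon entropy** of the word-frequency distribution (`entropy`).
* **Contrasts and trends** — Welch *t* tests with Cohen's *d*
  (`welch_t_test`) and mixed-effects trend models
  `log(ttr) ~ condition * generation + (1 + generation | chain)` with
  part-of-speech / morpheme extensions (`fit_trend`), plus a per-chain OLS
  slope fallback (`per_chain_slopes`).

The imperfect learner itself is a deliberately minimal generative model
(`agent_params`): per-meaning verbatim recall (probability depending on
exposure), majority-ending regularization of non-recalled verbs, and weak
class-preserving character noise. See the vignette
(`vignettes/iterated-learning.Rmd`) for the model, its assumptions, and what
it does and does not emulate.

## Worked example

The package embeds six printed example languages (`load_fixtures()`). Chain
T25 lost all double agent-marking between generations 0 and 10:

```r
library(iterlang)
fx <- load_fixtures()
fx[["T25-0"]]
#> Artificial language 'T25-0' (16 meanings)
#>                   round  square
#> sg.none             jal     rok
#> sg.fall_apart    jal bu  rok be
#> sg.grow_antlers  jal fu  rok fe
#> sg.fly_away      jal tu  rok te
#> pl.none            jald    rokd
#> ...
ttr(fx[["T25-0"]]); ttr(fx[["T25-10"]])            # 0.357  0.25
ttr_ending(fx[["T25-0"]]); ttr_ending(fx[["T25-10"]])  # 0.5  0.25
ttr_stem(fx[["T25-10"]])                           # 0.333
transmission_fidelity(fx[["T25-0"]], fx[["T25-10"]])   # 0.8646
```

At generation 0 each event's verb endings look like {u, u, e, e}
(`ttr_ending` = 0.5); by generation 10 they are invariant ({e, e, e, e}, …),
the floor value 0.25 — agent-marking is gone. The stem TTR 0.33 reflects
that two of the three surviving verbs share a first letter (`fu`, `fe`),
having absorbed the old endings into their stems.

A full simulated experiment, measured and modelled:

```r
chains <- run_experiment(experiment_config(master_seed = 1))
rec <- metric_table(chains, c("ttr_all", "fidelity"))

f2 <- rec[rec$metric == "fidelity" & rec$generation == 2, ]
welch_t_test(f2$value[f2$condition == "N"], f2$value[f2$condition != "N"])
#> Welch two-sample t-test: t(35.9) = 6.81, p = 6e-08
#> mean difference 0.0162, 95% CI [0.0114, 0.0210], Cohen's d = 1.59

fit_trend(rec)
#>                   term estimate      se    df       t        p
#>            (Intercept) -1.02000 0.00764 441.0 -134.00 0.00e+00
#>             conditionN -0.00226 0.01080 441.0   -0.21 8.34e-01
#>             conditionP -0.02010 0.01080 441.0   -1.86 6.36e-02
#>             generation -0.01730 0.00379  42.3   -4.57 4.23e-05
#>  conditionN:generation  0.01420 0.00536  42.3    2.66 1.11e-02
#>  conditionP:generation  0.01170 0.00536  42.3    2.18 3.50e-02
```

Read: generation-2 learners who had short exposure reproduce their input
less faithfully (large *d*); overall log-TTR falls by about 1.7% per
generation in the reference condition T, and the positive N × generation
interaction cancels most of that decline in the uninterrupted condition —
simplification tracks imperfect learning.

The same pipeline is scriptable:

```sh
exec/iterlang simulate --seed 1 --out chains.tsv
exec/iterlang measure  --in chains.tsv --out metrics.tsv
exec/iterlang analyze  --in metrics.tsv --model overall --out trend
```

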