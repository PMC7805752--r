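# spascreen

Simulating lexical medical screenings with a large-scale semantic-pointer
neural model, and relating microscopic neural damage to the behavioural
deficits those screenings measure.

Clinical screenings such as a picture-naming test for children's word
retrieval or a word-list repetition task for early-dementia detection probe
the language system end to end: perceive, process, remember, speak.
`spascreen` implements a neurocomputational model of that chain — a mental
lexicon of concepts, lemmata and phonological forms encoded as
64-dimensional *semantic pointers*, buffers of leaky integrate-and-fire
neuron ensembles representing them, associative cleanup memories mapping
between lexical levels, circular-convolution binding of words to ordinal
positions, and a gated recurrent short-term memory — and then lesions it:
`ablate()` silences a random fraction of a chosen component's neurons, and
sweep drivers chart task performance as a function of the ablated fraction.

The core quantities are:

* **similarity trajectories** `s_p(t) = p · x̂(t)/‖x̂(t)‖` between a buffer's
  decoded state and every vocabulary pointer,
* **binding algebra** `m = Σ_i Pos_i ⊛ c_i` (circular convolution with
  unitary position pointers) for list memory, recovered by
  `m ⊛ Pos_i†` plus cleanup,
* **correct-item counts** per screening run, and their per-fraction means,
  onsets and floors across an ablation sweep.

## A worked example

```r
library(spascreen)

# a reduced-scale mental lexicon: 100 entries, 25 superordinate categories
lex <- generate_lexicon(n_entries = 100, n_superordinates = 25,
                        n_syllable_parts = 120, seed = 42)

# physiological picture naming: 20 scenes, distractors then target
items <- wwt_item_set(lex)
trial <- run_wwt_naming(lex, items = items, seed = 1)
trial
#> <screening_trial> task 'wwt': 20 / 20 correct (seed 1)

# repetition of the ten-word list through the binding memory
rep_trial <- run_demtect_repetition(lex, seed = 1)
rep_trial
#> <screening_trial> task 'demtect': 9 / 10 correct (seed 1)

# lesion the concept production buffer and chart naming performance
sw <- run_sweep(sweep_config("wwt", "concept_prod", lexicon = lex,
                             base_seed = 11, items = items))
tidy(sw)      # per-fraction mean/min/max correct counts
glance(sw)    # onset and floor of the decline, pooled median, cut-off share
autoplot(sw)  # the performance-versus-ablation curve
```

A `screening_trial` is a tibble (one row per item: target, produced symbol,
correct flag); an `ablation_sweep` is a tibble of
`(fraction, rep, seed, n_correct)` rows. `n_correct(trial)` gives the
headline score; 20/20 on naming and about seven of ten list words are the
unimpaired reference values, and the sweep's `onset` / `floor` are the
largest ablation fraction with unimpaired mean performance and the smallest
fraction with a collapsed (≤ 1 correct) mean.

A thin command-line front end is installed at `inst/cli/spascreen`
(`generate-lexicon`, `run-wwt`, `run-demtect`, `sweep`).

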