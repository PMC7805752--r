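---
title: "The semantic-pointer screening model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The semantic-pointer screening model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

spascreen simulates two medical-screening subtasks — picture-induced word
naming and immediate repetition of a ten-word list — with a large-scale
neural model of lexical and cognitive processing, and then relates
microscopic neural damage (silencing a fraction of a component's neurons) to
macroscopic behavioural deficits (fewer correctly produced words). This
vignette explains the model, the free parameters and how they were fixed,
the synthetic lexicon, numerical choices, and known limitations.

## Semantic pointers and the binding algebra

All content — concepts, lemmata, phonological forms, task-control conditions
and ordinal positions — is represented by *semantic pointers*: named unit
vectors in $\mathbb{R}^D$ with $D = 64$. Pointers are drawn with i.i.d.
Gaussian components and normalised; a vocabulary owns the draw so that a
`(seed, insertion index)` pair is fully reproducible. Two structural
operations act on pointers:

* **Binding** is circular convolution, $a \circledast b$. It is commutative,
  linear in each argument, and has $(1, 0, \dots, 0)$ as identity element.
* **Unbinding** is binding with the index-involution approximate inverse
  $a^\dagger$ (first component fixed, the rest reversed):
  $(a \circledast b) \circledast b^\dagger \approx a$.

Ordinal position pointers are *unitary* (their discrete Fourier spectrum has
unit magnitude everywhere), so binding with a position is norm-preserving
and exactly invertible — the only approximation error left in a
position-bound memory trace is the crosstalk of the other stored items.

A list is stored as a superposition
$m = \sum_i \mathrm{Pos}_i \circledast c_i$. Unbinding with
$\mathrm{Pos}_i$ recovers $c_i$ plus crosstalk whose projection onto any
fixed vocabulary entry has standard deviation about
$\sqrt{k-1}/\sqrt{kD}$ for $k$ stored items. At $D = 64$, $k = 10$ and a
100-entry vocabulary the expected maximum distractor similarity (~0.36)
already exceeds the signal coefficient ($1/\sqrt{10} \approx 0.32$): a
*single* 64-dimensional trace cannot support the screening's behavioural
range of 5–9 recalled words out of 10. This is why the short-term memory is
a small bank of submemory traces (below).

## The neural substrate

A **buffer** is an array of $D$ independent one-dimensional leaky
integrate-and-fire ensembles of 50 neurons each (64 × 50 = 3,200 neurons),
with ±1 scalar encoders. Neuron parameters are the standard defaults of
NEF-style simulators: membrane time constant 20 ms, refractory period 2 ms,
maximum rates uniform in 200–400 Hz, intercepts uniform over the represented
range. Identity decoders are ridge-regularised least squares
(regularisation 0.1 × maximum rate); an all-silent ensemble degrades to zero
decoders with a flag rather than an error, so fully ablated components still
run. The per-ensemble represented radius defaults to $4/\sqrt{D}$, i.e.
about four standard deviations of the components of a random unit pointer —
resolution is spent where pointer components actually live.

**Connections** are first-order low-pass synapses (τ = 10 ms) carrying the
identity, a weight matrix, or the circular convolution of two decoded
source states (the bind/unbind pathways). Routing gates are multiplicative
masks on connection outputs driven by the task schedule.

An **associative memory** maps one vocabulary to another through one
thresholded detector population per entry; the total neuron budget is twice
a buffer's (6,400), split evenly. A detector receives the dot product of the
memory's input with its entry's pointer and ramps from 0 to 1 over 0.15
similarity units above threshold. *Cleanup* memories add mutual inhibition
between the detectors (winner-take-all), snapping a noisy state to its best
entry. Detector decoders use a deliberately higher regularisation (0.5):
with the default 0.1 a detector's decoder weights partially cancel, and
random neuron deletion then swings its output wildly (a 20 % lesion could
silence a detector outright); with 0.5 every neuron contributes a small
positive share and a lesioned detector's output shrinks roughly in
proportion to its surviving neurons — the graceful degradation regime the
ablation experiments probe.

A **gated memory** is a buffer with recurrent feedback through a slow
synapse (τ = 100 ms). Feedback gain is 0.99: the decoded feedback loop is
measured to be slightly expansive, and just-below-unit gain nulls that drift
so stored items neither grow (a spurious primacy gradient) nor fade over the
task's ~10 s. The memory ensembles use a tighter radius (0.3 ≈ 2.3 standard
deviations of a normalized superposition's components) because the recurrent
decode distortion scales with the radius; at radius 0.5 the accumulated warp
over three seconds of holding was the single largest loss of recall
fidelity. Reset is modelled as population inhibition: an output gate
(`act_<label>`) that silences the memory, emptying it within tens of
milliseconds.

**Rate mode and tabulation.** The screenings run in rate mode: each
ensemble's decoded output is a static function of its input, which the
engine tabulates once per build (129 nodes over 1.5x the radius, exact at
the nodes, interpolation error below 0.5 % of the radius) and interpolates
during stepping; a test asserts the tables match per-neuron evaluation. Spiking mode integrates membrane state per neuron and is
checked against rate mode at steady state. The network step is 2 ms for the
screening runs (the generic network default is 1 ms); with 10 ms synapses
and piecewise-constant inputs the trajectories are insensitive to this
choice.

**Ablation** silences `round(fraction × N)` uniformly drawn neurons
completely — no spikes, no bias-driven activity, no contribution to any
decoded output — for the whole run. Decoders are *not* re-solved: this is a
lesion, not re-learning. A fraction of 0 is bit-identical to the intact
model; re-application of the same specification is idempotent. For the
memory bank, the target `mem` draws the ablated set jointly across all
submemory neurons.

## The synthetic mental lexicon

The knowledge repository is generated, not read from data. Each entry is a
concept (`C_*`), lemma (`W_*`) and phonological form (`P_*`) in 1:1:1
correspondence, a category (one of the superordinate concepts of the deep
concept network), an association partner, and a random 1–3-part syllable
decomposition over a shared syllable-part pool (the deep phonological
network; represented but not exercised by the two tasks). Concepts of the
same category are drawn around a shared category core with mixing
coefficient 0.4 — strong enough that semantically related entries visibly
co-activate during lexical access, yet below the cleanup confusion regime.
Full scale is ~1,000 entries, ~250 superordinates and ~1,200 syllable
parts; the quantitative experiments in this package run at a reduced scale
of 100 entries / 25 superordinates, which keeps a full ablation sweep at
minutes instead of days while preserving every mechanism.

The screening fixtures are always present regardless of scale or seed: the
ten-word repetition list (Teller, Hund, Lampe, Brief, Apfel, Hose, Tisch,
Wiese, Glas, Baum) and the naming example scene in which the distractors
grass, man and wheel precede the target wheelbarrow.

## The screening model

The wired architecture comprises a visual pathway (`visual_in` →
`con_visual`), an auditory pathway (`audio_in` → `phono_audio` →
`word_audio` → `con_audio`), the cognitive processing module
(`concept_perc` → cleanup → `concept_in` → `concept_through` → cleanup →
`concept_out`, plus `position`, `bind`, `unbind` and the memory bank), the
speaking pathway (`concept_prod` → cleanup → `word_prod` → `phono_prod`),
and the `input_control` buffer carrying the timed task conditions. The
comprehension and cue-facilitation pathways of the full architecture are
out of scope here and not wired.

Design choices worth recording:

* **Lexical co-activation.** Where buffers access the mental lexicon
  (`concept_perc`, `concept_prod`) the connection adds a symmetric
  sum of outer products over the association relations, scaled by gain 0.3
  and then normalised so a lexical pointer keeps unit amplitude. This
  reproduces the characteristic picture of lexical access — several related
  entries visibly active below the target — without inflating the signal
  the downstream thresholds see.
* **Auditory level-up mappings are winner-take-all associative memories.**
  A purely linear associator over M = 100 entries at D = 64 injects
  crosstalk of norm $\approx \sqrt{M/D} > 1$ and the perception pathway
  locks onto wrong concepts; thresholded detectors with competition model
  the fact that one word is heard at a time.
* **The lemma-to-phono relay is winner-take-all too**: only one articulatory
  form can be realised at a time. Without competition, lemma-pair overlaps
  (up to ~0.4 at D = 64) saturate the relay into full-amplitude phantom
  productions. Its detection threshold is low (0.2; a 1:1 relay needs no
  separation margin), which is what lets production survive deep upstream
  lesions before collapsing.
* **Short-term memory bank.** Items are routed to 2 gated submemory traces
  in rotation by the task control (which knows the item index from the
  schedule); each trace holds 5 position-bound items, inside the capacity
  knee of a 64-dimensional trace. Recall unbinds the matching trace with
  gain 2.5, chosen so a well-stored item's recalled similarity is about 1 —
  the activation scale of every other buffer.
* **Fixed timing replaces somatosensory feedback.** Presentations last
  0.25 s with 0.1 s gaps; production windows 0.5 s; the store gate opens
  0.10 s after stimulus onset so the perception chain has settled on the
  new word before its binding is integrated (earlier opening smears
  adjacent items into each other's bindings).
* **Action selection.** Utilities are dot products between the decoded
  input-control state and condition pointers; the reference selector takes
  the argmax above threshold 0.3 with a 0.05 hysteresis margin (tie-break by
  declaration order). Routing gates follow the schedule directly; the
  selector is run over the decoded trajectory and the realized action
  sequence (PROCESS_NOMEN → SPEAK; KEEP → RECALL) is asserted in the tests.
  A mutual-inhibition neural selector is provided and must agree with the
  reference on steady inputs.

## Scoring

A window's production is the vocabulary entry that is the
maximal-similarity candidate with raw (unnormalised) similarity ≥ 0.4
sustained for ≥ 30 ms; no sustained winner is a null production, counted
incorrect. Naming is scored on the phonological production buffer against
the target's form; repetition is scored on the conceptual production buffer
with unordered credit, each list word creditable once. Similarity *plots*,
by contrast, use the conventional normalised state direction; a decoded
state of exactly zero yields zero rows rather than a division.

## Calibration protocol

The free parameters above (thresholds, gains, radii, timing, submemory
count) were fixed on the physiological runs only — 20/20 named items on
every naming run and a repetition distribution of about seven words (all
runs within five to nine) — and then frozen before the lesion experiments.
The ablation sweeps re-use exactly this configuration; onset and floor
percentages are read off per-fraction means of three independent
build+lesion repetitions per level, as `find_thresholds()` documents.

## What the synthetic data does and does not show

The generator emulates the *structure* of a mental lexicon (three levels,
categories, associations, non-orthogonal pointer geometry) but not word
frequency, age-of-acquisition, phonotactics or real German phonology; item
labels are opaque symbols. Passing tests therefore demonstrate the
mechanisms — binding capacity, cleanup competition, lesion-response shapes —
not psycholinguistic coverage of any particular word corpus. Runtimes are
kept to minutes by the reduced 100-entry lexicon and rate mode; the
full-scale spiking model the architecture mirrors runs orders of magnitude
longer per item.

## Known limitations

* The cue-facilitation and comprehension runs of the naming test, the
  remaining four repetition-screening subtasks, writing, articulation and
  learning are all out of scope; the corresponding pathways are absent or
  inert.
* Rate mode is deterministic; run-to-run variability comes from the seeded
  neural builds and ablation draws, not spiking noise.
* The bind/unbind buffers are driven by the algebraic circular convolution
  of their source buffers' decoded states rather than by product-neuron
  networks; the buffers themselves (and everything downstream) remain
  neural.
* Behavioural thresholds from lesion sweeps are grid quantities (10 % steps;
  1 % for the memory sweep) and carry that resolution.
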