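---
title: "Hypernym substitution and its readability evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypernym substitution and its readability evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medsimplify)
```

## The problem

Biomedical definitions and clinical notes are written at a collegiate
reading level while the average adult reads at roughly a 7th--8th grade
level. One productive simplification strategy is *hypernym substitution*:
replace a complex domain term with its superordinate umbrella term
("lymphoma is a type of cancer", so "lymphoma" can become "cancer"). The
substitution usually costs some specificity but buys a large drop in
lexical difficulty, because hypernyms tend to be shorter, more frequent
words.

`medsimplify` implements a rule-based version of this idea end to end,
together with the full evaluation harness needed to benchmark any
simplifier (rule-based or neural): four readability formulas, two sentence
complexity measures, exact paired Wilcoxon signed-rank tests, Cohen's
kappa for human rating studies, and seeded synthetic data generators so
everything is testable without licensed terminology resources.

## The substitution rule

A token span is rewritten only if it is judged **complex and biomedical**:

1. **Complex** — the maximum per-token complexity score over the span
   reaches the decision threshold (default **0.65**). Complexity scoring
   is a pluggable interface; the shipped default scorer is deterministic:
   words on a fixed 100-word common list score 0, any other word scores
   `0.25 * max(0, syllables - 1) + 0.05 * max(0, length - 4)`, clamped to
   [0, 1]. Calibration intuition: "cancer" scores 0.35, "receptor" 0.70,
   "histamine" 0.75. Taking the span *maximum* favours recall on
   multi-word terms whose function words dilute an average.
2. **Biomedical** — the span fuzzy-matches a term of the hypernym lexicon.
   Matching is character 3-gram TF-IDF cosine: terms are padded with two
   boundary markers per side (so prefixes and suffixes get their own
   grams), `IDF = ln(N/df)` over the lexicon terms as documents, profiles
   L2-normalized. The acceptance cutoff `min_sim` defaults to 0.4; there
   is no universally correct value for fuzzy terminology lookup, so it is
   a configurable parameter rather than a constant.

Among the candidate hypernyms recorded for the matched term (across
WordNet-style entries, semantic-type labels and custom rows), the one
with the **fewest total syllables** is substituted; ties break to fewer
characters, then lexicographically.

Three surface repairs are applied and recorded per substitution: a
preceding "a/an" is re-agreed to the replacement's initial letter (case
preserved), sentence-initial capitalization is transferred, and whitespace
is normalized. No further grammar repair is attempted: rule-based
simplifiers are known to leave residual inflection artifacts, and
aggressive repair risks changing meaning.

### Span construction choices

The design space here was genuinely open; the package fixes it as follows.

* Candidate spans are token n-grams up to 3 tokens, inside one sentence.
* **Edge rule**: the first and last token of a span must have a positive
  complexity score. Without it, a window such as "h4 histamine receptor"
  passes both gates (the trigram still cosine-matches "histamine
  receptor" at ~0.84) and the zero-scoring "h4" is deleted along with the
  match.
* **Overlap resolution is by match quality**: all qualifying windows are
  collected, then the highest-similarity window claims its tokens first
  (ties: leftmost, then longest). Resolving purely by position
  (longest-first at each leftmost start) lets weak windows do damage in
  both directions: "Lymphoma was found" cosine-matches "lymphoma" at
  ~0.89 (grams outside the lexicon vocabulary barely dilute a TF-IDF
  profile), and a window starting at "showed" can swallow the exact term
  "carcinoma" two tokens later. Similarities are compared after rounding
  to 9 decimals so that two exact matches (cosine 1 up to float noise)
  tie and the tie-break actually fires.

```{r}
lex <- read_lexicon(system.file("extdata", "example_lexicon.tsv",
                                package = "medsimplify"))
tt <- tokenize(
  "Interacting selectively and non-covalently with a h4 histamine receptor.")
identify_targets(tt, lex)[, c("surface", "complexity_score", "hypernym")]
```

## Tokenization and syllable conventions

Every metric rests on one fixed, deterministic convention: sentences end
at runs of `.`, `!`, `?`; word tokens are maximal alphanumeric runs (so
hyphenated compounds split, and punctuation never counts as a word);
syllables are maximal vowel-letter runs (`a e i o u y`) minus a terminal
silent "e" (unless the count would reach zero), plus one for a terminal
consonant+"le", floored at one. Tokens without vowels ("h4") count one
syllable; digits count as characters but never as vowels. Abbreviation
aware sentence splitting is deliberately not attempted — the target texts
are short definitions.

Published grade levels for the same text can differ under other
tokenizer/syllabifier conventions; comparisons are meaningful *within*
one convention, which is why the harness always compares pre vs post
under its own rules rather than against externally printed grades.

## The evaluation harness

Per definition (never pooled over a corpus):

* **FKS** `206.835 - 1.015 W/S - 84.6 Y/W` (higher = easier; not clamped
  to its nominal 0--100 scale),
* **FKG** `0.39 W/S + 11.8 Y/W - 15.59`,
* **ARI** `4.71 C/W + 0.5 W/S - 21.43`,
* **GFI** `0.4 (W/S + 100 X/W)` with `X` = words of 3+ syllables,

with `W, S, C, Y` words, sentences, characters, syllables. Grade values
are reported unrounded; `round_grade()` provides the half-up display
rounding used when quoting "nth grade".

**MTLD** (lexical diversity) uses the standard factor threshold 0.72, a
trailing partial factor `(1 - TTR)/(1 - 0.72)`, and averages a forward and
a reverse pass. When zero factors accrue (e.g. all tokens distinct — common
in very short definitions) the measure is *undefined*, reported `NA`, and
excluded from corpus summaries with the exclusion counted — not infinity,
not the token count.

**MDD** (syntactic complexity) is the mean linear distance `|head - dep|`
over dependency arcs read from standard CoNLL-U, pooling all arcs of a
definition's sentences (robust when single sentences contribute one arc),
excluding the root arc and punctuation dependents. The package does not
bundle a parser; parses arrive as CoNLL-U produced upstream.

**Paired tests.** Deltas are tested with a two-sided Wilcoxon signed-rank
test: zero differences discarded (Wilcoxon's treatment, not Pratt's),
average ranks for ties, and an *exact* p-value from the full `2^n` sign
distribution (computed by convolution over doubled ranks, valid under
ties) for up to 25 non-zero pairs, otherwise a normal approximation with
continuity and tie corrections — the two agree to within 0.01 at the
crossover. Significance stars follow the three tiers `*` p < 0.05, `**`
p < 0.01, `***` p < 0.005. Confidence intervals for mean deltas use a
seeded nonparametric bootstrap (10,000 resamples by default), since no
distributional form is assumed anywhere else.

**Human ratings.** Cohen's kappa (unweighted — plain kappa is what rating
studies of this kind report) with the conventional bands (0.61--0.80
"substantial", etc.), undefined when both raters are constant and
identical; Likert rating tables compare systems pairwise per metric with
the same exact Wilcoxon machinery, flagging all-zero-difference pairs as
degenerate rather than erroring.

## The synthetic generator

`gen_corpus()` emulates the *shape* of terminology-glossary definitions:
about 3 sentences and about 30 words per definition under the defaults
(sentences ~ `1 + Pois(2)`, words per sentence ~ `1 + Pois(9)`), filler
drawn from the fixed 100-monosyllable common list, and pseudo-biomedical
terms built by consonant--vowel syllable concatenation (3--6 syllables,
vowels `a i o u` only, so the syllable counter is exact on them by
construction). Default complex-term density is 0.2 — a few terms per
definition, matching the feel of glossary text.

Every term gets a hypernym with at least `hypernym_syllable_gap` (default
2) fewer syllables, capped at 3 syllables so a replacement always scores
below the 0.65 threshold: substitution can never re-flag its own output,
which makes simplification provably idempotent on generated corpora.
About 30% of terms carry a second, longer candidate to exercise
minimal-syllable selection. Failure injection blanks exactly
`ceiling(rate * n)` records to exercise failure logging and the aligned
evaluation of partially-lost corpora. Three RNG streams (vocabulary,
text, failure injection) derive from one master seed so artifacts never
perturb each other.

What the generator does **not** emulate: real medical morphology and
collocation, grammaticality, sense ambiguity, abbreviations/acronyms, or
the character-length profile of real glossary entries (generated
definitions average ~170--190 characters, below the ~230 of real ones,
because the filler vocabulary is deliberately monosyllabic). Passing
tests on synthetic corpora therefore demonstrate the *mechanics* —
gating, substitution, bookkeeping, statistics — and the algebraically
forced direction of readability change, not performance on real clinical
language.

Because generated hypernyms have strictly fewer syllables and identical
word counts, per-definition FKG must fall and FKS must rise for every
definition that receives a substitution — the test suite asserts this
exactly on a 200-definition corpus, and the corpus-level report reproduces
the expected sign pattern (FKS up; FKG, ARI, GFI down; all `***`).

```{r, eval = FALSE}
g <- gen_corpus(200, seed = 1337)
simp <- simplify_corpus(g$corpus, g$lexicon)
evaluate_simplification(g$corpus, simplified_corpus(simp))
```

## Numerical and degenerate-input choices

* Empty/whitespace-only text is an explicit error class; corpus runs
  isolate it per record into the failure log instead of aborting.
* Formulas return `NA` (undefined marker) on zero words or sentences;
  undefined values are dropped at alignment time with drop counts logged.
* A single-term lexicon makes every IDF zero; the index then falls back
  to raw term-frequency profiles.
* Queries whose grams never occur in the lexicon return empty matches.
* Ranking ties in the matcher break lexicographically; hypernym-selection
  ties break by characters then lexicographically; similarity comparisons
  round to 9 decimals.
* The exact Wilcoxon enumeration is a convolution over doubled ranks
  (integers even under average-rank ties), so "exact" really is exact in
  the presence of ties, up to `exact_limit = 25`.

## Problem sizes

The shipped tests and the reproduction script use 200-definition corpora
for directional benchmarks, 1000 definitions with a 25.7% injected
failure rate for the alignment structure (1000 → 743 usable pairs), 100
random projective trees for the MDD oracle, and full-enumeration Wilcoxon
checks up to `n = 12`. These sizes give stable averages (binomial noise
on corpus means well under the asserted margins) while keeping a full run
in the low minutes on one core.

## Known limitations

* The default complexity scorer is a transparent stand-in interface
  implementation, not a trained model; its threshold semantics (0.65) are
  kept so trained scorers can be plugged in without touching the
  pipeline.
* Biomedical recognition is gazetteer-style (lexicon membership via fuzzy
  match); terms absent from the lexicon are invisible to the pipeline.
* Only a/an agreement and sentence-initial capitalization are repaired;
  verb inflection, determiner insertion and sense disambiguation are out
  of scope.
* MDD depends on upstream parses; no parser ships with the package.
* Word-level metrics cannot see grammaticality: a text can score "easier"
  while reading worse, which is precisely why the harness also supports
  human rating analysis.
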