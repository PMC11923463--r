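---
title: "drugpulse: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{drugpulse: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugpulse)
```

## What the package models

drugpulse mines drug discourse from short-text social-media corpora for
pharmacovigilance-style surveillance. Its unit of data is a timestamped
short text (a tweet); its unit of inference is a *mention* of a drug or
symptom concept in such a text. Five stages feed each other:

1. **Preprocessing** — texts carrying hyperlinks are excluded outright
   (link-bearing posts are overwhelmingly headlines or quotations, not
   first-person discourse), user handles are masked to `@USER`, and every
   timestamp is binned into consecutive 7-day windows anchored at the
   study start (default 2020-02-01 through 2022-04-30, weeks 0–117). The
   anchored-bin convention, not ISO weeks, keeps "week 0" aligned with the
   start of data collection.
2. **Entity extraction** — lexicon scanning that maps colloquial surface
   forms ("hcq", "vit d") to canonical concepts with a class (drug or
   symptom) and an optional ATC level-1 letter. Matching is
   case-insensitive, word-boundary-guarded, and longest-match-first with
   left-to-right tie-breaking, so nested surfaces are never double
   counted. A hook accepts an external model tagger; its raw spans are
   normalized against the same lexicon, and unmapped surfaces are dropped
   (and counted) because every downstream stage requires canonical
   concepts. Concepts are then thresholded: drugs kept only with strictly
   more than 1000 mentions, symptoms strictly more than 250.
3. **Targeted sentiment** — each (tweet, entity) pair becomes the scorer
   input `"<text> [SEP] <canonical>"`. The scorer is pluggable; the
   shipped baseline counts positive vs negative valence-lexicon cues in
   the tweet part and returns positive/neutral/negative. Aggregates are
   per-mention (a tweet naming two drugs contributes to both): per-entity
   class proportions whose denominator is all mentions the scorer labeled
   (neutral included; abstentions excluded), and weekly polarity ratios in
   which a week with no scored mentions is *missing*, never zero.
4. **Topic modeling** — our own collapsed Gibbs sampler for latent
   Dirichlet allocation. Token topics are resampled from
   $p(z_i = k \mid \cdot) \propto (n_{dk} + \alpha)\,
   (n_{kw} + \beta) / (n_k + V\beta)$ with the current token excluded.
   Model selection over a K grid reports held-out perplexity and UMass
   coherence; K* is the grid value with the highest mean coherence among
   those whose mean perplexity lies within a relative tolerance band
   (default 10%) of the grid minimum, and the full diagnostics table is
   returned so users can override.
5. **Co-occurrence networks** — each retained entity becomes a binary
   vector over tweets (presence/absence; multiplicity is collapsed here
   and only here). Edge weights are cosine similarities, which for binary
   rows reduce to $|T_i \cap T_j| / \sqrt{|T_i|\,|T_j|}$. An edge exists
   iff its weight strictly exceeds a threshold τ (0.005 drug–drug, 0.05
   drug–symptom by default) and isolated nodes are pruned afterwards.
   Communities come from our own Louvain (fast unfolding)
   implementation; partitions are compared to ATC classes by adjusted
   Rand index and normalized mutual information; networks export to GEXF
   1.2 / GraphML for Gephi.

## Tunable parameters that matter

| parameter | default | why |
|---|---|---|
| study window | 2020-02-01..2022-04-30 | pandemic-era discourse window; 118 weekly bins |
| URL pattern | `https?://` or `www.`-token | matches shortened-link rendering; configurable |
| min mentions, drug / symptom | > 1000 / > 250 | strict "more than"; a concept at exactly the threshold is excluded |
| τ drug–drug / drug–symptom | 0.005 / 0.05 | strict `>`; sparser cross-class supports need the larger τ |
| LDA α, β | 50/K, 0.01 | common collapsed-Gibbs defaults; both exposed |
| Gibbs sweeps | 500 (fits), 100 (fold-in) | past typical burn-in for corpora this size |
| bigram merge | count ≥ 20, NPMI ≥ 0.3 | collocations such as "wash hand" become single tokens |
| coherence topN | 20 | matches the reported top-keyword depth |
| Louvain resolution | 1.0 | classic modularity |

## The synthetic-data generator: what it emulates, and what it does not

Real platform corpora cannot be redistributed, so every stage is tested
against `generate_corpus()`, which emits a deterministic corpus *plus
ground truth* from a stated world:

- **Topics.** Documents are token bags from an LDA model: θ ~ Dir(α)
  per document, planted topic-word rows either supplied or sampled from
  Dir(β). Note that Dir(0.01)-sampled topics are nearly degenerate (a
  handful of words carry all mass); when a test needs a realized
  vocabulary of a stated size, topics are planted block-structured (90%
  of each topic's mass uniform on its own vocabulary block) — the
  standard topic-recovery construction.
- **Entities.** Each entity has a marginal per-tweet rate; entities
  sharing a community block co-occur with joint probability
  `rate_i * rate_j * boost`, realized by a latent block activation with
  probability 1/boost followed by per-member Bernoulli(rate × boost)
  draws (feasible iff rate × boost ≤ 1). Surface variants are chosen
  uniformly and injected into alternating token slots, so recorded
  character spans are exact and mentions never collide.
- **Sentiment.** A tweet with mentions draws *one* latent 3-class label
  from the profile of a uniformly chosen anchor mention, and a
  deterministic cue token is planted next to each mention. One label per
  tweet — not per mention — because the baseline scorer counts cues over
  the whole tweet and could not disambiguate mixed polarities; the cost
  is slight per-drug profile mixing when entities co-occur, which is why
  profile-recovery checks use single-entity worlds. An optional
  profile switch at a given week emulates opinion shifts.
- **Volume and noise.** Timestamps follow a relative weekly-volume shape;
  URLs are appended with probability `url_fraction` (default 0.64,
  mirroring the roughly one-third retention reported for large pandemic
  tweet collections); some tweets carry a leading user handle.

What the generator does **not** emulate: grammar, retweet cascades, user
networks, bots, misspellings outside the variant list, or adversarial
substrings. A green extraction test therefore establishes lexicon-scan
correctness, not robustness to noisy orthography; a green sentiment test
establishes the aggregation pipeline, not classifier quality (the
model-based tagger and scorer the pipeline was designed around remain
external plug-ins).

## Numerical choices, ties and degenerate inputs

- Yates-corrected chi-square uses `max(|O−E| − 1/2, 0)` per cell, so
  identical rows give exactly 0; a zero expected cell (a zero margin) is
  an error rather than a silently defined value.
- The evaluation harness reproduces the printed accuracy comparison
  (97.8% vs 89%) with n = 1000 evaluated items *per method* — the only
  table consistent with the published statistic of 61.4.
- UMass coherence follows the pair convention written into this
  package's contract: for top words ordered by decreasing probability,
  pairs i < j contribute `log((D(w_i, w_j) + 1) / D(w_j))` — the
  conditioning document frequency is the lower-ranked word's. Zero-df
  conditioning words skip the pair.
- Dominant-topic ties break to the lowest topic id; top-k concept ties
  break lexicographically and are logged; neighbor-rank ties break by
  node name. All three are deterministic by construction.
- Louvain visits nodes in sorted order (seed shuffles reproducibly),
  accepts only strictly positive modularity gains (ties to the lowest
  community id), and aggregates until no gain remains; the reported Q is
  recomputed from the final partition, not accumulated.
- Perplexity fold-in freezes the fitted topic-word distributions and
  Gibbs-samples held-out document mixtures (100 sweeps); out-of-vocabulary
  held-out tokens are dropped and counted. A uniform topic-word model
  scores exactly V — used as a closed-form test anchor.
- Empty corpora halt the pipeline gracefully at preprocess; an empty
  edge set defines Q = 0 with a warning; zero incidence rows are
  excluded before cosine (zero vectors have no defined similarity).

## Open design points resolved here

- Whether incidence vectors are binary or frequency-weighted is not
  specified by the study this design follows; binary presence/absence was
  chosen for scale invariance (a count mode can be added behind the same
  interface without changing edge semantics).
- Quote-tweets and media links count as URL-bearing: any hyperlink
  pattern excludes the text.
- Duplicate tweet ids keep the first record with a warning.
- The drug–symptom network emits only cross-class edges by default;
  within-class edges are available behind a flag.
- "Entities with sentiment" (the ratio denominator) means all mentions
  the scorer labeled with any of the three classes; scorer abstentions
  are excluded and counted.

## Known limitations

- The lexicon arm is exact-match only; recall against colloquial
  spellings is bounded by the variant list. The model-tagger hook exists
  precisely so a trained NER model can lift this.
- Louvain is a greedy heuristic: on small graphs the test suite checks
  it never exceeds the exhaustive-search optimum, but it carries no
  global-optimality guarantee.
- Coherence comparisons across very small vocabularies are weakly
  informative (topN is capped at V); perplexity carries most of the
  selection signal there.
- Weekly ratios for thinly mentioned entities are noisy; the series
  deliberately reports missing (not zero) weeks so downstream smoothing
  is explicit.

Every empirical number quoted in this vignette (61.4; TV = 0.035;
dominant-topic accuracy 0.992; select_k winners 3,3,3,5,5) is computed by
the test suite in `tests/testthat/`, not asserted here.
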