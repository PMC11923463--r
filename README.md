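# drugpulse

Mining drug discourse from short-text social-media corpora, for
pharmacovigilance and infodemiology researchers who need drug/symptom
surveillance signals from platforms they cannot redistribute.

The package implements an end-to-end pipeline over timestamped short
texts (tweets):

- **Preprocessing** — URL-bearing posts excluded, user handles masked to
  `@USER`, anchored 7-day weekly binning over a configurable study
  window (default 2020-02-01 .. 2022-04-30, weeks 0–117).
- **Entity extraction & normalization** — case-insensitive,
  word-boundary, longest-match-first lexicon scanning that maps
  colloquial surfaces (`hcq`, `vit d`) to canonical concepts, with a
  hook for external model taggers and strict frequency thresholds
  (drugs > 1000 mentions, symptoms > 250).
- **Targeted sentiment** — pluggable scorer over the
  `"<text> [SEP] <entity>"` contract; per-entity distributions and
  weekly polarity-ratio series (missing, not zero, on empty weeks).
- **Topic modeling** — own collapsed-Gibbs LDA,
  `p(z=k|·) ∝ (n_dk+α)(n_kw+β)/(n_k+Vβ)`, with held-out perplexity,
  UMass coherence, and grid selection of K.
- **Co-occurrence networks** — binary entity×tweet incidence; edge
  weight = cosine similarity, for binary rows
  `|T_i∩T_j|/√(|T_i||T_j|)`; edges kept iff weight strictly exceeds τ
  (0.005 drug–drug, 0.05 drug–symptom); Louvain community detection,
  modularity, ARI/NMI agreement with ATC classes, and GEXF/GraphML
  export for Gephi.
- **Synthetic corpus generator** — seeded worlds with planted topics,
  entity co-mention blocks (joint rate `r_i·r_j·boost`), sentiment cue
  tokens and weekly volume shapes, plus full ground truth, so every
  stage is testable without platform data.

A reference evaluation harness reproduces the Yates-corrected chi-square
comparison of two extraction methods: accuracies 97.8% vs 89% at n = 1000
per method give χ²₁ = 61.39.

## Worked example

```r
library(drugpulse)

cfg <- generator_config(
  n_tweets = 5000, seed = 42, url_fraction = 0.3,
  community_blocks = list(list(members = c("ivermectin", "hydroxychloroquine"),
                               boost = 12)))
sim  <- generate_corpus(cfg)
kept <- filter_urls(sim$corpus)$kept

mentions <- extract_mentions(kept, build_matcher(sim_lexicon(cfg)))
head(sort(table(mentions$canonical), decreasing = TRUE), 5)
#>         ivermectin              fever hydroxychloroquine          vitamin d
#>                106                101                 98                 76
#>               zinc
#>                 73

scored <- score_mentions(mentions, kept)$scored
sentiment_distribution(scored, c("ivermectin", "zinc"))
#>    canonical   n p_positive p_neutral p_negative
#> 1 ivermectin 106      0.274     0.500      0.226
#> 2       zinc  73      0.288     0.479      0.233

m   <- build_incidence(mentions, unique(mentions$canonical), kept$tweet_id)
net <- build_network(m, tau = 0.005)
net
#> cooc_network: 10 nodes, 32 edges (tau = 0.005)

louvain(net, seed = 1)$modularity
#> [1] 0.241

top_neighbors(net, "ivermectin", k = 3)
#>             neighbor weight
#> 1 hydroxychloroquine 0.3630
#> 2              cough 0.0580
#> 3          vitamin d 0.0446
```

The planted ivermectin–hydroxychloroquine co-mention block surfaces as
the dominant edge (cosine 0.363, an order of magnitude above background)
— exactly the kind of drug–drug signal the network stage is built to
expose. Mention counts track the planted base rates, and sentiment
proportions sum to 1 over positive/neutral/negative with the default
balanced profile.

## Command line

```sh
exec/drugpulse simulate   --n 2000 --seed 7 --out corpus.jsonl
exec/drugpulse preprocess --in corpus.jsonl --out kept.jsonl
exec/drugpulse extract    --in kept.jsonl --lexicon inst/extdata/example_lexicon.csv --out mentions.csv
exec/drugpulse network    --corpus kept.jsonl --mentions mentions.csv \
                          --lexicon inst/extdata/example_lexicon.csv \
                          --min-drug 10 --tau 0.005 --louvain --out net.gexf
exec/drugpulse run        --config pipeline.json
```

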