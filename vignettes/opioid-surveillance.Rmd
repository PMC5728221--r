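---
title: "Detecting illicit drug marketing on microblogs: methods and design"
author: "opiwatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting illicit drug marketing on microblogs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opiwatch)
```

## The surveillance problem

Illicit online pharmacies and individual dealers use public social media to
advertise prescription-controlled substances — including fentanyl and its
analogues — for direct-to-consumer sale. Such posts are rare: in a
keyword-filtered tweet stream about an abused drug, the overwhelming
majority of messages are news reports, and the signal of interest is a tiny
minority of promotional posts carrying hyperlinks to external marketplaces.

`opiwatch` implements that surveillance cascade as a reusable, fully
testable funnel:

1. **Ingest** a keyword-filtered tweet corpus (JSONL).
2. **Topic-model** the corpus with a Biterm Topic Model (BTM), the standard
   topic model for short texts.
3. **Label topic themes** ("news", "online pharmacy", other) — manually via
   a label file, or with a transparent lexicon heuristic.
4. **Isolate news** documents (argmax topic theme) and keep the complement
   as the candidate pool.
5. **Detect sale promotions** in the pool with a selling-argument lexicon
   ("buy", "discount", "price", ...) combined with the topic signal.
6. **Deduplicate** (exact duplicates and retweet variants) and extract
   hyperlinks.
7. **Triage** each link's website category from structured feature records,
   and quantify annotation reliability with Cohen's kappa.

Every stage reports counts into a `funnel_report`, the audit trail of a run.

## The Biterm Topic Model

Tweets are too short for per-document topic mixtures to be estimable (the
sparsity that cripples LDA on microblogs). BTM instead models the corpus as
a bag of *biterms*: unordered pairs of words co-occurring in the same tweet
(the whole tweet is one context window; a document of length $L$ yields
$\binom{L}{2}$ biterms, with repeated tokens contributing pairs from
distinct positions). Generatively, each biterm $b = (w_1, w_2)$ draws a
topic $k \sim \theta$ from a single corpus-level topic distribution, then
both words independently from that topic's word distribution $\phi_k$, with
Dirichlet priors $\theta \sim \mathrm{Dir}(\alpha)$ and
$\phi_k \sim \mathrm{Dir}(\beta)$.

### Collapsed Gibbs sampling

With $\theta$ and $\phi$ integrated out, the sampler resamples each
biterm's topic from its full conditional. Writing $n_k$ for the number of
biterms in topic $k$, $n_{w|k}$ for word-slot counts,
$n_{\cdot|k} = 2 n_k$, $M$ for the vocabulary size:

$$
P(z_b = k \mid \mathbf{z}_{-b}, B) \;\propto\;
(n_k + \alpha)\,
\frac{(n_{w_1|k} + \beta)(n_{w_2|k} + \beta)}
     {(n_{\cdot|k} + M\beta)(n_{\cdot|k} + 1 + M\beta)},
$$

with all counts taken after removing $b$. The sweep is implemented in C++
(`src/btm_gibbs.cpp`), iterates biterms in fixed input order, and draws all
randomness from R's RNG stream, so `set.seed()` makes every fit, dump and
report bit-reproducible. Point estimates use the smoothed count formulas

$$
\hat\theta_k = \frac{n_k + \alpha}{|B| + K\alpha}, \qquad
\hat\phi_{k,w} = \frac{n_{w|k} + \beta}{n_{\cdot|k} + M\beta},
$$

with counts averaged over post-burn-in sweeps. The per-sweep corpus
log-likelihood trace is kept as a convergence diagnostic.

### Defaults and what they mean

| Parameter | Default | Meaning |
|---|---|---|
| `K` | 40 | number of latent topics; enough to separate news sub-themes from promotional chatter in a five-month keyword stream |
| `alpha` | 1 | flat prior on the global topic distribution |
| `beta` | 0.01 | sparse prior on topic-word distributions (topics concentrate on few words, appropriate for tweet vocabularies) |
| `n_sweeps` / `burn_in` | 1000 / 500 | single chain, counts averaged over the last 500 sweeps |
| `top_words` | 10 | words shown per topic summary |

### Document-level inference

BTM has no per-document topic variable, so document assignment is a derived
quantity:
$P(k \mid d) = \sum_{b \in d} P(k \mid b)\,P(b \mid d)$ with
$P(b \mid d)$ uniform over the document's biterms and
$P(k \mid b) \propto \hat\theta_k \hat\phi_{k,w_1} \hat\phi_{k,w_2}$.
Single-token documents fall back to the unigram posterior
$P(k \mid w) \propto \hat\theta_k \hat\phi_{k,w}$; empty documents get the
uniform vector and an `unassigned` flag. Documents go to a theme by the
argmax of this posterior. These rules are deliberate choices: probability
thresholding instead of argmax is left as configuration, and the fit is run
on the full corpus by default (fitting only the non-news remainder is a
config change, not a code change).

### The enumeration oracle

`exact_posterior_small()` computes exact per-biterm topic marginals by
summing the collapsed joint over all $K^{|B|}$ assignments, using the
Dirichlet-multinomial integral
$\log P(\mathbf z) = \sum_k \log\Gamma(n_k+\alpha)
 + \sum_{w,k} \log\Gamma(n_{w|k}+\beta)
 - \sum_k \log\Gamma(2n_k + M\beta)$ (up to constants). It is derived from
the joint, not from the sampler's conditional, so the two routes are
independent; the test suite checks that long-run Gibbs assignment
frequencies match the oracle within a per-biterm total-variation distance
of 0.02.

Two numerical subtleties are worth recording. First, on two-topic test
instances the posterior is exactly symmetric under label exchange, and the
chain migrates between the two labelings slowly at $\beta = 0.01$; the
agreement tests therefore run long chains (4 million post-burn-in sweeps,
well under a second each) so that Monte-Carlo error sits comfortably below
the tolerance. Second, the conditional above multiplies
$(n_{w_1|k}+\beta)(n_{w_2|k}+\beta)$ for *both* words, which for a
same-word biterm ($w_1 = w_2$) differs from the exact joint's
$(n_{w|k}+\beta)(n_{w|k}+1+\beta)$; this follows the model's reference
implementation, same-word biterms are retained in corpora, and
oracle-comparison instances simply use distinct-word biterms.

## Corpus handling

Tokenization lowercases, strips a leading `RT @handle:` prefix, URLs and
mentions, splits on unicode word characters, and drops a frozen English
stopword list (shipped as a data file, so results are reproducible) and
tokens shorter than 2 characters. The vocabulary maps tokens occurring at
least `min_count` times (default 1 — tweet corpora are small) to contiguous
indices ordered by descending frequency with lexicographic tie-breaks.

Duplicate collapsing groups tweets by a canonical key: text with case, the
retweet prefix and (by default) URLs removed and whitespace squeezed.
Stripping URLs treats shortened-link variants of the same advertisement as
one cluster; this is configurable. The cluster representative is never a
retweet when a non-retweet exists, then the earliest timestamp wins, then
input order. Exact-key clustering only: near-duplicate (fuzzy) matching is
out of scope.

## Sale detection and triage

Selling arguments are matched as exact lowercase tokens (never substrings:
"pricey" does not match "price"). The shipped lexicon contains the three
core terms plus a clearly marked extension list; both are plain text files
users can edit and version. A candidate tweet is flagged when it matches at
least one term **or** its topic carries the online-pharmacy theme — the OR
rule maximizes recall, which is the right operating point for a
surveillance funnel whose output is small and human-reviewed; AND is
available by configuration, and each flagged tweet carries its evidence
(matched terms, topic, theme) for audit.

Link triage is deliberately offline: crawling illicit pharmacies raises the
same ethical and legal issues as purchasing from them, so features
(platform kind, no-prescription offer, posted price list, unresolved
redirection) arrive as structured records filled in by a human coder. The
rule order is fixed: unresolved redirection → unclassifiable (this wins
over pharmacy features, with the conflict logged); classifieds platform →
classified ad; any pharmacy signal → online pharmacy; otherwise
unclassifiable for lack of features. Two-annotator reliability uses Cohen's
$\kappa = (p_o - p_e)/(1 - p_e)$; the degenerate case of two identical
constant annotators is defined as 1 with a warning.

Report percentages are rounded half-up to one decimal (so a
27,940-document news partition in a 28,711-tweet corpus prints as 97.3%),
and `funnel_report()` enforces the conservation invariants
`news + candidates = total` and `sum(category counts) = unique link
tweets`.

## The synthetic corpus generator

Real keyword-filtered tweet streams from the relevant period are not
redistributable, so the generator plays that role in all tests. It
emulates: short documents (5–15 tokens) drawn one-topic-per-document from
$K$ latent word distributions; a dominant news theme (default 97.3% of
documents); a small planted minority of sale promotions (default 2.7% of
the non-news remainder) that get a selling argument and a URL appended;
and planted exact duplicates and `RT @synth_user:` variants (default 5%
each) with the cluster map recorded as ground truth.

Design notes:

* **One topic per document** rather than the biterm-level generative story:
  the standard short-text assumption BTM itself exploits, adequate for
  recovery testing and much easier to reason about as ground truth.
* **Uniqueness by construction**: when duplicates are to be planted, base
  documents are resampled until unique under the canonical key, so the
  planted duplicates are provably the only ones and cluster-map recovery
  can be asserted exactly.
* **Balanced recovery benchmark**: the topic-recovery test uses equal topic
  proportions (`alpha_true = Inf`, the symmetric limit) — a skewed random
  draw can leave a topic with a handful of documents, which measures data
  scarcity rather than sampler correctness. Under the benchmark conditions
  (K = 5, M = 100, 2,000 documents of length 8, fit with $\alpha = 1$,
  $\beta = 0.01$) the mean matched total-variation distance between true
  and estimated $\phi$ rows is about 0.03–0.04 across seeds, against an
  acceptance bound of 0.10. Matching uses the optimal one-to-one topic
  assignment (exhaustive over permutations for $K \le 8$, greedy beyond).
* What the generator does **not** emulate: natural language (tokens are
  synthetic words), user/account structure, temporal bursts, near-duplicate
  spam variation, and multilingual content. Passing tests show the
  *mechanics* of the funnel are correct, not that the lexicons or theme
  labels generalize to live data — theme labeling is human-in-the-loop in a
  real deployment.

## Validation modes in the pipeline

`run_pipeline()` has two assignment modes. The default (`"argmax"`) is the
real pipeline: fit BTM, label themes, assign documents by posterior argmax.
The `"truth"` mode (synthetic corpora only) substitutes the generator's
ground-truth topics and labels for the model's — the ground truth plays
the human analyst — which isolates the filter/dedup/triage mechanics from
topic-model estimation error and lets the planted funnel counts be asserted
exactly: detection recall 1.0 on planted sale tweets, one unique link tweet
per planted sale cluster, and exact recovery of the planted duplicate
cluster map.

## Problem sizes used by the test suite

The shipped tests run the funnel fixtures at 2,000 base documents, the
recovery benchmark at 2,000 documents × 1,000 sweeps (a few seconds in the
compiled sampler), and the oracle comparisons on instances of at most 6
biterms with 4 million-sweep chains; the whole suite completes in well
under a minute. All sizes are configuration, not limits: the same code ran
the 40-topic configuration on tens of thousands of tweets in the motivating
application.

## Known limitations

* Exact-duplicate clustering only; paraphrased spam forms new clusters.
* The selling-argument lexicon is small and English-only; recall on real
  data depends on lexicon curation (the funnel records evidence precisely
  so that curation can be audited).
* BTM's single global $\theta$ assumes corpus-level topic mixing; strong
  temporal drift would warrant windowed fits.
* Document-topic assignment by argmax discards posterior uncertainty;
  threshold-based assignment is configurable but unexplored here.
* Website categories come from human-coded features; the package computes
  agreement (kappa) but cannot resolve redirects or verify site content.
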