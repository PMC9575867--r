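---
title: "Scoring online societal association: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring online societal association: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osascore)
```

## The score and its assumptions

`osascore` quantifies how strongly a public account — a political leader or
a health organization — associates with its online audience during a health
crisis. The composite, the *online societal association* (OSA), is the
equally weighted product of three per-user components computed over an
analysis window:

$$\mathrm{OSA}_u \;=\; \overline{E}_u \times S_u \times D_u$$

where $\overline{E}_u$ is the impact-weighted mean daily engagement, $S_u$
the signed majority-class sentiment strength, and $D_u$ the
inclusivity-and-diversity strength. A product (rather than a sum) means a
user must be non-trivial on *every* axis to score well; the $10^{-6}$
sentinels below exist precisely so that a neutral or community-silent user
is heavily penalized without annihilating the product to an uninformative
exact zero.

The score assumes: tweets carry the four public engagement counts (likes,
replies, retweets, quotes); impressions are unavailable, so engagement is
absolute, not a rate per view; texts are in one language the classifier and
keyword lists understand (a preprocessing hook — any function applied to
texts before classification — is the place to plug a translator); and the
account roster correctly unions multi-handle users.

### User impact

$$\mathrm{impact}_u = \frac{\tanh\!\big(\log_{10}(\sqrt{f}/g)\cdot L\cdot T\big)}{A^2}$$

with $f$ followers, $g$ following, $L$ public list count, $T$ the tweets
*collected in the window* (the definition is explicit about the collection
timeframe, so we do not use the lifetime profile counter), and $A$ the
profile age in days at the window's reference date. The square-root-and-log
follower ratio blunts the extreme right tail of audience sizes; $\tanh$
bounds the numerator so $|\mathrm{impact}| \le 1/A^2$; dividing by $A^2$
encodes that a young account with a large audience is more remarkable than
an old one. Raw impacts are min–max scaled to $[0,1]$ within each user
group before reporting and weighting. Degenerate groups (one user, or all
impacts tied) scale to 1.0, matching the convention that the top of a group
scores 1.000. Preconditions: $f \ge 1$, $g \ge 1$, $A \ge 1$; $L = 0$
legitimately gives impact 0.

Numerically, $\tanh$ saturates to exactly 1.0 in double precision once its
argument exceeds about 19, which realistic accounts reach easily; the bound
is therefore checked non-strictly in the test suite.

### Engagement and the smoothing chain

Per active day, the pooled counts give
$(\ell + r + t + q) / (4\,n_\mathrm{day})$ — the denominator's factor 4 is
the number of engagement variables pooled in the numerator. Days without
tweets have no defined value and emit no row; before filtering, each user's
series is re-indexed onto a dense calendar from their first to their last
active day and interior gaps are linearly interpolated. Interpolating
(rather than deleting) keeps the calendar dense, which the windowed filters
require, and keeps the final mean over a well-defined set of days.

The standardization chain is, in order: exponential moving average,
z-score outlier replacement, Savitzky–Golay filtering. The stages and the
order are as listed; each is configurable:

| parameter | default | meaning |
|---|---|---|
| `ema_span` | 151 days | EMA span; weight $\alpha = 2/(\mathrm{span}+1)$, finite-history normalized |
| `z_threshold` | 3 | replace days with $|z| > 3$ by linear interpolation of neighbors |
| `savgol_degree` | 8 | Savitzky–Golay polynomial degree |
| `savgol_window` | 31 days | filter window; must be odd and exceed the degree |

The span and the degree are fixed method constants; the z threshold and the
filter window are not dictated by the method, so we chose $|z|>3$ (the
conventional outlier cut) and 31 days (a month of context around each day —
the shortest conventional window that comfortably exceeds degree 8 while
still tracking month-scale dynamics), both exposed in the configuration.
Replacement-by-interpolation rather than deletion is deliberate: deleting
days would change the series length mid-chain and break the filter windows.
Constant series are fixed points of all three stages, which the tests
assert; a window equal to degree + 1 makes the Savitzky–Golay stage an
exact interpolator, a second tested identity. Series must be longer than
the filter window; shorter series raise an error telling the user to
configure a smaller window (or disable smoothing), rather than silently
degrading.

Two orderings are not fixed by the method's description and are package
choices. First, smoothing is applied to the raw daily series *before*
impact weighting; since the weight is a per-user constant, weighting before
or after changes the series only by that constant factor. Second, the
user-level value is the mean over the user's retained calendar days (not
over tweets); day-level and tweet-level averaging coincide only when every
day has equal tweet counts, and the day reading matches the statistic's
"per day" framing.

The impact factor used for weighting is the *scaled* impact by default
(`use_scaled_impact = TRUE`): raw impacts are of order $1/A^2 \approx
10^{-6}$ for decade-old accounts, which would collapse every engagement
curve to dust; the within-group scaled score keeps curves interpretable
while leaving within-group rankings identical (normalization divides the
scale factor out of the composite). Setting the flag to `FALSE` reproduces
the literal raw-impact product.

### Sentiment strength

A pluggable classifier maps each text to one of
{negative, neutral, positive}. The bundled fallback is a deterministic
signed-lexicon scorer — positive-term occurrences minus negative-term
occurrences on lowercased word tokens, sign deciding the label, zero giving
neutral — shipped as a two-column CSV (`term,polarity`). Model-based
classifiers (e.g. a fine-tuned transformer) plug in as any function from a
character vector to labels; none is bundled.

The strength is the signed majority-class fraction:
$10^{-6}$ if the majority class is neutral, $+\,n_{\mathrm{pos}}/n$ if
positive, $-\,n_{\mathrm{neg}}/n$ if negative. Ties for the majority —
including a positive/negative tie — resolve to neutral: any signed choice
would be arbitrary, and the sentinel is the conservative outcome. The
default aggregation pools all of a user's tweets over the window; an
alternative `daily_majority` mode first reduces each active day to its
majority label and then applies the statistic to day-labels, weighing every
active day equally regardless of volume. Both modes are exposed because the
statistic's day-level phrasing and its single-per-user reporting pull in
different directions; neither is asserted as canonical.

### Inclusivity-and-diversity strength

$D_u$ is the fraction of the user's tweets containing at least one
community keyword — a tweet counts once however many keywords it contains,
because the numerator counts *tweets that mention a community*, not keyword
occurrences. Matching is case-insensitive on unicode word boundaries;
multi-word keywords must appear as contiguous phrases; `"nurse"` does not
match `"nurses"` (stem variants are listed explicitly). Zero mentions give
the $10^{-6}$ sentinel. The bundled lexicon is a synthetic, category-
balanced stand-in (~100 English terms across gender, age, culture,
ethnicity and employment, all with `country = "all"`); per-country analyses
should load their own lists, and strengths computed against different
lexicons are not comparable.

### Normalization and ranking

Within each user group, the composite is divided by the group maximum, so
the top user scores exactly 1.000 and everyone else is a fraction of the
top; groups are never scaled against each other. Divide-by-max was chosen
over min–max because the reported non-top values behave like ratios and
min–max would force the bottom user to an artificial 0; min–max remains
available as a config flag. Negative composites (negative-majority
sentiment) stay negative after scaling — the sign is information. A group
whose every composite is non-positive cannot be normalized this way and
raises an error instructing the caller to report raw scores. Ranking ties
break lexicographically by `user_id` so reports are deterministic.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the pipeline
assumes: per-user daily tweet counts are Poisson; per-tweet total
interactions are negative-binomial (heavily overdispersed, `size = 0.5`)
with day-specific multipliers on scheduled spike dates, emulating
event-driven surges; each tweet's sentiment is drawn from a categorical mix
and *realized as a planted lexicon token*, so the bundled classifier
recovers the drawn label exactly; community keywords are embedded Bernoulli
per tweet. Defaults describe the study conditions: a Dec 2019 – Dec 2021
window, ten leaders (≈4.8 tweets/day, engagement mean 150) and ten health
organizations (≈17.9 tweets/day, engagement mean 30), which yields on the
order of 1.7×10⁵ tweets at full scale, with a 0.2/0.5/0.3
negative/neutral/positive mix and a 0.3 mention probability. The first
leader carries two handles to exercise roster merging. Total interactions
are split across the four count fields by sequential binomials with fixed
likes-heavy proportions (0.6/0.1/0.25/0.05); the composite only ever sums
the four, so the split is a free choice. One global stream is seeded once
per simulation: equal seeds give byte-identical corpora.

`plant_known_strengths()` goes further for recovery tests: label and
keyword counts are *placed*, not sampled, so downstream strengths equal the
planted fractions exactly; fractions must be exactly expressible at the
configured tweet count and the planted class must form a strict majority,
else the call errors rather than approximating. Planted users share
identical profile metrics, so impacts tie, the degenerate scaling rule sets
every weight to 1, and the planted components alone drive the ranking.

What the generator does **not** model: retweet cascades and network
topology, follower growth over time, topic drift, multilingual text, or any
correlation between sentiment and engagement. Passing tests on synthetic
cohorts therefore validate the *arithmetic and invariances* of the pipeline
— not the sociological claims one might draw from real corpora, and not
classifier quality on natural language.

## Numerical choices and degenerate inputs

- Sentinels are exactly `1e-6` and are asserted with `expect_identical`.
- All daily grouping is in UTC; timestamps parse as RFC 3339 and round-trip
  through both file dialects bit-exactly.
- Profile age is whole-day calendar arithmetic; age ≤ 0 is an error because
  the impact divides by its square.
- `following = 0` and `followers = 0` are errors (the ratio and its log are
  undefined), not silent clamps.
- Empty tweet files parse to an empty table with a warning; scoring an
  empty corpus is an error.
- A constant series has zero standard deviation; the outlier stage returns
  it unchanged rather than producing 0/0.
- Handle merging takes profile metrics from the roster-designated primary
  handle and never sums followers across handles — the audiences of one
  person's accounts overlap, so summing would double-count.

## Problem sizes in the tests

The unit and property suites run on corpora of tens to a few hundred tweets
over 1–3-month windows, where the brute-force per-tweet oracle (plain loops
over individual tweets, written against the definitions rather than the
pipeline) is fast and exact agreement can be demanded; the cross-check runs
over 50 seeded corpora. The bound suite draws 1,000 random valid profiles.
The acceptance script scores one full-scale cohort (~1.7×10⁵ tweets, 20
users, the two-year window) through the complete smoothing chain. These
sizes were chosen so the whole suite exercises every code path, including
full scale, while remaining quick enough to run routinely.

## Known limitations

- The bundled community lexicon is a stand-in; absolute inclusivity
  strengths depend entirely on the lexicon supplied.
- The fallback sentiment classifier is a bag-of-terms scorer: adequate for
  planted-token synthetic text and smoke tests, not a substitute for a
  trained model on natural language.
- Engagement is absolute, not per impression; cross-account comparisons
  inherit audience-size effects beyond what the impact term captures.
- The window-level sentiment statistic discards within-window dynamics; the
  `daily_majority` mode is a coarse alternative, not a time-series model.
- Normalization is within-group only; scores are not comparable across
  groups or across differently configured runs.
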