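# osascore

Scores the **online societal association (OSA)** of public social-media
accounts — political leaders and health organizations — from their tweet
streams during a health crisis. OSA is a composite of how much engagement an
account draws (weighted by its standing), how strongly its tweets lean
positive or negative, and how inclusively it addresses the communities in
its audience. The package is aimed at infodemiology and crisis-communication
researchers who want a reproducible, testable implementation of this kind of
composite influence score, together with a seeded synthetic-cohort generator
for validating every stage.

## The score

For each canonical user (an account roster may map several handles to one
user), over an analysis window:

- **User impact**

  ```
  impact_user = tanh( log10( sqrt(followers) / following ) × listedCount × tweetCount ) / profileAge²
  ```

  where `tweetCount` is the number of tweets collected in the window and
  `profileAge` is days from profile creation to the window's reference date.
  Impacts are min–max scaled to [0, 1] within each user group.

- **Engagement.** Per active day,

  ```
  dailyAvgEng_Tweet = (likes + replies + retweets + quotes) / (4 × dailyTweetCount)
  ```

  The per-user daily series is standardized by an exponential moving average
  (151-day span), z-score outlier replacement (|z| > 3, linear
  interpolation), and an 8th-degree Savitzky–Golay filter (31-day window),
  then multiplied by the user's scaled impact and averaged over the user's
  calendar:

  ```
  dailyAvgEng_user = mean( dailyAvgEng_Tweet × impact_user )
  ```

- **Sentiment strength.** Tweets are classified into
  {negative, neutral, positive} by a pluggable classifier (a deterministic
  signed-lexicon scorer is bundled). If the majority class is neutral the
  strength is the sentinel `1e-6`; if positive, the positive fraction; if
  negative, minus the negative fraction.

- **Inclusivity-and-diversity strength.** The fraction of tweets mentioning
  any community keyword (gender, age, culture, ethnicity, employment-sector
  terms; case-insensitive whole-word matching), with sentinel `1e-6` for
  users who never mention a community.

- **Composite.**

  ```
  OSA = dailyAvgEng_user × sentiStrength × iDStrength
  ```

  normalized within each user group by dividing by the group maximum, so
  each group's top user scores exactly 1.000; negative composites stay
  negative.

## Worked example

```r
library(osascore)

cfg <- simulation_config(
  seed = 42,
  window = analysis_window("2020-01-01", "2020-12-31"),
  n_leaders = 3, n_health_orgs = 3,
  tweets_per_day = c(leader = 3, health_org = 6),
  sentiment_mix = c(negative = 0.15, neutral = 0.35, positive = 0.5))
cohort <- simulate_cohort(cfg)
res <- score_cohort(cohort$tweets, cohort$profiles, cohort$roster,
                    window = cfg$window)
rank_report(res, k = 3)
```

```
  user_id  group      n_tweets scaled_impact daily_avg_eng_user senti_strength id_strength normalized_osa rank
1 health03 health_org     2258        1                    7.94          0.505       0.302         1          1
2 health02 health_org     2262        0.770                5.96          0.484       0.314         0.747      2
3 health01 health_org     2204        0                    0             0.503       0.299         0          3
4 leader01 leader         1089        1                   38.3           0.492       0.333         1          1
5 leader02 leader         1065        0.0357               1.31          0.494       0.305         0.0314     2
6 leader03 leader         1100        0                    0             0.489       0.293         0          3
```

Each group's most impactful account normalizes to exactly 1.000; the others
are reported as a fraction of their group's top. `senti_strength` near 0.5
reflects the configured 50% positive tweet mixture; `id_strength` near 0.3
reflects the 30% community-mention probability. Content tables come from the
same corpus:

```r
top_hashtags(cohort$tweets, k = 5)
#>   token       count  rank
#> 1 covid19       502     1
#> 2 tokyo2020     459     2
#> 3 yomevacuno    449     3
#> 4 cop25         448     4
#> 5 coronavirus   444     5
```

Real corpora enter through `read_tweets()` (Twitter-API-v2-shaped JSON
Lines or a flat CSV), `read_profiles()` and `read_roster()`;
`merge_handles()` unions multi-handle accounts into canonical users. A thin
command-line wrapper with `simulate` / `score` / `content` subcommands is
installed at `inst/cli/osascore.R`.

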