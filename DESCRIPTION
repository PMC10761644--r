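Package: cohaz
Title: Compound Heatwave-Drought Exposure, Spatial Scan Clusters, and
    Community Determinants of Psychiatric Emergency Visits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the joint impact of heatwaves and droughts
    on mental-health related emergency department (ED) visits at the county
    scale. Builds county-day exposure calendars from daily mean temperature
    (percentile-threshold heatwave events, excess heat factor intensity) and
    weekly drought-monitor categories; detects high-risk spatial clusters of
    event-day visits with an elliptical-window Bernoulli scan statistic and
    Monte Carlo permutation inference; quantifies additive and multiplicative
    interaction of the two hazards (RERI, synergy index, multiplicative
    ratio); and ranks household and community determinants of high-risk
    clustering with multivariate adaptive regression splines under a Poisson
    lack-of-fit. A synthetic-data generator with planted clusters, planted
    hot spells, Markov-chain drought categories, and planted covariate shifts
    makes the full pipeline testable without restricted surveillance data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
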