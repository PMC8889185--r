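Package: colonysim
Title: Agent-Based Simulation and Motif Analysis of Insect Colony Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates worker movement and directed pairwise interactions in a
    bounded insect nest using activity-gated correlated random walks, with
    among-individual variation in activity level and path sinuosity (including
    a negatively correlated behavioural syndrome). Converts the resulting
    time-ordered interaction logs into weighted and majority-rule binary
    directed networks grown to target edge counts, computes triangle
    transitivity and triad significance profiles against a uniform-condition
    null ensemble to quantify feed-forward-loop over-representation, and runs
    time-ordered information-diffusion experiments measuring transmission
    speed (T50) and efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp
Suggests:
    broom,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
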