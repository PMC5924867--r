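Package: hhequity
Title: Intra-Household Food Allocation and Dietary Adequacy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intra-household allocation of food and
    nutrients from repeated 24-hour dietary recalls. Converts portion-level
    recall records into nutrient intakes and Minimum Dietary Diversity for
    Women (MDD-W) scores, estimates usual intakes with Box-Cox
    transformation and best linear unbiased predictors from mixed-effects
    models, computes probability of adequacy against requirement
    distributions (including a tabulated low-bioavailability iron method)
    and the mean probability of adequacy (MPA) over 11 micronutrients,
    derives pairwise allocation ratios between household members (food
    shares, food-share-to-energy shares, relative dietary energy adequacy
    ratios, MPA ratios), and tests equity and its determinants with
    cluster-adjusted linear mixed models. Includes a synthetic-data
    generator with known variance components and allocation effects so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
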