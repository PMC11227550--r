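Package: funmorph
Title: Functional Data Analysis of Landmark-Based Shape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based geometric morphometrics with a functional-data
    representation of shape. Reads and writes TPS landmark files, averages
    digitisation replicates, performs generalised Procrustes analysis,
    converts aligned configurations into multivariate functional data over
    the landmark-index continuum, and decomposes them by multivariate
    functional principal component analysis estimated from univariate
    FPCA scores. Principal component scores feed a linear discriminant
    analysis built from explicit within- and between-class scatter
    matrices and a replicated stratified train/test protocol over four
    score-based classifiers (Gaussian naive Bayes, radial-kernel support
    vector machine, random forest, and elastic-net multinomial
    regression). Includes a synthetic landmark-data generator with known
    class structure for end-to-end validation, broom-style tidiers and
    ggplot2 ordination plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
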