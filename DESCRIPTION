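Package: tsrgrowth
Title: Hierarchical Bayesian Biphasic Growth Analysis of the
    Temperature-Size Rule in Lake Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test the temperature-size rule in wild freshwater
    fish from standard agency age-length surveys.  Provides a synthetic
    survey generator with known growth truths, growing-degree-day thermal
    covariates (GDD5 and its trailing ten-year mean), per-survey
    age-length keys with a five-age-group inclusion filter, a
    hierarchical Bayesian biphasic (hockey-stick) growth model linking
    juvenile growth, age at maturity and adult growth to lake
    temperature, a subsidiary Bayesian regression of 95th-percentile age
    (longevity) on temperature, convergence diagnostics (rank-normalised
    split R-hat, autocorrelation effective sample size, highest posterior
    density intervals), and temperature-dependent derived posteriors of
    size at maturity, lifetime growth curves and maximum size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
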