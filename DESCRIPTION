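Package: respshift
Title: Detecting Strategy Shifts in Test-Taking with Joint Accuracy and
    Response-Time Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Psychometric models for identifying between- and within-person
    differences in test-taking strategies from item accuracy and response-time
    data. Provides mixture Rasch models estimated by conditional maximum
    likelihood with EM over latent classes, the lognormal response-time model
    with person speed and item time-intensity effects, and a joint
    accuracy/response-time model with two latent response states
    (construct-driven versus erratic) whose transitions follow either a
    lag-1 Markov chain or a per-person change point, estimated by Gibbs
    sampling. State classifications are used to trim erratic responses,
    rescore examinees by expected a posteriori estimation, and quantify the
    gain in criterion validity after disattenuation for post-trim
    unreliability, with a bootstrap significance test. A synthetic-data
    generator with known ground truth supports parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
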