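Package: dbstune
Title: Semi-Automated Optimization of Deep Brain Stimulation Frequency
    from Quantified Rigidity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tuning deep brain stimulation (DBS) frequency in
    Parkinson's disease from quantitative rigidity measurements. Converts
    robotic-manipulandum torque traces into a single rigidity value (RoMaR,
    the slope of the angular impulse of the rectified, low-pass-filtered
    torque), models rigidity as a function of stimulation frequency with a
    Matern Gaussian process, selects frequencies to test by expected
    improvement (Bayesian optimization) under a patient tolerability
    ceiling, learns a latent patient-preference function from pairwise
    choices with a probit Gaussian process fitted by damped Newton-Raphson,
    and evaluates sampling efficiency against brute-force, equal-interval
    and random frequency selection. A virtual-patient simulator provides
    ground-truth rigidity curves, noisy measurements, synthetic torque
    traces and probit preference choices so the full protocol can be run
    and validated without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
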