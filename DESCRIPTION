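Package: oknrivalry
Title: No-Report Binocular Rivalry Analysis from Optokinetic Nystagmus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers perceptual dominance timelines from 1 kHz horizontal gaze
    recordings of binocular rivalry using the cumulative-smooth-pursuit (CSP)
    procedure: slow-phase segmentation by velocity, acceleration and duration
    criteria, segment alignment into a cumulative pursuit trajectory, a
    bootstrap-aggregated ("bagged") velocity profile with 95% confidence
    intervals, and CI-threshold classification of left/right/mixed percepts.
    Computes the Ratio-of-Prime-Direction (RPD) priming statistic, its
    moving-average temporal profile, mixed-percept quality filters and the
    Ocular Dominance Index, and runs the group-level inferential battery
    (one-sided one-sample t with Cohen's d and JZS Bayes factors, rank
    correlations, mixed and repeated-measures ANOVA, post-hoc and assumption
    tests, noncentral-t power analysis). Includes a generative simulator of
    optokinetic-nystagmus gaze traces driven by a latent perceptual
    alternation process, for calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite,
    car
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
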