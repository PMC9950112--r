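Package: selstop
Title: Selective Stop-Signal Task Analysis with a Two-Step Restart Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of multi-effector selective stop-signal
    experiments. Provides a generative two-step restart race model (global
    inhibition followed by a selective restart of the effector that must keep
    moving), an adaptive stop-signal-delay staircase, synthetic surface-EMG
    traces with latent burst onsets, EMG muscle-reaction-time extraction,
    race-model independence testing, stop-signal reaction time estimation by
    the mean and integration methods, and the decomposition of selective Stop
    Errors into Compliant and Non-Compliant subsets relative to the estimated
    end of the global inhibition step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
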