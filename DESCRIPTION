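Package: genenetdsp
Title: Discrete-Time Signal Processing and Control for Gene Network Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Difference-equation simulators for gene network motifs (two-gene
    cascade, positive/negative autoregulation, coherent/incoherent and
    interlocked feedforward loops, negative feedback networks) with Gaussian
    extrinsic noise injection; closed-form analytics (steady-state level,
    63.2% response time, production/degradation co-modulation design, matrix
    form of the recursion); ARX parameter estimation by least squares, the
    Wiener filter and the LMS adaptive filter; z-domain transfer functions,
    Bode/frequency response, DFT periodicity detection; and digital feedback
    control including step-disturbance steady-state error via the final value
    theorem, pole and state-space stability analysis, and an in-silico PID
    loop with online plant identification and PI pole-placement tuning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
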