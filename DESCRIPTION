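Package: reintroplan
Title: Stable-Stage-Aligned Release Planning for Reintroductions
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Plans conservation reintroductions with stage-structured
    (Lefkovitch/Leslie) female-only projection matrices. Given a 2- to
    5-stage projection matrix and a management goal (a desired number of
    breeding females after T time units), computes the stable-stage-
    distribution-aligned release vector obtained by back-projecting the
    target through the dominant eigenvalue, the per-step release schedule,
    scaled variants, ranked pools of candidate matrices with similar vital
    rates, and deterministic trajectory comparisons between stable-stage
    and arbitrary (out-of-distribution) releases. Includes a seeded
    generator of random valid life histories and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
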