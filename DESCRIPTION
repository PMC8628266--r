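Package: ritkit
Title: Biodistribution, Internal Dosimetry and Therapy-Outcome Analysis for
    Preclinical Radioimmunotherapy
Version: 0.1.0
Authors@R: person("ritkit", "developers", role = c("aut", "cre"),
    email = "ritkit@example.org")
Description: Tools for the computational chain of a preclinical
    antibody radioimmunotherapy study: ingestion and normalization of
    biodistribution measurements expressed as percent injected dose per
    gram (%ID/g), construction of per-group organ time-activity curves,
    prediction of absorbed dose (Gy) for a beta-emitting therapy nuclide
    from a gamma-emitting imaging surrogate via time-integrated activity
    and the mean energy emitted per transition, and analysis of therapy
    outcomes (caliper tumor volumes, humane-endpoint survival, body
    weight). Includes a synthetic cohort generator emulating antibody
    organ kinetics and dose-dependent tumor growth delay, so the whole
    pipeline is testable without animal data, plus a command-line
    interface for reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
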