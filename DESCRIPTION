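Package: subrep
Title: Ecology of Sub-Exponential Replicator Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic models of communities of template-directed
    oligonucleotide replicators whose single strands reversibly pair into
    replication-inert duplexes, producing self-inhibited, sub-exponential
    ("parabolic") growth. Provides the mass-regulated community ODEs, a
    resource-explicit chemostat variant, and a phenomenological power-law
    model; closed-form intrinsic and density-dependent growth rates;
    analytic equilibrium solvers for the normalized production and the
    surviving species set; invasion analysis with exclusion zones and
    order-invariant community assembly; and parameter-sweep and
    fluctuating-environment experiments, with configuration handling and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
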