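Package: prockb
Title: Process-Centered Biological Knowledge Representation and Rule-Based Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A process-centered knowledge model for metabolic networks and the
    forward-chaining machinery to saturate it. Biological processes (metabolic
    reactions, post-translational modifications, protein complex assemblies,
    pathways), their participants and their activities are held in a small core
    schema; instance knowledge is loaded from tabular assertion files and
    enriched to fixpoint under schema entailments (subsumption, sub-property,
    inverse, domain/range) and an editable catalog of safe Horn rules, with
    declared-versus-inferred provenance tracked on every assertion. Includes a
    synthetic network generator with a constructive ground-truth ledger,
    metrics and diff reports, Turtle export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    yaml,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
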