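Package: fedheart
Title: Simulation of Asynchronous Federated Learning for Heart Disease
    Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained simulator for privacy-preserving federated
    learning on tabular heart-disease records. Encodes clinical attributes
    with a discretised 16-attribute schema, trains small feed-forward
    networks at simulated client nodes, exchanges deep and shallow
    parameter subsets on a periodic schedule, aggregates updates on a
    simulated server with temporal staleness down-weighting, and compares
    the asynchronous protocol against a synchronous federated-averaging
    baseline on accuracy, precision, F1 and communication cost. Includes
    a seeded synthetic-data generator with a known logistic ground truth,
    a radial-basis-kernel support-vector decision head for local
    classification, and full audit trails (block logs, aggregation
    traces, data-purge enforcement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
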