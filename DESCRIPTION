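Package: hetpath
Title: Time-Resolved Drug Repositioning on Heterogeneous Knowledge Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds typed heterogeneous knowledge networks (hetnets) from
    dated subject-predicate-object triple tables, extracts degree-weighted
    path count (DWPC) metapath features between drug and disease nodes via
    sparse degree-weighted adjacency-matrix products, and learns
    ElasticNet-regularized logistic models of drug-treats-disease
    relationships. Supports cleaning rules for text-mined triples (concept
    remapping, edge-type condensation, sparse-type and low-support filters,
    hub removal), time-resolved network slices dated by earliest supporting
    publication, past/future indication splits for prospective evaluation,
    relative-approval-year performance curves, and edge-dropout /
    edge-replacement ablations quantifying per-edge-type importance. A
    synthetic generator produces dated hetnets and gold standards with
    planted, recoverable signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
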