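# Shared toy fixtures, all built in code.

# two-type metagraph: TREATS (directed), RELATED_TO and ASSOCIATED_WITH (undirected)
toy_metagraph <- function() {
  metagraph(
    tibble::tibble(
      type = c("Chemicals & Drugs", "Disorders"),
      abbrev = c("CD", "DO")
    ),
    tibble::tibble(
      source = c("Chemicals & Drugs", "Chemicals & Drugs", "Disorders"),
      predicate = c("TREATS", "RELATED_TO", "ASSOCIATED_WITH"),
      target = c("Disorders", "Chemicals & Drugs", "Disorders"),
      abbrev = c("t", "rt", "aw"),
      directed = c(TRUE, FALSE, FALSE)
    )
  )
}

# C1-rt-C2, C2-t->D1, C1-t->D1 (the worked DWPC example network)
toy_net <- function() {
  hetnet(
    tibble::tibble(
      id = c("C1", "C2", "D1"),
      type = c("Chemicals & Drugs", "Chemicals & Drugs", "Disorders")
    ),
    tibble::tibble(
      source = c("C1", "C2", "C1"), target = c("C2", "D1", "D1"),
      metaedge = c("CDrtCD", "CDtDO", "CDtDO")
    ),
    toy_metagraph()
  )
}

# raw triple-table rows in the one-pmid-per-row input layout
triple_row <- function(s, st, p, o, ot, pmid) {
  tibble::tibble(
    subject = s, subject_type = st, predicate = p,
    object = o, object_type = ot, pmid = pmid
  )
}

cd <- "Chemicals & Drugs"
do <- "Disorders"

# small random hetnet for oracle-equivalence sweeps; uses the synthetic
# generator at reduced size so all hetnet invariants hold by construction
small_random_net <- function(seed) {
  cfg <- synth_config(
    seed = seed, n_drugs = 12, n_diseases = 8, n_anatomy = 5, n_phenomena = 5,
    mean_degree = 2, n_positives = 5, effect_size = 1
  )
  generate_temporal_hetnet(cfg)$net
}

# study predictions joined with approval years, standardized across models
standardized_timesplit <- function(study, years, config) {
  ts <- timesplit_run(study$net, study$indications, years, config)
  pr <- dplyr::left_join(
    ts$predictions,
    study$indications[, c("drug", "disease", "approval_year")],
    by = c("drug", "disease")
  )
  standardize_probabilities(pr)
}
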