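# Run configuration: one object bundling the prefix map, the IRI-minting
# policy, the template vocabulary, the GO seeds and the fixture vocabulary.
# Defaults are complete enough to run the packaged fixtures end to end.

#' Assemble a run configuration
#'
#' @param prefixes CURIE prefix map ([default_prefixes()]).
#' @param policy A [uri_policy()].
#' @param vocab A [vocabulary_config()].
#' @param seeds A [go_seed_config()].
#' @param fv A [fixture_vocab()].
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(prefixes = default_prefixes(), policy = uri_policy(),
                       vocab = vocabulary_config(), seeds = go_seed_config(),
                       fv = fixture_vocab()) {
  structure(list(prefixes = prefixes, policy = policy, vocab = vocab,
                 seeds = seeds, fv = fv), class = "run_config")
}

#' Load a run configuration from a YAML or JSON file
#'
#' Any subset of the keys may be present; missing values keep their
#' defaults. Recognized keys: `base_namespace`, `strategy`, `prefixes`
#' (map), `vocabulary` (fields of [vocabulary_config()]), `go_seeds`
#' (vector of GO accessions).
#'
#' @param path Config file path.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) np_error(sprintf("no such file: %s", path), "np_io_error")
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext == "json") jsonlite::fromJSON(path) else yaml::read_yaml(path)
  prefixes <- default_prefixes()
  if (!is.null(doc$prefixes)) {
    extra <- unlist(doc$prefixes)
    prefixes[names(extra)] <- extra
  }
  policy <- uri_policy(
    base_namespace = if (!is.null(doc$base_namespace)) doc$base_namespace
    else formals(uri_policy)$base_namespace,
    strategy = if (!is.null(doc$strategy)) doc$strategy else "slug")
  vocab <- if (!is.null(doc$vocabulary)) {
    do.call(vocabulary_config, doc$vocabulary)
  } else vocabulary_config()
  seeds <- if (!is.null(doc$go_seeds)) {
    go_seed_config(seeds = as.character(unlist(doc$go_seeds)))
  } else go_seed_config()
  run_config(prefixes = prefixes, policy = policy, vocab = vocab, seeds = seeds)
}
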