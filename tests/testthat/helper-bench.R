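# Shared cache for the expensive end-to-end benchmark runs so the
# acceptance tests can reuse one trained model across criteria.
.bench_cache <- new.env(parent = emptyenv())

get_benchmark <- function(seed, epochs = 5L) {
  key <- paste0("seed", seed, "_ep", epochs)
  if (is.null(.bench_cache[[key]]))
    .bench_cache[[key]] <- run_imputation_benchmark(seed, epochs = epochs)
  .bench_cache[[key]]
}
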