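# Expensive artifacts computed once and shared across test files (test
# files run in one session; the first file that needs a result builds it).

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.test_cache[[key]]))
    .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

mechanism_result <- function() {
  cached("mechanism", context_identifiability_experiment(seeds = 1:3))
}

tiny_fit <- function() {
  cached("tiny_fit", {
    pairs <- make_pairs(10, 16, seed = 99)
    fit_model(list(train = pairs[1:7], val = pairs[8:10]),
              model = "omninet",
              config = omninet_config(base_channels = 2L, seed = 5L),
              control = train_control(loss = "mse", learning_rate = 1e-3,
                                      max_epochs = 3L, patience = 2L,
                                      batch_size = 4L, context_size = 2L,
                                      context_size_test = 4L, seed = 11L))
  })
}
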