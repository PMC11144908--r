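# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# A small study cohort with the default phantom (16 HC / 16 PD).
test_cohort <- function() {
  memo("cohort", function() {
    cases <- generate_cohort(16, 16, phantom_params(), seed = 20260901)
    labels <- vapply(cases, `[[`, "", "label")
    stacks <- lapply(cases, function(cs) {
      vol <- reconstruct_setmag(cs$echoes)
      zs <- select_slices(cs$snpc_mask, dim(vol$intensity)[3L])
      detect_brainstem(vol, zs, case_id = cs$case_id)
    })
    list(cases = cases, labels = labels, stacks = stacks)
  })
}

# A CNN trained on the cohort's training half (reduced epochs).
test_cnn <- function() {
  memo("cnn", function() {
    co <- test_cohort()
    sp <- split_cases(co$labels, 0.8, seed = 11)
    bundle <- train_cnn(co$stacks[sp$train], co$labels[sp$train],
                        n_folds = 3, seed = 4, epochs = 10)
    list(bundle = bundle, split = sp)
  })
}
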