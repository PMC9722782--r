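# A small real federation run shared by several test files; built once per
# test session.  2 sites x 4 cases, 16^3 patches, 3 rounds: big enough to
# exercise the whole round protocol, small enough to run in seconds.
.mini_run_cache <- new.env(parent = emptyenv())

make_mini_dataset <- function() {
  if (is.null(.mini_run_cache$dataset)) {
    .mini_run_cache$dataset <- generate_federation(
      list(site_spec("S1", 4), site_spec("S2", 4)),
      tiny_phantom_cfg(), seed = 71
    )
  }
  .mini_run_cache$dataset
}

make_mini_run <- function() {
  if (is.null(.mini_run_cache$run)) {
    ds <- make_mini_dataset()
    mcfg <- tiny_model_config(base_filters = 2, patch_size = 16, seed = 1)
    .mini_run_cache$run <- run_federation(
      federation_config(max_rounds = 3, seed = 13),
      ds, init_model(mcfg)
    )
  }
  .mini_run_cache$run
}
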