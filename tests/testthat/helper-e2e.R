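# The end-to-end experiment under the package's reference study
# conditions (600/300/300 subjects, prevalence 20%, seed 7) takes a few
# minutes; it is run once and shared by every test that inspects it.
.e2e_cache <- new.env(parent = emptyenv())

get_e2e <- function() {
  if (is.null(.e2e_cache$ex)) {
    .e2e_cache$ex <- run_af_pipeline(seed = 7, config = af_pipeline_config(),
      verbose = FALSE)
  }
  .e2e_cache$ex
}
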