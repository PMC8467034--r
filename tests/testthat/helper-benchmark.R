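# The scaled-down end-to-end benchmark is expensive (a few minutes), so it
# is trained once per test run and shared by the tests that grade it.
.benchCache <- new.env(parent = emptyenv())

getBenchmark <- function() {
  if (is.null(.benchCache$bench))
    .benchCache$bench <- runSmallBenchmark(seed = 1)
  .benchCache$bench
}
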