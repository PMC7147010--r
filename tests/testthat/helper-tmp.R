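# fresh temp directory per call, cleaned up at the end of the test run
withr_like_tempdir <- function() {
  d <- tempfile("ewstest")
  dir.create(d, recursive = TRUE)
  d
}
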