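.onLoad <- function(libname, pkgname) {
  # keep large activation buffers on glibc's heap free lists instead of
  # round-tripping them through mmap/munmap every training batch
  .tune_allocator()
  invisible()
}
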