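.onLoad <- function(libname, pkgname) {
  .fb_plugins$storage <- list()
  .fb_plugins$compute <- list()
  register_storage_scheme("file", storage_localfs)
  register_storage_scheme("mem", storage_mem)
  register_compute_scheme("localexec", compute_localexec)
  register_compute_scheme("mockq", compute_mockq)
}
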