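.onLoad <- function(libname, pkgname) {
  init_unit_registry()
  register_backend(h5_backend())
  register_backend(tsv_backend())
  register_backend(raw_backend())
  invisible(NULL)
}
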