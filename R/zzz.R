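.onLoad <- function(libname, pkgname) {
  # OpenBabel prints kekulization/parse warnings straight to stderr; candidate
  # validation probes thousands of strings, so keep only hard errors.
  try({
    OB <- getNamespace("ChemmineOB")
    OB$OBMessageHandler_SetOutputLevel(OB$obErrorLog_get(), 0L)
  }, silent = TRUE)
  invisible()
}
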