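.onLoad <- function(libname, pkgname) {
  # default heat-stress formula: livestock temperature-humidity index
  assign("thi_default",
         function(temp, rh) 0.8 * temp + (rh / 100) * (temp - 14.4) + 46.4,
         envir = .his_registry)
}
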