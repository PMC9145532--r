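#' @include benchmark.R
NULL

.onLoad <- function(libname, pkgname) {
  registerAligner("gm",
    function(unlabeled, atlas, cfg, ...) alignGM(unlabeled, atlas, cfg),
    nativeColors = TRUE)
  registerAligner("gm-realistic",
    function(unlabeled, atlas, cfg, nCenters = 100L, ...)
      alignGMRealistic(unlabeled, atlas, cfg, nCenters = nCenters),
    nativeColors = TRUE)
  invisible(NULL)
}
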