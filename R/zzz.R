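#' @import data.table
#' @importFrom stats setNames
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", "unit", "n_units", "library", "read", "lane", "transcript",
  "lanes_detected", "hits", "N", "d"))
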