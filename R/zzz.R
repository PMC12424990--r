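#' @import data.table
#' @importFrom stats vcov median setNames ave
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".N", "base", "cycle", "frame", "frag", "intensity", "inv_k0", "kind",
  "mz", "mz0", "occ_row", "prec", "q1_hi", "q1_lo", "repeat_index", "rt_s",
  "subcycle"
))
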