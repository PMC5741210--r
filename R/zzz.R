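#' @import data.table
#' @importFrom stats phyper rbinom rgeom rpois runif setNames
#' @importFrom utils head packageVersion
NULL

.datatable.aware <- TRUE
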