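#' Identifier of a record, result or outcome
#'
#' @param x a ChemicalRecord, QsarReadyResult or ProcessingOutcome
#' @return the user-supplied (or synthesized) identifier string
#' @export
setGeneric("identifier", function(x) standardGeneric("identifier"))
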