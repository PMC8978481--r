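# Shared lexical patterns and RDF constants (loaded before the other files).

XSD_DATETIME <- "http://www.w3.org/2001/XMLSchema#dateTime"
RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"

CAS_PATTERN <- "^[0-9]{2,7}-[0-9]{2}-[0-9]$"
INCHIKEY_PATTERN <- "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"
ISO_DATETIME_PATTERN <-
  "^[0-9]{4}-[0-9]{2}-[0-9]{2}T[0-9]{2}:[0-9]{2}:[0-9]{2}$"

`%||%` <- function(a, b) if (is.null(a)) b else a
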