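# JSONL input/output for reaction records.

record_to_json <- function(r) {
  jsonlite::toJSON(
    list(reactants = r$reactants,
         reagent = if (is.null(r$reagent)) NULL else jsonlite::unbox(r$reagent),
         product = jsonlite::unbox(r$target),
         is_null = jsonlite::unbox(isTRUE(r$is_null)),
         spectra = list(ir = r$spectra$IR$intensities,
                        nmr = r$spectra$NMR$intensities,
                        ms = r$spectra$MS$intensities)),
    digits = NA, null = "null"
  )
}

#' Write reaction records as JSON lines
#'
#' One record per line with fields `reactants`, `reagent`, `product`,
#' `is_null` and dense `spectra` (`ir`, `nmr`, `ms`).
#'
#' @param records Reaction records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reactions_jsonl <- function(records, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (r in records) writeLines(record_to_json(r), con)
  invisible(path)
}

#' Read reaction records from JSON lines
#'
#' @param path File written by [write_reactions_jsonl()].
#' @return List of reaction records.
#' @export
read_reactions_jsonl <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    list(reactants = x$reactants,
         reagent = x$reagent,
         target = x$product,
         is_null = isTRUE(x$is_null),
         spectra = list(IR = spectrum(x$spectra$ir, "IR"),
                        NMR = spectrum(x$spectra$nmr, "NMR"),
                        MS = spectrum(x$spectra$ms, "MS")))
  })
}
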