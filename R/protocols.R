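#' Survey protocol labels
#'
#' The seven protocol variants compared by the case study, in canonical
#' (publication) order: detections from all methods over the full 74-day
#' deployment (`All-74`), camera traps alone over 74 days (`CT-74`), all
#' methods over the 16 labour-intensive survey days (`All-16`), camera traps
#' over those 16 days (`CT-16`), artificial refuges and pitfall traps
#' combined (`LI`), and each labour-intensive method alone (`AR`, `PF`).
#'
#' @return Character vector of length 7.
#' @export
#' @examples
#' protocol_levels()
protocol_levels <- function() {
  c("All-74", "CT-74", "All-16", "CT-16", "LI", "AR", "PF")
}

#' Base detection methods
#'
#' The four directly-observed method layers from which all seven protocols
#' derive by union: `LI = AR | PF`, `All-16 = CT-16 | LI`,
#' `All-74 = CT-74 | LI`, with `CT-16` nested in `CT-74`.
#'
#' @return Character vector of length 4.
#' @export
base_methods <- function() {
  c("CT-16", "CT-74", "AR", "PF")
}

#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata` directory, e.g.
#'   `"detection_table.csv"` or `"cost_profiles.csv"`. With no argument,
#'   lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
#' @examples
#' trapcost_example()
#' trapcost_example("detection_table.csv")
trapcost_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "trapcost")))
  }
  path <- system.file("extdata", file, package = "trapcost", mustWork = FALSE)
  if (!nzchar(path)) {
    stop("no packaged file called '", file, "'", call. = FALSE)
  }
  path
}

# protocol factor in canonical order
as_protocol <- function(x) {
  factor(as.character(x), levels = protocol_levels())
}

check_protocol <- function(protocol) {
  if (length(protocol) != 1L || !protocol %in% protocol_levels()) {
    stop("unknown protocol label '", paste(protocol, collapse = ", "),
         "'; expected one of: ", paste(protocol_levels(), collapse = ", "),
         call. = FALSE)
  }
  protocol
}
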