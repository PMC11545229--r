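#' Define the tissue-to-channel assignment of a 4-plex iTRAQ run
#'
#' Each iTRAQ run labels the four tissues of one patient with the reporter
#' ions 114--117. The default layout tags the noncancerous reference (N) with
#' 114, the primary tumor (T) with 115, and the first- and second-generation
#' PDX tumors (P1, P2) with 116 and 117.
#'
#' @param N,T,P1,P2 Reporter channel label ("114".."117") assigned to each
#'   tissue class. The assignment must be a bijection onto the 4-plex set.
#'
#' @return A named character vector mapping tissue class to channel label,
#'   with class `channel_assignment`.
#' @examples
#' channel_assignment()
#' channel_assignment(N = "117", T = "116", P1 = "115", P2 = "114")
#' @export
channel_assignment <- function(N = "114", T = "115", P1 = "116", P2 = "117") {
  assignment <- c(N = as.character(N), T = as.character(T),
                  P1 = as.character(P1), P2 = as.character(P2))
  plex <- c("114", "115", "116", "117")
  if (!setequal(assignment, plex) || anyDuplicated(assignment) > 0) {
    abort(paste0(
      "channel assignment must be a bijection from {N, T, P1, P2} onto {",
      paste(plex, collapse = ", "), "}"))
  }
  structure(assignment, class = "channel_assignment")
}
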