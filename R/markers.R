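# Marker identifiers ---------------------------------------------------------
#
# Eight tumor markers exist: four analytes (CEA, CA19-9, CA125, CA15-3), each
# assayed in two specimen types (PE = pleural effusion fluid, PB = peripheral
# blood).  The canonical display order follows clinical reporting convention:
# PE before PB, and within a fluid CA19-9, CA125, CA15-3, CEA.

MARKER_FLUIDS   <- c("PE", "PB")
MARKER_ANALYTES <- c("CA19-9", "CA125", "CA15-3", "CEA")

#' The eight marker identifiers
#'
#' Marker identifiers are strings of the form `"<fluid>.<analyte>"`, e.g.
#' `"PE.CEA"`. Exactly eight exist: analytes CEA, CA19-9, CA125 and CA15-3,
#' each measured in pleural effusion (`PE`) and peripheral blood (`PB`).
#'
#' @param order `"canonical"` returns the display order used for panel
#'   strings (PE block then PB block; CA19-9, CA125, CA15-3, CEA within
#'   each); `"csv"` returns the cohort-file column order (CEA, CA19-9,
#'   CA125, CA15-3 within each fluid).
#' @return Character vector of length 8.
#' @export
#' @examples
#' marker_ids()
marker_ids <- function(order = c("canonical", "csv")) {
  order <- match.arg(order)
  analytes <- switch(order,
    canonical = MARKER_ANALYTES,
    csv = c("CEA", "CA19-9", "CA125", "CA15-3")
  )
  as.vector(vapply(MARKER_FLUIDS, function(f) paste(f, analytes, sep = "."),
                   character(length(analytes))))
}

#' @rdname marker_ids
#' @param marker Character vector of marker identifiers.
#' @return `marker_analyte()` / `marker_fluid()` return the analyte / fluid
#'   component of each identifier.
#' @export
marker_analyte <- function(marker) {
  stopifnot(all(marker %in% marker_ids()))
  sub("^(PE|PB)\\.", "", marker)
}

#' @rdname marker_ids
#' @export
marker_fluid <- function(marker) {
  stopifnot(all(marker %in% marker_ids()))
  sub("\\..*$", "", marker)
}

# Rank of each marker in the canonical display order; used to sort panels.
marker_rank <- function(marker) match(marker, marker_ids("canonical"))

#' Canonical panel string
#'
#' A marker panel is a non-empty subset of the eight markers.  Its canonical
#' string form joins the members with `+` after sorting them into canonical
#' marker order (e.g. `"PE.CA19-9+PE.CA15-3+PE.CEA+PB.CEA"`).
#'
#' @param panel Character vector of marker identifiers (a set; duplicates are
#'   an error).
#' @return Length-1 character string.
#' @export
panel_string <- function(panel) {
  panel <- validate_panel(panel)
  paste(panel, collapse = "+")
}

#' @rdname panel_string
#' @param x A `+`-joined panel string.
#' @return `parse_panel()` returns the member markers in canonical order.
#' @export
parse_panel <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  validate_panel(strsplit(x, "+", fixed = TRUE)[[1]])
}

# Checks membership/duplicates and returns the panel in canonical order.
validate_panel <- function(panel) {
  if (length(panel) == 0L) stop("panel must be non-empty")
  if (anyDuplicated(panel)) stop("panel contains duplicate markers")
  bad <- setdiff(panel, marker_ids())
  if (length(bad)) stop("unknown marker(s): ", paste(bad, collapse = ", "))
  panel[order(marker_rank(panel))]
}
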