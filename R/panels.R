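# Panel enumeration and pricing ----------------------------------------------

#' Enumerate all non-empty marker panels
#'
#' With the eight markers this yields the 2^8 - 1 = 255 combinations the
#' pipeline scores.  Panels are returned in canonical order: by size, then
#' lexicographically by canonical panel string.
#'
#' @param markers Character vector of distinct marker ids (default all 8).
#' @return List of character vectors, each a panel in canonical marker
#'   order.
#' @export
#' @examples
#' length(enumerate_panels())  # 255
enumerate_panels <- function(markers = marker_ids("canonical")) {
  if (length(markers) == 0L) stop("marker set must be non-empty")
  if (anyDuplicated(markers)) stop("marker set contains duplicates")
  markers <- validate_panel(markers)
  n <- length(markers)
  panels <- list()
  for (size in seq_len(n)) {
    subsets <- utils::combn(markers, size, simplify = FALSE)
    strs <- vapply(subsets, panel_string, character(1))
    panels <- c(panels, subsets[order(strs, method = "radix")])
  }
  panels
}

#' Unit price table for the tumor-marker assays
#'
#' Prices are per analyte in RMB; the PE and PB assays of one analyte share
#' a price, and the three CA markers (CA125, CA15-3, CA19-9) share one
#' price.  The defaults (CEA 56.5, CA 84.0) are back-solved from the
#' cheapest published panel costs and reproduce all twenty distinct
#' combination costs.
#'
#' @param cea Price of a CEA assay.
#' @param ca Price of a CA-marker assay (CA19-9, CA125, CA15-3).
#' @return Named numeric vector of per-analyte prices, class `price_table`.
#' @export
price_table <- function(cea = 56.5, ca = 84.0) {
  stopifnot(cea > 0, ca > 0)
  structure(c("CEA" = cea, "CA19-9" = ca, "CA125" = ca, "CA15-3" = ca),
            class = "price_table")
}

#' Cost of a marker panel
#'
#' Additive cost model: the panel's cost is the sum of the unit prices of
#' its member assays.
#'
#' @param panel Marker panel (character vector or `+`-joined string).
#' @param prices A [price_table()].
#' @return Cost in RMB.
#' @export
#' @examples
#' panel_cost(c("PE.CEA", "PB.CEA"))  # 113
panel_cost <- function(panel, prices = price_table()) {
  if (is.character(panel) && length(panel) == 1L && grepl("+", panel, fixed = TRUE)) {
    panel <- parse_panel(panel)
  }
  panel <- validate_panel(panel)
  analytes <- marker_analyte(panel)
  missing <- setdiff(analytes, names(prices))
  if (length(missing)) stop("no price for analyte(s): ",
                            paste(missing, collapse = ", "))
  sum(unname(prices[analytes]))
}

#' Group panels by distinct cost
#'
#' @param panels List of marker panels.
#' @param prices A [price_table()].
#' @return Data frame `cost`, `panel` (canonical string), `n_markers`,
#'   sorted by cost then panel; costs repeat within a group. Attribute
#'   `"costs"` holds the sorted unique cost values.
#' @export
distinct_costs <- function(panels, prices = price_table()) {
  if (length(panels) == 0L) stop("panels must be non-empty")
  df <- data.frame(
    panel = vapply(panels, panel_string, character(1)),
    cost = vapply(panels, panel_cost, numeric(1), prices = prices),
    n_markers = lengths(panels))
  df <- df[order(df$cost, df$n_markers, df$panel, method = "radix"), ]
  rownames(df) <- NULL
  structure(df, costs = sort(unique(df$cost)))
}

#' Best-AUC-per-cost ladder
#'
#' For each distinct panel cost, keeps the panel whose cross-validated AUC
#' is highest (ties broken toward fewer markers, then the lexicographically
#' smaller canonical string) and labels the rungs `C1`, `C2`, ... in order
#' of increasing cost — the published twenty-rung ladder under the default
#' price table.
#'
#' @param records Performance records (`panel`, `auc`, and optionally
#'   `sensitivity`/`specificity` columns) covering every panel, for a
#'   single model.
#' @param prices A [price_table()].
#' @param panels The panel universe the records must cover (default: all
#'   panels appearing in `records`; pass `enumerate_panels()` to require
#'   completeness).
#' @return Data frame of class `costed_ladder`: `rung`, `panel`, `cost`,
#'   `n_markers`, `auc` (+ `sensitivity`, `specificity` when present), with
#'   strictly increasing costs.
#' @export
build_ladder <- function(records, prices = price_table(), panels = NULL) {
  stopifnot(is.data.frame(records), all(c("panel", "auc") %in% names(records)))
  if (length(unique(records$model %||% "one")) > 1L) {
    stop("records mix models; filter to one model before building the ladder")
  }
  if (anyDuplicated(records$panel)) stop("duplicate panel records")
  if (!is.null(panels)) {
    need <- vapply(panels, panel_string, character(1))
    missing <- setdiff(need, records$panel)
    if (length(missing)) {
      stop("missing record for panel(s): ", paste(utils::head(missing, 5),
                                                  collapse = ", "))
    }
  }
  records$cost <- vapply(records$panel, panel_cost, numeric(1),
                         prices = prices)
  records$n_markers <- vapply(records$panel,
                              function(p) length(parse_panel(p)), integer(1))
  keep <- c("panel", "cost", "n_markers", "auc",
            intersect(c("sensitivity", "specificity"), names(records)))
  records <- records[keep]
  split_by_cost <- split(records, records$cost)
  best <- lapply(split_by_cost, function(g) {
    g <- g[order(-g$auc, g$n_markers, g$panel, method = "radix"), ]
    g[1, ]
  })
  ladder <- do.call(rbind, best)
  ladder <- ladder[order(ladder$cost), ]
  ladder <- cbind(rung = paste0("C", seq_len(nrow(ladder))), ladder)
  rownames(ladder) <- NULL
  class(ladder) <- c("costed_ladder", "data.frame")
  ladder
}

#' Published twenty-rung ladder fixture
#'
#' Loads the transcription of the published best-per-cost table (stacking
#' model: combination, cost, AUC, sensitivity, specificity) shipped with the
#' package for replay mode.  No random state or model code is touched.
#'
#' @return A `costed_ladder` data frame with rungs C1..C20.
#' @export
load_table2 <- function() {
  path <- system.file("extdata", "table2.csv", package = "mpecost",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df$panel <- vapply(df$panel, function(p) panel_string(parse_panel(p)),
                     character(1))
  df$n_markers <- vapply(df$panel, function(p) length(parse_panel(p)),
                         integer(1))
  df <- df[c("rung", "panel", "cost", "n_markers", "auc",
             "sensitivity", "specificity")]
  stopifnot(!is.unsorted(df$cost, strictly = TRUE))
  class(df) <- c("costed_ladder", "data.frame")
  df
}
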