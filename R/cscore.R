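# Cost-effectiveness framework -----------------------------------------------
#
# The comprehensive score (C-score) trades diagnostic accuracy against cost:
#   C-score = w * AUC + (1 - w) * (1 - regularized(cost))
# where regularized() is min-max scaling of the candidate costs to [0, 1]
# and w in [0, 1] is the weight put on accuracy.

#' Min-max regularization of panel costs
#'
#' @param costs Numeric vector with at least two distinct values.
#' @return `(x - min) / (max - min)` elementwise, in `[0, 1]`.
#' @export
regularize_costs <- function(costs) {
  stopifnot(is.numeric(costs), !anyNA(costs))
  lo <- min(costs); hi <- max(costs)
  if (hi == lo) stop("all costs equal; min-max regularization is degenerate")
  (costs - lo) / (hi - lo)
}

#' The comprehensive score
#'
#' @param auc AUC in `[0, 1]`.
#' @param regularized_cost Min-max-scaled cost in `[0, 1]`.
#' @param w Weight on AUC, in `[0, 1]`; `w = 1` scores accuracy only,
#'   `w = 0` cost only.
#' @return `w * auc + (1 - w) * (1 - regularized_cost)`, vectorized.
#' @export
#' @examples
#' c_score(0.937, 1, 0.99)  # 0.92763
c_score <- function(auc, regularized_cost, w) {
  for (v in list(auc, regularized_cost, w)) {
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
      stop("auc, regularized_cost and w must all lie in [0, 1]")
    }
  }
  w * auc + (1 - w) * (1 - regularized_cost)
}

#' Round half away from zero
#'
#' Fixed-precision rounding used for reported scores (base `round()` rounds
#' half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Default weight grid for the C-score sweep
#'
#' Covers 0 to 0.9 in steps of 0.1 plus the accuracy-heavy values 0.95 and
#' 0.99 and the limit 1.0.
#' @return Numeric vector.
#' @export
default_w_grid <- function() {
  c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.99, 1.0)
}

#' C-score sweep over a weight grid
#'
#' Scores every ladder rung at every weight.  Per weight, the rung with the
#' highest / lowest C-score is flagged as argmax / argmin; exact score ties
#' are broken toward the lower-cost rung (and reported in attribute
#' `"ties"`).
#'
#' @param ladder A `costed_ladder` ([build_ladder()] / [load_table2()]).
#' @param w_grid Numeric weights in `[0, 1]` ([default_w_grid()]).
#' @return Data frame with one row per (w, rung): `w`, `rung`, `panel`,
#'   `cost`, `auc`, `regularized_cost`, `c_score`, `is_argmax`,
#'   `is_argmin`.
#' @export
sweep_w <- function(ladder, w_grid = default_w_grid()) {
  stopifnot(inherits(ladder, "data.frame"), nrow(ladder) >= 2)
  if (length(w_grid) == 0L) stop("w grid must be non-empty")
  if (any(w_grid < 0 | w_grid > 1)) stop("w grid values must lie in [0, 1]")
  reg <- regularize_costs(ladder$cost)
  ties <- character(0)
  out <- lapply(w_grid, function(w) {
    s <- c_score(ladder$auc, reg, w)
    # ties toward lower cost: order by score desc, then cost asc
    ord_max <- order(-s, ladder$cost, method = "radix")
    ord_min <- order(s, ladder$cost, method = "radix")
    if (sum(s == s[ord_max[1]]) > 1L || sum(s == s[ord_min[1]]) > 1L) {
      ties <<- c(ties, sprintf("w=%g", w))
    }
    data.frame(w = w, rung = ladder$rung, panel = ladder$panel,
               cost = ladder$cost, auc = ladder$auc, regularized_cost = reg,
               c_score = s,
               is_argmax = seq_len(nrow(ladder)) == ord_max[1],
               is_argmin = seq_len(nrow(ladder)) == ord_min[1])
  })
  structure(do.call(rbind, out), ties = ties)
}

#' Argmax / argmin rungs per weight
#'
#' @param sweep Output of [sweep_w()].
#' @return Data frame `w`, `argmax`, `argmin` (rung labels).
#' @export
sweep_extremes <- function(sweep) {
  ws <- unique(sweep$w)
  data.frame(
    w = ws,
    argmax = vapply(ws, function(w) sweep$rung[sweep$w == w & sweep$is_argmax],
                    character(1)),
    argmin = vapply(ws, function(w) sweep$rung[sweep$w == w & sweep$is_argmin],
                    character(1)))
}

#' Median-split quadrant segmentation of a ladder
#'
#' Computes the median cost and median AUC over the rungs (even counts
#' average the two central values) and assigns each rung to one of four
#' quadrants by strict comparison; a rung sitting exactly on a median is
#' assigned to the "low" side and listed in attribute `"median_ties"`.
#'
#' @param ladder A `costed_ladder`.
#' @return Data frame `rung`, `panel`, `cost`, `auc`, `quadrant` with
#'   attributes `median_cost`, `median_auc`.
#' @export
quadrant_segmentation <- function(ladder) {
  stopifnot(nrow(ladder) >= 2)
  med_cost <- stats::median(ladder$cost)
  med_auc <- stats::median(ladder$auc)
  high_auc <- ladder$auc > med_auc
  high_cost <- ladder$cost > med_cost
  quadrant <- paste0(ifelse(high_auc, "high-AUC", "low-AUC"), "/",
                     ifelse(high_cost, "high-cost", "low-cost"))
  on_median <- ladder$rung[ladder$auc == med_auc | ladder$cost == med_cost]
  structure(
    data.frame(rung = ladder$rung, panel = ladder$panel, cost = ladder$cost,
               auc = ladder$auc, quadrant = quadrant),
    median_cost = med_cost, median_auc = med_auc, median_ties = on_median)
}

#' Flag ladder rungs missing an anchor marker
#'
#' The published ladder's low-AUC outliers share one feature: their panels
#' omit the strongest single marker (PE.CEA).  This helper returns the rungs
#' whose panel excludes a given anchor.
#'
#' @param ladder A `costed_ladder`.
#' @param anchor A marker id (default `"PE.CEA"`).
#' @return Character vector of rung labels.
#' @export
flag_missing_anchor <- function(ladder, anchor = "PE.CEA") {
  stopifnot(anchor %in% marker_ids())
  has <- vapply(ladder$panel, function(p) anchor %in% parse_panel(p),
                logical(1))
  ladder$rung[!has]
}

#' Persona-based panel recommendations
#'
#' Maps each persona's weight to the argmax rung of the sweep at that
#' weight: the default personas are `budget` (w = 0.5, cost-driven),
#' `balanced` (w = 0.95) and `accuracy_first` (w = 0.99).
#'
#' @param sweep Output of [sweep_w()]; must contain every persona weight.
#' @param personas Named numeric vector of weights.
#' @return Data frame `persona`, `w`, `rung`, `panel`, `cost`, `auc`,
#'   `c_score`.
#' @export
recommend <- function(sweep, personas = c(budget = 0.5, balanced = 0.95,
                                          accuracy_first = 0.99)) {
  missing <- setdiff(personas, unique(sweep$w))
  if (length(missing)) {
    stop("persona weight(s) not in the computed grid: ",
         paste(missing, collapse = ", "))
  }
  rows <- lapply(seq_along(personas), function(i) {
    hit <- sweep[sweep$w == personas[i] & sweep$is_argmax, ]
    data.frame(persona = names(personas)[i], w = personas[i],
               rung = hit$rung, panel = hit$panel, cost = hit$cost,
               auc = hit$auc, c_score = hit$c_score)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a C-score sweep CSV
#'
#' Round-trips at full double precision
#' (`w,rung,combination,cost,auc,regularized_cost,c_score,is_argmax,is_argmin`).
#'
#' @param sweep Output of [sweep_w()].
#' @param path File path.
#' @return `read_sweep_csv()` returns the sweep data frame.
#' @export
write_sweep_csv <- function(sweep, path) {
  out <- sweep
  names(out)[names(out) == "panel"] <- "combination"
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[names(df) == "combination"] <- "panel"
  df$is_argmax <- as.logical(df$is_argmax)
  df$is_argmin <- as.logical(df$is_argmin)
  df
}
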