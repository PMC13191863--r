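#' Build the cost-effectiveness frontier
#'
#' Sorts strategies by effect (ties broken toward lower cost, then id),
#' marks strictly dominated strategies (`D`: some other strategy costs no
#' more and yields no less effect, with at least one strict inequality),
#' then iteratively removes extended-dominated strategies (`ED`: a member
#' whose incremental cost-effectiveness ratio against the previous
#' surviving member exceeds that of the next member - a mixture of its
#' neighbours would deliver more effect for less money), recomputing ICERs
#' until the sequence is strictly increasing. Survivors are the
#' non-dominated frontier (`ND`) and carry pairwise incremental cost,
#' effect and ICER against the previous frontier member.
#'
#' @param rows a data.frame with columns `strategy` (or `id`), `cost`,
#'   `effect` (any additional columns are preserved).
#' @return an `msim_frontier` data.frame sorted by effect with columns
#'   `strategy`, `cost`, `effect`, `inc_cost`, `inc_effect`, `icer`,
#'   `status` (`ND`/`ED`/`D`). Incremental columns are `NA` off the
#'   frontier and for its cheapest member.
#' @examples
#' rows <- data.frame(strategy = c("a", "b", "c"),
#'                    cost = c(0, 10, 40), effect = c(1, 2, 2.5))
#' build_frontier(rows)
#' @export
build_frontier <- function(rows) {
  rows <- as.data.frame(rows)
  if ("id" %in% names(rows) && !"strategy" %in% names(rows))
    names(rows)[names(rows) == "id"] <- "strategy"
  stopifnot(all(c("strategy", "cost", "effect") %in% names(rows)),
            nrow(rows) >= 1L)
  if (any(rows$effect < 0))
    warning("negative effects present; frontier still computed")

  ord <- order(rows$effect, rows$cost, rows$strategy)
  rows <- rows[ord, , drop = FALSE]
  n <- nrow(rows)

  status <- rep("ND", n)
  for (i in seq_len(n)) {
    dom <- rows$cost <= rows$cost[i] & rows$effect >= rows$effect[i] &
      (rows$cost < rows$cost[i] | rows$effect > rows$effect[i])
    if (any(dom)) status[i] <- "D"
  }

  cand <- which(status != "D")
  icers_of <- function(idx) {
    m <- length(idx)
    if (m < 2L) return(numeric(0))
    (rows$cost[idx[-1L]] - rows$cost[idx[-m]]) /
      (rows$effect[idx[-1L]] - rows$effect[idx[-m]])
  }
  repeat {
    ic <- icers_of(cand)
    if (length(ic) < 2L) break
    viol <- which(ic[-length(ic)] >= ic[-1L])
    if (length(viol) == 0L) break
    drop <- cand[viol[1L] + 1L]      # the member whose ICER is not bettered
    status[drop] <- "ED"
    cand <- setdiff(cand, drop)
  }

  rows$inc_cost <- rows$inc_effect <- rows$icer <- NA_real_
  if (length(cand) >= 2L) {
    m <- length(cand)
    rows$inc_cost[cand[-1L]] <- rows$cost[cand[-1L]] - rows$cost[cand[-m]]
    rows$inc_effect[cand[-1L]] <- rows$effect[cand[-1L]] - rows$effect[cand[-m]]
    rows$icer[cand[-1L]] <- rows$inc_cost[cand[-1L]] / rows$inc_effect[cand[-1L]]
  }
  rows$status <- status
  rownames(rows) <- NULL
  class(rows) <- c("msim_frontier", "data.frame")
  rows
}

#' @export
print.msim_frontier <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  df$cost <- round(df$cost, 2)
  df$icer <- round(df$icer, 0)
  print(df, row.names = FALSE, digits = digits)
  invisible(x)
}

#' ICERs of every strategy against a fixed baseline
#'
#' `(cost_i - cost_0) / (effect_i - effect_0)` for each strategy against
#' the named baseline. A zero effect difference gives `NA` with
#' `note = "undefined"`; a strategy that is cheaper *and* more effective
#' than the baseline gets `note = "dominant"` (its negative ICER is not a
#' meaningful ratio).
#'
#' @param rows as in [build_frontier()].
#' @param baseline_id the baseline's `strategy` value.
#' @return a data.frame `strategy`, `cost`, `effect`, `icer_vs_baseline`,
#'   `note`.
#' @export
icer_vs_baseline <- function(rows, baseline_id) {
  rows <- as.data.frame(rows)
  if ("id" %in% names(rows) && !"strategy" %in% names(rows))
    names(rows)[names(rows) == "id"] <- "strategy"
  if (!baseline_id %in% rows$strategy)
    stop("baseline strategy not present: ", baseline_id)
  b <- rows[rows$strategy == baseline_id, ]
  dc <- rows$cost - b$cost
  de <- rows$effect - b$effect
  icer <- ifelse(de == 0, NA_real_, dc / de)
  note <- rep("", nrow(rows))
  note[de == 0] <- "undefined"
  note[dc < 0 & de > 0] <- "dominant"
  note[dc > 0 & de < 0] <- "dominated"
  data.frame(strategy = rows$strategy, cost = rows$cost, effect = rows$effect,
             icer_vs_baseline = icer, note = note, stringsAsFactors = FALSE)
}

#' Net monetary benefit
#'
#' `wtp * effect - cost`: the strategy maximizing NMB at a willingness to
#' pay is the cost-effective choice at that threshold.
#'
#' @param cost,effect numeric vectors (recycled).
#' @param wtp willingness to pay per effect unit, `>= 0`.
#' @return numeric vector of net monetary benefits.
#' @export
nmb <- function(cost, effect, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0")
  wtp * effect - cost
}
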