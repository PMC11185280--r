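# Follow-up prescription linkage.
#
# A follow-up prescription is a prescription of the same drug and
# administration route that starts within the linkage window (default 10
# minutes, boundary inclusive) of the previous prescription's end. Chains of
# follow-ups form "continuous prescription" units: the denominator against
# which alert disappearance is judged. Overlapping prescriptions of the same
# drug/route are duplicate therapy, not follow-ups, and are never chained.

#' Chain follow-up prescriptions into continuous-prescription units
#'
#' Prescriptions are grouped by case, drug code and route, then linked
#' greedily in start-time order: a prescription joins an existing chain when
#' the gap between the chain's end and its own start is in
#' `[0, linkage_window]`. When several open chains qualify, the one ending
#' closest to the new start (smallest gap) is extended; ties break by chain
#' creation order. Every prescription belongs to exactly one chain; a lone
#' prescription forms a singleton chain.
#'
#' @param prescriptions validated prescription tibble (see [cpoe_dataset()]).
#' @param linkage_window maximum gap, in seconds, bridged between the end of
#'   one prescription and the start of its follow-up. Default 600 (10
#'   minutes), boundary inclusive.
#' @return tibble with one row per chain: `chain_id`, `case_id`, `drug_code`,
#'   `route`, list-columns `member_rx_ids` (in link order) and `coverage`
#'   (tibble of disjoint sorted spans; gaps <= `linkage_window` between
#'   members are bridged into one span).
#' @export
build_chains <- function(prescriptions, linkage_window = 600) {
  stopifnot(linkage_window >= 0)
  rx <- prescriptions
  if (!nrow(rx)) {
    return(tibble::tibble(chain_id = character(), case_id = character(),
                          drug_code = character(), route = character(),
                          member_rx_ids = list(), coverage = list()))
  }
  # deterministic processing order regardless of input row order
  o <- order(rx$case_id, rx$drug_code, rx$route, rx$start_ts, rx$end_ts, rx$rx_id)
  rx <- rx[o, ]
  key <- paste(rx$case_id, rx$drug_code, rx$route, sep = "\r")

  chains <- vector("list", nrow(rx))
  n_chain <- 0L
  split_idx <- split(seq_len(nrow(rx)), key)
  split_idx <- split_idx[order(vapply(split_idx, `[`, integer(1), 1L))]

  for (idx in split_idx) {
    # open chains within this (case, drug, route) group: index into `chains`
    open <- integer(0)
    for (i in idx) {
      s <- rx$start_ts[i]
      gaps <- vapply(open, function(ci) as.numeric(s - chains[[ci]]$end_ts,
                                                   units = "secs"), numeric(1))
      ok <- which(gaps >= 0 & gaps <= linkage_window)
      if (length(ok)) {
        # extend the chain ending closest to this start; ties -> oldest chain
        pick <- open[ok[order(gaps[ok], ok)[1]]]
        chains[[pick]]$members <- c(chains[[pick]]$members, rx$rx_id[i])
        chains[[pick]]$spans_s <- c(chains[[pick]]$spans_s, s)
        chains[[pick]]$spans_e <- c(chains[[pick]]$spans_e, rx$end_ts[i])
        chains[[pick]]$end_ts <- max(chains[[pick]]$end_ts, rx$end_ts[i])
      } else {
        n_chain <- n_chain + 1L
        chains[[n_chain]] <- list(case_id = rx$case_id[i],
                                  drug_code = rx$drug_code[i],
                                  route = rx$route[i],
                                  members = rx$rx_id[i],
                                  spans_s = s, spans_e = rx$end_ts[i],
                                  end_ts = rx$end_ts[i])
        open <- c(open, n_chain)
      }
    }
  }
  chains <- chains[seq_len(n_chain)]

  coverage <- lapply(chains, function(ch) {
    merge_spans_within(ch$spans_s, ch$spans_e, linkage_window)
  })
  tibble::tibble(
    chain_id = sprintf("CH%06d", seq_len(n_chain)),
    case_id = vapply(chains, `[[`, character(1), "case_id"),
    drug_code = vapply(chains, `[[`, character(1), "drug_code"),
    route = vapply(chains, `[[`, character(1), "route"),
    member_rx_ids = lapply(chains, `[[`, "members"),
    coverage = coverage)
}

# merge spans, bridging gaps <= window into one span
merge_spans_within <- function(s, e, window) {
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  ks <- s[1]; ke <- e[1]
  for (i in seq_along(s)[-1]) {
    j <- length(ks)
    if (as.numeric(s[i] - ke[j], units = "secs") <= window) {
      ke[j] <- max(ke[j], e[i])
    } else {
      ks <- c(ks, s[i]); ke <- c(ke, e[i])
    }
  }
  tibble::tibble(start_ts = ks, end_ts = ke)
}

#' Is a continuous prescription active during an interval?
#'
#' A chain is active in the half-open interval `[interval_start,
#' interval_end)` iff some coverage span intersects it with strictly positive
#' duration. A one-time prescription with `start == end` is never active.
#'
#' @param chain one row of the [build_chains()] result (a list or one-row
#'   tibble with a `coverage` element).
#' @param interval_start,interval_end POSIXct interval bounds,
#'   `interval_start < interval_end`.
#' @return logical scalar.
#' @export
chain_active_in <- function(chain, interval_start, interval_end) {
  stopifnot(interval_start < interval_end)
  cov <- if (is.data.frame(chain$coverage)) chain$coverage else chain$coverage[[1]]
  any(spans_overlap(cov$start_ts, cov$end_ts, interval_start, interval_end))
}
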