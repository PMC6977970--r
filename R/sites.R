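# Site analysis: unique alignments become strand-resolved insertion events;
# plus/minus events are paired into site calls whose coordinate offset gives
# the TSD length, with abundance-weighted frequencies.

#' Convert unique alignment hits into insertion events
#'
#' The event coordinate is the plus-strand position of the first target base
#' 3' of the junction on the read's strand: for plus-strand hits that is
#' \code{ref_start}; for minus-strand hits it is the plus-strand coordinate
#' of the hit's rightmost base, \code{ref_start + nchar(query) - 1} (modulo
#' the reference length). Events with identical (site, strand) are merged by
#' abundance summation.
#'
#' @param hits Data frame from \code{\link{align_reads}}; only uniquely
#'   aligned rows are admissible.
#' @param n_ref Reference length for circular wrap-around.
#' @param merge_window Optional coordinate window: events on the same strand
#'   within this many bp of a heavier event are merged into it (default 0,
#'   exact-coordinate aggregation; junction chemistry is base-precise).
#' @return Data frame with columns \code{site}, \code{strand},
#'   \code{abundance}, sorted by descending abundance.
#' @export
call_events <- function(hits, n_ref, merge_window = 0) {
  hits <- hits[hits$aligned, , drop = FALSE]
  if (nrow(hits) > 0 && !all(hits$unique))
    stop_contract("call_events requires uniquely aligned hits only")
  if (nrow(hits) == 0)
    return(data.frame(site = integer(0), strand = character(0),
                      abundance = integer(0)))
  site <- ifelse(hits$strand == "+",
                 hits$ref_start,
                 wrap_coord(hits$ref_start + nchar(hits$query) - 1L, n_ref))
  ev <- stats::aggregate(abundance ~ site + strand,
                         data = data.frame(site = site, strand = hits$strand,
                                           abundance = hits$abundance),
                         FUN = sum)
  if (merge_window > 0) ev <- merge_events(ev, n_ref, merge_window)
  ev <- ev[order(-ev$abundance, ev$site, ev$strand), , drop = FALSE]
  ev$site <- as.integer(ev$site)
  ev$abundance <- as.integer(ev$abundance)
  rownames(ev) <- NULL
  ev
}

# Merge events on the same strand lying within `window` bp of a heavier
# event into that event's coordinate (greedy, heaviest first).
merge_events <- function(ev, n_ref, window) {
  out <- NULL
  for (s in unique(ev$strand)) {
    e <- ev[ev$strand == s, , drop = FALSE]
    e <- e[order(-e$abundance, e$site), , drop = FALSE]
    taken <- rep(FALSE, nrow(e))
    for (i in seq_len(nrow(e))) {
      if (taken[i]) next
      d <- abs(e$site - e$site[i])
      d <- pmin(d, n_ref - d)  # circular distance
      grp <- !taken & d <= window
      e$abundance[i] <- sum(e$abundance[grp])
      taken[grp] <- TRUE
      taken[i] <- TRUE
      out <- rbind(out, e[i, , drop = FALSE])
    }
  }
  out
}

#' Pair plus- and minus-strand events into site calls
#'
#' For each plus-strand event whose frequency exceeds \code{min_frequency},
#' selects the minus-strand event within the downstream window maximising
#' joint abundance; the coordinate offset of the pair gives the TSD length
#' \code{L = q - p + 1} (circular wrap). Calls are labelled TS1, TS2, ... by
#' descending frequency; unpaired events are reported separately.
#'
#' @param events Data frame from \code{\link{call_events}}.
#' @param n_ref Reference length.
#' @param max_offset Maximum downstream offset considered when pairing
#'   (default 50 bp, generous for TSDs).
#' @param min_frequency Minimum abundance-weighted event frequency for a
#'   plus event to seed a call (default 0.001).
#' @return A list of class \code{site_calls}: \code{calls} (data frame:
#'   \code{label}, \code{plus_site}, \code{minus_site}, \code{tsd_len},
#'   \code{plus_abundance}, \code{minus_abundance}, \code{frequency}),
#'   \code{unpaired} (leftover events), and \code{total_abundance}.
#' @export
pair_sites <- function(events, n_ref, max_offset = 50, min_frequency = 0.001) {
  total <- sum(events$abundance)
  plus <- events[events$strand == "+", , drop = FALSE]
  minus <- events[events$strand == "-", , drop = FALSE]
  calls <- NULL
  used_minus <- rep(FALSE, nrow(minus))
  if (total > 0 && nrow(plus) > 0) {
    plus <- plus[order(-plus$abundance, plus$site), , drop = FALSE]
    for (i in seq_len(nrow(plus))) {
      if (plus$abundance[i] / total < min_frequency) next
      if (nrow(minus) == 0) next
      d <- (minus$site - plus$site[i]) %% n_ref  # downstream offset = L - 1
      cand <- which(!used_minus & d < max_offset)
      if (length(cand) == 0) next
      joint <- plus$abundance[i] + minus$abundance[cand]
      j <- cand[which.max(joint)]
      used_minus[j] <- TRUE
      calls <- rbind(calls, data.frame(
        plus_site = plus$site[i], minus_site = minus$site[j],
        tsd_len = as.integer(d[j] + 1L),
        plus_abundance = plus$abundance[i],
        minus_abundance = minus$abundance[j],
        frequency = (plus$abundance[i] + minus$abundance[j]) / total))
    }
  }
  if (is.null(calls))
    calls <- data.frame(plus_site = integer(0), minus_site = integer(0),
                        tsd_len = integer(0), plus_abundance = integer(0),
                        minus_abundance = integer(0), frequency = numeric(0))
  calls <- calls[order(-calls$frequency, calls$plus_site), , drop = FALSE]
  calls <- cbind(label = if (nrow(calls)) paste0("TS", seq_len(nrow(calls)))
                         else character(0),
                 calls)
  rownames(calls) <- NULL
  paired_plus <- calls$plus_site
  unpaired <- rbind(
    plus[!(plus$site %in% paired_plus), , drop = FALSE],
    minus[!used_minus, , drop = FALSE])
  rownames(unpaired) <- NULL
  structure(list(calls = calls, unpaired = unpaired,
                 total_abundance = total, n_ref = n_ref),
            class = "site_calls")
}

#' @export
print.site_calls <- function(x, ...) {
  cat("<site_calls>", nrow(x$calls), "paired site(s),",
      nrow(x$unpaired), "unpaired event(s), total abundance",
      x$total_abundance, "\n")
  if (nrow(x$calls)) print(x$calls, row.names = FALSE)
  invisible(x)
}

#' Infer the consensus TSD length
#'
#' For a single call, returns its \code{L = q - p + 1}; across multiple
#' calls, returns the abundance-weighted mode of the per-call lengths.
#'
#' @param calls A \code{site_calls} object or its \code{calls} data frame.
#' @return Integer TSD length, or \code{NA} when no paired call exists.
#' @export
infer_tsd <- function(calls) {
  df <- if (inherits(calls, "site_calls")) calls$calls else calls
  if (nrow(df) == 0) return(NA_integer_)
  w <- tapply(df$plus_abundance + df$minus_abundance, df$tsd_len, sum)
  as.integer(names(w)[which.max(w)])
}

#' Per-position strand coverage of insertion events
#'
#' @param events Data frame from \code{\link{call_events}}.
#' @return Data frame with 1-based inclusive coordinates: \code{site},
#'   \code{strand}, \code{abundance} (one row per event; coordinates are
#'   junction positions, not interval covers).
#' @export
event_coverage <- function(events) {
  events[order(events$site, events$strand), , drop = FALSE]
}
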