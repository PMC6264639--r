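#' Per-group majority state of a window
#'
#' Summarizes a window's epigenetic change pattern as the most frequent
#' non-undefined state within each classification group. A group with no
#' defined sample, or whose top two states tie, is reported as undefined.
#'
#' @param profile per-sample state vector (named by sample ID or aligned
#'   to `classification$samples`).
#' @param classification a [sample_classification()].
#' @param undefined the undefined label.
#' @return Named character vector: group label -> majority state (or the
#'   undefined label).
#' @examples
#' cls <- sample_classification(paste0("s", 1:5),
#'                              c("A", "A", "A", "B", "B"))
#' group_majority(c("Tx", "Tx", "Quies", "Quies", "Quies"), cls)
#' @export
group_majority <- function(profile, classification,
                           undefined = "undefined") {
  profile <- .align_profile(profile, classification)
  g <- unname(classification$assignment[classification$samples])
  out <- stats::setNames(rep(undefined, length(classification$groups)),
                         classification$groups)
  for (grp in classification$groups) {
    s <- profile[g == grp]
    s <- s[s != undefined & !is.na(s)]
    if (length(s) == 0L) next
    counts <- sort(table(s), decreasing = TRUE)
    if (length(counts) > 1L && counts[1L] == counts[2L]) next  # tie
    out[[grp]] <- names(counts)[1L]
  }
  out
}

#' Pattern summaries for the significant windows of a scan
#'
#' Applies [group_majority()] to every significant window of a scan.
#'
#' @param scan an `mi_scan` from [scan_windows()].
#' @param windows optional `data.frame` of windows with a `window_index`
#'   column (e.g. from [significant_windows()]); defaults to the scan's
#'   significant windows.
#' @return A `data.frame` with chrom, start, end, mi and one column per
#'   group holding its majority state.
#' @export
pattern_summaries <- function(scan, windows = significant_windows(scan)) {
  undef <- scan$vocab$undefined
  grp_states <- t(vapply(windows$window_index, function(i) {
    group_majority(scan$profiles[i, ], scan$classification,
                   undefined = undef)
  }, character(length(scan$classification$groups))))
  if (nrow(windows) == 0L) {
    grp_states <- matrix(character(), nrow = 0L,
                         ncol = length(scan$classification$groups))
  }
  colnames(grp_states) <- scan$classification$groups
  cbind(windows[, c("chrom", "start", "end", "mi"), drop = FALSE],
        as.data.frame(grp_states, stringsAsFactors = FALSE))
}

#' Distribution of epigenetic change patterns
#'
#' Tabulates the ordered per-group state tuples of a set of pattern
#' summaries and reports each pattern's share of the windows whose pattern
#' is fully defined (any summary with an undefined group entry is excluded
#' from the denominator). Sorted by proportion descending.
#'
#' @param summaries `data.frame` from [pattern_summaries()] (or any frame
#'   holding one column per group).
#' @param group_order character vector naming the group columns, in order.
#' @param undefined the undefined label.
#' @return A `data.frame` with the group columns, `count` and
#'   `proportion` (summing to 1 over the rows).
#' @export
pattern_distribution <- function(summaries, group_order,
                                 undefined = "undefined") {
  pat <- summaries[, group_order, drop = FALSE]
  defined <- rowSums(pat == undefined | is.na(pat)) == 0L
  pat <- pat[defined, , drop = FALSE]
  if (nrow(pat) == 0L) {
    out <- pat
    out$count <- integer()
    out$proportion <- numeric()
    return(out)
  }
  key <- do.call(paste, c(pat, sep = "\r"))
  counts <- sort(table(key), decreasing = TRUE)
  parts <- strsplit(names(counts), "\r", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  colnames(out) <- group_order
  out$count <- as.integer(counts)
  out$proportion <- out$count / sum(out$count)
  rownames(out) <- NULL
  out
}
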