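#' Windowing parameters
#'
#' Controls how the genome is tiled and how each sample's segmentation is
#' collapsed into one state per window. The majority rule follows the scan
#' design: within a window a sample is assigned the state with the largest
#' bp coverage provided that state covers at least `min_fraction` (default
#' 80%) of the covered bp; otherwise the window is `undefined` for that
#' sample. On segmentations aligned to a uniform 200 bp grid the
#' bp-weighted rule coincides with counting 200 bp segments.
#'
#' @param window_length window length in bp (>= 200).
#' @param step distance between window starts in bp (defaults to
#'   `window_length`, i.e. consecutive non-overlapping windows).
#' @param min_fraction minimum majority fraction in (0, 1], default 0.8.
#' @return An object of class `WindowingParams`.
#' @export
windowing_params <- function(window_length = 5000, step = window_length,
                             min_fraction = 0.8) {
  window_length <- as.numeric(window_length)
  step <- as.numeric(step)
  if (is.na(window_length) || window_length < 200) {
    stop("window_length must be >= 200 bp", call. = FALSE)
  }
  if (is.na(step) || step < 1) stop("step must be >= 1 bp", call. = FALSE)
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must be in (0, 1]", call. = FALSE)
  }
  structure(list(window_length = window_length, step = step,
                 min_fraction = min_fraction),
            class = "WindowingParams")
}

#' Enumerate genome windows
#'
#' Emits windows chromosome by chromosome, in the chromosome order of the
#' layout, with starts at 0, step, 2*step, ... Trailing partial windows
#' shorter than `window_length` are dropped so that every window shares the
#' same frequency denominator.
#'
#' @param layout a [genome_layout()].
#' @param params a [windowing_params()].
#' @return A `data.frame` with columns `chrom`, `start`, `end` (BED
#'   convention, 0-based half-open).
#' @examples
#' lay <- genome_layout("chr1", 20000)
#' make_windows(lay, windowing_params(5000))
#' @export
make_windows <- function(layout, params) {
  stopifnot(inherits(params, "WindowingParams"))
  pieces <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    if (len < params$window_length) {
      return(NULL)
    }
    starts <- seq(0, len - params$window_length, by = params$step)
    data.frame(chrom = layout$chrom[i], start = starts,
               end = starts + params$window_length,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Collapse one sample's segmentation over a set of windows
#'
#' For every window, computes the bp coverage of each state from the
#' track's intervals and applies the majority rule: the top state is
#' assigned when it covers at least `min_fraction` of the covered bp and is
#' not tied with the runner-up; otherwise the vocabulary's undefined label.
#' Windows whose total covered bp is below `min_fraction` of the window
#' length (assembly gaps) are undefined.
#'
#' @param track a `StateTrack`.
#' @param windows `data.frame` from [make_windows()].
#' @param params a [windowing_params()].
#' @return Character vector of length `nrow(windows)`: a vocabulary state
#'   or the undefined label per window.
#' @export
collapse_track <- function(track, windows, params) {
  stopifnot(inherits(track, "StateTrack"),
            inherits(params, "WindowingParams"))
  undef <- track$vocab$undefined
  out <- rep(undef, nrow(windows))
  if (nrow(windows) == 0L || nrow(track$intervals) == 0L) return(out)

  ivs <- track$intervals
  igr <- GenomicRanges::GRanges(ivs$chrom,
                                IRanges::IRanges(ivs$start + 1, ivs$end))
  wgr <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start + 1,
                                                 windows$end))
  hits <- GenomicRanges::findOverlaps(igr, wgr)
  if (length(hits) == 0L) return(out)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- pmin(ivs$end[q], windows$end[s]) - pmax(ivs$start[q],
                                                windows$start[s])
  dt <- data.table::data.table(win = s, state = ivs$state[q], bp = ov)
  agg <- dt[, list(bp = sum(bp)), by = c("win", "state")]
  data.table::setorderv(agg, c("win", "bp"), order = c(1L, -1L))
  bp <- win <- state <- NULL  # NSE notes
  stats <- agg[, list(top_state = state[1L], top = bp[1L],
                      second = if (.N > 1L) bp[2L] else 0,
                      cov = sum(bp)),
               by = "win"]
  wl <- params$window_length
  mf <- params$min_fraction
  eps <- 1e-9
  ok <- stats$cov >= mf * wl - eps &
    stats$top >= mf * stats$cov - eps &
    stats$top > stats$second
  out[stats$win[ok]] <- stats$top_state[ok]
  out
}

#' Majority state of one window for one sample
#'
#' Convenience wrapper over [collapse_track()] for a single window.
#'
#' @param track a `StateTrack`.
#' @param window list or one-row `data.frame` with `chrom`, `start`, `end`.
#' @param params a [windowing_params()].
#' @return A single state label or the undefined label.
#' @export
window_state <- function(track, window, params) {
  w <- data.frame(chrom = window$chrom, start = window$start,
                  end = window$end, stringsAsFactors = FALSE)
  collapse_track(track, w, params)[1L]
}

#' Per-sample window profile
#'
#' Applies the majority rule to every sample in a fixed order, producing
#' the window's epigenetic profile vector (one entry per sample, each a
#' vocabulary state or the undefined label).
#'
#' @param tracks named list of `StateTrack`s (names are sample IDs), or an
#'   unnamed list (sample IDs taken from the tracks).
#' @param window list or one-row `data.frame` with `chrom`, `start`, `end`.
#' @param params a [windowing_params()].
#' @param sample_order character vector of sample IDs fixing the order.
#' @return Named character vector of states, one per sample.
#' @export
build_profile <- function(tracks, window, params,
                          sample_order = names(tracks)) {
  tracks <- .name_tracks(tracks)
  if (is.null(sample_order)) sample_order <- names(tracks)
  missing <- setdiff(sample_order, names(tracks))
  if (length(missing)) {
    stop("no track for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vapply(sample_order,
         function(sid) window_state(tracks[[sid]], window, params),
         character(1))
}

#' Profile matrix over all windows and samples
#'
#' The scan workhorse: collapses every sample's track over every window.
#'
#' @inheritParams build_profile
#' @param windows `data.frame` from [make_windows()].
#' @return Character matrix (windows x samples), `colnames` the sample IDs.
#' @export
profile_matrix <- function(tracks, windows, params,
                           sample_order = names(tracks)) {
  tracks <- .name_tracks(tracks)
  if (is.null(sample_order)) sample_order <- names(tracks)
  missing <- setdiff(sample_order, names(tracks))
  if (length(missing)) {
    stop("no track for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  mat <- vapply(sample_order,
                function(sid) collapse_track(tracks[[sid]], windows, params),
                character(nrow(windows)))
  if (nrow(windows) == 1L) mat <- matrix(mat, nrow = 1L,
                                         dimnames = list(NULL, sample_order))
  mat
}

.name_tracks <- function(tracks) {
  if (inherits(tracks, "StateTrack")) tracks <- list(tracks)
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    names(tracks) <- vapply(tracks, function(t) t$sample_id, character(1))
  }
  tracks
}
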