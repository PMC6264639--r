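#' Sample classification
#'
#' Maps each sample ID to one group label (e.g. cancer vs. normal, brain
#' vs. other tissues). Group order follows first appearance.
#'
#' @param sample_ids character vector of unique sample IDs.
#' @param groups parallel vector of group labels.
#' @return An object of class `SampleClassification` with fields
#'   `assignment` (named character: sample -> group), `samples` and
#'   `groups`.
#' @export
sample_classification <- function(sample_ids, groups) {
  sample_ids <- as.character(sample_ids)
  groups <- as.character(groups)
  if (length(sample_ids) != length(groups)) {
    stop("sample_ids and groups must have equal length", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(groups) || any(!nzchar(groups))) {
    stop("every sample needs a non-empty group label", call. = FALSE)
  }
  structure(list(assignment = stats::setNames(groups, sample_ids),
                 samples = sample_ids,
                 groups = unique(groups)),
            class = "SampleClassification")
}

#' @export
print.SampleClassification <- function(x, ...) {
  cat("SampleClassification: ", length(x$samples), " samples in ",
      length(x$groups), " group(s)\n", sep = "")
  print(table(x$assignment))
  invisible(x)
}

#' Scan parameters for the mutual-information test
#'
#' @param n_permutations number of composition-preserving shuffles of the
#'   profile vector used to build the null distribution (default 10,000).
#' @param seed master seed; per-window generators are derived
#'   deterministically from (seed, chrom, start) so results do not depend
#'   on window iteration order.
#' @param mi_threshold minimum MI (bits) for a window to be called
#'   significant (default 0.3).
#' @param fdr_threshold maximum BH-adjusted p-value (default 1e-4).
#' @param p_add_one if `TRUE`, report the permutation p-value as
#'   (r + 1) / (n + 1) instead of the default r / n (which can be exactly
#'   0 when no shuffle reaches the observed MI).
#' @return An object of class `MIParams`.
#' @export
mi_params <- function(n_permutations = 10000, seed = 1,
                      mi_threshold = 0.3, fdr_threshold = 1e-4,
                      p_add_one = FALSE) {
  n_permutations <- as.integer(n_permutations)
  if (is.na(n_permutations) || n_permutations < 1L) {
    stop("n_permutations must be >= 1", call. = FALSE)
  }
  if (mi_threshold < 0) stop("mi_threshold must be >= 0", call. = FALSE)
  if (fdr_threshold < 0 || fdr_threshold > 1) {
    stop("fdr_threshold must be in [0, 1]", call. = FALSE)
  }
  structure(list(n_permutations = n_permutations, seed = as.integer(seed),
                 mi_threshold = mi_threshold,
                 fdr_threshold = fdr_threshold,
                 p_add_one = isTRUE(p_add_one)),
            class = "MIParams")
}

# Align a profile vector to the classification's sample order.
.align_profile <- function(profile, classification) {
  if (length(profile) == 0L) stop("empty profile", call. = FALSE)
  if (!is.null(names(profile))) {
    missing <- setdiff(classification$samples, names(profile))
    extra <- setdiff(names(profile), classification$samples)
    if (length(missing) || length(extra)) {
      stop("profile and classification cover different sample sets",
           call. = FALSE)
    }
    profile <- profile[classification$samples]
  } else if (length(profile) != length(classification$samples)) {
    stop("unnamed profile length differs from the number of samples",
         call. = FALSE)
  }
  unname(profile)
}

#' Mutual information between a window profile and the classification
#'
#' Computes MI(G : S) in bits between the group vector G and the window's
#' per-sample state vector S. Samples whose state is the undefined label
#' are removed first, and all frequencies (group marginal, state marginal,
#' joint) are recomputed over the retained samples only; zero-probability
#' terms of the double sum are skipped. Returns 0 when fewer than two
#' samples are retained or when either marginal is degenerate (one group
#' or one state).
#'
#' @param profile character vector of per-sample states, named by sample
#'   ID or aligned to `classification$samples`.
#' @param classification a [sample_classification()].
#' @param undefined the undefined label (default `"undefined"`).
#' @return MI in bits (non-negative scalar).
#' @examples
#' cls <- sample_classification(paste0("s", 1:8), rep(c("A", "B"), each = 4))
#' prof <- rep(c("Tx", "Quies"), each = 4)
#' mutual_information(prof, cls)  # 1 bit: perfect symmetric split
#' @export
mutual_information <- function(profile, classification,
                               undefined = "undefined") {
  profile <- .align_profile(profile, classification)
  keep <- profile != undefined & !is.na(profile)
  if (sum(keep) < 2L) return(0)
  g <- unname(classification$assignment[classification$samples])[keep]
  s <- profile[keep]
  joint <- table(g, s)
  tot <- sum(joint)
  pj <- joint / tot
  pg <- rowSums(pj)
  ps <- colSums(pj)
  cells <- which(pj > 0, arr.ind = TRUE)
  mi <- sum(vapply(seq_len(nrow(cells)), function(i) {
    r <- cells[i, 1L]; c <- cells[i, 2L]
    pj[r, c] * log2(pj[r, c] / (pg[r] * ps[c]))
  }, numeric(1)))
  max(mi, 0)
}

#' Permutation p-value for a window's MI
#'
#' Shuffles the full profile vector (undefined entries included, so the
#' vector's composition is preserved) against the fixed classification,
#' recomputing MI with the same undefined-exclusion rule for every
#' shuffle. The empirical p-value is the fraction of shuffles whose MI is
#' greater than or equal to the observed MI; with the default r / n
#' convention it can be exactly 0.
#'
#' @inheritParams mutual_information
#' @param params an [mi_params()]; `n_permutations`, `seed` and
#'   `p_add_one` are used.
#' @return A list with elements `mi` (observed, bits), `p_raw`
#'   (empirical p-value) and `n_ge` (shuffles scoring >= observed).
#' @export
permutation_pvalue <- function(profile, classification,
                               params = mi_params(),
                               undefined = "undefined") {
  profile <- .align_profile(profile, classification)
  g <- unname(classification$assignment[classification$samples])
  gi <- match(g, classification$groups)
  states <- sort(unique(profile[profile != undefined]))
  si <- match(profile, states)
  si[is.na(si)] <- 0L
  set.seed(params$seed)
  res <- cpp_perm_mi(as.integer(si), as.integer(gi),
                     n_states = max(1L, length(states)),
                     n_groups = length(classification$groups),
                     n_perm = params$n_permutations)
  p_raw <- if (params$p_add_one) {
    (res$n_ge + 1) / (res$n_perm + 1)
  } else {
    res$n_ge / res$n_perm
  }
  list(mi = res$mi, p_raw = p_raw, n_ge = res$n_ge)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment: sort p-values ascending, take
#' `adjusted_i = min_{j >= i} (p_j * N / j)` capped at 1, and return the
#' adjusted values in the original order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of BH-adjusted p-values, same order as input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

# Deterministic per-window seed derived from the master seed and the
# window's coordinates, so scans are order- and parallelisation-invariant.
window_seed <- function(seed, chrom, start) {
  cc <- utf8ToInt(as.character(chrom))
  ch <- sum(cc * seq_along(cc))
  as.integer((as.double(seed) %% 2147483647 * 48271 +
                ch * 9973 + as.double(start)) %% 2147483629)
}

#' Genome-wide mutual-information scan
#'
#' The full pipeline for one classification: enumerate windows over the
#' layout, collapse every sample's chromatin-state track per window
#' (majority rule), compute each window's MI against the classification,
#' attach a permutation p-value, and adjust p-values genome-wide across
#' all scanned windows with Benjamini-Hochberg. Windows where every sample
#' is undefined are kept (MI 0, p 1, flagged) so the multiple-testing
#' family size is stable.
#'
#' @param tracks named list of `StateTrack`s covering all classification
#'   samples.
#' @param classification a [sample_classification()].
#' @param layout a [genome_layout()].
#' @param wparams a [windowing_params()].
#' @param mparams an [mi_params()].
#' @return An object of class `mi_scan`: a list with `results` (a
#'   `data.frame` with columns chrom, start, end, mi, p_raw, p_adj,
#'   n_defined, n_states_observed, all_undefined), `profiles` (the
#'   windows x samples state matrix), `classification`, `wparams`,
#'   `mparams` and `vocab`.
#' @export
scan_windows <- function(tracks, classification, layout,
                         wparams = windowing_params(),
                         mparams = mi_params()) {
  tracks <- .name_tracks(tracks)
  windows <- make_windows(layout, wparams)
  prof <- profile_matrix(tracks, windows, wparams,
                         sample_order = classification$samples)
  vocab <- tracks[[1L]]$vocab
  undef <- vocab$undefined

  g <- unname(classification$assignment[classification$samples])
  gi <- as.integer(match(g, classification$groups))
  n_groups <- length(classification$groups)

  nw <- nrow(windows)
  mi <- numeric(nw)
  p_raw <- numeric(nw)
  n_defined <- integer(nw)
  n_states_obs <- integer(nw)
  all_undef <- logical(nw)

  for (i in seq_len(nw)) {
    row <- prof[i, ]
    def <- row != undef
    n_defined[i] <- sum(def)
    states <- sort(unique(row[def]))
    n_states_obs[i] <- length(states)
    if (n_defined[i] == 0L) {
      all_undef[i] <- TRUE
      mi[i] <- 0
      p_raw[i] <- 1
      next
    }
    si <- match(row, states)
    si[is.na(si)] <- 0L
    obs <- cpp_mi(as.integer(si), gi, n_states = max(1L, length(states)),
                  n_groups = n_groups)
    if (obs <= 0) {
      # MI is non-negative, so every shuffle scores >= an observed 0
      mi[i] <- 0
      p_raw[i] <- 1
      next
    }
    set.seed(window_seed(mparams$seed, windows$chrom[i], windows$start[i]))
    res <- cpp_perm_mi(as.integer(si), gi,
                       n_states = max(1L, length(states)),
                       n_groups = n_groups,
                       n_perm = mparams$n_permutations)
    mi[i] <- res$mi
    p_raw[i] <- if (mparams$p_add_one) {
      (res$n_ge + 1) / (res$n_perm + 1)
    } else {
      res$n_ge / res$n_perm
    }
  }

  results <- data.frame(windows, mi = mi, p_raw = p_raw,
                        p_adj = bh_adjust(p_raw),
                        n_defined = n_defined,
                        n_states_observed = n_states_obs,
                        all_undefined = all_undef,
                        stringsAsFactors = FALSE)
  structure(list(results = results, profiles = prof,
                 classification = classification, wparams = wparams,
                 mparams = mparams, vocab = vocab),
            class = "mi_scan")
}

#' @export
print.mi_scan <- function(x, ...) {
  sig <- significant_windows(x)
  cat("mi_scan: ", nrow(x$results), " windows x ",
      length(x$classification$samples), " samples; ",
      nrow(sig), " significant (MI >= ", x$mparams$mi_threshold,
      ", FDR <= ", format(x$mparams$fdr_threshold), ")\n", sep = "")
  invisible(x)
}

#' Significant windows of a scan
#'
#' Filters the scan table to windows with `mi >= mi_threshold` and
#' `p_adj <= fdr_threshold`, sorted by MI descending.
#'
#' @param scan an `mi_scan` from [scan_windows()].
#' @param mi_threshold,fdr_threshold override the scan's thresholds.
#' @return A `data.frame` subset of `scan$results` with an extra column
#'   `window_index` linking back to `scan$profiles` rows.
#' @export
significant_windows <- function(scan,
                                mi_threshold = scan$mparams$mi_threshold,
                                fdr_threshold = scan$mparams$fdr_threshold) {
  res <- scan$results
  keep <- which(res$mi >= mi_threshold & res$p_adj <= fdr_threshold)
  out <- res[keep, , drop = FALSE]
  out$window_index <- keep
  out <- out[order(-out$mi, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a scan result table and significant-window BED
#'
#' The full table is tab-separated (chrom, start, end, mi, p_raw, p_adj,
#' n_defined, n_states_observed, then one column per sample with its
#' collapsed state). The BED6 lists significant windows with
#' `score = floor(MI * 1000)` (BED score convention) and name
#' `mi_<value>`.
#'
#' @param scan an `mi_scan`.
#' @param table_path path for the full tab-separated table.
#' @param bed_path optional path for the significant-window BED6.
#' @return Invisibly, the paths written.
#' @export
write_scan <- function(scan, table_path, bed_path = NULL) {
  tab <- cbind(scan$results, as.data.frame(scan$profiles,
                                           stringsAsFactors = FALSE))
  tab$start <- as.integer(tab$start)  # avoid scientific notation
  tab$end <- as.integer(tab$end)
  utils::write.table(tab, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- table_path
  if (!is.null(bed_path)) {
    sig <- significant_windows(scan)
    bed <- data.frame(chrom = sig$chrom, start = as.integer(sig$start),
                      end = as.integer(sig$end),
                      name = sprintf("mi_%.4f", sig$mi),
                      score = pmin(1000L, as.integer(floor(sig$mi * 1000))),
                      strand = rep(".", nrow(sig)),
                      stringsAsFactors = FALSE)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, bed_path)
  }
  invisible(paths)
}
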