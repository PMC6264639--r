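#' Downsampling experiment specification
#'
#' @param fractions removal proportions in (0, 1); by default 0.2 to 0.8
#'   in steps of 0.2. A fraction of 0 (no removal) is also accepted.
#' @param replicates random removals per fraction (default 5).
#' @param keywords lowercase substrings marking "positive" terms (e.g.
#'   "brain", "neuron", "nerve", "axon").
#' @param seed master seed for the removals.
#' @return An object of class `DownsampleSpec`.
#' @export
downsample_spec <- function(fractions = seq(0.2, 0.8, by = 0.2),
                            replicates = 5,
                            keywords = c("brain", "neuron", "nerve",
                                         "axon"),
                            seed = 1) {
  if (any(fractions < 0 | fractions >= 1)) {
    stop("fractions must lie in [0, 1)", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    stop("replicates must be >= 1", call. = FALSE)
  }
  structure(list(fractions = fractions, replicates = replicates,
                 keywords = tolower(as.character(keywords)),
                 seed = as.integer(seed)),
            class = "DownsampleSpec")
}

#' Keyword-matched "positive" terms of an enrichment table
#'
#' Case-insensitive substring match of any keyword against the term
#' names. An empty keyword list matches nothing.
#'
#' @param enrichment `data.frame` from [fisher_enrichment()].
#' @param keywords character vector of substrings.
#' @return The matching subset of `enrichment`.
#' @export
positive_terms <- function(enrichment, keywords) {
  if (length(keywords) == 0L || nrow(enrichment) == 0L) {
    return(enrichment[integer(), , drop = FALSE])
  }
  nm <- tolower(enrichment$term_name)
  hit <- Reduce(`|`, lapply(tolower(keywords),
                            function(k) grepl(k, nm, fixed = TRUE)))
  enrichment[hit, , drop = FALSE]
}

# Scan + gene overlap + enrichment for one sample subset; returns the
# performance number (mean -log10 enrichment p over keyword-positive
# terms) or NA when it is undefined.
.subset_performance <- function(sample_ids, tracks, classification,
                                layout, genes, terms, wparams, mparams,
                                keywords, min_term_size) {
  groups_present <- unique(unname(classification$assignment[sample_ids]))
  if (length(groups_present) < 2L) {
    return(list(performance = NA_real_, best = NA_real_,
                n_significant = NA_integer_,
                n_groups = length(groups_present)))
  }
  sub_cls <- sample_classification(
    sample_ids, unname(classification$assignment[sample_ids]))
  scan <- scan_windows(tracks[sample_ids], sub_cls, layout,
                       wparams = wparams, mparams = mparams)
  sig <- significant_windows(scan)
  study <- overlap_genes(sig, genes)$gene_ids
  enr <- fisher_enrichment(study, genes$gene_id, terms,
                           min_term_size = min_term_size)
  pos <- positive_terms(enr, keywords)
  if (nrow(pos) == 0L) {
    return(list(performance = NA_real_, best = NA_real_,
                n_significant = nrow(sig), n_groups = length(groups_present)))
  }
  nl <- -log10(pmax(pos$p_fisher, .Machine$double.xmin))
  list(performance = mean(nl), best = max(nl), n_significant = nrow(sig),
       n_groups = length(groups_present))
}

#' Downsampling robustness experiment
#'
#' Repeatedly removes a proportion of the epigenomes uniformly at random,
#' reruns the scan, gene retrieval and GO enrichment on the remainder,
#' and scores each run as the mean over keyword-matched "positive" terms
#' of -log10 of the Fisher enrichment p-value (the best single term's
#' -log10 p is reported alongside). A replicate that loses all samples of
#' a group, or whose tested terms contain no positive term, is recorded
#' as NA and excluded from the per-fraction mean.
#'
#' @param tracks named list of `StateTrack`s.
#' @param classification a [sample_classification()].
#' @param layout a [genome_layout()].
#' @param genes gene annotation `data.frame` from [read_genes()] (the
#'   background is all its genes).
#' @param terms a [term_annotation_set()].
#' @param spec a [downsample_spec()].
#' @param wparams,mparams scan parameters.
#' @param min_term_size passed to [fisher_enrichment()].
#' @return A list: `replicates` (`data.frame` fraction, replicate,
#'   n_samples, n_groups, n_significant, performance, best) and `summary`
#'   (`data.frame` fraction, mean_performance, mean_best, n_defined).
#' @export
downsample_performance <- function(tracks, classification, layout, genes,
                                   terms, spec = downsample_spec(),
                                   wparams = windowing_params(),
                                   mparams = mi_params(),
                                   min_term_size = 1L) {
  tracks <- .name_tracks(tracks)
  samples <- classification$samples
  n <- length(samples)
  rows <- list()
  for (f in spec$fractions) {
    for (r in seq_len(spec$replicates)) {
      n_remove <- round(f * n)
      set.seed(window_seed(spec$seed,
                           sprintf("frac_%g_rep_%d", f, r), n_remove))
      keep <- if (n_remove > 0L) {
        sort(sample(samples, n - n_remove))
      } else samples
      perf <- .subset_performance(keep, tracks, classification, layout,
                                  genes, terms, wparams, mparams,
                                  spec$keywords, min_term_size)
      rows[[length(rows) + 1L]] <-
        data.frame(fraction = f, replicate = r, n_samples = length(keep),
                   n_groups = perf$n_groups,
                   n_significant = perf$n_significant,
                   performance = perf$performance, best = perf$best,
                   stringsAsFactors = FALSE)
    }
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(unique(reps$fraction), function(f) {
    sub <- reps[reps$fraction == f, , drop = FALSE]
    data.frame(fraction = f,
               mean_performance = mean(sub$performance, na.rm = TRUE),
               mean_best = mean(sub$best, na.rm = TRUE),
               n_defined = sum(!is.na(sub$performance)),
               stringsAsFactors = FALSE)
  }))
  list(replicates = reps, summary = summ)
}

#' Write a downsampling result as tab-separated tables
#'
#' @param result list from [downsample_performance()].
#' @param replicates_path,summary_path output paths.
#' @return Invisibly, the paths.
#' @export
write_downsample <- function(result, replicates_path, summary_path) {
  utils::write.table(result$replicates, replicates_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$summary, summary_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(replicates_path, summary_path))
}
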