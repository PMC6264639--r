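#' Specification of a synthetic multi-sample chromatin-state dataset
#'
#' Describes a toy genome, a set of samples in >= 2 groups, a background
#' distribution over chromatin states, and a list of planted windows in
#' which each group is pushed towards a target state with a configurable
#' association strength. Planted windows can also be scrambled into a
#' 50/50 two-state mix (guaranteeing the majority rule fails) at a
#' configurable rate, emulating undefined-state windows.
#'
#' @param layout a [genome_layout()] of toy chromosomes.
#' @param samples_per_group named integer vector: group label -> number of
#'   samples (>= 2 groups).
#' @param vocab a [state_vocabulary()].
#' @param planted_windows `data.frame` with columns `chrom`, `start`,
#'   `end`, `strength` (in \[0, 1\]) plus one column per group naming that
#'   group's target state. Starts/ends must be multiples of
#'   `segment_length` and lie within the layout.
#' @param segment_length resolution of the simulated segmentation in bp
#'   (default 200, the ChromHMM mnemonic grid).
#' @param background_probs optional named probability vector over
#'   `vocab$states` for background segments (uniform by default).
#' @param undefined_rate probability that a sample's planted window is
#'   scrambled below the majority threshold (default 0).
#' @param seed integer seed making generation deterministic.
#' @return An object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(layout, samples_per_group, vocab,
                           planted_windows, segment_length = 200,
                           background_probs = NULL, undefined_rate = 0,
                           seed = 1) {
  stopifnot(inherits(layout, "GenomeLayout"),
            inherits(vocab, "StateVocabulary"))
  if (is.null(names(samples_per_group)) || length(samples_per_group) < 2L) {
    stop("samples_per_group must be a named vector with >= 2 groups",
         call. = FALSE)
  }
  if (any(samples_per_group < 1L)) {
    stop("each group needs at least one sample", call. = FALSE)
  }
  groups <- names(samples_per_group)
  req <- c("chrom", "start", "end", "strength", groups)
  missing_cols <- setdiff(req, colnames(planted_windows))
  if (length(missing_cols)) {
    stop("planted_windows lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(planted_windows$strength < 0 | planted_windows$strength > 1)) {
    stop("association strengths must lie in [0, 1]", call. = FALSE)
  }
  lens <- stats::setNames(layout$length, layout$chrom)
  if (any(!(planted_windows$chrom %in% layout$chrom)) ||
      any(planted_windows$start < 0) ||
      any(planted_windows$end > lens[planted_windows$chrom])) {
    stop("planted windows must lie within the genome layout", call. = FALSE)
  }
  if (any(planted_windows$start %% segment_length != 0) ||
      any(planted_windows$end %% segment_length != 0)) {
    stop("planted windows must align to the segment grid", call. = FALSE)
  }
  for (g in groups) {
    bad <- setdiff(unique(planted_windows[[g]]), vocab$states)
    if (length(bad)) {
      stop("target states not in the vocabulary: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(background_probs)) {
    background_probs <- stats::setNames(
      rep(1 / length(vocab$states), length(vocab$states)), vocab$states)
  } else {
    if (!setequal(names(background_probs), vocab$states)) {
      stop("background_probs must be named by the vocabulary states",
           call. = FALSE)
    }
    if (abs(sum(background_probs) - 1) > 1e-8) {
      stop("background_probs must sum to 1", call. = FALSE)
    }
    background_probs <- background_probs[vocab$states]
  }
  if (undefined_rate < 0 || undefined_rate > 1) {
    stop("undefined_rate must lie in [0, 1]", call. = FALSE)
  }
  structure(list(layout = layout, samples_per_group = samples_per_group,
                 vocab = vocab, planted_windows = planted_windows,
                 segment_length = segment_length,
                 background_probs = background_probs,
                 undefined_rate = undefined_rate,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate a synthetic dataset with planted informative windows
#'
#' Background segments are drawn independently per sample and segment
#' from the background distribution. Inside each planted window, each
#' sample of group g receives the group's target state (all segments of
#' the window) with probability equal to the window's association
#' strength, and a random other state otherwise; with probability
#' `undefined_rate` the window is instead filled with an alternating
#' 50/50 mix of two states so that no state reaches the 80% majority.
#' Generation is deterministic given the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return A list: `tracks` (named list of `StateTrack`s),
#'   `classification` (a [sample_classification()]) and `truth` (the
#'   planted-window `data.frame`).
#' @export
simulate_tracks <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  groups <- names(spec$samples_per_group)
  sample_ids <- unlist(lapply(groups, function(g) {
    sprintf("%s_%02d", g, seq_len(spec$samples_per_group[[g]]))
  }))
  sample_groups <- rep(groups, times = spec$samples_per_group)
  cls <- sample_classification(sample_ids, sample_groups)
  seg <- spec$segment_length
  states <- spec$vocab$states
  planted <- spec$planted_windows

  tracks <- vector("list", length(sample_ids))
  names(tracks) <- sample_ids
  for (si in seq_along(sample_ids)) {
    grp <- sample_groups[si]
    chrom_v <- character(); start_v <- numeric(); state_v <- character()
    for (ci in seq_len(nrow(spec$layout))) {
      chrom <- spec$layout$chrom[ci]
      n_seg <- floor(spec$layout$length[ci] / seg)
      if (n_seg == 0L) next
      seg_states <- sample(states, n_seg, replace = TRUE,
                           prob = spec$background_probs)
      pw <- planted[planted$chrom == chrom, , drop = FALSE]
      for (pi in seq_len(nrow(pw))) {
        idx <- seq(pw$start[pi] / seg + 1L, pw$end[pi] / seg)
        target <- pw[[grp]][pi]
        if (stats::runif(1) < spec$undefined_rate) {
          other <- if (length(states) > 1L) {
            sample(setdiff(states, target), 1L)
          } else target
          seg_states[idx] <- rep(c(target, other), length.out = length(idx))
        } else if (stats::runif(1) < pw$strength[pi]) {
          seg_states[idx] <- target
        } else {
          alt <- if (length(states) > 1L) {
            sample(setdiff(states, target), 1L)
          } else target
          seg_states[idx] <- alt
        }
      }
      chrom_v <- c(chrom_v, rep(chrom, n_seg))
      start_v <- c(start_v, seq(0, by = seg, length.out = n_seg))
      state_v <- c(state_v, seg_states)
    }
    tracks[[si]] <- state_track(sample_ids[si], chrom_v, start_v,
                                start_v + seg, state_v, spec$vocab)
  }
  list(tracks = tracks, classification = cls, truth = planted)
}

#' Generate a matching synthetic gene and term annotation
#'
#' Creates one gene spanning each planted window plus background genes in
#' non-planted regions, a "positive" functional term containing exactly
#' the planted genes (its name carries a recognisable keyword), and a few
#' background terms with random background genes, so the gene-retrieval,
#' enrichment and downsampling modules can be exercised end-to-end with
#' known truth.
#'
#' @param spec a [synthetic_spec()].
#' @param n_background_genes number of background genes (default 30).
#' @param n_background_terms number of background terms (default 5).
#' @param genes_per_term genes drawn per background term (default 8).
#' @param positive_name name of the positive term; include the keyword
#'   your evaluation matches on (default mentions "neuron").
#' @return A list: `genes` (annotation `data.frame`), `terms` (a
#'   [term_annotation_set()]) and `positive_term_id`.
#' @export
simulate_annotation <- function(spec, n_background_genes = 30,
                                n_background_terms = 5,
                                genes_per_term = 8,
                                positive_name =
                                  "synthetic neuron differentiation") {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed + 7L)
  planted <- spec$planted_windows
  pg <- data.frame(gene_id = sprintf("PGENE_%02d", seq_len(nrow(planted))),
                   symbol = sprintf("PGENE_%02d", seq_len(nrow(planted))),
                   chrom = planted$chrom, start = planted$start,
                   end = planted$end, strand = "+",
                   stringsAsFactors = FALSE)
  # background genes: tile non-planted cells of the planted windows' grid
  cell <- max(planted$end - planted$start)
  cells <- make_windows(spec$layout,
                        windowing_params(window_length = max(cell, 200),
                                         step = max(cell, 200)))
  key <- function(d) paste(d$chrom, d$start, sep = ":")
  free <- cells[!(key(cells) %in% key(planted)), , drop = FALSE]
  take <- free[seq(1L, nrow(free),
                   length.out = min(n_background_genes, nrow(free))), ,
               drop = FALSE]
  bg <- data.frame(gene_id = sprintf("BGENE_%02d", seq_len(nrow(take))),
                   symbol = sprintf("BGENE_%02d", seq_len(nrow(take))),
                   chrom = take$chrom, start = take$start, end = take$end,
                   strand = "+", stringsAsFactors = FALSE)
  genes <- rbind(pg, bg)
  rownames(genes) <- NULL

  pos_id <- "GO:SYN0001"
  term_ids <- c(pos_id,
                sprintf("GO:SYNB%03d", seq_len(n_background_terms)))
  term_names <- c(positive_name,
                  sprintf("synthetic background process %d",
                          seq_len(n_background_terms)))
  genes_by_term <- c(list(pg$gene_id),
                     lapply(seq_len(n_background_terms), function(i) {
                       sample(bg$gene_id,
                              min(genes_per_term, nrow(bg)))
                     }))
  names(genes_by_term) <- term_ids
  terms <- term_annotation_set(
    data.frame(term_id = term_ids, term_name = term_names,
               namespace = "BP", stringsAsFactors = FALSE),
    genes_by_term)
  list(genes = genes, terms = terms, positive_term_id = pos_id)
}

#' Write a synthetic dataset to a directory
#'
#' Writes one mnemonic BED per sample (under `tracks/`), the
#' classification table, a chrom.sizes file, the planted-window truth
#' table and, when an annotation is supplied, a GFF3 of the synthetic
#' genes and a gene-to-term table. All files are plain text.
#'
#' @param sim list from [simulate_tracks()].
#' @param dir output directory (created if needed).
#' @param annotation optional list from [simulate_annotation()].
#' @return Invisibly, the directory.
#' @export
write_dataset <- function(sim, dir, annotation = NULL) {
  dir.create(file.path(dir, "tracks"), recursive = TRUE,
             showWarnings = FALSE)
  for (sid in names(sim$tracks)) {
    write_state_bed(sim$tracks[[sid]],
                    file.path(dir, "tracks", paste0(sid, ".bed")))
  }
  utils::write.table(
    data.frame(sample = sim$classification$samples,
               group = unname(sim$classification$assignment)),
    file.path(dir, "classification.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  layout <- genome_layout(
    unique(sim$tracks[[1L]]$intervals$chrom),
    vapply(unique(sim$tracks[[1L]]$intervals$chrom), function(ch) {
      max(sim$tracks[[1L]]$intervals$end[
        sim$tracks[[1L]]$intervals$chrom == ch])
    }, numeric(1)))
  write_chrom_sizes(layout, file.path(dir, "chrom.sizes"))
  truth <- sim$truth
  truth$start <- as.integer(truth$start)
  truth$end <- as.integer(truth$end)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(annotation)) {
    g <- annotation$genes
    gff <- data.frame(g$chrom, "chromMI_synthetic", "gene",
                      as.integer(g$start + 1), as.integer(g$end),
                      ".", g$strand, ".",
                      sprintf("ID=%s;Name=%s", g$gene_id, g$symbol),
                      stringsAsFactors = FALSE)
    writeLines(c("##gff-version 3",
                 do.call(paste, c(gff, sep = "\t"))),
               file.path(dir, "genes.gff3"))
    rows <- do.call(rbind, lapply(annotation$terms$terms$term_id,
                                  function(tid) {
      i <- match(tid, annotation$terms$terms$term_id)
      data.frame(gene = annotation$terms$genes[[tid]], term = tid,
                 name = annotation$terms$terms$term_name[i],
                 namespace = annotation$terms$terms$namespace[i],
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(rows, file.path(dir, "gene2term.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(dir)
}

#' Score a scan against the planted truth
#'
#' A planted window counts as recovered when it survives the scan's
#' MI/FDR filter; any surviving non-planted window is a false positive.
#'
#' @param scan an `mi_scan` from [scan_windows()].
#' @param truth planted-window `data.frame` (chrom, start, end).
#' @return A list: `sensitivity`, `specificity`, `tp`, `fp`, `fn`, `tn`,
#'   `n_planted`, `n_background`, and `planted_ranks` (ranks of the
#'   planted windows when all windows are sorted by MI descending).
#' @export
truth_eval <- function(scan, truth) {
  res <- scan$results
  sig <- significant_windows(scan)
  key <- function(d) paste(d$chrom, d$start, d$end, sep = ":")
  planted <- key(truth)
  sig_keys <- key(sig)
  all_keys <- key(res)
  tp <- sum(planted %in% sig_keys)
  fn <- length(planted) - tp
  fp <- sum(!(sig_keys %in% planted))
  n_bg <- sum(!(all_keys %in% planted))
  tn <- n_bg - fp
  ranks <- rank(-res$mi, ties.method = "min")[all_keys %in% planted]
  list(sensitivity = if (length(planted)) tp / length(planted) else NA,
       specificity = if (n_bg) tn / n_bg else NA,
       tp = tp, fp = fp, fn = fn, tn = tn,
       n_planted = length(planted), n_background = n_bg,
       planted_ranks = sort(ranks))
}
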