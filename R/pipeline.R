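#' Run configuration
#'
#' Flat key/value configuration tying file paths and parameters together
#' for the command-style entry points. Unknown keys are rejected so typos
#' fail early.
#'
#' @param states_dir directory of per-sample mnemonic BED files (one
#'   `<sample>.bed[.gz]` per classification sample).
#' @param classification_file two-column sample/group table.
#' @param chrom_sizes chrom.sizes file defining the genome layout.
#' @param vocab_file optional one-column vocabulary file; the Roadmap
#'   15-state vocabulary is used when omitted.
#' @param reduction_file optional two-column state-reduction map applied
#'   to every track before scanning.
#' @param genes_file optional gene annotation (GFF3/GTF/BED).
#' @param gene2term_file optional gene-to-term table.
#' @param window,step,min_fraction windowing parameters.
#' @param permutations,mi_min,fdr_max,seed MI-scan parameters.
#' @param out_dir output directory.
#' @return An object of class `RunConfig` (a named list).
#' @export
run_config <- function(states_dir, classification_file, chrom_sizes,
                       vocab_file = NULL, reduction_file = NULL,
                       genes_file = NULL, gene2term_file = NULL,
                       window = 5000, step = window, min_fraction = 0.8,
                       permutations = 10000, mi_min = 0.3,
                       fdr_max = 1e-4, seed = 1, out_dir = ".") {
  structure(list(states_dir = states_dir,
                 classification_file = classification_file,
                 chrom_sizes = chrom_sizes, vocab_file = vocab_file,
                 reduction_file = reduction_file, genes_file = genes_file,
                 gene2term_file = gene2term_file,
                 window = as.numeric(window), step = as.numeric(step),
                 min_fraction = as.numeric(min_fraction),
                 permutations = as.integer(permutations),
                 mi_min = as.numeric(mi_min),
                 fdr_max = as.numeric(fdr_max), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "RunConfig")
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments and
#' blank lines ignored. Keys match the arguments of [run_config()].
#'
#' @param path file path.
#' @param ... overrides applied after the file is read.
#' @return A `RunConfig`.
#' @export
read_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*[=:]\\s*(.*)$",
                                  lines))
  args <- stats::setNames(lapply(kv, function(m) trimws(m[3L])),
                          vapply(kv, function(m) m[2L], character(1)))
  overrides <- list(...)
  args[names(overrides)] <- overrides
  bad <- setdiff(names(args), names(formals(run_config)))
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, args)
}

.load_inputs <- function(config) {
  for (f in c("classification_file", "chrom_sizes")) {
    if (!file.exists(config[[f]])) {
      stop("file not found: ", config[[f]], call. = FALSE)
    }
  }
  vocab <- if (is.null(config$vocab_file)) roadmap15_vocabulary()
           else load_vocabulary(config$vocab_file)
  cls <- read_classification(config$classification_file)
  layout <- read_chrom_sizes(config$chrom_sizes)
  tracks <- lapply(cls$samples, function(sid) {
    cand <- file.path(config$states_dir,
                      c(paste0(sid, ".bed"), paste0(sid, ".bed.gz")))
    hit <- cand[file.exists(cand)]
    if (!length(hit)) {
      stop("no state BED found for sample '", sid, "' in ",
           config$states_dir, call. = FALSE)
    }
    read_state_bed(hit[1L], vocab, sample_id = sid)
  })
  names(tracks) <- cls$samples
  if (!is.null(config$reduction_file)) {
    red <- load_reduction(config$reduction_file, vocab)
    tracks <- lapply(tracks, reduce_track, reduction = red)
    vocab <- red$target_vocab
  }
  list(tracks = tracks, classification = cls, layout = layout,
       vocab = vocab)
}

.write_manifest <- function(config, outputs, path) {
  inputs <- c(config$classification_file, config$chrom_sizes,
              config$vocab_file, config$reduction_file, config$genes_file,
              config$gene2term_file)
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  lines <- c(
    sprintf("chromMI_version = %s",
            as.character(utils::packageVersion("chromMI"))),
    vapply(setdiff(names(unclass(config)), "out_dir"), function(k) {
      v <- config[[k]]
      sprintf("param.%s = %s", k, if (is.null(v)) "" else as.character(v))
    }, character(1)),
    vapply(unlist(inputs), function(f) {
      sprintf("input.%s = md5:%s", basename(f), unname(tools::md5sum(f)))
    }, character(1)),
    vapply(outputs, function(f) {
      sprintf("output.%s = md5:%s", basename(f), unname(tools::md5sum(f)))
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full scan pipeline from a configuration
#'
#' Reads the state tracks, classification and layout, applies an optional
#' vocabulary reduction, runs [scan_windows()], and writes the scan table,
#' the significant-window BED6, the pattern-distribution table and a run
#' manifest (parameters plus input/output checksums) into the output
#' directory. On error, partially written outputs are removed.
#'
#' @param config a [run_config()].
#' @return Invisibly, the `mi_scan` object.
#' @export
run_scan <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- file.path(config$out_dir,
                       c("scan.tsv", "significant.bed", "patterns.tsv",
                         "manifest.txt"))
  on_fail <- function(e) {
    unlink(outputs)
    stop(e)
  }
  scan <- tryCatch({
    inp <- .load_inputs(config)
    wp <- windowing_params(config$window, config$step,
                           config$min_fraction)
    mp <- mi_params(config$permutations, config$seed, config$mi_min,
                    config$fdr_max)
    scan <- scan_windows(inp$tracks, inp$classification, inp$layout,
                         wparams = wp, mparams = mp)
    write_scan(scan, outputs[1L], outputs[2L])
    summ <- pattern_summaries(scan)
    dist <- pattern_distribution(summ, inp$classification$groups,
                                 undefined = inp$vocab$undefined)
    utils::write.table(dist, outputs[3L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    .write_manifest(config, outputs[1:3], outputs[4L])
    scan
  }, error = on_fail)
  invisible(scan)
}

#' Run gene retrieval and term enrichment from a configuration
#'
#' Overlaps a set of significant windows with the configured gene
#' annotation, tests term enrichment against the whole annotation as
#' background, and writes the gene list, per-gene window counts and the
#' enrichment table.
#'
#' @param config a [run_config()] with `genes_file` and `gene2term_file`
#'   set.
#' @param windows `data.frame` of significant windows (chrom, start,
#'   end), e.g. from [significant_windows()] or read back from the scan
#'   BED.
#' @param min_term_size passed to [fisher_enrichment()].
#' @return Invisibly, the enrichment `data.frame`.
#' @export
run_enrich <- function(config, windows, min_term_size = 1L) {
  if (is.null(config$genes_file) || is.null(config$gene2term_file)) {
    stop("run_enrich needs genes_file and gene2term_file", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  genes <- read_genes(config$genes_file)
  terms <- read_gene2term(config$gene2term_file)
  ov <- overlap_genes(windows, genes)
  if (length(ov$gene_ids) == 0L) {
    warning("no genes overlap the supplied windows; empty enrichment")
  }
  enr <- fisher_enrichment(ov$gene_ids, genes$gene_id, terms,
                           min_term_size = min_term_size)
  utils::write.table(ov$per_gene,
                     file.path(config$out_dir, "genes_per_window.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(enr, file.path(config$out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(enr)
}
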