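#' Chromatin-state segmentation track for one sample
#'
#' A `StateTrack` holds one sample's chromatin-state segmentation as a set
#' of labelled genomic intervals in BED convention (0-based, half-open).
#' Per chromosome the intervals are sorted and non-overlapping; every label
#' belongs to the track's vocabulary. Adjacent intervals sharing a state
#' are kept as given (never merged), mirroring the 200 bp resolution of
#' ChromHMM mnemonic files.
#'
#' @param sample_id sample identifier.
#' @param chrom,start,end,state parallel vectors describing the intervals.
#' @param vocab `StateVocabulary` the labels must belong to.
#' @return An object of class `StateTrack` with fields `sample_id`,
#'   `intervals` (a `data.frame` with columns chrom, start, end, state) and
#'   `vocab`.
#' @export
state_track <- function(sample_id, chrom, start, end, state, vocab) {
  stopifnot(inherits(vocab, "StateVocabulary"))
  n <- length(chrom)
  if (length(start) != n || length(end) != n || length(state) != n) {
    stop("chrom, start, end and state must have equal length", call. = FALSE)
  }
  ints <- data.frame(chrom = as.character(chrom),
                     start = as.numeric(start),
                     end = as.numeric(end),
                     state = as.character(state),
                     stringsAsFactors = FALSE)
  if (n > 0L) {
    if (anyNA(ints$start) || anyNA(ints$end) ||
        any(ints$start != floor(ints$start)) ||
        any(ints$end != floor(ints$end)) || any(ints$start < 0)) {
      stop("malformed coordinates: starts/ends must be non-negative integers",
           call. = FALSE)
    }
    bad <- which(ints$start >= ints$end)
    if (length(bad)) {
      stop("interval with start >= end at row ", bad[1L], call. = FALSE)
    }
    unknown <- which(!(ints$state %in% vocab$states))
    if (length(unknown)) {
      stop("unknown state '", ints$state[unknown[1L]], "' at row ",
           unknown[1L], " (vocabulary '", vocab$name, "')", call. = FALSE)
    }
    ord <- order(ints$chrom, ints$start, ints$end)
    ints <- ints[ord, , drop = FALSE]
    rownames(ints) <- NULL
    same_chrom <- ints$chrom[-1L] == ints$chrom[-n]
    if (n > 1L && any(same_chrom & ints$start[-1L] < ints$end[-n])) {
      i <- which(same_chrom & ints$start[-1L] < ints$end[-n])[1L]
      stop("overlapping intervals on ", ints$chrom[i], " near position ",
           ints$start[i + 1L], call. = FALSE)
    }
  }
  structure(list(sample_id = as.character(sample_id), intervals = ints,
                 vocab = vocab),
            class = "StateTrack")
}

#' @export
print.StateTrack <- function(x, ...) {
  cat("StateTrack '", x$sample_id, "': ", nrow(x$intervals),
      " intervals on ", length(unique(x$intervals$chrom)),
      " chromosome(s), vocabulary '", x$vocab$name, "'\n", sep = "")
  invisible(x)
}

#' Read a chromatin-state mnemonic BED file
#'
#' Parses a tab-separated BED file whose fourth column carries a
#' chromatin-state label (ChromHMM mnemonic style). Coordinates follow the
#' BED standard (0-based half-open). Gzip-compressed input is accepted.
#' Rows are validated against the vocabulary; unknown labels, malformed
#' coordinates and overlapping intervals are errors. Adjacent rows with the
#' same state are preserved as given.
#'
#' @param path path to a BED file (optionally `.gz`).
#' @param vocab `StateVocabulary` of admissible labels.
#' @param sample_id sample identifier; defaults to the file name without
#'   its BED/gz extensions.
#' @return A [state_track()] object.
#' @export
read_state_bed <- function(path, vocab,
                           sample_id = sub("\\.bed(\\.gz)?$", "",
                                           basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  empty <- state_track(sample_id, character(), numeric(), numeric(),
                       character(), vocab)
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    lines <- readLines(con)
    if (length(lines) == 0L) return(empty)
    dt <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                            colClasses = list(character = 1L),
                            showProgress = FALSE, data.table = TRUE)
  } else {
    if (file.size(path) == 0L) return(empty)
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            colClasses = list(character = 1L),
                            showProgress = FALSE, data.table = TRUE)
  }
  if (nrow(dt) == 0L) return(empty)
  if (ncol(dt) < 4L) {
    stop("BED file needs at least 4 columns (chrom, start, end, state): ",
         path, call. = FALSE)
  }
  start <- suppressWarnings(as.numeric(dt[[2L]]))
  end <- suppressWarnings(as.numeric(dt[[3L]]))
  if (anyNA(start) || anyNA(end)) {
    line <- which(is.na(start) | is.na(end))[1L]
    stop("malformed coordinates at line ", line, " of ", path, call. = FALSE)
  }
  st <- as.character(dt[[4L]])
  unknown <- which(!(st %in% vocab$states))
  if (length(unknown)) {
    stop("unknown state '", st[unknown[1L]], "' at line ", unknown[1L],
         " of ", path, call. = FALSE)
  }
  state_track(sample_id, as.character(dt[[1L]]), start, end, st, vocab)
}

#' Write a StateTrack as a mnemonic BED4 file
#'
#' Tab-separated chrom/start/end/state, no header. Reading the file back
#' with [read_state_bed()] reproduces the track.
#'
#' @param track a `StateTrack`.
#' @param path output path (plain text).
#' @return Invisibly, `path`.
#' @export
write_state_bed <- function(track, path) {
  stopifnot(inherits(track, "StateTrack"))
  ints <- track$intervals
  ints$start <- as.integer(ints$start)  # avoid scientific notation
  ints$end <- as.integer(ints$end)
  data.table::fwrite(ints, path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Apply a state-vocabulary reduction to a track
#'
#' Coordinates are unchanged; each state label is replaced by its target
#' under the reduction map and the result is validated against the target
#' vocabulary.
#'
#' @param track a `StateTrack` whose states belong to
#'   `reduction$source_vocab`.
#' @param reduction a [state_reduction()].
#' @return A `StateTrack` over the target vocabulary.
#' @export
reduce_track <- function(track, reduction) {
  stopifnot(inherits(track, "StateTrack"),
            inherits(reduction, "StateReduction"))
  unmapped <- setdiff(unique(track$intervals$state), names(reduction$mapping))
  if (length(unmapped)) {
    stop("track states not covered by the reduction: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  state_track(track$sample_id, track$intervals$chrom, track$intervals$start,
              track$intervals$end,
              unname(reduction$mapping[track$intervals$state]),
              reduction$target_vocab)
}

#' Genome layout (chromosome names and lengths)
#'
#' @param chrom chromosome names (unique).
#' @param length chromosome lengths in bp (> 0).
#' @return An object of class `GenomeLayout`: a `data.frame` with columns
#'   `chrom` and `length`.
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("duplicate chromosome names", call. = FALSE)
  if (anyNA(length) || any(length <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  structure(data.frame(chrom = chrom, length = length,
                       stringsAsFactors = FALSE),
            class = c("GenomeLayout", "data.frame"))
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two tab/whitespace-separated columns: chromosome name and length in bp.
#'
#' @param path file path.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  genome_layout(tab$chrom, tab$length)
}

#' Write a GenomeLayout as a chrom.sizes file
#' @param layout a `GenomeLayout`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_chrom_sizes <- function(layout, path) {
  tab <- data.frame(chrom = layout$chrom,
                    length = format(layout$length, scientific = FALSE,
                                    trim = TRUE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample-classification table
#'
#' Two tab-separated columns, `sample_id` and `group`, no header.
#'
#' @param path file path.
#' @return A [sample_classification()].
#' @export
read_classification <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("sample_id", "group"),
                           colClasses = "character")
  sample_classification(tab$sample_id, tab$group)
}
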