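#' Chromatin-state vocabulary
#'
#' A vocabulary is the ordered set of chromatin-state labels a segmentation
#' may use (e.g. the 15 ChromHMM mnemonics of the Roadmap consolidated
#' epigenomes), plus a reserved label for windows where no state reaches the
#' majority threshold. The reserved label is never itself a member of the
#' vocabulary.
#'
#' @param states character vector of unique, non-empty state labels.
#' @param name identifier for the vocabulary.
#' @param undefined reserved label assigned when no state dominates a
#'   window; must not collide with any member of `states`.
#' @return An object of class `StateVocabulary`.
#' @examples
#' vocab <- state_vocabulary(c("active", "inactive"), name = "binary")
#' vocab$states
#' @export
state_vocabulary <- function(states, name = "custom", undefined = "undefined") {
  states <- as.character(states)
  if (length(states) < 1L) {
    stop("a vocabulary needs at least one state", call. = FALSE)
  }
  if (anyNA(states) || any(!nzchar(states))) {
    stop("state labels must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(states)) {
    stop("duplicate state labels: ",
         paste(unique(states[duplicated(states)]), collapse = ", "),
         call. = FALSE)
  }
  if (undefined %in% states) {
    stop("the reserved undefined label ('", undefined,
         "') must not be a vocabulary state", call. = FALSE)
  }
  structure(list(name = name, states = states, undefined = undefined),
            class = "StateVocabulary")
}

#' @export
print.StateVocabulary <- function(x, ...) {
  cat("StateVocabulary '", x$name, "': ", length(x$states), " states (",
      paste(x$states, collapse = ", "), "); undefined = '", x$undefined,
      "'\n", sep = "")
  invisible(x)
}

#' The Roadmap Epigenomics 15-state ChromHMM vocabulary
#'
#' Mnemonics of the consolidated-epigenome 15-state core model
#' (TssA ... Quies), in their conventional order.
#'
#' @param undefined reserved undefined label.
#' @return A `StateVocabulary` with 15 states.
#' @export
roadmap15_vocabulary <- function(undefined = "undefined") {
  state_vocabulary(
    c("TssA", "TssAFlnk", "TxFlnk", "Tx", "TxWk", "EnhG", "Enh", "ZNF/Rpts",
      "Het", "TssBiv", "BivFlnk", "EnhBiv", "ReprPC", "ReprPCWk", "Quies"),
    name = "roadmap15", undefined = undefined)
}

#' State-vocabulary reduction
#'
#' A total map from every state of a source vocabulary to a state of a
#' (usually smaller) target vocabulary, e.g. collapsing the 15 Roadmap
#' mnemonics to 5 functional classes or to a binary active/inactive scheme.
#'
#' @param source_vocab,target_vocab `StateVocabulary` objects.
#' @param mapping named character vector: `names(mapping)` are source
#'   states, values are target states. Must cover every source state
#'   exactly once.
#' @return An object of class `StateReduction`.
#' @export
state_reduction <- function(source_vocab, target_vocab, mapping) {
  stopifnot(inherits(source_vocab, "StateVocabulary"),
            inherits(target_vocab, "StateVocabulary"))
  mapping <- vapply(mapping, as.character, character(1))
  src <- names(mapping)
  if (is.null(src) || anyNA(src) || any(!nzchar(src))) {
    stop("mapping must be a named character vector (source -> target)",
         call. = FALSE)
  }
  dup <- unique(src[duplicated(src)])
  if (length(dup)) {
    conflicting <- dup[vapply(dup, function(s)
      length(unique(mapping[src == s])) > 1L, logical(1))]
    if (length(conflicting)) {
      stop("conflicting targets for source states: ",
           paste(conflicting, collapse = ", "), call. = FALSE)
    }
    mapping <- mapping[!duplicated(src)]
    src <- names(mapping)
  }
  missing_src <- setdiff(source_vocab$states, src)
  if (length(missing_src)) {
    stop("uncovered states: ", paste(missing_src, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(src, source_vocab$states)
  if (length(extra)) {
    stop("mapping covers states absent from the source vocabulary: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  bad_tgt <- setdiff(unique(mapping), target_vocab$states)
  if (length(bad_tgt)) {
    stop("mapping targets not in the target vocabulary: ",
         paste(bad_tgt, collapse = ", "), call. = FALSE)
  }
  structure(list(source_vocab = source_vocab, target_vocab = target_vocab,
                 mapping = mapping[source_vocab$states]),
            class = "StateReduction")
}

#' @export
print.StateReduction <- function(x, ...) {
  cat("StateReduction ", x$source_vocab$name, " (",
      length(x$source_vocab$states), " states) -> ", x$target_vocab$name,
      " (", length(x$target_vocab$states), " states)\n", sep = "")
  invisible(x)
}

#' Read a vocabulary from a one-column text file
#'
#' One state label per line, in order; lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param name,undefined passed to [state_vocabulary()].
#' @return A `StateVocabulary`.
#' @export
load_vocabulary <- function(path, name = basename(path),
                            undefined = "undefined") {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  state_vocabulary(lines, name = name, undefined = undefined)
}

#' Read a state reduction from a two-column text file
#'
#' Tab- or whitespace-separated `source_state  target_state` rows; lines
#' starting with `#` are ignored. The map must cover every state of
#' `source_vocab`. If `target_vocab` is omitted it is constructed from the
#' distinct targets in order of first appearance.
#'
#' @param path file path.
#' @param source_vocab `StateVocabulary` the map must cover.
#' @param target_vocab optional target `StateVocabulary`.
#' @param name name for a constructed target vocabulary.
#' @return A `StateReduction`.
#' @export
load_reduction <- function(path, source_vocab, target_vocab = NULL,
                           name = basename(path)) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           comment.char = "#",
                           col.names = c("source", "target"),
                           colClasses = "character")
  if (is.null(target_vocab)) {
    target_vocab <- state_vocabulary(unique(tab$target), name = name,
                                     undefined = source_vocab$undefined)
  }
  mapping <- stats::setNames(tab$target, tab$source)
  state_reduction(source_vocab, target_vocab, mapping)
}

#' Bundled default reductions of the Roadmap 15-state vocabulary
#'
#' Returns the reduction shipped with the package collapsing the 15
#' Roadmap mnemonics to 5 functional classes (TSS, transcription, enhancer,
#' bivalent, heterochromatin) or to 2 (active vs. inactive). These default
#' groupings are editable text files under `inst/extdata/` and are
#' documented approximations of commonly used schemes, not a canonical
#' standard.
#'
#' @param n 5 or 2: number of target states.
#' @return A `StateReduction` from the Roadmap 15-state vocabulary.
#' @export
roadmap_reduction <- function(n = 5) {
  n <- as.integer(n)
  if (!n %in% c(5L, 2L)) stop("only 5- and 2-state defaults are bundled",
                              call. = FALSE)
  f <- system.file("extdata",
                   sprintf("roadmap15_to_%d.tsv", n),
                   package = "chromMI", mustWork = TRUE)
  load_reduction(f, roadmap15_vocabulary(),
                 name = sprintf("roadmap%d", n))
}

#' Compose two reductions
#'
#' Build the reduction equivalent to applying `first` then `second`
#' (e.g. 15 to 5 to 2 states).
#'
#' @param first,second `StateReduction` objects with
#'   `first$target_vocab` equal to `second$source_vocab` (same state set).
#' @return A `StateReduction` from `first$source_vocab` to
#'   `second$target_vocab`.
#' @export
compose_reductions <- function(first, second) {
  stopifnot(inherits(first, "StateReduction"),
            inherits(second, "StateReduction"))
  if (!setequal(first$target_vocab$states, second$source_vocab$states)) {
    stop("target vocabulary of `first` does not match source of `second`",
         call. = FALSE)
  }
  state_reduction(first$source_vocab, second$target_vocab,
                  stats::setNames(unname(second$mapping[first$mapping]),
                                  names(first$mapping)))
}
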