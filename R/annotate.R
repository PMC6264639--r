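#' Read a gene annotation
#'
#' Reads gene intervals from GFF3/GTF (rows of type `gene` only) or BED.
#' GFF/GTF 1-based coordinates are converted to the package's internal
#' BED convention (0-based half-open); BED input is taken as is.
#'
#' @param path annotation file.
#' @param format `"gff3"`, `"gtf"` or `"bed"`; guessed from the file
#'   extension by default.
#' @return A `data.frame` with columns `gene_id`, `symbol`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
read_genes <- function(path, format = c("auto", "gff3", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, gff = "gff3", gff3 = "gff3", gtf = "gtf",
                     bed = "bed",
                     stop("cannot guess annotation format from '", path,
                          "'", call. = FALSE))
  }
  if (format == "bed") {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            showProgress = FALSE)
    if (ncol(dt) < 4L) stop("gene BED needs >= 4 columns", call. = FALSE)
    out <- data.frame(gene_id = as.character(dt[[4L]]),
                      symbol = as.character(dt[[4L]]),
                      chrom = as.character(dt[[1L]]),
                      start = as.numeric(dt[[2L]]),
                      end = as.numeric(dt[[3L]]),
                      strand = if (ncol(dt) >= 6L) as.character(dt[[6L]])
                               else "*",
                      stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = ifelse(format == "gtf",
                                                    "gtf", "gff3"))
    md <- S4Vectors::mcols(gr)
    if ("type" %in% colnames(md)) {
      gr <- gr[as.character(md$type) == "gene"]
      md <- S4Vectors::mcols(gr)
    }
    if (length(gr) == 0L) stop("no gene rows in ", path, call. = FALSE)
    ids <- if ("gene_id" %in% colnames(md)) as.character(md$gene_id)
           else if ("ID" %in% colnames(md)) as.character(md$ID)
           else as.character(seq_along(gr))
    sym <- if ("gene_name" %in% colnames(md)) as.character(md$gene_name)
           else if ("Name" %in% colnames(md)) as.character(md$Name)
           else ids
    out <- data.frame(gene_id = ids, symbol = sym,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1,
                      end = as.numeric(GenomicRanges::end(gr)),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
  }
  bad <- which(out$start >= out$end)
  if (length(bad)) stop("gene with start >= end at row ", bad[1L],
                        call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Genes overlapping a set of windows
#'
#' A gene is retrieved when its interval intersects a window by at least
#' 1 bp, strand-agnostic (half-open abutment is not an overlap). Also
#' returns, per gene, the number of overlapping windows — the
#' "concentration" of informative windows in a gene — and the gene list
#' per window.
#'
#' @param windows `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param genes `data.frame` from [read_genes()].
#' @return A list: `gene_ids` (sorted unique IDs), `per_window` (list of
#'   gene-ID vectors, one per window row), `per_gene` (`data.frame` of
#'   gene_id, symbol, n_windows sorted by n_windows descending).
#' @export
overlap_genes <- function(windows, genes) {
  nw <- nrow(windows)
  per_window <- rep(list(character()), nw)
  if (nw == 0L || nrow(genes) == 0L) {
    return(list(gene_ids = character(), per_window = per_window,
                per_gene = data.frame(gene_id = character(),
                                      symbol = character(),
                                      n_windows = integer(),
                                      stringsAsFactors = FALSE)))
  }
  wgr <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start + 1,
                                                 windows$end))
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start + 1,
                                                 genes$end))
  hits <- GenomicRanges::findOverlaps(wgr, ggr)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  if (length(hits)) {
    per_window[seq_len(nw)] <- split(genes$gene_id[s],
                                     factor(q, levels = seq_len(nw)))
  }
  cnt <- table(factor(genes$gene_id[s], levels = unique(genes$gene_id)))
  cnt <- cnt[cnt > 0L]
  per_gene <- data.frame(gene_id = names(cnt),
                         symbol = genes$symbol[match(names(cnt),
                                                     genes$gene_id)],
                         n_windows = as.integer(cnt),
                         stringsAsFactors = FALSE)
  per_gene <- per_gene[order(-per_gene$n_windows, per_gene$gene_id), ,
                       drop = FALSE]
  rownames(per_gene) <- NULL
  list(gene_ids = sort(unique(genes$gene_id[s])),
       per_window = per_window, per_gene = per_gene)
}

#' Term annotation set
#'
#' Container for gene -> functional-term annotations (e.g. Gene Ontology).
#'
#' @param term_info `data.frame` with columns `term_id`, `term_name`,
#'   `namespace` (e.g. BP/CC/MF).
#' @param genes_by_term named list (term_id -> character vector of gene
#'   IDs).
#' @return An object of class `TermAnnotationSet`.
#' @export
term_annotation_set <- function(term_info, genes_by_term) {
  stopifnot(all(c("term_id", "term_name", "namespace") %in%
                  colnames(term_info)))
  missing <- setdiff(term_info$term_id, names(genes_by_term))
  if (length(missing)) {
    stop("terms without gene sets: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  genes_by_term <- lapply(genes_by_term, function(g) unique(as.character(g)))
  structure(list(terms = term_info[, c("term_id", "term_name", "namespace")],
                 genes = genes_by_term[term_info$term_id]),
            class = "TermAnnotationSet")
}

#' @export
print.TermAnnotationSet <- function(x, ...) {
  cat("TermAnnotationSet: ", nrow(x$terms), " terms, ",
      length(unique(unlist(x$genes))), " genes\n", sep = "")
  invisible(x)
}

#' Read a gene-to-term table
#'
#' Tab-separated columns `gene_id`, `term_id`, and optionally `term_name`
#' and `namespace` (defaulting to the term ID and `"BP"`).
#'
#' @param path file path.
#' @return A [term_annotation_set()].
#' @export
read_gene2term <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#", quote = "",
                           colClasses = "character", fill = TRUE)
  if (ncol(tab) < 2L) stop("gene-to-term table needs >= 2 columns",
                           call. = FALSE)
  colnames(tab)[1:2] <- c("gene_id", "term_id")
  name <- if (ncol(tab) >= 3L && any(nzchar(tab[[3L]]))) tab[[3L]]
          else tab$term_id
  ns <- if (ncol(tab) >= 4L && any(nzchar(tab[[4L]]))) tab[[4L]]
        else rep("BP", nrow(tab))
  first <- !duplicated(tab$term_id)
  info <- data.frame(term_id = tab$term_id[first],
                     term_name = name[first], namespace = ns[first],
                     stringsAsFactors = FALSE)
  term_annotation_set(info, split(tab$gene_id, tab$term_id))
}

#' Read an OBO ontology (is_a edges only)
#'
#' Minimal parser for `[Term]` stanzas keeping `id`, `name`, `namespace`
#' and `is_a` relations; obsolete terms are skipped.
#'
#' @param path OBO file.
#' @return A list: `terms` (`data.frame` term_id, term_name, namespace)
#'   and `edges` (`data.frame` child, parent).
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  terms <- list(); edges <- list()
  bounds <- c(starts, length(lines) + 1L)
  for (i in seq_along(starts)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "[")]
    get1 <- function(key) {
      v <- block[startsWith(block, paste0(key, ": "))]
      if (length(v)) sub(paste0("^", key, ": "), "", v[1L]) else NA_character_
    }
    if (any(block == "is_obsolete: true")) next
    id <- get1("id")
    if (is.na(id)) next
    terms[[length(terms) + 1L]] <-
      data.frame(term_id = id, term_name = get1("name"),
                 namespace = get1("namespace"), stringsAsFactors = FALSE)
    isa <- block[startsWith(block, "is_a: ")]
    if (length(isa)) {
      parents <- sub(" !.*$", "", sub("^is_a: ", "", isa))
      edges[[length(edges) + 1L]] <-
        data.frame(child = id, parent = trimws(parents),
                   stringsAsFactors = FALSE)
    }
  }
  list(terms = if (length(terms)) do.call(rbind, terms)
       else data.frame(term_id = character(), term_name = character(),
                       namespace = character(), stringsAsFactors = FALSE),
       edges = if (length(edges)) do.call(rbind, edges)
       else data.frame(child = character(), parent = character(),
                       stringsAsFactors = FALSE))
}

#' Propagate gene annotations to ancestor terms
#'
#' Every gene directly annotated to a term is also annotated to all the
#' term's ancestors (transitive `is_a` closure). Namespaces are not
#' crossed when term metadata is present in `annotations`. Cycles in the
#' parent graph are an error.
#'
#' @param annotations a [term_annotation_set()] of direct annotations.
#' @param edges `data.frame` with columns `child`, `parent`.
#' @param terms optional `data.frame` (term_id, term_name, namespace)
#'   supplying metadata for ancestor terms absent from `annotations`.
#' @return A `TermAnnotationSet` with the ancestor closure applied.
#' @export
propagate_terms <- function(annotations, edges, terms = NULL) {
  stopifnot(inherits(annotations, "TermAnnotationSet"))
  parents <- split(edges$parent, edges$child)
  anc_cache <- new.env(parent = emptyenv())
  visiting <- new.env(parent = emptyenv())
  ancestors <- function(id) {
    if (!is.null(anc_cache[[id]])) return(anc_cache[[id]])
    if (isTRUE(visiting[[id]])) {
      stop("cycle detected in the ontology at term ", id, call. = FALSE)
    }
    visiting[[id]] <- TRUE
    ps <- parents[[id]]
    out <- character()
    for (p in ps) out <- union(out, c(p, ancestors(p)))
    visiting[[id]] <- FALSE
    anc_cache[[id]] <- out
    out
  }
  info <- annotations$terms
  if (!is.null(terms)) {
    extra <- terms[!(terms$term_id %in% info$term_id), , drop = FALSE]
    info <- rbind(info, extra[, c("term_id", "term_name", "namespace")])
  }
  ns_of <- stats::setNames(info$namespace, info$term_id)
  genes <- annotations$genes
  for (id in names(annotations$genes)) {
    for (anc in ancestors(id)) {
      if (!is.na(ns_of[id]) && !is.na(ns_of[anc]) &&
          ns_of[id] != ns_of[anc]) next
      genes[[anc]] <- union(genes[[anc]], annotations$genes[[id]])
    }
  }
  keep <- info$term_id %in% names(genes)
  new_ids <- setdiff(names(genes), info$term_id)
  if (length(new_ids)) {
    info <- rbind(info[keep, , drop = FALSE],
                  data.frame(term_id = new_ids, term_name = new_ids,
                             namespace = NA_character_,
                             stringsAsFactors = FALSE))
  } else {
    info <- info[keep, , drop = FALSE]
  }
  term_annotation_set(info, genes)
}

#' GO-term over-representation test
#'
#' For each term, tests whether the study gene set is enriched for the
#' term's genes relative to the background with a one-sided Fisher exact
#' test (hypergeometric upper tail of the 2x2 table: study-in-term,
#' study-not-in-term, background-only-in-term, rest). P-values are
#' BH-adjusted within each namespace; results are sorted by p ascending.
#'
#' @param study_genes character vector of study gene IDs (must be a
#'   subset of the background).
#' @param background_genes character vector of background gene IDs
#'   (typically every annotated gene in the genome).
#' @param terms a [term_annotation_set()].
#' @param min_term_size smallest background-gene count for a term to be
#'   tested (default 1).
#' @return A `data.frame` with columns term_id, term_name, namespace, k
#'   (study genes in term), K (study size), n (background genes in term),
#'   N (background size), p_fisher, p_adj.
#' @export
fisher_enrichment <- function(study_genes, background_genes, terms,
                              min_term_size = 1L) {
  study <- unique(as.character(study_genes))
  bg <- unique(as.character(background_genes))
  if (length(setdiff(study, bg))) {
    stop("study genes must be a subset of the background", call. = FALSE)
  }
  N <- length(bg)
  K <- length(study)
  rows <- lapply(seq_len(nrow(terms$terms)), function(i) {
    tid <- terms$terms$term_id[i]
    tg <- intersect(terms$genes[[tid]], bg)
    n <- length(tg)
    if (n < min_term_size) return(NULL)
    k <- length(intersect(tg, study))
    # one-sided over-representation tail P(X >= k), hypergeometric
    p <- stats::phyper(k - 1, n, N - n, K, lower.tail = FALSE)
    data.frame(term_id = tid, term_name = terms$terms$term_name[i],
               namespace = terms$terms$namespace[i],
               k = k, K = K, n = n, N = N, p_fisher = min(p, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term_id = character(), term_name = character(),
                      namespace = character(), k = integer(),
                      K = integer(), n = integer(), N = integer(),
                      p_fisher = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE))
  }
  out$p_adj <- NA_real_
  for (ns in unique(out$namespace)) {
    idx <- which(out$namespace %in% ns)
    out$p_adj[idx] <- bh_adjust(out$p_fisher[idx])
  }
  out <- out[order(out$p_fisher, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
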