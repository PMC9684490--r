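#' Read a gene expression matrix from TSV
#'
#' Reads a tab-separated table with gene identifiers in the first column and
#' sample identifiers in the header row, returning a numeric genes-by-samples
#' matrix. Optionally subtracts each gene's row mean, which removes baseline
#' offsets the bilinear expression model has no intercept for.
#'
#' @param path Path to a TSV file (first column gene ids, header sample ids).
#' @param center Logical; if `TRUE` each gene row is mean-centered.
#' @return Numeric matrix with gene ids as rownames and sample ids as colnames.
#' @export
read_expression <- function(path, center = TRUE) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression file needs a gene column plus >=1 sample column")
  genes <- as.character(tab[[1L]])
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0L) {
    stop("duplicate gene id(s) in expression file: ",
         paste(unique(dup), collapse = ", "))
  }
  vals <- tab[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric expression value at row %d, column '%s'",
                     bad[1L], names(vals)[j]))
      }
      vals[[j]] <- num
    }
  }
  E <- as.matrix(vals)
  if (anyNA(E)) stop("missing values in expression matrix")
  rownames(E) <- genes
  if (anyDuplicated(colnames(E))) stop("duplicate sample ids in expression file")
  if (center) E <- E - rowMeans(E)
  E
}

#' Write an expression matrix as TSV
#'
#' @param E Numeric matrix with gene rownames and sample colnames.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(E, path) {
  tab <- data.frame(gene = rownames(E), E, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TF-gene edge list from TSV
#'
#' Accepts either three columns (`gene`, `tf`, `weight`) or two columns
#' (`gene`, `tf`; every weight defaults to 1). Weights must be finite and
#' non-negative; a duplicated (gene, tf) pair is an error.
#'
#' @param path Path to the TSV file. A header row is detected by a
#'   non-numeric third field named `weight` or by the literal column names
#'   `gene`/`tf`; headerless files are accepted.
#' @param role One of `"prior"`, `"gold_standard"`, `"prediction"`; stored as
#'   an attribute for provenance.
#' @return A `grncf_edge_list`: data.frame with columns `gene`, `tf`,
#'   `weight` and attribute `role`.
#' @export
read_edge_list <- function(path, role = c("prior", "gold_standard", "prediction")) {
  role <- match.arg(role)
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character())
  if (length(first) == 0L || !nzchar(first)) {
    return(edge_list(character(), character(), numeric(), role = role))
  }
  fields <- strsplit(first, "\t", fixed = TRUE)[[1L]]
  has_header <- length(fields) >= 2L &&
    (tolower(fields[1L]) %in% c("gene", "gene_id")) &&
    (tolower(fields[2L]) %in% c("tf", "tf_id"))
  tab <- utils::read.delim(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L) return(edge_list(character(), character(), numeric(), role = role))
  if (ncol(tab) == 2L) {
    el <- edge_list(as.character(tab[[1L]]), as.character(tab[[2L]]),
                    rep(1, nrow(tab)), role = role)
  } else if (ncol(tab) >= 3L) {
    w <- tab[[3L]]
    if (!is.numeric(w)) {
      suppressWarnings(w <- as.numeric(w))
      if (anyNA(w)) stop("non-numeric weight in edge list ", path)
    }
    el <- edge_list(as.character(tab[[1L]]), as.character(tab[[2L]]), w, role = role)
  } else {
    stop("edge list must have 2 or 3 columns: ", path)
  }
  el
}

#' Construct an edge list in memory
#'
#' @param gene,tf Character vectors of equal length.
#' @param weight Numeric vector of finite, non-negative weights.
#' @param role Provenance tag.
#' @return A `grncf_edge_list` data.frame.
#' @export
edge_list <- function(gene, tf, weight = rep(1, length(gene)),
                      role = c("prior", "gold_standard", "prediction")) {
  role <- match.arg(role)
  gene <- as.character(gene); tf <- as.character(tf)
  stopifnot(length(gene) == length(tf), length(gene) == length(weight))
  if (length(weight) > 0L) {
    if (any(!is.finite(weight))) stop("edge weights must be finite")
    if (any(weight < 0)) stop("edge weights must be >= 0")
    key <- paste(gene, tf, sep = "\r")
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1L]
      stop("duplicate (gene, tf) pair in edge list: ",
           gsub("\r", " / ", d, fixed = TRUE))
    }
  }
  out <- data.frame(gene = gene, tf = tf, weight = as.numeric(weight),
                    stringsAsFactors = FALSE)
  class(out) <- c("grncf_edge_list", "data.frame")
  attr(out, "role") <- role
  out
}

#' Write an edge list as TSV
#'
#' @param el A `grncf_edge_list` (or data.frame with gene/tf/weight columns).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(el, path) {
  utils::write.table(el[, c("gene", "tf", "weight")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an edge ranking
#'
#' An edge ranking maps retained (gene, tf) pairs to a confidence score;
#' larger scores mean more confident predictions.
#'
#' @param gene,tf Character vectors.
#' @param score Numeric vector of finite confidence scores.
#' @return A `grncf_edge_ranking` data.frame with columns gene, tf, score.
#' @export
edge_ranking <- function(gene, tf, score) {
  gene <- as.character(gene); tf <- as.character(tf)
  stopifnot(length(gene) == length(tf), length(gene) == length(score))
  if (length(score) > 0L && any(!is.finite(score))) stop("scores must be finite")
  out <- data.frame(gene = gene, tf = tf, score = as.numeric(score),
                    stringsAsFactors = FALSE)
  class(out) <- c("grncf_edge_ranking", "data.frame")
  out
}

#' Write a ranked edge list as TSV
#'
#' Rows are sorted by descending confidence; ties are broken by (gene, tf)
#' lexicographic order so output is byte-stable across runs.
#'
#' @param ranking A `grncf_edge_ranking`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ranked_edges <- function(ranking, path) {
  ord <- order(-ranking$score, ranking$gene, ranking$tf, method = "radix")
  out <- ranking[ord, c("gene", "tf", "score"), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranked edge list written by [write_ranked_edges()]
#'
#' @param path Path to the TSV.
#' @return A `grncf_edge_ranking`.
#' @export
read_ranked_edges <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L) return(edge_ranking(character(), character(), numeric()))
  edge_ranking(tab[[1L]], tab[[2L]], tab[[3L]])
}

#' Read a differential-expression table for gold-standard construction
#'
#' @param path TSV with columns `gene`, `tf`, `log2fc`, `padj` (header
#'   optional; columns taken positionally when absent).
#' @return data.frame with those four columns; `padj` may contain `NA`.
#' @export
read_de_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("gene", tolower(first), fixed = TRUE)
  tab <- utils::read.delim(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 4L) stop("DE table needs columns gene, tf, log2fc, padj")
  out <- data.frame(gene = as.character(tab[[1L]]), tf = as.character(tab[[2L]]),
                    log2fc = as.numeric(tab[[3L]]), padj = as.numeric(tab[[4L]]),
                    stringsAsFactors = FALSE)
  out
}
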