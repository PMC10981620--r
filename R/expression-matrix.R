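#' Construct a validated expression matrix
#'
#' The shared currency of the screen: a numeric features-by-samples matrix
#' with unique feature and sample identifiers. Both the mRNA and the miRNA
#' side of the pipeline use this container.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   complete (non-missing) entries and unique dimnames.
#' @param feature_kind Either `"gene"` or `"mirna"`.
#' @param unit Free-text declaration of the expression unit (e.g.
#'   `"log2-normalized"` or `"raw counts"`). Stored as metadata only; no
#'   transformation is applied.
#' @return The matrix with class `"expression_matrix"` and attributes
#'   `feature_kind` and `unit`.
#' @export
expression_matrix <- function(values, feature_kind = c("gene", "mirna"),
                              unit = "log2-normalized") {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("expression matrix is empty", call. = FALSE)
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    stop("expression matrix requires row (feature) and column (sample) names",
         call. = FALSE)
  }
  dup_f <- unique(fid[duplicated(fid)])
  if (length(dup_f)) {
    stop("duplicate feature IDs: ", paste(dup_f, collapse = ", "),
         call. = FALSE)
  }
  dup_s <- unique(sid[duplicated(sid)])
  if (length(dup_s)) {
    stop("duplicate sample IDs: ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)
    stop("missing values in expression matrix, e.g. feature '",
         fid[bad[1L, 1L]], "', sample '", sid[bad[1L, 2L]], "'",
         call. = FALSE)
  }
  structure(values, feature_kind = feature_kind, unit = unit,
            class = c("expression_matrix", class(values)))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d %s feature(s) x %d sample(s) [%s]\n",
              nrow(x), attr(x, "feature_kind"), ncol(x), attr(x, "unit")))
  invisible(x)
}

#' Read a features-by-samples expression TSV
#'
#' Expects a tab-separated file whose header row holds sample IDs and whose
#' first column holds feature IDs. Every data cell must parse as a number;
#' offending cells are reported with their feature and sample ID rather than
#' silently dropped or imputed.
#'
#' @param path Path to the TSV file. Lines starting with `#` are ignored.
#' @param feature_kind `"gene"` or `"mirna"`.
#' @param unit Declared expression unit, recorded as metadata.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, feature_kind = c("gene", "mirna"),
                                unit = "log2-normalized") {
  feature_kind <- match.arg(feature_kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "#", quote = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("empty expression matrix in ", path, call. = FALSE)
  }
  fid <- raw[[1L]]
  sid <- colnames(raw)[-1L]
  dup_f <- unique(fid[duplicated(fid)])
  if (length(dup_f)) {
    stop("duplicate feature IDs in ", path, ": ",
         paste(dup_f, collapse = ", "), call. = FALSE)
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)
    msgs <- vapply(seq_len(min(nrow(bad), 10L)), function(i) {
      sprintf("feature '%s', sample '%s' (value '%s')",
              fid[bad[i, 1L]], sid[bad[i, 2L]], cells[bad[i, 1L], bad[i, 2L]])
    }, character(1L))
    stop("non-numeric cells in ", path, ": ", paste(msgs, collapse = "; "),
         call. = FALSE)
  }
  dimnames(vals) <- list(fid, sid)
  expression_matrix(vals, feature_kind = feature_kind, unit = unit)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_tsv()]: values are rendered with 6 significant
#' digits and a `#`-prefixed provenance header is written first.
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @param seed Optional RNG seed to record in the header comment.
#' @export
write_expression_tsv <- function(x, path, seed = NULL) {
  header <- results_header(seed)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(c("feature_id", colnames(x)), collapse = "\t"), con)
  body <- apply(format_num(unclass(x)), 1L, paste, collapse = "\t")
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

# shared provenance comment for all written tables
results_header <- function(seed = NULL) {
  v <- as.character(utils::packageVersion("mirimmune"))
  if (is.null(seed)) sprintf("# mirimmune %s", v)
  else sprintf("# mirimmune %s; seed=%d", v, as.integer(seed))
}

# render numerics with 6 significant digits, leave other columns alone
format_num <- function(x) {
  if (is.matrix(x)) {
    out <- formatC(signif(x, 6L), format = "g", digits = 6L)
    dim(out) <- dim(x)
    return(out)
  }
  x
}
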