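#' Construct a gene-set collection
#'
#' An ordered collection of named gene sets, the container used both for the
#' Gene Ontology term sets and for the immune signature collection.
#'
#' @param sets Named list of character vectors (member gene IDs), names are
#'   set IDs.
#' @param descriptions Character vector of per-set descriptions, recycled to
#'   the collection length.
#' @return Object of class `"gene_set_collection"`: a named list of unique
#'   member vectors with a `descriptions` attribute.
#' @export
gene_set_collection <- function(sets, descriptions = "") {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop("`sets` must be a named list of member vectors", call. = FALSE)
  }
  ids <- names(sets)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate set IDs: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (any(lengths(sets) == 0L)) {
    stop("gene sets must be non-empty", call. = FALSE)
  }
  descriptions <- rep_len(as.character(descriptions), length(sets))
  names(descriptions) <- ids
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d set(s), member counts %d-%d\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' One set per line: set ID, description, then one or more member gene IDs,
#' all tab-separated (the de facto standard gene-set exchange format).
#' Duplicate members within a line are removed; the total number removed is
#' reported as a warning and recorded in the `n_duplicates_removed` attribute.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection()] preserving file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("GMT line ", short[1L], " has fewer than 3 fields in ", path,
         call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1L), 1L)
  desc <- vapply(fields, `[[`, character(1L), 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  n_dup <- sum(vapply(members, function(m) sum(duplicated(m)), integer(1L)))
  if (n_dup > 0L) {
    warning(n_dup, " duplicate member(s) removed while reading ", path,
            call. = FALSE)
  }
  names(members) <- ids
  out <- gene_set_collection(members, desc)
  attr(out, "n_duplicates_removed") <- n_dup
  out
}

#' Write a gene-set collection as GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(id) {
    paste(c(id, desc[[id]], collection[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GO-term annotation table
#'
#' TSV with columns `term_id`, `name` and (optionally) `description`. Term
#' IDs must be unique and names non-empty; a missing description column or
#' empty description cells are accepted and filled with `""`.
#'
#' @param path Path to the annotation TSV.
#' @return `data.frame` with columns `term_id`, `name`, `description`.
#' @export
read_go_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "#", quote = "")
  need <- c("term_id", "name")
  miss <- setdiff(need, colnames(raw))
  if (length(miss)) {
    stop("GO table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"description" %in% colnames(raw)) raw$description <- ""
  raw$description[is.na(raw$description)] <- ""
  go_term_table(raw[, c("term_id", "name", "description")])
}

#' Construct a validated GO-term table
#'
#' @param df `data.frame` with columns `term_id`, `name`, `description`.
#' @return The validated `data.frame` (row names dropped).
#' @export
go_term_table <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("term_id", "name", "description") %in% colnames(df)))
  dup <- unique(df$term_id[duplicated(df$term_id)])
  if (length(dup)) {
    stop("duplicate GO term IDs: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(df$name))) {
    stop("GO terms with empty names: ",
         paste(df$term_id[!nzchar(df$name)], collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Write a results table as TSV
#'
#' Deterministic column order (as supplied), 6-significant-digit rendering of
#' numeric columns, and a `#` provenance header with package version and,
#' when given, the RNG seed. An empty record list yields a header-only file.
#'
#' @param records `data.frame` of homogeneous result records.
#' @param path Output path.
#' @param seed Optional RNG seed recorded in the provenance comment.
#' @export
write_results_table <- function(records, path, seed = NULL) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(signif(out[[j]], 6L), format = "g", digits = 6L)
    }
  }
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(results_header(seed), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path Path to the TSV.
#' @return `data.frame` with types re-inferred.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, quote = "")
}
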