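#' Parse FASTA text into a named sequence vector
#'
#' Sequences are carried throughout the package as named upper-case character
#' vectors (one element per record, names = record ids); an optional
#' `description` attribute holds the remainder of each header line.
#'
#' @param text A single string (or character vector of lines) of FASTA text.
#' @param type `"nucleotide"` to enforce the A/C/G/T/N alphabet, `"any"` to
#'   accept amino-acid sequences too.
#' @return Named character vector of upper-case sequences, in file order,
#'   with a `description` attribute.
#' @export
parse_fasta <- function(text, type = c("nucleotide", "any")) {
  type <- match.arg(type)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(structure(character(0), description = character(0)))
  }
  if (!startsWith(lines[[1]], ">")) {
    mc_stop("FASTA format error: sequence data before any '>' header")
  }
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  read_fasta(tf, type = type)
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @inheritParams parse_fasta
#' @return Named character vector of upper-case sequences (see [parse_fasta()]).
#' @export
read_fasta <- function(path, type = c("nucleotide", "any")) {
  type <- match.arg(type)
  first <- readLines(path, n = 1L)
  if (length(first) == 1L && nzchar(trimws(first)) && !startsWith(first, ">")) {
    mc_stop("FASTA format error: sequence data before any '>' header in ", path)
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  if (any(!nzchar(ids))) mc_stop("FASTA format error: empty record id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    mc_stop("duplicate id ", paste(dup, collapse = ", "), " in FASTA input")
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    mc_stop("empty sequence for record ", ids[!nzchar(seqs)][1L])
  }
  names(seqs) <- ids
  if (type == "nucleotide") check_nucleotide(seqs, "FASTA record")
  structure(seqs, description = setNames(desc, ids))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    mc_stop("all sequences must be named")
  }
  desc <- attr(seqs, "description")
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    hd <- if (!is.null(desc) && !is.na(desc[id]) && nzchar(desc[id])) {
      paste(id, desc[id])
    } else id
    body <- gsub(sprintf("(.{1,%d})", width), "\\1\n", seqs[[i]])
    cat(">", hd, "\n", body, file = con, sep = "")
  }
  invisible(path)
}

#' Load a feature-by-sample abundance table
#'
#' Reads a tab-delimited table (first column = feature id, remaining columns =
#' samples) into an [abundance_matrix()].
#'
#' @param path Path to the TSV file.
#' @param group_labels Named character vector mapping every sample column to
#'   its group label.
#' @param raw Logical; whether the values are raw counts (rarefaction is only
#'   permitted on raw counts).
#' @return An `abundance_matrix`.
#' @export
load_abundance_table <- function(path, group_labels, raw = TRUE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  feats <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- feats
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    mc_stop("negative abundance ", feats[bad[1, 1]], "/", colnames(m)[bad[1, 2]])
  }
  abundance_matrix(m, group_labels, raw = raw)
}

#' Construct an abundance matrix
#'
#' The central container: a numeric features x samples matrix carrying sample
#' group labels and a flag distinguishing raw counts from normalized values.
#'
#' @param m Numeric matrix, features in rows, samples in columns, both named.
#' @param group_labels Named character vector, one label per sample column.
#' @param raw Logical flag: `TRUE` for raw counts.
#' @return An object of class `abundance_matrix` (a matrix with attributes
#'   `groups` and `raw`).
#' @export
abundance_matrix <- function(m, group_labels, raw = TRUE) {
  if (!is.matrix(m) || !is.numeric(m)) mc_stop("abundance matrix must be numeric")
  if (is.null(colnames(m))) mc_stop("abundance matrix must have sample (column) names")
  if (any(!is.finite(m)) || any(m < 0)) mc_stop("abundance values must be finite and non-negative")
  missing <- setdiff(colnames(m), names(group_labels))
  if (length(missing) > 0L) {
    mc_stop("sample missing from group_labels: ", paste(missing, collapse = ", "))
  }
  structure(m,
            groups = setNames(as.character(group_labels[colnames(m)]), colnames(m)),
            raw = isTRUE(raw),
            class = c("abundance_matrix", "matrix", "array"))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d features x %d samples (%s); groups: %s\n",
              nrow(x), ncol(x), if (attr(x, "raw")) "raw counts" else "normalized",
              paste(sprintf("%s=%d", names(table(attr(x, "groups"))),
                            as.integer(table(attr(x, "groups")))), collapse = ", ")))
  invisible(x)
}

sample_groups <- function(m) attr(m, "groups")

#' Write an abundance matrix as TSV
#'
#' @param m Matrix (features x samples).
#' @param path Output path.
#' @param feature_col Name of the first (feature id) column.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(m, path, feature_col = "feature") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- feature_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# numbers are written at full precision; scientific notation for tiny values
# (the style differential-abundance tables are conventionally printed in)
format_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v != 0 && abs(v) < 1e-3) format(v, scientific = TRUE, digits = 12)
    else format(v, scientific = FALSE, digits = 12)
  }, character(1))
}

#' Write a differential-abundance report
#'
#' Emits the two-group differential test table as a TSV with a deterministic
#' column order (`feature`, per-group mean/sd, `p_value`, `q_value`,
#' `direction`, `significant`, `stars`), rows sorted by ascending p-value with
#' ties broken by feature id.
#'
#' @param table A `data.frame` as returned by [differential_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path) {
  need <- c("feature", "p_value", "q_value")
  if (!all(need %in% names(table))) mc_stop("report table missing required columns")
  if (anyNA(table$p_value) || anyNA(table$q_value)) {
    mc_stop("report table has missing p/q values")
  }
  tab <- table[order(table$p_value, table$feature), , drop = FALSE]
  out <- tab
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], format_num)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a differential-abundance report
#'
#' @param path Path written by [write_report()].
#' @return A `data.frame` with numeric columns restored.
#' @export
read_report <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (cn in setdiff(names(df), c("feature", "direction", "stars"))) {
    if (cn == "significant") df[[cn]] <- as.logical(df[[cn]])
    else df[[cn]] <- as.numeric(df[[cn]])
  }
  df
}
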