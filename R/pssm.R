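#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that enforces the
#' contracts this package needs: the file must be non-empty, ids (the first
#' whitespace-delimited token of each header) must be unique, and sequences
#' must be non-empty. Non-standard residue letters (X, B, Z, U) are permitted
#' but reported with a warning, since PSI-BLAST still emits 20 scores for
#' those positions.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` and `sequence`, one row per record,
#'   in file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "ACDE", ">p2", "MKLV"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop_input("empty FASTA file: ", path)
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop_input("malformed FASTA: line ", first,
               " does not start a record ('>' expected): ",
               substr(lines[first], 1L, 40L))
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop_input("malformed FASTA '", path, "': ",
                                   conditionMessage(e))
  )
  if (length(set) == 0L) stop_input("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  if (any(!nzchar(ids))) {
    stop_input("malformed FASTA: record ", which(!nzchar(ids))[1L],
               " has an empty id")
  }
  if (anyDuplicated(ids)) {
    stop_input("duplicate sequence id(s): ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop_input("zero-length sequence for id(s): ",
               paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  odd <- grepl("[XBZU]", seqs)
  if (any(odd)) {
    warning("non-standard residue letters (X/B/Z/U) in: ",
            paste(ids[odd], collapse = ", "), call. = FALSE)
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Filter protein records by sequence length
#'
#' Retains records strictly longer than `min_len` and strictly shorter than
#' `max_len` residues. The defaults (50, 5000) are the usual proteome
#' pre-filter that drops peptides too short to produce an informative profile
#' and unwieldy giant proteins; both bounds are exclusive.
#'
#' @param records Data frame with columns `id` and `sequence`, as returned by
#'   [read_fasta()].
#' @param min_len,max_len Exclusive length bounds; `0 < min_len < max_len`.
#' @return The retained rows, in input order.
#' @export
#' @examples
#' recs <- data.frame(id = c("a", "b"),
#'                    sequence = c(strrep("A", 50), strrep("A", 51)))
#' length_filter(recs)$id  # only "b": bounds are strict
length_filter <- function(records, min_len = 50L, max_len = 5000L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  if (min_len < 0 || max_len <= 0 || min_len >= max_len) {
    stop_input("invalid length bounds: need 0 <= min_len < max_len, got ",
               min_len, ", ", max_len)
  }
  len <- nchar(records$sequence)
  records[len > min_len & len < max_len, , drop = FALSE]
}

#' Construct a PSSM object
#'
#' A position-specific scoring matrix: one row per residue of the protein,
#' one column per amino acid in the declared column order. `normalized = TRUE`
#' asserts that every row is a probability distribution (entries in `[0, 1]`,
#' rows summing to 1 within 1e-9).
#'
#' @param matrix Numeric L x 20 matrix.
#' @param protein_id Identifier of the protein the matrix describes.
#' @param column_order Character vector of 20 amino-acid letters naming the
#'   columns; defaults to the PSI-BLAST order ([aa_alphabet()]).
#' @param normalized Logical; whether rows are probability profiles.
#' @param sequence Optional residue string of length L (row labels).
#' @return An object of class `pssm`.
#' @export
pssm <- function(matrix, protein_id = "query", column_order = aa_alphabet(),
                 normalized = FALSE, sequence = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop_input("PSSM matrix must be a numeric matrix")
  }
  if (ncol(matrix) != 20L) {
    stop_input("PSSM must have exactly 20 columns, got ", ncol(matrix))
  }
  if (nrow(matrix) < 1L) stop_input("PSSM must have at least one row")
  if (length(column_order) != 20L || anyDuplicated(column_order)) {
    stop_input("column_order must be 20 distinct amino-acid letters")
  }
  if (!is.null(sequence) && nchar(sequence) != nrow(matrix)) {
    stop_input("sequence length (", nchar(sequence),
               ") does not match row count (", nrow(matrix), ")")
  }
  if (isTRUE(normalized)) {
    if (any(matrix < -1e-9) || any(matrix > 1 + 1e-9)) {
      stop_input("normalized PSSM entries must lie in [0, 1]")
    }
    if (any(abs(rowSums(matrix) - 1) > 1e-9)) {
      stop_input("normalized PSSM rows must sum to 1 within 1e-9")
    }
  }
  dimnames(matrix) <- list(NULL, column_order)
  structure(
    list(protein_id = protein_id, matrix = matrix,
         column_order = column_order, normalized = isTRUE(normalized),
         sequence = sequence),
    class = "pssm"
  )
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM for '%s': %d x 20 (%s)\n", x$protein_id,
              nrow(x$matrix), if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' @export
dim.pssm <- function(x) dim(x$matrix)

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the text matrix produced by `psiblast -out_ascii_pssm`: two header
#' lines, a column-header line of amino-acid letters, then one row per
#' residue carrying the position index, the residue letter and (first block)
#' 20 integer log-odds scores. The weighted-percentage block and trailing
#' statistics are ignored. The file's own column letter order is recorded on
#' the returned object.
#'
#' @param path Path to the ASCII PSSM file.
#' @return A raw (unnormalized) [pssm()] object; `protein_id` is the file
#'   base name without extension.
#' @export
parse_psiblast_pssm <- function(path) {
  if (!file.exists(path)) stop_input("PSSM file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  # locate the column header: the first line whose leading tokens are >= 20
  # single amino-acid letters
  header_idx <- NA_integer_
  cols <- NULL
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) >= 20L && all(nchar(tok) == 1L) &&
        all(tok %in% c(LETTERS, "*"))) {
      header_idx <- i
      cols <- tok[1:20]
      break
    }
  }
  if (is.na(header_idx)) {
    stop_input("not a PSI-BLAST ASCII PSSM (no amino-acid column header): ",
               path)
  }

  rows <- list()
  residues <- character(0)
  expect_pos <- 1L
  for (i in seq(header_idx + 1L, length(lines))) {
    line <- trimws(lines[i])
    if (!nzchar(line)) break                      # blank line ends the matrix
    tok <- strsplit(line, "[ \t]+")[[1]]
    if (!grepl("^[0-9]+$", tok[1])) break         # trailing statistics block
    if (length(tok) < 22L) {
      stop_input("malformed PSSM row at line ", i, " of ", path,
                 ": expected position, residue and 20 scores, got ",
                 length(tok), " fields")
    }
    pos <- as.integer(tok[1])
    if (pos != expect_pos) {
      stop_input("PSSM rows out of order at line ", i, " of ", path,
                 ": position ", pos, " where ", expect_pos, " expected")
    }
    res <- tok[2]
    if (nchar(res) != 1L || !res %in% LETTERS) {
      stop_input("invalid residue letter '", res, "' at line ", i, " of ", path)
    }
    scores <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(scores)) {
      stop_input("non-numeric score in PSSM row at line ", i, " of ", path)
    }
    rows[[expect_pos]] <- scores
    residues[expect_pos] <- res
    expect_pos <- expect_pos + 1L
  }
  if (length(rows) == 0L) stop_input("PSSM file has no matrix rows: ", path)

  m <- do.call(rbind, rows)
  odd <- residues %in% c("X", "B", "Z", "U")
  if (any(odd)) {
    warning("PSSM '", path, "' has non-standard residue(s) at position(s) ",
            paste(which(odd), collapse = ", "), "; rows kept as-is",
            call. = FALSE)
  }
  pssm(m, protein_id = sub("\\.[^.]*$", "", basename(path)),
       column_order = cols, normalized = FALSE,
       sequence = paste(residues, collapse = ""))
}

#' Normalize a raw PSSM into row-wise probability profiles
#'
#' Maps each log-odds score through a bounded monotone transform and rescales
#' each row to sum to 1, so that entry (i, j) can be read as the relative
#' probability of amino acid j at position i. The default transform is the
#' elementwise logistic `1 / (1 + exp(-x))` (the common convention for
#' PSSM-derived features); `"softmax"` applies `exp(x)` row-wise instead.
#'
#' @param x A raw `pssm` (normalizing twice is an error, by contract).
#' @param transform `"logistic"` (default) or `"softmax"`.
#' @return A `pssm` with `normalized = TRUE`; shape and column order
#'   preserved, every entry in `[0, 1]`, rows summing to 1 within 1e-9.
#' @export
#' @examples
#' p <- pssm(matrix(0, 3, 20))
#' normalize_pssm(p)$matrix[1, 1]  # logistic(0) = 0.5, rescaled to 1/20
normalize_pssm <- function(x, transform = c("logistic", "softmax")) {
  stopifnot(inherits(x, "pssm"))
  transform <- match.arg(transform)
  if (x$normalized) stop_input("PSSM is already normalized")
  m <- x$matrix
  m <- switch(transform,
    logistic = 1 / (1 + exp(-m)),
    softmax  = exp(m - apply(m, 1L, max))  # shift for overflow safety
  )
  m <- m / rowSums(m)
  pssm(m, protein_id = x$protein_id, column_order = x$column_order,
       normalized = TRUE, sequence = x$sequence)
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#'
#' Emits a file that [parse_psiblast_pssm()] reads back exactly: two header
#' lines, the 20-letter column header (duplicated, as psiblast prints the
#' log-odds and percentage blocks side by side), one row per position with
#' integer log-odds, a zero percentage block, and a trailing statistics
#' stanza. Scores are rounded to integers, matching the native format, so
#' only integer-valued raw matrices round-trip losslessly.
#'
#' @param x A raw `pssm` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(x, path) {
  stopifnot(inherits(x, "pssm"))
  if (x$normalized) {
    stop_input("write_pssm() expects a raw (integer log-odds) PSSM")
  }
  m <- round(x$matrix)
  L <- nrow(m)
  residues <- if (!is.null(x$sequence)) strsplit(x$sequence, "")[[1]]
              else x$column_order[max.col(m, ties.method = "first")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "",
    paste("Last position-specific scoring matrix computed, weighted",
          "observed percentages rounded down, information per position,",
          "and relative weight of gapless real matches to pseudocounts")
  ), con)
  writeLines(paste0("            ",
                    paste(sprintf("%3s", x$column_order), collapse = ""),
                    "  ",
                    paste(sprintf("%3s", x$column_order), collapse = "")),
             con)
  for (i in seq_len(L)) {
    writeLines(paste0(sprintf("%5d %s ", i, residues[i]),
                      paste(sprintf("%3d", m[i, ]), collapse = ""),
                      "  ",
                      paste(sprintf("%3d", rep(0L, 20L)), collapse = ""),
                      sprintf("  %4.2f %8.2f", 0, 0)),
               con)
  }
  writeLines(c("", "                      K         Lambda",
               "Standard Ungapped    0.1337     0.3176",
               "Standard Gapped      0.0410     0.2670",
               "PSI Ungapped         0.1337     0.3176",
               "PSI Gapped           0.0410     0.2670"), con)
  invisible(path)
}

#' PSI-BLAST run configuration
#'
#' Records the profile-search parameters used to produce PSSMs: an e-value
#' inclusion threshold of 0.001 and 3 search iterations against a large
#' non-redundant protein database. This package never runs PSI-BLAST itself
#' (the database is far beyond desk scale); the config documents the intended
#' provenance of real input PSSMs and feeds [psiblast_command()].
#'
#' @param evalue Inclusion e-value threshold.
#' @param iterations Number of PSI-BLAST iterations.
#' @param db BLAST protein database name.
#' @return A list of class `psiblast_config`.
#' @export
psiblast_config <- function(evalue = 0.001, iterations = 3L, db = "nr") {
  stopifnot(evalue > 0, iterations >= 1L)
  structure(list(evalue = evalue, iterations = as.integer(iterations), db = db),
            class = "psiblast_config")
}

#' Shell command to generate an ASCII PSSM with PSI-BLAST
#'
#' Convenience formatter for users who have a local `psiblast` and database;
#' the returned string is never executed by this package.
#'
#' @param query_fasta Path to a single-sequence FASTA query.
#' @param out_pssm Desired output path for the ASCII PSSM.
#' @param config A [psiblast_config()].
#' @return The command line as a single string.
#' @export
#' @examples
#' psiblast_command("p1.fasta", "p1.pssm")
psiblast_command <- function(query_fasta, out_pssm,
                             config = psiblast_config()) {
  stopifnot(inherits(config, "psiblast_config"))
  sprintf(
    "psiblast -query %s -db %s -num_iterations %d -evalue %g -out_ascii_pssm %s",
    query_fasta, config$db, config$iterations, config$evalue, out_pssm)
}
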