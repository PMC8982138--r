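# Core tabular data structures: sequencing count tables (W), observed
# concentration tables (V), and their alignment into a paired dataset with
# the observed taxa stored in the leading columns.

#' Construct a sequencing count table
#'
#' A count table holds the read counts `W` (samples by taxa) from a
#' broad-range assay such as 16S rRNA amplicon sequencing, together with the
#' per-sample read depths `M` (the row sums of `W`).
#'
#' @param W Integer matrix of nonnegative read counts, samples as rows and
#'   taxa as columns.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to `rownames(W)`.
#' @param taxon_ids Character vector of unique taxon identifiers; defaults to
#'   `colnames(W)`.
#' @return An object of class `count_table` with elements `W`, `M`,
#'   `sample_ids`, `taxon_ids`.
#' @examples
#' ct <- count_table(matrix(c(5, 0, 10, 0, 15, 1), 2, 3,
#'                          dimnames = list(c("s1", "s2"), c("A", "B", "C"))))
#' ct$M  # read depths 30 and 1
#' @export
count_table <- function(W, sample_ids = rownames(W), taxon_ids = colnames(W)) {
  W <- as.matrix(W)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(W)))
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon", seq_len(ncol(W)))
  check_count_matrix(W, "W")
  check_ids(sample_ids, nrow(W), "sample_ids")
  check_ids(taxon_ids, ncol(W), "taxon_ids")
  storage.mode(W) <- "double"
  dimnames(W) <- list(sample_ids, taxon_ids)
  structure(
    list(W = W, M = rowSums(W), sample_ids = sample_ids, taxon_ids = taxon_ids),
    class = "count_table"
  )
}

#' Construct an observed concentration table
#'
#' Holds observed concentrations `V` (e.g., 16S gene copies per swab from
#' taxon-specific qPCR) for a subset of the taxa in a paired count table.
#' Concentrations are modeled as Poisson counts, so entries must be
#' nonnegative integers; real-valued input is rounded with a warning.
#'
#' @param V Matrix of nonnegative integer concentrations, samples as rows.
#' @param sample_ids,taxon_ids Identifiers as in [count_table()].
#' @return An object of class `concentration_table`.
#' @export
concentration_table <- function(V, sample_ids = rownames(V),
                                taxon_ids = colnames(V)) {
  V <- as.matrix(V)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(V)))
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon", seq_len(ncol(V)))
  if (any(is.na(V))) {
    stop("missing values in V are not supported; concentrations must be ",
         "available for every sample and every observed taxon", call. = FALSE)
  }
  if (any(V != round(V))) {
    warning("non-integer concentrations rounded to integers ",
            "(the concentration model is a Poisson count model)")
    V <- round(V)
  }
  check_count_matrix(V, "V")
  check_ids(sample_ids, nrow(V), "sample_ids")
  check_ids(taxon_ids, ncol(V), "taxon_ids")
  storage.mode(V) <- "double"
  dimnames(V) <- list(sample_ids, taxon_ids)
  structure(
    list(V = V, sample_ids = sample_ids, taxon_ids = taxon_ids),
    class = "concentration_table"
  )
}

check_count_matrix <- function(m, name) {
  if (any(is.na(m))) stop(name, " contains missing values", call. = FALSE)
  if (any(m < 0)) stop(name, " contains negative entries", call. = FALSE)
  if (any(m != round(m))) {
    stop(name, " contains non-integer entries", call. = FALSE)
  }
  invisible(m)
}

check_ids <- function(ids, len, name) {
  if (length(ids) != len) {
    stop(name, " has length ", length(ids), " but expected ", len,
         call. = FALSE)
  }
  if (anyDuplicated(ids)) stop(name, " contains duplicates", call. = FALSE)
  invisible(ids)
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", length(x$sample_ids), "samples x",
      length(x$taxon_ids), "taxa; read depths",
      min(x$M), "-", max(x$M), "\n")
  invisible(x)
}

#' @export
print.concentration_table <- function(x, ...) {
  cat("concentration_table:", length(x$sample_ids), "samples x",
      length(x$taxon_ids), "observed taxa\n")
  invisible(x)
}

#' Read a count table from delimited text
#'
#' Expects a header row of taxon identifiers and a first column of sample
#' identifiers; the delimiter is inferred from the file extension (`.csv`
#' for comma, otherwise tab). Read depths are recomputed as row sums.
#'
#' @param path Path to a CSV/TSV file.
#' @return A validated [count_table()].
#' @export
read_count_table <- function(path) {
  count_table(read_id_matrix(path))
}

#' Read a concentration table from delimited text
#' @inheritParams read_count_table
#' @return A validated [concentration_table()].
#' @export
read_concentration_table <- function(path) {
  concentration_table(read_id_matrix(path))
}

read_id_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, colClasses = "character",
                          fileEncoding = "UTF-8")
  m <- as.matrix(df)
  suppressWarnings(storage.mode(m) <- "double")
  if (any(is.na(m))) {
    stop("non-numeric or missing entries in ", path, call. = FALSE)
  }
  m
}

write_id_matrix <- function(m, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a count or concentration table to delimited text
#'
#' @param x A `count_table` or `concentration_table`.
#' @param path Output path (`.csv` for comma-delimited, otherwise tab).
#' @return The path, invisibly.
#' @export
write_abundance_table <- function(x, path) {
  m <- if (inherits(x, "count_table")) x$W else x$V
  write_id_matrix(m, path)
}

#' Align a count table and a concentration table
#'
#' Reorders the count table so the taxa with observed concentrations occupy
#' the leading columns, in the order of the concentration table, and puts
#' both tables in a common sample order. Taxon matching is by exact
#' identifier.
#'
#' @param counts A [count_table()] with all `q` taxa.
#' @param conc A [concentration_table()] for `qobs < q` of those taxa.
#' @return An object of class `paired_abundance`: a list with the reordered
#'   `counts`, `conc`, the number of observed taxa `qobs`, and the column
#'   permutation `taxon_perm` applied to the count table.
#' @export
align_tables <- function(counts, conc) {
  stopifnot(inherits(counts, "count_table"),
            inherits(conc, "concentration_table"))
  missing_taxa <- setdiff(conc$taxon_ids, counts$taxon_ids)
  if (length(missing_taxa) > 0) {
    stop("concentration taxa absent from count table: ",
         paste(missing_taxa, collapse = ", "), call. = FALSE)
  }
  if (!setequal(counts$sample_ids, conc$sample_ids)) {
    stop("sample identifiers of the two tables differ", call. = FALSE)
  }
  qobs <- length(conc$taxon_ids)
  q <- length(counts$taxon_ids)
  if (qobs >= q) {
    stop("all taxa have observed concentrations (qobs >= q); ",
         "the joint model requires at least one unobserved taxon",
         call. = FALSE)
  }
  rest <- setdiff(counts$taxon_ids, conc$taxon_ids)
  taxon_perm <- match(c(conc$taxon_ids, rest), counts$taxon_ids)
  sample_perm <- match(counts$sample_ids, conc$sample_ids)
  counts_out <- count_table(counts$W[, taxon_perm, drop = FALSE])
  conc_out <- concentration_table(conc$V[sample_perm, , drop = FALSE])
  structure(
    list(counts = counts_out, conc = conc_out, qobs = qobs,
         taxon_perm = taxon_perm),
    class = "paired_abundance"
  )
}

#' @export
print.paired_abundance <- function(x, ...) {
  cat("paired_abundance:", length(x$counts$sample_ids), "samples,",
      length(x$counts$taxon_ids), "taxa (", x$qobs,
      "with observed concentrations )\n")
  invisible(x)
}

#' Filter taxa by prevalence
#'
#' Retains taxa with a nonzero read count in at least
#' `ceiling(min_prevalence * n)` samples. Taxa listed in `protect` (e.g.,
#' taxa with observed concentrations) are never removed; a warning is issued
#' if they would have been.
#'
#' @param counts A [count_table()].
#' @param min_prevalence Fraction of samples in `[0, 1]`.
#' @param protect Character vector of taxon identifiers exempt from removal.
#' @return A filtered [count_table()] (read depths recomputed).
#' @export
prevalence_filter <- function(counts, min_prevalence, protect = NULL) {
  stopifnot(inherits(counts, "count_table"),
            is.numeric(min_prevalence), length(min_prevalence) == 1,
            min_prevalence >= 0, min_prevalence <= 1)
  n <- nrow(counts$W)
  need <- ceiling(min_prevalence * n)
  prevalent <- colSums(counts$W > 0) >= need
  if (!is.null(protect)) {
    protected <- counts$taxon_ids %in% protect
    saved <- protected & !prevalent
    if (any(saved)) {
      warning("retaining low-prevalence taxa with observed concentrations: ",
              paste(counts$taxon_ids[saved], collapse = ", "))
    }
    prevalent <- prevalent | protected
  }
  count_table(counts$W[, prevalent, drop = FALSE])
}
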