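# Readers and writers: classic tab-delimited OTU tables, sample sheets,
# result reports.

.taxonomy_headers <- c("Consensus Lineage", "ConsensusLineage", "taxonomy",
                       "Taxonomy")

#' Read an OTU table
#'
#' Reads a classic tab-delimited OTU table: OTUs in rows, samples in
#' columns, first column OTU ids, optional trailing taxonomy column
#' (recognized by header `"Consensus Lineage"`, `"ConsensusLineage"` or
#' `"taxonomy"`). Leading `#` comment lines are ignored; if the last
#' comment line is itself tab-delimited with the right number of fields
#' (the `#OTU ID` header convention) it is used as the header. BIOM files
#' are read through the `biomformat` package when `format = "biom"`.
#'
#' @param path Path to the table.
#' @param format `"classic"` (tab-delimited) or `"biom"`.
#' @return An object of class `"otu_table"`: a list with `counts` (integer
#'   matrix, OTUs in rows, samples in columns) and `taxonomy` (named
#'   character vector or `NULL`).
#' @export
read_otu_table <- function(path, format = c("classic", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("no such file: ", path)
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    counts <- as(biomformat::biom_data(b), "matrix")
    storage.mode(counts) <- "integer"
    md <- biomformat::observation_metadata(b)
    taxonomy <- NULL
    if (!is.null(md) && length(md)) {
      taxonomy <- vapply(seq_len(nrow(counts)), function(i) {
        paste(unlist(md[i, ]), collapse = "; ")
      }, "")
      names(taxonomy) <- rownames(counts)
    }
    return(.new_otu_table(counts, taxonomy))
  }

  lines <- readLines(path)
  is_comment <- grepl("^#", lines)
  first_data <- which(!is_comment)[1]
  if (is.na(first_data)) {
    stop("no data rows in ", path)
  }
  header_line <- NULL
  if (first_data > 1L) {
    cand <- lines[first_data - 1L]
    n_fields <- length(strsplit(lines[first_data], "\t", fixed = TRUE)[[1]])
    if (length(strsplit(cand, "\t", fixed = TRUE)[[1]]) == n_fields) {
      header_line <- sub("^#\\s*", "", cand)
    }
  }
  if (is.null(header_line)) {
    header_line <- lines[first_data]
    body <- lines[-seq_len(first_data)]
  } else {
    body <- lines[first_data:length(lines)]
  }
  header <- strsplit(header_line, "\t", fixed = TRUE)[[1]]
  rows <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(rows) != length(header))
  if (length(bad)) {
    stop(sprintf("line %d of %s has %d fields; expected %d",
                 bad[1], path, lengths(rows)[bad[1]], length(header)))
  }
  mat <- do.call(rbind, rows)
  otu_ids <- mat[, 1L]
  if (anyDuplicated(otu_ids)) {
    stop("duplicate OTU ids in ", path, ": ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  }
  tax_col <- which(header %in% .taxonomy_headers)
  taxonomy <- NULL
  if (length(tax_col)) {
    tax_col <- tax_col[length(tax_col)]
    taxonomy <- setNames(mat[, tax_col], otu_ids)
  } else {
    tax_col <- integer(0)
  }
  count_cols <- setdiff(seq_along(header)[-1L], tax_col)
  sample_ids <- header[count_cols]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in ", path)
  }
  counts <- matrix(NA_integer_, nrow = length(otu_ids),
                   ncol = length(count_cols),
                   dimnames = list(otu_ids, sample_ids))
  for (j in seq_along(count_cols)) {
    v <- mat[, count_cols[j]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) | num != floor(num) | num < 0)
    if (length(bad)) {
      stop(sprintf(
        "%s: cell (OTU '%s', sample '%s') is not a non-negative integer count: '%s'",
        path, otu_ids[bad[1]], sample_ids[j], v[bad[1]]))
    }
    counts[, j] <- as.integer(num)
  }
  .new_otu_table(counts, taxonomy)
}

.new_otu_table <- function(counts, taxonomy = NULL) {
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d OTUs x %d samples%s\n", nrow(x$counts),
              ncol(x$counts),
              if (is.null(x$taxonomy)) "" else " (with taxonomy)"))
  cat("  samples:", paste(colnames(x$counts), collapse = ", "), "\n")
  invisible(x)
}

#' Write an OTU table
#'
#' Writes the classic tab-delimited layout read by [read_otu_table()],
#' with an `#OTU ID` header line and the taxonomy (if any) as a trailing
#' `Consensus Lineage` column.
#'
#' @param x An `"otu_table"` object (or a bare counts matrix, OTUs in
#'   rows).
#' @param path Output path.
#' @export
write_otu_table <- function(x, path) {
  if (is.matrix(x)) x <- .new_otu_table(x)
  if (!inherits(x, "otu_table")) stop("'x' must be an otu_table")
  header <- c("#OTU ID", colnames(x$counts))
  body <- cbind(rownames(x$counts),
                matrix(as.character(x$counts), nrow = nrow(x$counts)))
  if (!is.null(x$taxonomy)) {
    header <- c(header, "Consensus Lineage")
    body <- cbind(body, unname(x$taxonomy[rownames(x$counts)]))
  }
  writeLines(c(paste(header, collapse = "\t"),
               apply(body, 1L, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-delimited sample metadata with required columns `sample_id`,
#' `subject_id`, `site` and `replicate`. Sites must be `BAL`, `OW` or
#' `control`; the (subject, site, replicate) triple must be unique.
#'
#' @param path Path to the sheet.
#' @return A data frame of class `"sample_sheet"`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("sample_id", "subject_id", "site", "replicate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("sample sheet is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param df A data frame with the required columns.
#' @export
validate_sample_sheet <- function(df) {
  allowed <- c("BAL", "OW", "control")
  bad_site <- setdiff(unique(df$site), allowed)
  if (length(bad_site)) {
    stop("unknown site(s) ", paste(sQuote(bad_site), collapse = ", "),
         "; allowed values are ", paste(allowed, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in sample sheet")
  }
  key <- paste(df$subject_id, df$site, df$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (subject_id, site, replicate): ",
         key[duplicated(key)][1])
  }
  if (any(df$replicate < 1 | df$replicate != floor(df$replicate))) {
    stop("'replicate' must be a positive integer")
  }
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' @rdname read_sample_sheet
#' @param x A `"sample_sheet"` data frame.
#' @export
write_sample_sheet <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a subject's replicate count matrices
#'
#' Pulls the BAL and OW replicate count matrices (replicates in rows, OTUs
#' in columns) for one subject out of an OTU table and its sample sheet.
#'
#' @param otu An `"otu_table"` object.
#' @param sheet A `"sample_sheet"` data frame.
#' @param subject Subject identifier.
#' @return A list with `bal` and `ow` matrices and `taxonomy`.
#' @export
subject_matrices <- function(otu, sheet, subject) {
  if (!inherits(otu, "otu_table")) stop("'otu' must be an otu_table")
  sheet <- validate_sample_sheet(as.data.frame(sheet))
  sub <- sheet[sheet$subject_id == subject, ]
  if (nrow(sub) == 0L) {
    stop("subject ", sQuote(subject), " not found in sample sheet")
  }
  pick <- function(site) {
    rows <- sub[sub$site == site, ]
    if (nrow(rows) == 0L) {
      stop("no ", site, " samples for subject ", sQuote(subject))
    }
    rows <- rows[order(rows$replicate), ]
    missing_samples <- setdiff(rows$sample_id, colnames(otu$counts))
    if (length(missing_samples)) {
      stop("sample(s) absent from OTU table: ",
           paste(missing_samples, collapse = ", "))
    }
    m <- t(otu$counts[, rows$sample_id, drop = FALSE])
    storage.mode(m) <- "integer"
    m
  }
  list(bal = pick("BAL"), ow = pick("OW"), taxonomy = otu$taxonomy)
}

#' Render a p-value with its Monte-Carlo floor
#'
#' Monte-Carlo p-values cannot resolve below `1/(n_trials + 1)`; values at
#' the floor are rendered as `"<floor"` at the resolution of the trial
#' count (e.g. `"<0.0001"` for 10,000 trials), as in a printed outlier
#' report.
#'
#' @param p P-value(s).
#' @param n_trials Number of Monte-Carlo trials, or `NULL` for analytic
#'   p-values (plain formatting).
#' @return Character vector.
#' @export
format_p_value <- function(p, n_trials = NULL) {
  if (is.null(n_trials)) {
    return(sprintf("%.4g", p))
  }
  digits <- max(1L, ceiling(log10(n_trials)))
  floor_p <- 1 / (n_trials + 1)
  ifelse(p <= floor_p,
         sprintf("<%.*f", digits, 1 / n_trials),
         sprintf("%.*f", digits, p))
}

#' Write an analysis result to a tab-delimited file
#'
#' Serializes outlier results, replicate comparisons, detection curves and
#' concordance tables. Numeric columns are written at full precision;
#' outlier reports additionally carry a rounded display column in which
#' Monte-Carlo p-values at the floor are rendered `"<floor"`. Provenance
#' (seed, alpha, trial count, theta) is recorded in `#` header lines.
#'
#' @param x Result object (`outlier_result`, `outlier_comparison`,
#'   `detection_curve`, `concordance`, or a plain data frame).
#' @param path Output path.
#' @param ... Unused.
#' @return The path, invisibly.
#' @export
write_results <- function(x, path, ...) UseMethod("write_results")

#' @export
write_results.default <- function(x, path, ...) {
  if (!is.data.frame(x) || nrow(x) == 0L) {
    stop("nothing to write: 'x' must be a non-empty result table")
  }
  .write_tsv(as.data.frame(x), path)
}

#' @export
write_results.outlier_result <- function(x, path, ...) {
  if (nrow(x) == 0L) stop("nothing to write: empty outlier result")
  df <- as.data.frame(x)
  n_trials <- attr(x, "n_trials")
  df$p_display <- format_p_value(df$p_value, n_trials)
  df$q_display <- format_p_value(df$q_value, n_trials)
  hdr <- c(sprintf("# alpha=%g", attr(x, "alpha")),
           sprintf("# theta_hat=%g", attr(x, "theta")))
  if (!is.null(n_trials)) {
    hdr <- c(hdr, sprintf("# n_trials=%d", n_trials),
             sprintf("# seed=%d", attr(x, "seed")),
             sprintf("# p_floor=%g", attr(x, "p_floor")))
  }
  .write_tsv(df, path, header_lines = hdr)
}

#' @export
write_results.outlier_comparison <- function(x, path, ...) {
  if (nrow(x) == 0L) stop("nothing to write: empty comparison table")
  df <- as.data.frame(x)
  n_trials <- attr(x, "n_trials")
  df$p_display <- format_p_value(df$p_value, n_trials)
  df$q_display <- format_p_value(df$q_value, n_trials)
  hdr <- c(sprintf("# alpha=%g", attr(x, "alpha")),
           sprintf("# theta_hat=%g", attr(x, "theta")),
           sprintf("# n_trials=%d", n_trials),
           sprintf("# seed=%d", attr(x, "seed")),
           sprintf("# n_pairs=%d", attr(x, "n_pairs")),
           sprintf("# additional_unadjusted_otus=%s",
                   paste(attr(x, "additional_otus"), collapse = ",")))
  .write_tsv(df, path, header_lines = hdr)
}

#' @export
write_results.detection_curve <- function(x, path, ...) {
  if (nrow(x) == 0L) stop("nothing to write: empty detection curve")
  hdr <- c(sprintf("# theta=%g", attr(x, "theta")),
           sprintf("# confidence=%g", attr(x, "confidence")))
  .write_tsv(as.data.frame(x), path, header_lines = hdr)
}

#' @export
write_results.concordance <- function(x, path, ...) {
  if (nrow(x) == 0L) stop("nothing to write: empty concordance table")
  hdr <- c(sprintf("# n_unique_a=%d", attr(x, "n_unique_a")),
           sprintf("# n_unique_b=%d", attr(x, "n_unique_b")),
           sprintf("# max_unique_proportion=%g",
                   attr(x, "max_unique_proportion")))
  .write_tsv(as.data.frame(x), path, header_lines = hdr)
}

.write_tsv <- function(df, path, header_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  write.table(format(df, digits = 15, scientific = NA, trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
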