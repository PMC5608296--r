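# TSV/CSV readers and writers for expression matrices, sample sheets and
# qPCR tables. TSV is the canonical dialect; CSV is accepted on read.
# Negative signals survive a round trip unchanged: zero-clamping is a
# pipeline stage, not an I/O behavior.

.sep_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read an expression matrix from TSV/CSV
#'
#' Expects unique gene identifiers in the first column and sample identifiers
#' in the header. Ragged rows, duplicate gene ids and non-numeric cells are
#' rejected with the offending line or gene named.
#'
#' @param path File path; `.csv` is read comma-separated, anything else
#'   tab-separated.
#' @return Numeric matrix (genes x samples) with dimnames.
#' @export
read_expression_matrix <- function(path) {
  sep <- .sep_for(path)
  nf <- utils::count.fields(path, sep = sep, quote = "\"")
  if (length(unique(nf)) > 1L)
    stop("parse error: ragged row(s) at line(s) ",
         paste(which(nf != nf[1]), collapse = ", "), " in ", path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("parse error: duplicate gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (nrow(vals) == 1L) num <- matrix(num, nrow = 1L,
                                      dimnames = list(NULL, colnames(vals)))
  bad <- which(is.na(num) & !(vals == "NA" | vals == ""), arr.ind = TRUE)
  if (nrow(bad))
    stop("parse error: non-numeric cell at line ", bad[1, 1] + 1L,
         " column ", bad[1, 2] + 1L, " in ", path)
  rownames(num) <- ids
  num
}

#' Write an expression matrix as TSV/CSV
#'
#' @param mat Numeric gene-by-sample matrix with dimnames.
#' @param path Output path; `.csv` writes comma-separated.
#' @param id_column Name of the gene-identifier column (default `gene_id`).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, id_column = "gene_id") {
  .check_matrix(mat, "matrix")
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = .sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

SAMPLE_GROUPS <- c("active_cd", "treated_cd", "control")
SAMPLE_POPULATIONS <- c("IEC", "IEL")

#' Read and validate a sample sheet
#'
#' Requires columns `sample_id` (unique), `group` (active_cd, treated_cd or
#' control) and `population` (IEC or IEL); additional clinical columns are
#' carried through as opaque metadata.
#'
#' @param path TSV/CSV path.
#' @return Data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, sep = .sep_for(path), header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "group", "population")
  if (!all(need %in% names(df)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad_g <- setdiff(unique(df$group), SAMPLE_GROUPS)
  if (length(bad_g))
    stop("unknown group(s): ", paste(bad_g, collapse = ", "))
  bad_p <- setdiff(unique(df$population), SAMPLE_POPULATIONS)
  if (length(bad_p))
    stop("unknown population(s): ", paste(bad_p, collapse = ", "))
  df
}

#' Write a sample sheet as TSV/CSV
#' @param sheet Data frame with `sample_id`, `group`, `population`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = .sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a wide qPCR table into long form
#'
#' Expects columns `gene_id`, `sample_id`, then one `ct_rep<k>` column per
#' replicate; missing replicate cells (`NA`) are dropped.
#'
#' @param path TSV/CSV path.
#' @return Long data frame: `gene_id`, `sample_id`, `replicate`, `ct`.
#' @export
read_qpcr_table <- function(path) {
  df <- utils::read.table(path, sep = .sep_for(path), header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  rep_cols <- grep("^ct_rep[0-9]+$", names(df), value = TRUE)
  if (!all(c("gene_id", "sample_id") %in% names(df)) || !length(rep_cols))
    stop("qPCR table needs gene_id, sample_id and ct_rep<k> columns")
  long <- do.call(rbind, lapply(seq_along(rep_cols), function(k) {
    data.frame(gene_id = df$gene_id, sample_id = df$sample_id,
               replicate = k, ct = df[[rep_cols[k]]],
               stringsAsFactors = FALSE)
  }))
  long <- long[!is.na(long$ct), ]
  long <- long[order(long$gene_id, long$sample_id, long$replicate), ]
  rownames(long) <- NULL
  .check_qpcr_table(long)
  long
}

#' Write a long qPCR table in wide replicate form
#' @param table Long data frame: `gene_id`, `sample_id`, `replicate`, `ct`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qpcr_table <- function(table, path) {
  .check_qpcr_table(table)
  wide <- stats::reshape(table, idvar = c("gene_id", "sample_id"),
                         timevar = "replicate", direction = "wide")
  names(wide) <- sub("^ct\\.", "ct_rep", names(wide))
  utils::write.table(wide, path, sep = .sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
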