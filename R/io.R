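# Plain-text interchange formats: TSV connectivity matrices and tree edge
# lists (with JSON sidecars), long-format CSV study tables and panels.
# Everything numeric is written with full precision and parsed
# locale-independently (period decimal separator, scientific notation
# accepted).

.read_table_checked <- function(path, sep, header) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = sep, header = header,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = NA, numerals = "no.loss")
}

#' Write / read a connectivity matrix as TSV
#'
#' The matrix is stored with ROI labels in the header row and first
#' column; the reader validates symmetry of labels and numeric cells.
#'
#' @param mat \code{connectivity_matrix}.
#' @param path output TSV path, conventionally
#'   \code{<subject>_<session>_<band>.plm.tsv}.
#' @export
write_connectivity_tsv <- function(mat, path) {
  stopifnot(inherits(mat, "connectivity_matrix"))
  df <- data.frame(roi = mat$roi_labels,
                   format(mat$values, digits = 17, trim = TRUE,
                          scientific = NA),
                   check.names = FALSE)
  names(df) <- c("roi", mat$roi_labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  attr(path, "band") <- mat$band
  invisible(path)
}

#' @rdname write_connectivity_tsv
#' @param band band name recorded on the returned object.
#' @return \code{read_connectivity_tsv}: a \code{connectivity_matrix}.
#' @export
read_connectivity_tsv <- function(path, band = NA_character_) {
  df <- .read_table_checked(path, "\t", TRUE)
  labels <- df[[1]]
  header <- names(df)[-1]
  if (!identical(labels, header)) {
    bad <- which(labels != header)[1]
    stop("row/column label mismatch at position ", bad, ": '", labels[bad],
         "' vs '", header[bad], "' in ", path)
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    suppressWarnings(num <- apply(df[, -1, drop = FALSE], 2, as.numeric))
    bad_cell <- which(is.na(num) & !is.na(as.matrix(df[, -1])), arr.ind = TRUE)
    if (nrow(bad_cell)) {
      stop("non-numeric cell at data line ", bad_cell[1, 1], " in ", path)
    }
    vals <- num
  }
  dimnames(vals) <- list(labels, labels)
  structure(list(band = band, roi_labels = labels, values = vals),
            class = "connectivity_matrix")
}

#' Write / read a spanning tree as a 3-column TSV edge list
#'
#' Columns \code{i}, \code{j} (0-based node indices) and \code{weight},
#' plus a JSON sidecar (\code{<path>.json}) with node labels, band and a
#' hash of the source matrix file when given.
#'
#' @param tree \code{spanning_tree}.
#' @param path output TSV path.
#' @param band,source_file optional metadata for the sidecar.
#' @export
write_tree_tsv <- function(tree, path, band = NULL, source_file = NULL) {
  stopifnot(inherits(tree, "spanning_tree"))
  df <- data.frame(i = tree$edges$i - 1L, j = tree$edges$j - 1L,
                   weight = tree$edges$weight)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(n_nodes = tree$n_nodes, labels = tree$labels, band = band)
  if (!is.null(source_file) && file.exists(source_file)) {
    sidecar$source_hash <- unname(tools::md5sum(source_file))
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_tree_tsv
#' @return \code{read_tree_tsv}: a \code{spanning_tree}.
#' @export
read_tree_tsv <- function(path) {
  df <- .read_table_checked(path, "\t", TRUE)
  if (!all(c("i", "j", "weight") %in% names(df))) {
    stop("tree edge list must have columns i, j, weight: ", path)
  }
  sidecar_path <- paste0(path, ".json")
  labels <- NULL
  n_nodes <- max(df$i, df$j) + 1L
  if (file.exists(sidecar_path)) {
    meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    n_nodes <- meta$n_nodes
    labels <- meta$labels
  }
  structure(list(n_nodes = as.integer(n_nodes), labels = labels,
                 edges = data.frame(i = df$i + 1L, j = df$j + 1L,
                                    weight = df$weight)),
            class = "spanning_tree")
}

#' Write / read a long-format study table or panel CSV
#'
#' Canonical long format: \code{subject,session,variable,value}. The
#' reader rejects malformed files with the offending line number.
#'
#' @param table data.frame with the four canonical columns.
#' @param path CSV path.
#' @export
write_study_table <- function(table, path) {
  need <- c("subject", "session", "variable", "value")
  stopifnot(all(need %in% names(table)))
  tb <- table[, need]
  tb$value <- format(tb$value, digits = 17, trim = TRUE, scientific = NA)
  utils::write.table(tb, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_study_table
#' @return \code{read_study_table}: the parsed data.frame.
#' @export
read_study_table <- function(path) {
  df <- .read_table_checked(path, ",", TRUE)
  need <- c("subject", "session", "variable", "value")
  if (!all(need %in% names(df))) {
    stop("study table must have header subject,session,variable,value: ",
         path)
  }
  suppressWarnings(v <- as.numeric(df$value))
  if (any(is.na(v) & !is.na(df$value))) {
    bad <- which(is.na(v) & !is.na(df$value))[1]
    stop("non-numeric value at data line ", bad, " in ", path)
  }
  df$value <- v
  df
}

# hormone/psych long panels reuse the study-table CSV layout with
# 'hormone' or 'variable' as the variable column
panel_to_study_table <- function(panel) {
  if ("hormone" %in% names(panel)) {
    data.frame(subject = panel$subject, session = panel$session,
               variable = panel$hormone, value = panel$value)
  } else {
    panel[, c("subject", "session", "variable", "value")]
  }
}

#' Hash of a configuration object
#'
#' MD5 of the canonical JSON serialization; used in run manifests so a
#' result can be traced to the exact configuration that produced it.
#'
#' @param config any serializable object.
#' @return hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- unclass(config)
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}
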