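#' Read a metabolite intensity table from delimited text
#'
#' Expects one header row and one leading identifier column. Empty cells,
#' `"NA"` and `"NaN"` are treated as missing. The delimiter is chosen from
#' the file extension (`.csv` -> comma, otherwise tab) unless `sep` is
#' given. The returned matrix is always oriented metabolites x samples.
#'
#' @param path File path.
#' @param orientation `"metabolites_in_rows"` (default) or
#'   `"samples_in_rows"`; the latter is transposed on read.
#' @param sep Optional delimiter override.
#' @return Numeric matrix with metabolite rownames and sample colnames.
#' @export
read_intensity_table <- function(path,
                                 orientation = c("metabolites_in_rows",
                                                 "samples_in_rows"),
                                 sep = NULL) {
  orientation <- match.arg(orientation)
  sep <- sep %||% guess_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA", "NaN"),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"", fill = FALSE)
  ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (orientation == "samples_in_rows") mat <- t(mat)
  validate_intensity_table(mat)
  mat
}

#' Write an intensity table as delimited text
#'
#' @param mat Metabolites x samples matrix.
#' @param path Output path; `.csv` writes comma-separated, anything else tab.
#' @param id_column Header for the identifier column.
#' @export
write_intensity_table <- function(mat, path, id_column = "metabolite_id") {
  validate_intensity_table(mat)
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = guess_sep(path), quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

validate_intensity_table <- function(mat) {
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("intensity table must carry metabolite rownames and sample colnames")
  }
  dup_m <- rownames(mat)[duplicated(rownames(mat))]
  if (length(dup_m)) {
    stop("duplicate metabolite identifier(s): ",
         paste(unique(dup_m), collapse = ", "))
  }
  dup_s <- colnames(mat)[duplicated(colnames(mat))]
  if (length(dup_s)) {
    stop("duplicate sample identifier(s): ",
         paste(unique(dup_s), collapse = ", "))
  }
  if (any(mat < 0, na.rm = TRUE)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative intensity at metabolite '%s', sample '%s'",
                 rownames(mat)[bad[1L]], colnames(mat)[bad[2L]]))
  }
  invisible(mat)
}

#' Read a sample annotation table
#'
#' One row per sample. Requires at least a `sample_id` column; the
#' canonical factor columns (`origin`, `host`, `passage`, `pigmentation`,
#' `braf`, `sex`, `site_class`, `batch`) are validated when present:
#' `host` must be human/mouse and `host == "human"` iff `passage == 0`.
#'
#' @param path File path (CSV/TSV by extension).
#' @param sep Optional delimiter override.
#' @return data.frame with one row per sample.
#' @export
read_sample_annotation <- function(path, sep = NULL) {
  sep <- sep %||% guess_sep(path)
  ann <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = c("", "NA"),
                           stringsAsFactors = FALSE, check.names = FALSE,
                           fill = FALSE)
  validate_sample_annotation(ann)
  ann
}

#' @rdname read_sample_annotation
#' @param ann Annotation data.frame to validate or write.
#' @export
validate_sample_annotation <- function(ann) {
  if (!"sample_id" %in% names(ann)) {
    stop("annotation must contain a 'sample_id' column")
  }
  dup <- ann$sample_id[duplicated(ann$sample_id)]
  if (length(dup)) {
    stop("duplicate sample_id(s): ", paste(unique(dup), collapse = ", "))
  }
  if ("host" %in% names(ann)) {
    bad <- setdiff(unique(ann$host), c("human", "mouse"))
    if (length(bad)) stop("invalid host value(s): ", paste(bad, collapse = ", "))
    if ("passage" %in% names(ann)) {
      viol <- (ann$host == "human") != (ann$passage == 0L)
      if (any(viol)) {
        stop("host/passage inconsistency (human iff passage 0) for sample(s): ",
             paste(ann$sample_id[viol], collapse = ", "))
      }
    }
  }
  invisible(ann)
}

#' @rdname read_sample_annotation
#' @export
write_sample_annotation <- function(ann, path) {
  validate_sample_annotation(ann)
  utils::write.table(ann, path, sep = guess_sep(path), quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Check that every table sample is annotated
#'
#' @param mat Intensity (or normalized) matrix, samples in columns.
#' @param ann Sample annotation data.frame.
#' @return The annotation subset, reordered to match `colnames(mat)`.
#' @export
align_annotation <- function(mat, ann) {
  validate_sample_annotation(ann)
  missing <- setdiff(colnames(mat), ann$sample_id)
  if (length(missing)) {
    stop("sample(s) absent from annotation: ", paste(missing, collapse = ", "))
  }
  ann[match(colnames(mat), ann$sample_id), , drop = FALSE]
}

#' Read a metabolite-set collection in GMT format
#'
#' One set per line: name, description, then member identifiers, all
#' TAB-separated. Duplicate members within a set are removed with a
#' warning; a line with fewer than three fields is a parse error; empty
#' sets are rejected.
#'
#' @param path GMT file path.
#' @return Named list of class `"metabolite_sets"`; each element is a list
#'   with `description` and `members` (character vector, order preserved).
#' @export
read_metabolite_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT parse error at line %d: expected >= 3 TAB-separated fields, got %d",
                   i, length(fields)))
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) {
      stop(sprintf("GMT parse error at line %d: set '%s' is empty",
                   i, fields[1L]))
    }
    if (anyDuplicated(members)) {
      warning(sprintf("set '%s': duplicate members removed", fields[1L]))
      members <- unique(members)
    }
    if (fields[1L] %in% names(sets)) {
      stop(sprintf("duplicate set name '%s' at line %d", fields[1L], i))
    }
    sets[[fields[1L]]] <- list(description = fields[2L], members = members)
  }
  structure(sets, class = "metabolite_sets")
}

#' @rdname read_metabolite_sets
#' @param sets A `"metabolite_sets"` collection.
#' @export
write_metabolite_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, sets[[nm]]$description, sets[[nm]]$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
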