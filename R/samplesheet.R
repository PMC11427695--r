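#' Parse and validate a sample sheet
#'
#' Reads a tab-separated sample sheet mapping sample IDs to their index
#' sequences. Mandatory columns are `sample_id` and `i7`; optional columns are
#' `i5` (dual index), `template` (per-sample barcode-template override for
#' mixed libraries) and `project`. Unknown columns are ignored with a warning.
#' Index sequences are upper-cased on read; matching downstream is therefore
#' case-insensitive.
#'
#' A sample ID may appear on several rows with distinct indices ("index
#' diversity"): all of that sample's reads are routed to the same output
#' files. Within one template group all i7 must have equal length (and
#' likewise all i5), and no two rows of a group may carry the identical
#' (i7, i5) pair, which would make them inseparable.
#'
#' @param source Path to a TSV file, or a character vector of lines.
#' @return A `mgi_sample_sheet`: a data frame with columns `sample_id`, `i7`,
#'   `i5` (NA when single-index), `template` (NA unless overridden) and
#'   `project`, rows in file order.
#' @export
parse_sample_sheet <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\t|\n", source)) {
    if (!file.exists(source)) {
      stop_io(sprintf("sample sheet not found: '%s'", source))
    }
    readLines(source)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop_validation("sample sheet needs a header line and at least one record")
  }

  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  header <- trimws(header)
  known <- c("sample_id", "i7", "i5", "template", "project")
  missing <- setdiff(c("sample_id", "i7"), header)
  if (length(missing)) {
    stop_validation(sprintf(
      "sample sheet is missing mandatory column(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  unknown <- setdiff(header, known)
  if (length(unknown)) {
    warning(sprintf(
      "ignoring unknown sample-sheet column(s): %s",
      paste(unknown, collapse = ", ")
    ), call. = FALSE)
  }

  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  get_col <- function(name) {
    idx <- match(name, header)
    if (is.na(idx)) {
      return(rep(NA_character_, length(fields)))
    }
    out <- vapply(fields, function(f) {
      if (length(f) >= idx) trimws(f[[idx]]) else ""
    }, character(1))
    out[!nzchar(out)] <- NA_character_
    out
  }

  sheet <- data.frame(
    sample_id = get_col("sample_id"),
    i7 = toupper(get_col("i7")),
    i5 = toupper(get_col("i5")),
    template = get_col("template"),
    project = get_col("project"),
    stringsAsFactors = FALSE
  )
  validate_sample_sheet(sheet)
}

validate_sample_sheet <- function(sheet) {
  n <- nrow(sheet)
  if (n == 0L) {
    stop_validation("sample sheet has no records")
  }
  if (anyNA(sheet$sample_id) || any(!nzchar(sheet$sample_id))) {
    stop_validation("every record needs a non-empty sample_id")
  }
  # line numbers in the original file: header is line 1
  for (col in c("i7", "i5")) {
    v <- sheet[[col]]
    present <- !is.na(v)
    if (col == "i7" && !all(present)) {
      stop_validation(sprintf(
        "missing i7 index on line(s) %s",
        paste(which(!present) + 1L, collapse = ", ")
      ))
    }
    bad <- present & grepl("[^ACGT]", v)
    if (any(bad)) {
      stop_validation(sprintf(
        "invalid character in %s index on line %d ('%s'): indices must be A/C/G/T only",
        col, which(bad)[1L] + 1L, v[which(bad)[1L]]
      ))
    }
  }
  mixed_i5 <- !all(is.na(sheet$i5)) && anyNA(sheet$i5)
  if (mixed_i5) {
    stop_validation("either all records carry an i5 index or none do")
  }

  groups <- template_group_of(sheet)
  for (g in unique(groups)) {
    rows <- which(groups == g)
    if (length(unique(nchar(sheet$i7[rows]))) > 1L) {
      stop_validation(sprintf(
        "i7 indices of unequal length within template group '%s'", g
      ))
    }
    i5g <- sheet$i5[rows]
    if (!all(is.na(i5g)) && length(unique(nchar(i5g))) > 1L) {
      stop_validation(sprintf(
        "i5 indices of unequal length within template group '%s'", g
      ))
    }
    key <- paste(sheet$i7[rows], ifelse(is.na(i5g), "", i5g), sep = "+")
    dup <- duplicated(key)
    if (any(dup)) {
      first <- rows[match(key[dup][1L], key)]
      second <- rows[dup][1L]
      stop_validation(sprintf(
        "duplicate index pair for rows %d ('%s') and %d ('%s'): samples would be inseparable",
        first + 1L, sheet$sample_id[first], second + 1L, sheet$sample_id[second]
      ))
    }
  }
  class(sheet) <- c("mgi_sample_sheet", "data.frame")
  sheet
}

# Template-group label per record: the override string, or "" for the
# default group (resolved against the run-level template at demux time).
template_group_of <- function(sheet) {
  ifelse(is.na(sheet$template), "", sheet$template)
}

#' Serialize a sample sheet back to TSV lines
#'
#' Inverse of [parse_sample_sheet()]: `parse_sample_sheet(format_sample_sheet(x))`
#' reproduces `x` for any valid sheet.
#'
#' @param sheet A `mgi_sample_sheet`.
#' @return Character vector of TSV lines (header first).
#' @export
format_sample_sheet <- function(sheet) {
  cols <- c("sample_id", "i7")
  for (opt in c("i5", "template", "project")) {
    if (!all(is.na(sheet[[opt]]))) cols <- c(cols, opt)
  }
  body <- apply(sheet[, cols, drop = FALSE], 1L, function(r) {
    r[is.na(r)] <- ""
    paste(r, collapse = "\t")
  })
  c(paste(cols, collapse = "\t"), unname(body))
}

#' Write a sample sheet to a TSV file
#'
#' @param sheet A `mgi_sample_sheet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  writeLines(format_sample_sheet(sheet), path)
  invisible(path)
}

#' @export
print.mgi_sample_sheet <- function(x, ...) {
  dual <- !all(is.na(x$i5))
  cat(sprintf(
    "Sample sheet: %d record(s), %d sample(s), %s index\n",
    nrow(x), length(unique(x$sample_id)), if (dual) "dual" else "single"
  ))
  print.data.frame(x, ...)
  invisible(x)
}

# Sample number (S1, S2, ...) by order of first appearance of the sample_id.
sample_numbers <- function(sheet) {
  ids <- unique(sheet$sample_id)
  stats::setNames(seq_along(ids), ids)
}
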