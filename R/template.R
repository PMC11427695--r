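#' Parse a barcode-template specification
#'
#' A barcode template describes the non-biological tail of the barcode-bearing
#' read (R2 for paired-end MGI runs, R1 for single-end): which segments (i7,
#' i5, UMI) it contains, in 5'->3' order, their lengths, and whether an index
#' segment is sequenced in reverse-complement orientation relative to the
#' sample sheet. The specification syntax is colon-separated
#' `<kind>[rc].<length>` segments with kinds `i7`, `i5`, `um`, e.g.
#' `"i5rc.8:i7.8:um.8"`.
#'
#' @param spec Template specification string, or an existing
#'   `mgi_barcode_template` (returned unchanged).
#' @return An `mgi_barcode_template`: data frame with columns `kind`
#'   (i7/i5/umi), `length` and `rc`, one row per segment in read order.
#' @examples
#' parse_template("i7.8:i5.8")
#' parse_template("i5rc.8:i7.8:um.8")
#' @export
parse_template <- function(spec) {
  if (inherits(spec, "mgi_barcode_template")) {
    return(spec)
  }
  if (length(spec) != 1L || !is.character(spec) || !nzchar(spec)) {
    stop_validation("template spec must be a single non-empty string")
  }
  parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^(i7|i5|um)(rc)?\\.([0-9]+)$", parts))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop_validation(sprintf(
      "cannot parse template segment '%s' (expected <i7|i5|um>[rc].<length>)",
      parts[bad][1L]
    ))
  }
  kind <- vapply(m, `[[`, character(1), 2L)
  rc <- vapply(m, `[[`, character(1), 3L) == "rc"
  len <- as.integer(vapply(m, `[[`, character(1), 4L))
  kind[kind == "um"] <- "umi"
  if (any(len < 1L)) {
    stop_validation("template segment lengths must be >= 1")
  }
  if (any(rc & kind == "umi")) {
    stop_validation("a UMI segment has no orientation: 'umrc' is invalid")
  }
  if (anyDuplicated(kind)) {
    stop_validation("each segment kind may appear at most once in a template")
  }
  if (!"i7" %in% kind) {
    stop_validation("a template must contain an i7 segment")
  }
  structure(
    data.frame(kind = kind, length = len, rc = rc, stringsAsFactors = FALSE),
    class = c("mgi_barcode_template", "data.frame")
  )
}

#' Format a barcode template back to its spec string
#'
#' Inverse of [parse_template()].
#'
#' @param t An `mgi_barcode_template`.
#' @return The spec string, e.g. `"i5rc.8:i7.8:um.8"`.
#' @export
format_template <- function(t) {
  kind <- ifelse(t$kind == "umi", "um", t$kind)
  paste0(kind, ifelse(t$rc, "rc", ""), ".", t$length, collapse = ":")
}

#' @export
print.mgi_barcode_template <- function(x, ...) {
  cat(sprintf(
    "Barcode template %s (%d bp)\n", format_template(x),
    expected_barcode_length(x)
  ))
  invisible(x)
}

#' Expected read-barcode length of a template
#'
#' The read barcode is the sum of its segment lengths: a dual 8 bp + 8 bp
#' index with no UMI gives a 16 bp barcode.
#'
#' @param t An `mgi_barcode_template` (or spec string).
#' @return Barcode length in bp.
#' @export
expected_barcode_length <- function(t) {
  t <- parse_template(t)
  sum(t$length)
}

#' Enumerate candidate barcode templates
#'
#' Builds every template compatible with the sheet's index lengths and the
#' observed barcode length: all orderings of the present index segments, all
#' reverse-complement on/off combinations per index segment, and — when the
#' barcode is longer than the indices — a single UMI segment covering the
#' whole remainder, placed in any gap (before, between, or after the index
#' segments).
#'
#' @param i7_len i7 length (bp).
#' @param i5_len i5 length (bp) or `NULL` for single-index.
#' @param barcode_len Total read-barcode length (bp).
#' @return List of `mgi_barcode_template`, deduplicated.
#' @export
enumerate_candidates <- function(i7_len, i5_len = NULL, barcode_len) {
  idx_lens <- c(i7 = as.integer(i7_len))
  if (!is.null(i5_len) && !is.na(i5_len)) {
    idx_lens <- c(idx_lens, i5 = as.integer(i5_len))
  }
  remainder <- barcode_len - sum(idx_lens)
  if (remainder < 0L) {
    stop_validation(sprintf(
      "barcode length %d bp is shorter than the combined index length %d bp",
      barcode_len, sum(idx_lens)
    ))
  }

  orders <- if (length(idx_lens) == 2L) {
    list(c("i7", "i5"), c("i5", "i7"))
  } else {
    list("i7")
  }
  out <- list()
  for (ord in orders) {
    rc_grid <- expand.grid(
      rep(list(c(FALSE, TRUE)), length(ord)),
      KEEP.OUT.ATTRS = FALSE
    )
    for (g in seq_len(nrow(rc_grid))) {
      rcs <- as.logical(rc_grid[g, ])
      slots <- if (remainder > 0L) 0:length(ord) else -1L
      for (slot in slots) {
        kind <- ord
        len <- unname(idx_lens[ord])
        rc <- rcs
        if (slot >= 0L) {
          kind <- append(kind, "umi", after = slot)
          len <- append(len, remainder, after = slot)
          rc <- append(rc, FALSE, after = slot)
        }
        out[[length(out) + 1L]] <- structure(
          data.frame(kind = kind, length = len, rc = rc,
                     stringsAsFactors = FALSE),
          class = c("mgi_barcode_template", "data.frame")
        )
      }
    }
  }
  specs <- vapply(out, format_template, character(1))
  out[!duplicated(specs)]
}

# Slice the index segments out of equal-length barcode strings according to a
# template; rc-flagged observations are reverse-complemented so they compare
# directly against the sample sheet. Returns list(i7=, i5=NULL|chr, umi=).
extract_template_fields <- function(barcodes, template) {
  offsets <- cumsum(c(0L, template$length))
  out <- list(i7 = NULL, i5 = NULL, umi = NULL)
  for (s in seq_len(nrow(template))) {
    piece <- substr(barcodes, offsets[s] + 1L, offsets[s + 1L])
    if (template$kind[s] != "umi" && template$rc[s]) {
      piece <- reverse_complement(piece)
    }
    out[[template$kind[s]]] <- piece
  }
  out
}

#' Detect the barcode template from read data
#'
#' Scores every candidate template (see [enumerate_candidates()]) by the
#' number of sampled read barcodes whose extracted indices exactly match a
#' sample-sheet record, and ranks candidates by that count. The top-ranked
#' template is the inferred layout; a warning is raised when even the best
#' candidate matches fewer than half of the sampled reads, which usually
#' means the sheet or the assumed barcode length is wrong.
#'
#' @param barcodes Character vector of read-barcode strings (the last
#'   `barcode_len` bases of the barcode-bearing mate), all equal length.
#' @param sheet A `mgi_sample_sheet`.
#' @param limit Number of barcodes to sample from the head (default 5000).
#' @return An `mgi_template_scores` data frame: `template` (spec string),
#'   `matches`, `sampled_reads`, ranked by matches descending (ties broken by
#'   spec-string order, all ties reported). Attribute `per_sample` holds the
#'   per-sample match counts under the best template, a hint for spotting
#'   mixed libraries.
#' @export
detect_template <- function(barcodes, sheet, limit = 5000L) {
  if (length(barcodes) == 0L) {
    stop_validation("no reads supplied for template detection")
  }
  if (nrow(sheet) == 0L) {
    stop_validation("empty sample sheet")
  }
  if (limit < 1L) {
    stop_validation("limit must be >= 1")
  }
  barcodes <- utils::head(toupper(barcodes), limit)
  blen <- unique(nchar(barcodes))
  if (length(blen) != 1L) {
    stop_validation("read barcodes of unequal length")
  }

  dual <- !all(is.na(sheet$i5))
  i7_len <- unique(nchar(sheet$i7))
  i5_len <- if (dual) unique(nchar(sheet$i5)) else NULL
  if (length(i7_len) != 1L || (dual && length(i5_len) != 1L)) {
    stop_validation(
      "template detection requires uniform index lengths across the sheet"
    )
  }

  sheet_keys <- paste0(sheet$i7, if (dual) sheet$i5 else "")
  candidates <- enumerate_candidates(i7_len, i5_len, blen)
  specs <- vapply(candidates, format_template, character(1))

  matches <- integer(length(candidates))
  per_sample_best <- NULL
  for (ci in seq_along(candidates)) {
    fields <- extract_template_fields(barcodes, candidates[[ci]])
    keys <- paste0(fields$i7, if (dual) fields$i5 else "")
    matches[ci] <- sum(keys %in% sheet_keys)
  }

  ord <- order(-matches, specs)
  scores <- data.frame(
    template = specs[ord],
    matches = matches[ord],
    sampled_reads = length(barcodes),
    stringsAsFactors = FALSE
  )

  best <- candidates[[ord[1L]]]
  fields <- extract_template_fields(barcodes, best)
  keys <- paste0(fields$i7, if (dual) fields$i5 else "")
  hit <- match(keys, sheet_keys)
  per_sample <- table(factor(sheet$sample_id[hit[!is.na(hit)]],
                             levels = unique(sheet$sample_id)))
  attr(scores, "per_sample") <- per_sample

  if (scores$matches[1L] < 0.5 * length(barcodes)) {
    warning(sprintf(
      paste0(
        "low-confidence template detection: best candidate matches only ",
        "%d of %d sampled reads"
      ),
      scores$matches[1L], length(barcodes)
    ), call. = FALSE)
  }
  class(scores) <- c("mgi_template_scores", "data.frame")
  scores
}
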