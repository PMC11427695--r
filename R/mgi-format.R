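#' Parse MGI read headers
#'
#' MGI (DNBSEQ) FASTQ headers encode the flowcell, lane, DNB coordinates and a
#' running serial: `@<flowcell>L<lane>C<col:3>R<row:3><serial>/<mate>`, e.g.
#' `@V300014293L2C001R0030000123/1`.
#'
#' @param headers Character vector of header lines (leading `@` included).
#' @return Data frame with columns `flowcell`, `lane`, `column`, `row`,
#'   `serial`, `mate` (numeric fields as integers).
#' @export
parse_mgi_read_id <- function(headers) {
  pat <- "^@(.+)L([0-9])C([0-9]{3})R([0-9]{3})([0-9]+)/([12])$"
  ok <- grepl(pat, headers)
  if (!all(ok)) {
    stop_validation(sprintf(
      "read header '%s' is not in MGI format (@<flowcell>L<lane>C<col>R<row><serial>/<mate>)",
      headers[!ok][1L]
    ))
  }
  data.frame(
    flowcell = sub(pat, "\\1", headers),
    lane = as.integer(sub(pat, "\\2", headers)),
    column = as.integer(sub(pat, "\\3", headers)),
    row = as.integer(sub(pat, "\\4", headers)),
    serial = as.integer(sub(pat, "\\5", headers)),
    mate = as.integer(sub(pat, "\\6", headers)),
    stringsAsFactors = FALSE
  )
}

# Compose an MGI header from parsed fields (simulator + tests share the
# grammar with the parser).
compose_mgi_read_id <- function(flowcell, lane, column, row, serial, mate) {
  sprintf(
    "@%sL%dC%03dR%03d%07d/%d",
    flowcell, lane, column, row, serial, mate
  )
}

#' Rewrite a read header in the chosen output dialect
#'
#' Under the `mgi` dialect the original header is kept verbatim (a templated
#' UMI is appended to the read id after `#`, before the `/mate` suffix).
#' Under the `illumina` dialect the MGI fields are mapped onto a syntactic
#' Illumina header
#' `@<flowcell>:1:<flowcell>:<lane>:<tile>:<x>:<y>[:<umi>] <mate>:N:0:<index>`
#' with `tile = column*1000 + row`, `x = serial`, `y = 1`; the index
#' annotation is the assigned sample's expected `i7[+i5]`, or the literal
#' `undetermined`.
#'
#' @param id Data frame as returned by [parse_mgi_read_id()] (vectorised).
#' @param dialect `"illumina"` or `"mgi"`.
#' @param umi Optional UMI string(s) (`NA`/`NULL` = none).
#' @param index_annot Index annotation string(s).
#' @param original Original header line(s), required for the `mgi` dialect.
#' @return Character vector of header lines.
#' @export
format_output_id <- function(id, dialect = c("illumina", "mgi"), umi = NULL,
                             index_annot = "undetermined", original = NULL) {
  dialect <- match.arg(dialect)
  has_umi <- !is.null(umi) && length(umi) > 0L
  if (has_umi) {
    umi_ok <- !is.na(umi) & nzchar(umi)
  }
  if (dialect == "mgi") {
    if (is.null(original)) {
      original <- compose_mgi_read_id(
        id$flowcell, id$lane, id$column, id$row, id$serial, id$mate
      )
    }
    if (has_umi && any(umi_ok)) {
      tagged <- sub("/([12])$", paste0("#", umi, "/\\1"), original)
      original[umi_ok] <- tagged[umi_ok]
    }
    return(original)
  }
  umi_part <- ""
  if (has_umi) {
    umi_part <- ifelse(umi_ok, paste0(":", umi), "")
  }
  sprintf(
    "@%s:1:%s:%d:%d:%d:1%s %d:N:0:%s",
    id$flowcell, id$flowcell, id$lane, id$column * 1000L + id$row,
    id$serial, umi_part, id$mate, index_annot
  )
}

#' Output FASTQ file name for a demultiplexed sample
#'
#' Illumina-style naming is `<sample>_S<number>_L<lane:03d>_R<mate>_001.fastq.gz`;
#' MGI-style naming is `<flowcell>_L<lane:02d>_<sample>_<mate>.fq.gz`.
#' Unassigned reads go to sample `Undetermined` (number 0); ambiguous reads to
#' `Ambiguous` when routed separately.
#'
#' @param sample_id Sample label.
#' @param sample_number 1-based sample number (order of first appearance in
#'   the sheet); 0 for `Undetermined`/`Ambiguous`.
#' @param lane Lane number.
#' @param mate 1 or 2.
#' @param dialect `"illumina"` or `"mgi"`.
#' @param flowcell Flowcell label (MGI dialect only).
#' @return File name (no directory).
#' @export
output_path <- function(sample_id, sample_number, lane, mate,
                        dialect = c("illumina", "mgi"), flowcell = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "illumina") {
    sprintf(
      "%s_S%d_L%03d_R%d_001.fastq.gz",
      sample_id, sample_number, lane, mate
    )
  } else {
    if (is.null(flowcell)) {
      stop_validation("MGI-dialect file naming requires the flowcell label")
    }
    sprintf("%s_L%02d_%s_%d.fq.gz", flowcell, lane, sample_id, mate)
  }
}
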