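#' Extract barcode fields from a read
#'
#' The read barcode occupies the last `expected_barcode_length(template)`
#' bases of the barcode-bearing mate (R2 for paired-end, R1 for single-end).
#' Segments are sliced 5'->3' within that region; index observations from
#' reverse-complement segments are flipped back before comparison with the
#' sample sheet, and the barcode region is removed from the returned trimmed
#' read.
#'
#' @param sequence Read sequence(s), character vector.
#' @param quality Matching quality string(s) (optional, trimmed alongside).
#' @param template An `mgi_barcode_template` or spec string.
#' @return List with `i7_obs`, `i5_obs` (`NULL` for single index), `umi`
#'   (`NULL` when untemplated), `barcode` (raw observed region) and `trimmed`
#'   (list with `sequence` and `quality`).
#' @export
extract_barcode <- function(sequence, quality = NULL, template) {
  template <- parse_template(template)
  blen <- expected_barcode_length(template)
  n <- nchar(sequence)
  if (any(n < blen)) {
    stop_validation(sprintf(
      "read of length %d is shorter than the %d bp barcode template",
      min(n), blen
    ))
  }
  barcode <- substr(sequence, n - blen + 1L, n)
  fields <- extract_template_fields(barcode, template)
  trimmed_seq <- substr(sequence, 1L, n - blen)
  trimmed_qual <- if (!is.null(quality)) substr(quality, 1L, n - blen)
  list(
    i7_obs = fields$i7,
    i5_obs = fields$i5,
    umi = fields$umi,
    barcode = barcode,
    trimmed = list(sequence = trimmed_seq, quality = trimmed_qual)
  )
}

#' Assign one read from its observed indices
#'
#' A single dictionary fetch on the concatenated observation: an entry
#' pointing at one sample gives a `sample` verdict, an entry tied between
#' distinct samples at the minimal distance gives `ambiguous`, and no entry
#' gives `undetermined`.
#'
#' @param i7_obs Observed i7 (sheet orientation).
#' @param i5_obs Observed i5, or `NULL` for single index.
#' @param table An `mgi_index_lookup`.
#' @return List with `verdict` (`sample`/`ambiguous`/`undetermined`),
#'   `record` (sheet row, `NA` unless a sample), `sample_id`, `d7`, `d5`.
#' @export
assign_read <- function(i7_obs, i5_obs = NULL, table) {
  key <- paste0(i7_obs, i5_obs %||% "")
  entry <- lookup_index(table, key)
  if (is.null(entry)) {
    return(list(verdict = "undetermined", record = NA_integer_,
                sample_id = NA_character_, d7 = NA_integer_,
                d5 = NA_integer_))
  }
  if (entry$ambiguous) {
    return(list(verdict = "ambiguous", record = NA_integer_,
                sample_id = NA_character_, d7 = entry$d7, d5 = entry$d5))
  }
  list(verdict = "sample", record = entry$records,
       sample_id = entry$sample_ids, d7 = entry$d7, d5 = entry$d5)
}

# ---- streaming engine ------------------------------------------------------

# Read one chunk of 4-line FASTQ records from an open connection.
read_fastq_chunk <- function(con, n_records) {
  lines <- readLines(con, n = 4L * n_records)
  if (length(lines) == 0L) {
    return(NULL)
  }
  if (length(lines) %% 4L != 0L) {
    stop_validation("truncated FASTQ input: record count is not a multiple of 4 lines")
  }
  k <- length(lines) / 4L
  list(
    header = lines[seq(1L, by = 4L, length.out = k)],
    sequence = lines[seq(2L, by = 4L, length.out = k)],
    quality = lines[seq(4L, by = 4L, length.out = k)],
    n = k
  )
}

# Buffered gzip writers: one open connection per output file, lines appended
# to an in-memory buffer flushed once it exceeds `buffer_lines`.
writer_pool <- function(out_dir, buffer_lines) {
  pool <- new.env(parent = emptyenv())
  list(
    add = function(file, lines) {
      w <- pool[[file]]
      if (is.null(w)) {
        w <- list(
          con = gzfile(file.path(out_dir, file), open = "wb"),
          buf = list()
        )
      }
      w$buf[[length(w$buf) + 1L]] <- lines
      if (sum(lengths(w$buf)) >= buffer_lines) {
        writeLines(unlist(w$buf, use.names = FALSE), w$con)
        w$buf <- list()
      }
      pool[[file]] <- w
    },
    close_all = function() {
      for (file in ls(pool)) {
        w <- pool[[file]]
        if (length(w$buf)) {
          writeLines(unlist(w$buf, use.names = FALSE), w$con)
        }
        close(w$con)
      }
      sort(ls(pool))
    }
  )
}

open_fastq <- function(path) {
  if (!file.exists(path)) {
    stop_io(sprintf("input FASTQ not found: '%s'", path))
  }
  con <- gzfile(path, open = "rt")
  con
}

#' Demultiplex an MGI FASTQ run
#'
#' Streams the input FASTQ file(s), extracts the read barcode from the tail
#' of the barcode-bearing mate (R2 for paired-end, R1 for single-end),
#' assigns each read through the mismatch-expansion lookup table, trims the
#' barcode from the barcode mate, rewrites headers and file names in the
#' requested dialect (UMIs, when templated, are carried into both mates'
#' headers) and writes per-sample gzip FASTQ preserving the input read order
#' exactly. Unassigned reads go to `Undetermined` files; ambiguous reads are
#' counted separately and either share the `Undetermined` files (default) or
#' get their own `Ambiguous` files.
#'
#' Per-record `template` overrides in the sample sheet partition it into
#' template groups (mixed libraries); each group gets its own lookup, a read
#' is assigned to the unique group yielding a sample verdict, and sample
#' verdicts from two or more groups make it ambiguous.
#'
#' @param r1 Path to the R1 FASTQ (gzip or plain).
#' @param r2 Optional path to the R2 FASTQ (paired-end).
#' @param sample_sheet A `mgi_sample_sheet` or path to one.
#' @param template Barcode template (`mgi_barcode_template` or spec string)
#'   for records without a per-record override.
#' @param m7,m5 Per-index mismatch allowances (defaults 1).
#' @param dialect Output dialect, `"illumina"` (default) or `"mgi"`.
#' @param output_dir Directory for the demultiplexed FASTQ (created if
#'   needed).
#' @param lane Optional forced lane label; without it the lane is taken from
#'   the read headers and mixed lanes in one file are an error.
#' @param separate_ambiguous Route ambiguous reads to their own files.
#' @param report_prefix File-name prefix for the report files written under
#'   `output_dir`, or `NULL` to skip writing reports.
#' @param chunk_size Reads per streaming chunk (default 10000).
#' @param buffer_lines Output buffer flush threshold in lines per file.
#' @param top_undetermined How many top undetermined barcodes to report.
#' @param keep_assignments Also return the per-read assignment table
#'   (serial, verdict, sample_id, d7, d5, umi) as attribute `assignments`.
#' @param max_keys Lookup-table size cap, see [build_lookup()].
#' @return An `mgi_run_report` (invisibly the same object written by
#'   [write_reports()] when `report_prefix` is set).
#' @export
demultiplex_run <- function(r1, r2 = NULL, sample_sheet, template = NULL,
                            m7 = 1L, m5 = 1L,
                            dialect = c("illumina", "mgi"),
                            output_dir, lane = NULL,
                            separate_ambiguous = FALSE,
                            report_prefix = NULL,
                            chunk_size = 10000L,
                            buffer_lines = 40000L,
                            top_undetermined = 50L,
                            keep_assignments = FALSE,
                            max_keys = 5e7) {
  dialect <- match.arg(dialect)
  sheet <- if (inherits(sample_sheet, "mgi_sample_sheet")) {
    sample_sheet
  } else {
    parse_sample_sheet(sample_sheet)
  }
  paired <- !is.null(r2)
  if (!dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }

  # template groups: per-record overrides plus the run-level default
  labels <- template_group_of(sheet)
  groups <- lapply(unique(labels), function(lab) {
    rows <- which(labels == lab)
    tmpl <- if (nzchar(lab)) {
      parse_template(lab)
    } else {
      if (is.null(template)) {
        stop_validation(
          "no barcode template given and the sample sheet has records without a template override"
        )
      }
      parse_template(template)
    }
    list(
      rows = rows,
      template = tmpl,
      blen = expected_barcode_length(tmpl),
      lookup = build_lookup(sheet, rows, m7 = m7, m5 = m5,
                            max_keys = max_keys)
    )
  })
  mmax <- as.integer(m7) + if (all(is.na(sheet$i5))) 0L else as.integer(m5)
  numbers <- sample_numbers(sheet)

  con1 <- open_fastq(r1)
  on.exit(try(close(con1), silent = TRUE), add = TRUE)
  con2 <- NULL
  if (paired) {
    con2 <- open_fastq(r2)
    on.exit(try(close(con2), silent = TRUE), add = TRUE)
  }

  report <- empty_lane_report(
    lane = NA, sample_ids = unique(sheet$sample_id), mmax = mmax
  )
  writers <- writer_pool(output_dir, buffer_lines)
  assignments <- if (keep_assignments) list()
  flowcell <- NULL
  lane_label <- lane
  ordinal <- 0L

  repeat {
    c1 <- read_fastq_chunk(con1, chunk_size)
    c2 <- if (paired) read_fastq_chunk(con2, chunk_size)
    if (is.null(c1)) {
      if (paired && !is.null(c2)) {
        stop_validation("paired files desynchronized: R2 has more reads than R1")
      }
      break
    }
    if (paired) {
      if (is.null(c2) || c2$n != c1$n) {
        stop_validation("paired files desynchronized: unequal read counts")
      }
      stem1 <- sub("/[12]$", "", c1$header)
      stem2 <- sub("/[12]$", "", c2$header)
      bad <- which(stem1 != stem2)
      if (length(bad)) {
        stop_validation(sprintf(
          "paired files desynchronized at read %d: '%s' vs '%s'",
          ordinal + bad[1L], c1$header[bad[1L]], c2$header[bad[1L]]
        ))
      }
    }
    bc <- if (paired) c2 else c1
    ids <- parse_mgi_read_id(bc$header)
    if (is.null(flowcell)) {
      flowcell <- ids$flowcell[1L]
    }
    lanes_seen <- unique(ids$lane)
    if (is.null(lane_label)) {
      if (length(lanes_seen) > 1L) {
        stop_validation(sprintf(
          "mixed lanes (%s) in one input file; pass an explicit lane label",
          paste(lanes_seen, collapse = ", ")
        ))
      }
      lane_label <- lanes_seen
    }
    if (is.na(report$lane)) {
      report$lane <- lane_label
    }

    res <- assign_chunk(bc$sequence, groups, sheet)
    verdict <- res$verdict
    rec <- res$record
    blen_of <- res$blen   # per-read barcode length used for trimming
    umi <- res$umi

    n <- bc$n
    n_bc <- nchar(bc$sequence)
    trimmed_seq <- substr(bc$sequence, 1L, n_bc - blen_of)
    trimmed_qual <- substr(bc$quality, 1L, n_bc - blen_of)

    sample_id <- ifelse(verdict == "sample", sheet$sample_id[rec], NA)
    annot <- rep("undetermined", n)
    is_s <- verdict == "sample"
    if (any(is_s)) {
      annot[is_s] <- ifelse(
        is.na(sheet$i5[rec[is_s]]),
        sheet$i7[rec[is_s]],
        paste0(sheet$i7[rec[is_s]], "+", sheet$i5[rec[is_s]])
      )
    }
    out_label <- ifelse(
      is_s, sample_id,
      ifelse(verdict == "ambiguous" & separate_ambiguous,
             "Ambiguous", "Undetermined")
    )
    out_number <- ifelse(is_s, numbers[sample_id], 0L)

    # headers per dialect; UMI goes into BOTH mates' headers
    if (dialect == "illumina") {
      ids1 <- ids
      ids1$mate <- 1L
      h1 <- format_output_id(ids1, "illumina", umi = umi,
                             index_annot = annot)
      h2 <- if (paired) {
        ids2 <- ids
        ids2$mate <- 2L
        format_output_id(ids2, "illumina", umi = umi, index_annot = annot)
      }
    } else {
      h1 <- format_output_id(NULL, "mgi", umi = umi, original = c1$header)
      h2 <- if (paired) {
        format_output_id(NULL, "mgi", umi = umi, original = c2$header)
      }
    }

    # route to per-sample files, preserving input order within each file
    if (paired) {
      seq1 <- c1$sequence; qual1 <- c1$quality
      seq2 <- trimmed_seq; qual2 <- trimmed_qual
    } else {
      seq1 <- trimmed_seq; qual1 <- trimmed_qual
    }
    for (lab in unique(out_label)) {
      sel <- which(out_label == lab)
      num <- out_number[sel[1L]]
      f1 <- output_path(lab, num, lane_label, 1L, dialect, flowcell)
      writers$add(f1, as.vector(rbind(
        h1[sel], seq1[sel], "+", qual1[sel]
      )))
      if (paired) {
        f2 <- output_path(lab, num, lane_label, 2L, dialect, flowcell)
        writers$add(f2, as.vector(rbind(
          h2[sel], seq2[sel], "+", qual2[sel]
        )))
      }
    }

    report <- accumulate_chunk_stats(
      report, verdict, sample_id, res$d7, res$d5, res$barcode,
      trimmed_r1 = if (paired) list(seq = seq1, qual = qual1) else
        list(seq = trimmed_seq, qual = trimmed_qual),
      trimmed_r2 = if (paired) list(seq = seq2, qual = qual2)
    )

    if (keep_assignments) {
      assignments[[length(assignments) + 1L]] <- data.frame(
        serial = ids$serial, verdict = verdict, sample_id = sample_id,
        d7 = res$d7, d5 = res$d5,
        umi = if (is.null(umi)) NA_character_ else umi,
        stringsAsFactors = FALSE
      )
    }
    ordinal <- ordinal + n
  }
  writers$close_all()

  run <- run_report_from_lanes(
    list(report), sheet = sheet,
    params = list(
      m7 = as.integer(m7), m5 = as.integer(m5), dialect = dialect,
      template = if (!is.null(template)) format_template(parse_template(template)),
      top_undetermined = as.integer(top_undetermined)
    )
  )
  if (!is.null(report_prefix)) {
    write_reports(run, file.path(output_dir, report_prefix))
  }
  if (keep_assignments) {
    attr(run, "assignments") <- do.call(rbind, assignments)
  }
  run
}

# Vectorised assignment of one chunk of barcode-mate sequences against all
# template groups. Returns per-read verdict/record/d7/d5/umi plus the barcode
# length used for trimming (the matched group's, default group's otherwise).
assign_chunk <- function(sequences, groups, sheet) {
  n <- length(sequences)
  per_group <- lapply(groups, function(g) {
    nb <- nchar(sequences)
    if (any(nb < g$blen)) {
      stop_validation(sprintf(
        "read of length %d bp is shorter than the %d bp barcode template",
        min(nb), g$blen
      ))
    }
    barcode <- substr(sequences, nb - g$blen + 1L, nb)
    fields <- extract_template_fields(barcode, g$template)
    key <- paste0(fields$i7, fields$i5 %||% "")
    lk <- lookup_many(g$lookup, key)
    # observed index combination in sheet orientation; this (not the raw
    # barcode region, which would drag a random UMI along) feeds the
    # top-undetermined tally
    obs <- if (is.null(fields$i5)) {
      fields$i7
    } else {
      paste0(fields$i7, "+", fields$i5)
    }
    list(rec = lk$record, d7 = lk$d7, d5 = lk$d5, umi = fields$umi,
         barcode = obs)
  })

  if (length(groups) == 1L) {
    g1 <- per_group[[1L]]
    verdict <- ifelse(is.na(g1$rec), "undetermined",
                      ifelse(g1$rec < 0L, "ambiguous", "sample"))
    gidx <- rep(1L, n)
    rec <- ifelse(g1$rec > 0L, g1$rec, NA_integer_)
    d7 <- g1$d7
    d5 <- g1$d5
  } else {
    sample_hits <- vapply(per_group, function(g) !is.na(g$rec) & g$rec > 0L,
                          logical(n))
    if (n == 1L) sample_hits <- matrix(sample_hits, nrow = 1L)
    n_hits <- rowSums(sample_hits)
    any_amb <- vapply(per_group, function(g) !is.na(g$rec) & g$rec < 0L,
                      logical(n))
    if (n == 1L) any_amb <- matrix(any_amb, nrow = 1L)
    verdict <- ifelse(
      n_hits == 1L, "sample",
      ifelse(n_hits > 1L | rowSums(any_amb) > 0L, "ambiguous",
             "undetermined")
    )
    gidx <- rep(1L, n)
    hit_g <- apply(sample_hits, 1L, function(h) if (sum(h) == 1L) which(h) else 1L)
    gidx[verdict == "sample"] <- hit_g[verdict == "sample"]
    rec <- d7 <- d5 <- rep(NA_integer_, n)
    for (gi in seq_along(per_group)) {
      sel <- verdict == "sample" & gidx == gi
      rec[sel] <- per_group[[gi]]$rec[sel]
      d7[sel] <- per_group[[gi]]$d7[sel]
      d5[sel] <- per_group[[gi]]$d5[sel]
    }
  }

  # UMI and trimming follow the assigned group; unassigned reads use the
  # default (first) group's template
  has_umi <- vapply(per_group, function(g) !is.null(g$umi), logical(1))
  umi <- NULL
  if (any(has_umi)) {
    umi <- rep(NA_character_, n)
    for (gi in seq_along(per_group)) {
      sel <- gidx == gi
      if (has_umi[gi]) umi[sel] <- per_group[[gi]]$umi[sel]
    }
  }
  blen_of <- vapply(groups, `[[`, integer(1), "blen")[gidx]
  barcode <- per_group[[1L]]$barcode
  for (gi in seq_along(per_group)[-1L]) {
    sel <- gidx == gi
    barcode[sel] <- per_group[[gi]]$barcode[sel]
  }
  list(verdict = verdict, record = rec, d7 = d7, d5 = d5, umi = umi,
       blen = blen_of, barcode = barcode)
}
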