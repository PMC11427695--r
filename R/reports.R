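# Per-lane demultiplexing/quality statistics and mergeable run reports.

# Empty accumulator for one lane. mmax is the largest total mismatch count a
# sample verdict can carry (m7 [+ m5]); projects maps sample_id -> project.
empty_lane_report <- function(lane, sample_ids, mmax, projects = NULL) {
  k <- mmax + 1L
  hist <- matrix(
    0L, nrow = length(sample_ids), ncol = k,
    dimnames = list(sample_ids, paste0("mm_", 0:mmax))
  )
  if (is.null(projects)) {
    projects <- stats::setNames(rep(NA_character_, length(sample_ids)),
                                sample_ids)
  }
  structure(
    list(
      lane = lane,
      sample_ids = sample_ids,
      projects = projects,
      reads = stats::setNames(integer(length(sample_ids)), sample_ids),
      mismatch_hist = hist,
      q30_bases = stats::setNames(numeric(length(sample_ids)), sample_ids),
      total_bases = stats::setNames(numeric(length(sample_ids)), sample_ids),
      undetermined = 0L,
      ambiguous = 0L,
      undetermined_tally = stats::setNames(numeric(0), character(0)),
      per_position_quality = list(
        R1 = list(sum = numeric(0), n = numeric(0)),
        R2 = list(sum = numeric(0), n = numeric(0))
      ),
      n_reads = 0L
    ),
    class = "mgi_lane_report"
  )
}

#' @export
print.mgi_lane_report <- function(x, ...) {
  cat(sprintf(
    "Lane %s: %d reads (%d undetermined, %d ambiguous) across %d sample(s)\n",
    as.character(x$lane), x$n_reads, x$undetermined, x$ambiguous,
    length(x$sample_ids)
  ))
  invisible(x)
}

# Add per-cycle quality sums/counts from a vector of quality strings.
accumulate_cycles <- function(acc, quals) {
  lens <- nchar(quals)
  maxlen <- max(c(lens, length(acc$sum)))
  if (maxlen > length(acc$sum)) {
    acc$sum <- c(acc$sum, numeric(maxlen - length(acc$sum)))
    acc$n <- c(acc$n, numeric(maxlen - length(acc$n)))
  }
  for (i in seq_along(quals)) {
    L <- lens[i]
    if (L == 0L) next
    q <- utf8ToInt(quals[i]) - 33L
    acc$sum[1:L] <- acc$sum[1:L] + q
    acc$n[1:L] <- acc$n[1:L] + 1
  }
  acc
}

q30_counts <- function(quals) {
  vapply(quals, function(q) {
    if (!nzchar(q)) 0 else sum(utf8ToInt(q) >= 63)  # Phred+33, Q30
  }, numeric(1), USE.NAMES = FALSE)
}

# Batch statistics update used by the streaming engine. trimmed_r1/r2 carry
# the biological (barcode-trimmed) sequence/quality of each mate.
accumulate_chunk_stats <- function(report, verdict, sample_id, d7, d5,
                                   barcode, trimmed_r1, trimmed_r2 = NULL) {
  is_s <- verdict == "sample"
  report$n_reads <- report$n_reads + length(verdict)
  report$undetermined <- report$undetermined + sum(verdict == "undetermined")
  report$ambiguous <- report$ambiguous + sum(verdict == "ambiguous")

  if (any(!is_s)) {
    obs <- barcode[!is_s]
    tal <- c(report$undetermined_tally,
             stats::setNames(rep(1, length(obs)), obs))
    merged <- tapply(tal, names(tal), sum)
    report$undetermined_tally <- stats::setNames(as.numeric(merged),
                                                 names(merged))
  }

  if (any(is_s)) {
    sid <- factor(sample_id[is_s], levels = report$sample_ids)
    report$reads <- report$reads + as.integer(table(sid))
    names(report$reads) <- report$sample_ids
    d <- (d7 + d5)[is_s]
    inc <- table(sid, factor(d, levels = 0:(ncol(report$mismatch_hist) - 1L)))
    report$mismatch_hist <- report$mismatch_hist + unclass(inc)

    q30_1 <- q30_counts(trimmed_r1$qual[is_s])
    tot_1 <- nchar(trimmed_r1$qual[is_s])
    q30 <- q30_1
    tot <- tot_1
    if (!is.null(trimmed_r2)) {
      q30 <- q30 + q30_counts(trimmed_r2$qual[is_s])
      tot <- tot + nchar(trimmed_r2$qual[is_s])
    }
    report$q30_bases <- report$q30_bases +
      as.numeric(tapply(q30, sid, sum, default = 0))
    report$total_bases <- report$total_bases +
      as.numeric(tapply(tot, sid, sum, default = 0))
    names(report$q30_bases) <- names(report$total_bases) <- report$sample_ids
  }

  report$per_position_quality$R1 <-
    accumulate_cycles(report$per_position_quality$R1, trimmed_r1$qual)
  if (!is.null(trimmed_r2)) {
    report$per_position_quality$R2 <-
      accumulate_cycles(report$per_position_quality$R2, trimmed_r2$qual)
  }
  report
}

#' Update lane statistics with one assigned read
#'
#' Incremental single-read form of the statistics accumulation the streaming
#' engine performs in batches: exactly one counter path (sample /
#' undetermined / ambiguous) is incremented, undetermined observations feed
#' the top-barcode tally, and quality accumulators take the trimmed
#' biological bases only.
#'
#' @param report An `mgi_lane_report`.
#' @param assignment List with `verdict`, `sample_id`, `d7`, `d5` and
#'   `observed_barcode`.
#' @param trimmed List with `r1 = list(sequence, quality)` and optionally
#'   `r2` (barcode-trimmed mates).
#' @return The updated `mgi_lane_report`.
#' @export
update_stats <- function(report, assignment, trimmed) {
  accumulate_chunk_stats(
    report,
    verdict = assignment$verdict,
    sample_id = assignment$sample_id %||% NA_character_,
    d7 = assignment$d7 %||% NA_integer_,
    d5 = assignment$d5 %||% NA_integer_,
    barcode = assignment$observed_barcode %||% NA_character_,
    trimmed_r1 = list(seq = trimmed$r1$sequence, qual = trimmed$r1$quality),
    trimmed_r2 = if (!is.null(trimmed$r2)) {
      list(seq = trimmed$r2$sequence, qual = trimmed$r2$quality)
    }
  )
}

# ---- run reports -----------------------------------------------------------

run_report_from_lanes <- function(lanes, sheet = NULL, params = list()) {
  if (!is.null(sheet)) {
    proj <- tapply(sheet$project, sheet$sample_id, function(p) p[1L])
    for (i in seq_along(lanes)) {
      lanes[[i]]$projects <- stats::setNames(
        as.character(proj[lanes[[i]]$sample_ids]), lanes[[i]]$sample_ids
      )
    }
  }
  merged <- Reduce(merge_lane_pair, lanes)
  merged$lane <- "all"
  structure(
    list(
      lanes = lanes,
      merged = merged,
      project_rollups = project_rollups(merged),
      params = params
    ),
    class = "mgi_run_report"
  )
}

project_rollups <- function(lane) {
  proj <- lane$projects
  proj[is.na(proj)] <- "(none)"
  reads <- tapply(lane$reads, proj, sum)
  q30 <- tapply(lane$q30_bases, proj, sum)
  tot <- tapply(lane$total_bases, proj, sum)
  data.frame(
    project = names(reads),
    reads = as.integer(reads),
    q30_pct = ifelse(tot > 0, round(100 * q30 / tot, 2), NA_real_),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' @export
print.mgi_run_report <- function(x, ...) {
  cat(sprintf(
    "Demultiplexing report: %d lane(s), %d reads total\n",
    length(x$lanes), x$merged$n_reads
  ))
  for (l in x$lanes) print(l)
  cat(sprintf(
    "  assigned %d | undetermined %d | ambiguous %d\n",
    sum(x$merged$reads), x$merged$undetermined, x$merged$ambiguous
  ))
  invisible(x)
}

#' Summarize a run report
#'
#' @param object An `mgi_run_report`.
#' @param ... Unused.
#' @return Data frame with one row per sample (merged over lanes): reads,
#'   percentage of the run, Q30 percentage.
#' @export
summary.mgi_run_report <- function(object, ...) {
  m <- object$merged
  data.frame(
    sample_id = m$sample_ids,
    reads = as.integer(m$reads),
    pct_of_run = ifelse(m$n_reads > 0,
                        round(100 * m$reads / m$n_reads, 2), NA_real_),
    q30_pct = ifelse(m$total_bases > 0,
                     round(100 * m$q30_bases / m$total_bases, 2), NA_real_),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

merge_lane_pair <- function(a, b) {
  if (!setequal(a$sample_ids, b$sample_ids)) {
    stop_validation(sprintf(
      "cannot merge reports over different sample sets (only in one: %s)",
      paste(
        c(setdiff(a$sample_ids, b$sample_ids),
          setdiff(b$sample_ids, a$sample_ids)),
        collapse = ", "
      )
    ))
  }
  if (ncol(a$mismatch_hist) != ncol(b$mismatch_hist)) {
    stop_validation("cannot merge reports built with different mismatch allowances")
  }
  ord <- a$sample_ids
  out <- a
  out$lane <- paste(unique(c(as.character(a$lane), as.character(b$lane))),
                    collapse = "+")
  out$reads <- a$reads + b$reads[ord]
  out$mismatch_hist <- a$mismatch_hist + b$mismatch_hist[ord, , drop = FALSE]
  out$q30_bases <- a$q30_bases + b$q30_bases[ord]
  out$total_bases <- a$total_bases + b$total_bases[ord]
  out$undetermined <- a$undetermined + b$undetermined
  out$ambiguous <- a$ambiguous + b$ambiguous
  out$n_reads <- a$n_reads + b$n_reads
  tal <- c(a$undetermined_tally, b$undetermined_tally)
  if (length(tal)) {
    merged <- tapply(tal, names(tal), sum)
    out$undetermined_tally <- stats::setNames(as.numeric(merged),
                                              names(merged))
  }
  for (mate in c("R1", "R2")) {
    pa <- a$per_position_quality[[mate]]
    pb <- b$per_position_quality[[mate]]
    L <- max(length(pa$sum), length(pb$sum))
    pad <- function(v) c(v, numeric(L - length(v)))
    out$per_position_quality[[mate]] <- list(
      sum = pad(pa$sum) + pad(pb$sum),
      n = pad(pa$n) + pad(pb$n)
    )
  }
  pa <- a$projects[ord]
  pb <- b$projects[ord]
  out$projects <- ifelse(is.na(pa), pb, pa)
  names(out$projects) <- ord
  out
}

#' Merge demultiplexing reports across lanes
#'
#' Sums all counters and histograms, recomputes the top-undetermined tally
#' from the combined tallies and combines per-cycle quality as
#' base-count-weighted means. Inputs must come from the same sample-sheet
#' universe (identical sample-id sets).
#'
#' @param reports List of `mgi_lane_report` objects and/or paths to
#'   serialized per-lane report files (`*.lane_<label>.json`).
#' @param params Optional parameter list recorded in the merged report.
#' @return An `mgi_run_report` whose `merged` component aggregates all input
#'   lanes.
#' @export
merge_reports <- function(reports, params = list()) {
  if (length(reports) == 0L) {
    stop_validation("no reports to merge")
  }
  lanes <- lapply(reports, function(r) {
    if (inherits(r, "mgi_lane_report")) r else read_lane_report(r)
  })
  run_report_from_lanes(lanes, params = params)
}

# ---- serialization ---------------------------------------------------------

lane_report_to_list <- function(x) {
  list(
    lane = as.character(x$lane),
    sample_ids = x$sample_ids,
    projects = as.vector(x$projects),
    reads = as.integer(x$reads),
    mismatch_hist = unname(split(x$mismatch_hist,
                                 row(x$mismatch_hist))),
    mismatch_max = ncol(x$mismatch_hist) - 1L,
    q30_bases = as.numeric(x$q30_bases),
    total_bases = as.numeric(x$total_bases),
    undetermined = x$undetermined,
    ambiguous = x$ambiguous,
    undetermined_barcodes = names(x$undetermined_tally),
    undetermined_counts = as.numeric(x$undetermined_tally),
    per_position_quality = x$per_position_quality,
    n_reads = x$n_reads
  )
}

write_lane_report <- function(x, path) {
  jsonlite::write_json(
    lane_report_to_list(x), path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read a serialized per-lane report
#'
#' @param path Path to a `*.lane_<label>.json` file written by
#'   [write_reports()].
#' @return The reconstructed `mgi_lane_report`.
#' @export
read_lane_report <- function(path) {
  if (!file.exists(path)) {
    stop_io(sprintf("report file not found: '%s'", path))
  }
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ids <- j$sample_ids
  rep <- empty_lane_report(j$lane, ids, j$mismatch_max)
  rep$projects <- stats::setNames(
    as.character(j$projects %||% rep(NA, length(ids))), ids
  )
  rep$reads <- stats::setNames(as.integer(j$reads), ids)
  hm <- j$mismatch_hist        # list of per-sample rows, or already a matrix
  if (is.list(hm)) hm <- do.call(rbind, hm)
  if (is.null(dim(hm))) hm <- matrix(hm, nrow = 1L)
  rep$mismatch_hist <- matrix(
    as.integer(hm), nrow = nrow(hm),
    dimnames = list(ids, paste0("mm_", 0:j$mismatch_max))
  )
  rep$q30_bases <- stats::setNames(as.numeric(j$q30_bases), ids)
  rep$total_bases <- stats::setNames(as.numeric(j$total_bases), ids)
  rep$undetermined <- as.integer(j$undetermined)
  rep$ambiguous <- as.integer(j$ambiguous)
  rep$undetermined_tally <- stats::setNames(
    as.numeric(j$undetermined_counts),
    as.character(j$undetermined_barcodes %||% character(0))
  )
  rep$per_position_quality <- list(
    R1 = list(sum = as.numeric(j$per_position_quality$R1$sum),
              n = as.numeric(j$per_position_quality$R1$n)),
    R2 = list(sum = as.numeric(j$per_position_quality$R2$sum),
              n = as.numeric(j$per_position_quality$R2$n))
  )
  rep$n_reads <- as.integer(j$n_reads)
  rep
}

#' Write the demultiplexing report files
#'
#' Writes, under `<prefix>`:
#' * `<prefix>.sample_stats.tsv` — per lane and sample: reads, percentage of
#'   the lane, mismatch histogram (`mm_0..mm_max`), Q30 percentage of the
#'   trimmed biological bases; samples in sheet order, lanes ascending;
#' * `<prefix>.undetermined.tsv` — top undetermined barcodes (count
#'   descending, ties lexicographic);
#' * `<prefix>.general.json` — run totals and parameters;
#' * `<prefix>.lane_<label>.json` — one full machine-readable report per
#'   lane, the input format of [merge_reports()].
#'
#' @param run An `mgi_run_report`.
#' @param prefix Output path prefix.
#' @param top_undetermined Rows kept in the undetermined table (default from
#'   the run's parameters, else 50).
#' @return Character vector of the files written, invisibly.
#' @export
write_reports <- function(run, prefix,
                          top_undetermined =
                            run$params$top_undetermined %||% 50L) {
  dir <- dirname(prefix)
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }

  lane_order <- order(vapply(run$lanes, function(l) as.character(l$lane),
                             character(1)))
  rows <- list()
  for (l in run$lanes[lane_order]) {
    hist <- l$mismatch_hist
    df <- data.frame(
      sample_id = l$sample_ids,
      lane = as.character(l$lane),
      reads = as.integer(l$reads),
      pct_of_lane = if (l$n_reads > 0) {
        round(100 * l$reads / l$n_reads, 2)
      } else {
        rep(0, length(l$sample_ids))
      },
      stringsAsFactors = FALSE
    )
    df <- cbind(df, as.data.frame(hist, optional = TRUE))
    df$q30_pct <- ifelse(l$total_bases > 0,
                         round(100 * l$q30_bases / l$total_bases, 2), NA)
    rows[[length(rows) + 1L]] <- df
  }
  stats_df <- do.call(rbind, rows)
  f_stats <- paste0(prefix, ".sample_stats.tsv")
  utils::write.table(stats_df, f_stats, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  tal <- run$merged$undetermined_tally
  f_und <- paste0(prefix, ".undetermined.tsv")
  if (length(tal)) {
    ord <- order(-tal, names(tal))
    und_df <- data.frame(
      barcode = names(tal)[ord],
      count = as.integer(tal[ord]),
      stringsAsFactors = FALSE
    )
    und_df <- utils::head(und_df, top_undetermined)
  } else {
    und_df <- data.frame(barcode = character(0), count = integer(0))
  }
  utils::write.table(und_df, f_und, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  general <- list(
    total_reads = run$merged$n_reads,
    assigned_reads = sum(run$merged$reads),
    undetermined_reads = run$merged$undetermined,
    ambiguous_reads = run$merged$ambiguous,
    lanes = vapply(run$lanes, function(l) as.character(l$lane), character(1)),
    samples = run$merged$sample_ids,
    project_rollups = run$project_rollups,
    parameters = run$params
  )
  f_gen <- paste0(prefix, ".general.json")
  jsonlite::write_json(general, f_gen, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")

  files <- c(f_stats, f_und, f_gen)
  for (l in run$lanes) {
    f <- paste0(prefix, ".lane_", as.character(l$lane), ".json")
    write_lane_report(l, f)
    files <- c(files, f)
  }
  invisible(files)
}
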