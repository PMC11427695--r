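# Independent brute-force oracles and small fixture builders. Everything
# here deliberately avoids the package's lookup-table code path: distances
# are computed by direct character comparison and assignment by a full scan
# over the sample sheet.

oracle_hamming1 <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Enumerate all strings over ACGTN within distance m of `center`.
oracle_ball <- function(center, m) {
  L <- nchar(center)
  grid <- expand.grid(rep(list(c("A", "C", "G", "T", "N")), L),
                      stringsAsFactors = FALSE)
  strings <- apply(grid, 1L, paste, collapse = "")
  d <- vapply(strings, oracle_hamming1, integer(1), b = center)
  d <- d[d <= m]
  d
}

# Full-scan assignment of many observations: per-index distances to every
# record, per-index caps, minimal total distance wins, a tie between
# distinct samples is ambiguous.
oracle_assign_many <- function(obs7, obs5 = NULL, sheet, m7, m5 = 0L) {
  n <- length(obs7)
  obsm7 <- do.call(rbind, strsplit(obs7, ""))
  d7m <- sapply(seq_len(nrow(sheet)), function(r) {
    ref <- strsplit(sheet$i7[r], "")[[1]]
    rowSums(obsm7 != matrix(ref, n, length(ref), byrow = TRUE))
  })
  if (n == 1L) d7m <- matrix(d7m, nrow = 1L)
  if (!is.null(obs5)) {
    obsm5 <- do.call(rbind, strsplit(obs5, ""))
    d5m <- sapply(seq_len(nrow(sheet)), function(r) {
      ref <- strsplit(sheet$i5[r], "")[[1]]
      rowSums(obsm5 != matrix(ref, n, length(ref), byrow = TRUE))
    })
    if (n == 1L) d5m <- matrix(d5m, nrow = 1L)
  } else {
    d5m <- matrix(0L, n, nrow(sheet))
  }
  elig <- d7m <= m7 & d5m <= m5
  tot <- d7m + d5m
  tot[!elig] <- Inf
  rmin <- do.call(pmin, as.data.frame(tot))
  idcode <- as.integer(factor(sheet$sample_id, levels = unique(sheet$sample_id)))
  best <- tot == rmin & is.finite(tot)
  coded <- t(t(best) * idcode)
  coded[coded == 0] <- NA
  id_hi <- suppressWarnings(do.call(pmax, c(as.data.frame(coded), na.rm = TRUE)))
  id_lo <- suppressWarnings(do.call(pmin, c(as.data.frame(coded), na.rm = TRUE)))
  verdict <- ifelse(!is.finite(rmin), "undetermined",
                    ifelse(id_hi != id_lo, "ambiguous", "sample"))
  rec <- max.col(best, ties.method = "first")
  rec[verdict != "sample"] <- NA_integer_
  data.frame(
    verdict = verdict,
    sample_id = ifelse(verdict == "sample", sheet$sample_id[rec], NA),
    d7 = ifelse(verdict == "sample", d7m[cbind(seq_len(n), rec)], NA),
    d5 = ifelse(verdict == "sample", d5m[cbind(seq_len(n), rec)], NA),
    stringsAsFactors = FALSE
  )
}

make_sheet <- function(ids, i7, i5 = NULL, template = NULL, project = NULL) {
  header <- c("sample_id", "i7",
              if (!is.null(i5)) "i5",
              if (!is.null(template)) "template",
              if (!is.null(project)) "project")
  rows <- paste(ids, i7, sep = "\t")
  if (!is.null(i5)) rows <- paste(rows, i5, sep = "\t")
  if (!is.null(template)) rows <- paste(rows, template, sep = "\t")
  if (!is.null(project)) rows <- paste(rows, project, sep = "\t")
  parse_sample_sheet(c(paste(header, collapse = "\t"), rows))
}

write_fastq_gz <- function(path, headers, seqs, quals = NULL) {
  if (is.null(quals)) quals <- vapply(nchar(seqs), strrep, "", x = "I")
  con <- gzfile(path, open = "wb")
  on.exit(close(con))
  writeLines(as.vector(rbind(headers, seqs, "+", quals)), con)
  path
}

read_fastq_gz <- function(path) {
  lines <- readLines(gzfile(path))
  k <- length(lines) / 4L
  list(
    header = lines[seq(1, by = 4, length.out = k)],
    sequence = lines[seq(2, by = 4, length.out = k)],
    quality = lines[seq(4, by = 4, length.out = k)]
  )
}

# Serial field of Illumina-dialect headers (@fc:1:fc:lane:tile:serial:y[:umi]).
illumina_serial <- function(headers) {
  vapply(strsplit(sub(" .*", "", headers), ":", fixed = TRUE),
         function(p) as.integer(p[[6]]), integer(1))
}

# All strings over ACGTN of length L (for exhaustive lookup-vs-oracle runs).
all_strings <- function(L, alphabet = c("A", "C", "G", "T", "N")) {
  grid <- expand.grid(rep(list(alphabet), L), stringsAsFactors = FALSE)
  apply(grid, 1L, paste, collapse = "")
}
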