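# Seeded simulator of ground-truthed MGI runs: the package's fixture factory
# for validating demultiplexing, template detection and reporting.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

#' Draw a set of well-separated random indices
#'
#' Rejection-samples `n` distinct indices such that every pair is at Hamming
#' distance at least `min_pairwise_distance` — the separation that makes
#' mismatch-tolerant demultiplexing unambiguous (pairwise distance > 2m
#' guarantees unique decoding at allowance m).
#'
#' @param n Number of indices.
#' @param length Index length (bp).
#' @param min_pairwise_distance Minimum pairwise Hamming distance.
#' @param seed Optional seed (the caller's RNG state is preserved).
#' @return Character vector of `n` indices.
#' @export
random_index_set <- function(n, length, min_pairwise_distance = 3L,
                             seed = NULL) {
  if (n < 1L) {
    stop_validation("need at least one index")
  }
  if (4^length < n) {
    stop_validation(sprintf(
      "cannot draw %d distinct indices of length %d (only %d exist)",
      n, length, 4^length
    ))
  }
  with_seed(seed, {
    picked <- character(0)
    attempts <- 0L
    max_attempts <- 1000L * n
    while (length(picked) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop_validation(sprintf(
          paste0(
            "could not find %d indices of length %d at pairwise distance ",
            ">= %d after %d draws; relax the constraints"
          ),
          n, length, min_pairwise_distance, max_attempts
        ))
      }
      cand <- random_dna(1L, length)
      if (length(picked) == 0L ||
          all(hamming_distance(rep(cand, length(picked)), picked) >=
                min_pairwise_distance)) {
        picked <- c(picked, cand)
      }
    }
    picked
  })
}

# Substitute k random positions of each sequence with a character drawn
# uniformly from the 4 alternatives (3 other bases + N). Returns the mutated
# strings; k may vary per sequence.
inject_substitutions <- function(seqs, k) {
  alphabet <- c("A", "C", "G", "T", "N")
  out <- seqs
  for (i in which(k > 0L)) {
    chars <- strsplit(out[i], "", fixed = TRUE)[[1L]]
    pos <- sample(length(chars), k[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(alphabet, chars[p]), 1L)
    }
    out[i] <- paste(chars, collapse = "")
  }
  out
}

# Per-base two-state quality mixture: mostly Q40 with a Q12 minority, so Q30
# statistics are non-degenerate. Phred+33: Q40 = 'I', Q12 = '-'.
random_quality <- function(n, length, p_high = 0.85) {
  if (length == 0L) {
    return(rep("", n))
  }
  chars <- sample(c("I", "-"), n * length, replace = TRUE,
                  prob = c(p_high, 1 - p_high))
  apply(matrix(chars, nrow = n), 1L, paste, collapse = "")
}

#' Simulate a ground-truthed MGI sequencing run
#'
#' Writes gzip FASTQ file(s) in the MGI header dialect, a matching TSV sample
#' sheet and a truth table recording, per read, the generating sample, the
#' number of substitution errors injected into each index and the emitted
#' UMI. Reads are emitted in strictly increasing serial order with the read
#' barcode (index segments, optional UMI, per the template) appended to the
#' tail of the barcode-bearing mate. Identical seeds give byte-identical
#' outputs.
#'
#' @param output_dir Directory for the generated files (created if needed).
#' @param n_samples Number of samples (default 4).
#' @param i7_len,i5_len Index lengths in bp (`i5_len = NULL` for single
#'   index; defaults 8 + 8, the common dual-index kit).
#' @param umi_len UMI length in bp (0 = no UMI).
#' @param template Barcode template (object or spec string); default: i7,
#'   then i5, then UMI, all forward.
#' @param reads_per_sample Reads per sample per lane (default 1000).
#' @param read_len Biological read length in bp (default 100).
#' @param substitution_rate Per-base substitution probability in the index
#'   segments (default 0).
#' @param max_errors_per_index Cap on injected errors per index segment per
#'   read (default `Inf`).
#' @param errors_per_index Exact number of errors to inject into every index
#'   segment of every read (overrides `substitution_rate`).
#' @param undetermined_fraction Probability a read receives a fully random
#'   barcode instead of its sample's (default 0).
#' @param lanes Number of lanes; each lane gets its own FASTQ file set.
#' @param paired Paired-end (barcode on the R2 tail) or single-end (R1 tail).
#' @param seed Integer seed; all randomness flows from it.
#' @param flowcell Flowcell label used in headers.
#' @param prefix File-name prefix for the generated files.
#' @param min_index_distance Minimum pairwise Hamming distance between
#'   sample indices (default 3, safe for 1 error per index).
#' @return List with `sample_sheet`, `truth`, `r1`/`r2` (per-lane file
#'   paths), and the drawn `i7`/`i5` index sets.
#' @export
simulate_run <- function(output_dir,
                         n_samples = 4L,
                         i7_len = 8L, i5_len = 8L, umi_len = 0L,
                         template = NULL,
                         reads_per_sample = 1000L,
                         read_len = 100L,
                         substitution_rate = 0,
                         max_errors_per_index = Inf,
                         errors_per_index = NULL,
                         undetermined_fraction = 0,
                         lanes = 1L,
                         paired = TRUE,
                         seed = 1L,
                         flowcell = "V350096291",
                         prefix = "sim",
                         min_index_distance = 3L) {
  if (substitution_rate < 0 || substitution_rate > 1 ||
      undetermined_fraction < 0 || undetermined_fraction > 1) {
    stop_validation("rates must lie in [0, 1]")
  }
  dual <- !is.null(i5_len) && !is.na(i5_len) && i5_len > 0L
  if (!dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  if (is.null(template)) {
    spec <- paste0(
      "i7.", i7_len,
      if (dual) paste0(":i5.", i5_len),
      if (umi_len > 0L) paste0(":um.", umi_len)
    )
    template <- parse_template(spec)
  } else {
    template <- parse_template(template)
  }
  tl <- stats::setNames(template$length, template$kind)
  if (tl[["i7"]] != i7_len ||
      (dual && (!"i5" %in% template$kind || tl[["i5"]] != i5_len)) ||
      (!dual && "i5" %in% template$kind) ||
      (umi_len > 0L) != ("umi" %in% template$kind) ||
      (umi_len > 0L && tl[["umi"]] != umi_len)) {
    stop_validation("template is inconsistent with the index/UMI lengths")
  }
  blen <- expected_barcode_length(template)

  with_seed(seed, {
    i7 <- random_index_set(n_samples, i7_len, min_index_distance)
    i5 <- if (dual) random_index_set(n_samples, i5_len, min_index_distance)
    sheet <- validate_sample_sheet(data.frame(
      sample_id = sprintf("S%02d", seq_len(n_samples)),
      i7 = i7,
      i5 = if (dual) i5 else NA_character_,
      template = NA_character_,
      project = NA_character_,
      stringsAsFactors = FALSE
    ))
    sheet_path <- file.path(output_dir, paste0(prefix, ".samplesheet.tsv"))
    write_sample_sheet(sheet, sheet_path)

    truth_rows <- list()
    r1_paths <- r2_paths <- character(0)
    for (lane in seq_len(lanes)) {
      n <- n_samples * reads_per_sample
      origin <- sample(rep(seq_len(n_samples), each = reads_per_sample))
      serial <- seq_len(n)
      col <- (serial %% 999L) + 1L
      row <- (serial %/% 999L) %% 999L + 1L

      is_rand <- stats::runif(n) < undetermined_fraction
      err_count <- function(len) {
        if (!is.null(errors_per_index)) {
          rep.int(as.integer(errors_per_index), n)
        } else {
          pmin(stats::rbinom(n, len, substitution_rate),
               max_errors_per_index)
        }
      }
      emit_index <- function(true_idx, len, rc) {
        clean <- true_idx[origin]
        if (rc) clean <- reverse_complement(clean)
        k <- err_count(len)
        emitted <- inject_substitutions(clean, k)
        k[is_rand] <- NA_integer_
        list(emitted = emitted, d = k)
      }

      segs <- list()
      d7 <- d5 <- rep(NA_integer_, n)
      umi <- rep(NA_character_, n)
      for (s in seq_len(nrow(template))) {
        kind <- template$kind[s]
        if (kind == "i7") {
          e <- emit_index(i7, i7_len, template$rc[s])
          segs[[s]] <- e$emitted
          d7 <- e$d
        } else if (kind == "i5") {
          e <- emit_index(i5, i5_len, template$rc[s])
          segs[[s]] <- e$emitted
          d5 <- e$d
        } else {
          umi <- random_dna(n, umi_len)
          segs[[s]] <- umi
        }
      }
      barcode <- do.call(paste0, segs)
      if (any(is_rand)) {
        barcode[is_rand] <- random_dna(sum(is_rand), blen)
        # record what a demultiplexer would extract as UMI
        if (umi_len > 0L) {
          f <- extract_template_fields(barcode[is_rand], template)
          umi[is_rand] <- f$umi
        }
      }

      bio_bc <- random_dna(n, read_len)
      seq_bc <- paste0(bio_bc, barcode)
      qual_bc <- random_quality(n, read_len + blen)
      h_bc <- compose_mgi_read_id(flowcell, lane, col, row, serial,
                                  if (paired) 2L else 1L)
      if (paired) {
        bio_1 <- random_dna(n, read_len)
        qual_1 <- random_quality(n, read_len)
        h_1 <- compose_mgi_read_id(flowcell, lane, col, row, serial, 1L)
      }

      write_gz_fastq <- function(path, h, s, q) {
        con <- gzfile(path, open = "wb")
        on.exit(close(con), add = TRUE)
        writeLines(as.vector(rbind(h, s, "+", q)), con)
        path
      }
      f1 <- file.path(output_dir,
                      sprintf("%s_L%02d_R1.fq.gz", prefix, lane))
      if (paired) {
        f2 <- file.path(output_dir,
                        sprintf("%s_L%02d_R2.fq.gz", prefix, lane))
        write_gz_fastq(f1, h_1, bio_1, qual_1)
        write_gz_fastq(f2, h_bc, seq_bc, qual_bc)
        r2_paths <- c(r2_paths, f2)
      } else {
        write_gz_fastq(f1, h_bc, seq_bc, qual_bc)
      }
      r1_paths <- c(r1_paths, f1)

      truth_rows[[lane]] <- data.frame(
        lane = lane,
        serial = serial,
        true_sample = ifelse(is_rand, "undetermined",
                             sheet$sample_id[origin]),
        d7 = d7,
        d5 = if (dual) d5 else NA_integer_,
        umi = if (umi_len > 0L) umi else NA_character_,
        stringsAsFactors = FALSE
      )
    }
    truth <- do.call(rbind, truth_rows)
    truth_path <- file.path(output_dir, paste0(prefix, ".truth.tsv"))
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    list(
      sample_sheet = sheet_path,
      truth = truth_path,
      r1 = r1_paths,
      r2 = if (paired) r2_paths,
      template = format_template(template),
      i7 = i7,
      i5 = if (dual) i5
    )
  })
}
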