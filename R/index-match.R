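#' Enumerate the Hamming ball around an index
#'
#' Generates every string obtainable from `index` by substituting at most `m`
#' positions with a character from A/C/G/T/N differing from the original, the
#' mismatch-expansion step behind the lookup table. An N read base always
#' counts as one mismatch against any expected base, so N-substituted
#' variants are part of every ball. The ball size follows the closed form
#' sum_{k=0..m} choose(L,k) * 4^k for an index of length L.
#'
#' @param index A single index string over A/C/G/T.
#' @param m Non-negative mismatch allowance, at most `nchar(index)`.
#' @return Named integer vector: names are the variant strings, values the
#'   substitution count (= Hamming distance to `index`).
#' @examples
#' hamming_ball("ACG", 1)  # 13 variants, distances 0/1
#' @export
hamming_ball <- function(index, m) {
  if (length(index) != 1L || !is.character(index) || grepl("[^ACGT]", index)) {
    stop_validation("hamming_ball() expects one index string over A/C/G/T")
  }
  m <- as.integer(m)
  if (is.na(m) || m < 0L) {
    stop_validation("mismatch allowance m must be a non-negative integer")
  }
  L <- nchar(index)
  if (m > L) {
    stop_validation(sprintf("m = %d exceeds index length %d", m, L))
  }
  chars <- strsplit(index, "", fixed = TRUE)[[1L]]
  alphabet <- c("A", "C", "G", "T", "N")

  variants <- index
  dists <- 0L
  if (m > 0L) {
    for (k in seq_len(m)) {
      combos <- utils::combn(L, k)
      for (j in seq_len(ncol(combos))) {
        pos <- combos[, j]
        alts <- lapply(pos, function(p) setdiff(alphabet, chars[p]))
        grid <- as.matrix(expand.grid(alts, stringsAsFactors = FALSE))
        new <- apply(grid, 1L, function(repl) {
          v <- chars
          v[pos] <- repl
          paste(v, collapse = "")
        })
        variants <- c(variants, new)
        dists <- c(dists, rep.int(k, length(new)))
      }
    }
  }
  stats::setNames(as.integer(dists), variants)
}

# Predicted ball size: sum_{k=0..m} C(L,k) 4^k (used by the memory guard).
ball_size <- function(L, m) {
  sum(choose(L, 0:m) * 4^(0:m))
}

# Exact base-5 numeric encoding of fixed-length keys over A/C/G/T/N
# (A=0, C=1, G=2, T=3, N=4 per position). Characters outside the alphabet
# encode to NA, which can never equal a dictionary key.
encode_keys <- function(keys, L) {
  if (length(keys) == 0L) {
    return(numeric(0))
  }
  digit <- rep(NA_real_, 256L)
  digit[utf8ToInt("ACGTN") + 1L] <- 0:4
  bytes <- as.integer(charToRaw(paste(keys, collapse = "")))
  d <- digit[bytes + 1L]
  as.vector(crossprod(matrix(d, nrow = L), 5^(seq_len(L) - 1L)))
}

#' Build the mismatch-expansion index lookup table
#'
#' Precomputes, for every sample-sheet record of a template group, all index
#' variants within the per-index mismatch allowances and stores them in a
#' hashed dictionary, so assigning a read is a single fetch on its observed
#' (concatenated) index regardless of the allowance. When variants of several
#' records collide on one key, only the record(s) at the minimal total
#' distance d7+d5 are kept; an exact tie between distinct samples marks the
#' key ambiguous. Records of the same sample (index diversity) never make a
#' key ambiguous.
#'
#' @param sheet A `mgi_sample_sheet`.
#' @param group Optional integer vector of record indices forming one
#'   template group (default: all records).
#' @param m7,m5 Per-index mismatch allowances (defaults 1; `m5` ignored for
#'   single-index sheets). Sequencers rarely produce more than one error per
#'   index, and large allowances blow up the expansion exponentially.
#' @param max_keys Refuse to build when the predicted key count exceeds this
#'   cap (default 5e7); lower `m7`/`m5` instead.
#' @return An `mgi_index_lookup` with the dictionary, key length and
#'   allowances.
#' @export
build_lookup <- function(sheet, group = NULL, m7 = 1L, m5 = 1L,
                         max_keys = 5e7) {
  if (is.null(group)) group <- seq_len(nrow(sheet))
  if (length(group) == 0L) {
    stop_validation("cannot build a lookup table for an empty template group")
  }
  m7 <- as.integer(m7)
  m5 <- as.integer(m5)
  if (m7 < 0L || m5 < 0L) {
    stop_validation("mismatch allowances must be non-negative")
  }
  if (m7 > 31L || m5 > 31L) {
    stop_validation("mismatch allowances above 31 are not supported")
  }
  i7 <- sheet$i7[group]
  i5 <- sheet$i5[group]
  dual <- !all(is.na(i5))
  L7 <- unique(nchar(i7))
  if (length(L7) != 1L) {
    stop_validation("i7 indices of unequal length within one lookup group")
  }
  m7 <- min(m7, L7)
  L5 <- 0L
  if (dual) {
    L5 <- unique(nchar(i5))
    if (length(L5) != 1L) {
      stop_validation("i5 indices of unequal length within one lookup group")
    }
    m5 <- min(m5, L5)
  } else {
    m5 <- 0L
  }

  predicted <- length(group) * ball_size(L7, m7) *
    if (dual) ball_size(L5, m5) else 1
  if (predicted > max_keys) {
    stop_validation(sprintf(
      paste0(
        "predicted lookup size %.3g keys exceeds the cap of %.3g; ",
        "reduce the mismatch allowances m7/m5"
      ),
      predicted, max_keys
    ))
  }

  # Enumerate every (key, record, d7, d5) once, with keys encoded as exact
  # base-5 numbers (A=0,C=1,G=2,T=3,N=4 by position); then resolve
  # collisions in one vectorised pass: per key, keep only the record(s) at
  # minimal total distance; a tie between distinct samples is ambiguous, a
  # tie between records of the same sample (index diversity) collapses to
  # the first record. Keys up to 22 bp fit a double exactly (5^22 < 2^53);
  # longer keys would overflow, so the key cap doubles as a length guard.
  L <- L7 + L5
  if (L > 22L) {
    stop_validation(sprintf(
      "combined index length %d exceeds the supported 22 bp", L
    ))
  }
  parts <- lapply(seq_along(group), function(r) {
    ball7 <- hamming_ball(i7[r], m7)
    num7 <- encode_keys(names(ball7), L7)
    if (dual) {
      ball5 <- hamming_ball(i5[r], m5)
      num5 <- encode_keys(names(ball5), L5)
      list(
        key = as.vector(outer(num7, num5 * 5^L7, "+")),
        d7 = rep(unname(ball7), times = length(ball5)),
        d5 = rep(unname(ball5), each = length(ball7)),
        rec = rep.int(group[r], length(ball7) * length(ball5))
      )
    } else {
      list(
        key = num7,
        d7 = unname(ball7),
        d5 = rep.int(0L, length(ball7)),
        rec = rep.int(group[r], length(ball7))
      )
    }
  })
  key <- unlist(lapply(parts, `[[`, "key"), use.names = FALSE)
  d7v <- unlist(lapply(parts, `[[`, "d7"), use.names = FALSE)
  d5v <- unlist(lapply(parts, `[[`, "d5"), use.names = FALSE)
  recv <- unlist(lapply(parts, `[[`, "rec"), use.names = FALSE)
  total <- d7v + d5v

  ord <- order(key, total, recv)
  key <- key[ord]; d7v <- d7v[ord]; d5v <- d5v[ord]
  recv <- recv[ord]; total <- total[ord]
  first <- !duplicated(key)
  grp <- cumsum(first)
  keep <- total == total[first][grp]

  key <- key[keep]; d7v <- d7v[keep]; d5v <- d5v[keep]
  recv <- recv[keep]; grp <- grp[keep]
  cnt <- tabulate(grp)[grp]

  amb <- list()
  if (any(cnt > 1L)) {
    multi <- which(cnt > 1L)
    drop <- logical(length(key))
    for (rows in split(multi, grp[multi])) {
      ids_here <- sheet$sample_id[recv[rows]]
      if (length(unique(ids_here)) == 1L) {
        drop[rows[-1L]] <- TRUE       # index diversity: same sample
      } else {
        amb[[length(amb) + 1L]] <- list(
          records = recv[rows], d7 = d7v[rows[1L]], d5 = d5v[rows[1L]]
        )
        recv[rows[1L]] <- -length(amb)  # sentinel into the ambiguous list
        drop[rows[-1L]] <- TRUE
      }
    }
    key <- key[!drop]; d7v <- d7v[!drop]; d5v <- d5v[!drop]
    recv <- recv[!drop]
  }

  # pack record + distances into one integer per key; ambiguous keys carry a
  # negative index into `amb`. Keys are already sorted, so queries are a
  # single binary-search fetch.
  code <- as.integer(ifelse(recv < 0L, recv, (recv * 32L + d7v) * 32L + d5v))

  structure(
    list(
      keys = key,
      codes = code,
      ambiguous_entries = amb,
      key_length = L7 + L5,
      i7_length = L7,
      i5_length = L5,
      dual = dual,
      m7 = m7,
      m5 = m5,
      group = group,
      sample_ids = stats::setNames(sheet$sample_id, seq_len(nrow(sheet)))
    ),
    class = "mgi_index_lookup"
  )
}

#' @export
print.mgi_index_lookup <- function(x, ...) {
  cat(sprintf(
    "Index lookup: %d keys of length %d (%s index), m7=%d m5=%d, %d record(s)\n",
    length(x$keys), x$key_length, if (x$dual) "dual" else "single",
    x$m7, x$m5, length(x$group)
  ))
  invisible(x)
}

#' Look up one observed index string
#'
#' One dictionary fetch: no scan over the sample sheet ever happens at
#' assignment time.
#'
#' @param table An `mgi_index_lookup`.
#' @param observed Observed index string (concatenated i7 then i5 for dual
#'   index), same length as the table keys.
#' @return A match entry — list with `records` (record indices), `sample_ids`,
#'   `d7`, `d5` and `ambiguous` — or `NULL` when the observation is outside
#'   every sample's mismatch neighbourhood.
#' @export
lookup_index <- function(table, observed) {
  if (nchar(observed) != table$key_length) {
    stop_validation(sprintf(
      "observed index length %d does not match lookup key length %d (template/sample-sheet inconsistency?)",
      nchar(observed), table$key_length
    ))
  }
  lk <- lookup_many(table, observed)
  code <- lk$code
  if (is.na(code)) {
    return(NULL)
  }
  if (code < 0L) {
    e <- table$ambiguous_entries[[-code]]
    records <- e$records
    d7 <- e$d7
    d5 <- e$d5
  } else {
    records <- code %/% 1024L
    d7 <- (code %% 1024L) %/% 32L
    d5 <- code %% 32L
  }
  list(
    records = records,
    sample_ids = unname(table$sample_ids[records]),
    d7 = d7,
    d5 = d5,
    ambiguous = length(records) > 1L
  )
}

# Batch fetch for the streaming engine. Returns parallel vectors: `record`
# (sheet row; NA = no match; negative = index into the ambiguous-entry
# list), `d7`, `d5` (NA on no-match).
lookup_many <- function(table, observed) {
  ok <- nchar(observed) == table$key_length
  if (!all(ok)) {
    stop_validation(sprintf(
      "observed index length %d does not match lookup key length %d",
      nchar(observed[!ok][1L]), table$key_length
    ))
  }
  qnum <- encode_keys(observed, table$key_length)
  pos <- findInterval(qnum, table$keys)
  hit <- !is.na(qnum) & pos >= 1L
  hit[hit] <- table$keys[pos[hit]] == qnum[hit]
  code <- rep(NA_integer_, length(observed))
  code[hit] <- table$codes[pos[hit]]
  amb <- !is.na(code) & code < 0L
  record <- ifelse(amb, code, code %/% 1024L)
  d7 <- ifelse(amb, NA_integer_, (code %% 1024L) %/% 32L)
  d5 <- ifelse(amb, NA_integer_, code %% 32L)
  if (any(amb)) {
    d7[amb] <- vapply(table$ambiguous_entries[-code[amb]], `[[`,
                      integer(1), "d7")
    d5[amb] <- vapply(table$ambiguous_entries[-code[amb]], `[[`,
                      integer(1), "d5")
  }
  list(record = record, d7 = d7, d5 = d5, code = code)
}
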