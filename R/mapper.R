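# k-mer seeded read-to-reference alignment with percent-identity scoring.
# Seeds are exact k-mer matches; candidates are ranked by seed count per
# (reference, strand); each candidate is extended by a banded local
# alignment (src/align.cpp) around the modal seed diagonal.  Identity is
# n_match / (n_match + n_mismatch + n_gapcols), i.e. the fraction of
# alignment columns that match.

kmerize <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(data.table(kmer = character(0), pos0 = integer(0)))
  data.table(kmer = substring(seq, 1:(L - k + 1L), k:L), pos0 = 0:(L - k))
}

#' Build a k-mer seed index over a reference set
#'
#' @param references Named character vector of reference sequences (or a
#'   `put_set`; see [put_sequences()]).
#' @param k Word size, at least 8 (default 11).
#' @return An object of class `kmer_index`.  References shorter than `k`
#'   are skipped with a warning.
#' @export
build_index <- function(references, k = 11) {
  refs <- put_sequences(references)
  if (k < 8) stopf("k must be >= 8")
  if (length(refs) == 0) stopf("reference set is empty")
  if (is.null(names(refs)) || any(!nzchar(names(refs)))) {
    stopf("references must be named")
  }
  short <- names(refs)[nchar(refs) < k]
  if (length(short) > 0) {
    warning(sprintf("%d reference(s) shorter than k skipped: %s",
                    length(short), paste(head(short, 5), collapse = ", ")))
    refs <- refs[nchar(refs) >= k]
    if (length(refs) == 0) stopf("no reference of length >= k")
  }
  tabs <- lapply(names(refs), function(id) {
    kt <- kmerize(refs[[id]], k)
    kt[, ref := id]
    kt
  })
  tab <- rbindlist(tabs)
  setkey(tab, kmer)
  structure(list(table = tab, k = k, refs = refs), class = "kmer_index")
}

#' @exportS3Method base::print
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: %d references, k = %d, %d seed positions\n",
              length(x$refs), x$k, nrow(x$table)))
  invisible(x)
}

# Align one oriented read against one reference around a seed diagonal.
extend_candidate <- function(seq, ref_seq, diag, band) {
  .banded_align(seq, ref_seq, as.integer(diag), as.integer(band))
}

#' Map a read against an indexed reference set
#'
#' Both strands are searched.  Among candidate alignments passing the
#' identity and aligned-fraction thresholds, the best is chosen by highest
#' identity, then most alignment columns, then lexicographically smallest
#' reference id, then forward strand -- a deterministic order.
#'
#' @param sequence A single read sequence.
#' @param index A `kmer_index` from [build_index()].
#' @param min_identity Minimum identity over alignment columns
#'   (default 0.98).
#' @param min_aln_frac Minimum fraction of the read covered by the
#'   alignment (default 0.9; guards against short spurious seed hits).
#' @param band Diagonal half-width of the banded extension (default 10).
#' @param max_candidates Candidate (reference, strand) pairs to extend,
#'   ranked by seed count (default 10).
#' @return `NULL` if nothing passes, else a list with `put_id`, `strand`
#'   (`"+"`/`"-"`), `identity`, `n_match`, `n_mismatch`, `n_gapcols`,
#'   `ref_start`, `ref_end` (0-based half-open), `read_start`, `read_end`,
#'   `aln_frac`, and `pairs`: a data.table of `ref_pos` (0-based) and
#'   `base`, the read base carried at that reference position (reference
#'   strand orientation) -- the pileup substrate.
#' @export
map_read <- function(sequence, index, min_identity = 0.98,
                     min_aln_frac = 0.9, band = 10, max_candidates = 10) {
  stopifnot(inherits(index, "kmer_index"))
  L <- nchar(sequence)
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else revcomp(sequence)
    km <- kmerize(s, index$k)
    if (nrow(km) == 0) next
    hits <- index$table[km, on = "kmer", nomatch = NULL]
    if (nrow(hits) == 0) next
    hits[, diag_ := pos0 - i.pos0]
    cand <- hits[, .N, by = ref][order(-N, ref)]
    cand <- head(cand, max_candidates)
    for (rid in cand$ref) {
      dd <- hits[ref == rid, diag_]
      d0 <- as.integer(names(sort(table(dd), decreasing = TRUE))[1])
      a <- extend_candidate(s, index$refs[[rid]], d0, band)
      cols <- a$n_match + a$n_mismatch + a$n_gapcols
      if (cols == 0) next
      ident <- a$n_match / cols
      frac <- (a$read_end - a$read_start) / L
      if (ident < min_identity || frac < min_aln_frac) next
      better <- is.null(best) ||
        ident > best$identity + 1e-12 ||
        (abs(ident - best$identity) <= 1e-12 && cols > best$n_cols) ||
        (abs(ident - best$identity) <= 1e-12 && cols == best$n_cols &&
           (rid < best$put_id || (rid == best$put_id && strand == "+" &&
                                    best$strand == "-")))
      if (better) {
        best <- list(put_id = rid, strand = strand, identity = ident,
                     n_match = a$n_match, n_mismatch = a$n_mismatch,
                     n_gapcols = a$n_gapcols, n_cols = cols,
                     ref_start = a$ref_start, ref_end = a$ref_end,
                     read_start = a$read_start, read_end = a$read_end,
                     aln_frac = frac,
                     pairs = data.table(ref_pos = a$ref_pos, base = a$base))
      }
    }
  }
  best
}

#' Map a table of reads
#'
#' @param reads Data.frame with `read_id`, `sequence` and optionally
#'   `library`.
#' @inheritParams map_read
#' @return An object of class `alignment_set`: a data.table with one row
#'   per mapped read (`read_id`, `library`, `put_id`, `strand`,
#'   `identity`, counts, coordinates, `aln_frac`) and a `pairs`
#'   list-column.  Unmapped reads are absent; their ids are kept in
#'   `attr(, "unmapped")`.
#' @export
map_reads <- function(reads, index, min_identity = 0.98, min_aln_frac = 0.9,
                      band = 10, max_candidates = 10) {
  lib <- if (is.null(reads$library)) rep(NA_character_, nrow(reads)) else reads$library
  rows <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    a <- map_read(reads$sequence[i], index, min_identity = min_identity,
                  min_aln_frac = min_aln_frac, band = band,
                  max_candidates = max_candidates)
    if (is.null(a)) next
    rows[[i]] <- data.table(
      read_id = reads$read_id[i], library = lib[i], put_id = a$put_id,
      strand = a$strand, identity = a$identity, n_match = a$n_match,
      n_mismatch = a$n_mismatch, n_gapcols = a$n_gapcols,
      ref_start = a$ref_start, ref_end = a$ref_end,
      read_start = a$read_start, read_end = a$read_end,
      aln_frac = a$aln_frac, pairs = list(a$pairs)
    )
  }
  got <- !vapply(rows, is.null, logical(1))
  out <- if (any(got)) rbindlist(rows[got]) else
    data.table(read_id = character(0), library = character(0),
               put_id = character(0), strand = character(0),
               identity = numeric(0), n_match = integer(0),
               n_mismatch = integer(0), n_gapcols = integer(0),
               ref_start = integer(0), ref_end = integer(0),
               read_start = integer(0), read_end = integer(0),
               aln_frac = numeric(0), pairs = list())
  setattr(out, "unmapped", reads$read_id[!got])
  setattr(out, "class", c("alignment_set", class(out)))
  out
}

#' Export alignments as a SAM-like TSV
#'
#' Columns: read_id, put_id, strand, ref_start (1-based), ref_end,
#' identity, n_match, n_mismatch, n_gapcols, aln_frac.
#'
#' @param alignments An `alignment_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignment_tsv <- function(alignments, path) {
  tab <- as.data.frame(alignments[, .(read_id, put_id, strand,
                                      ref_start = ref_start + 1L, ref_end,
                                      identity, n_match, n_mismatch,
                                      n_gapcols, aln_frac)])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
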