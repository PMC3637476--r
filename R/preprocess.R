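# Read cleaning for 454 cDNA reads: N removal, terminal and internal
# polyA/T handling, and a minimum-length filter.  "polyA/T" means a
# homopolymer of A or a homopolymer of T (a poly(A) tail or its reverse
# complement); mixed A/T runs do not count.  The rules are applied in a
# fixed order so every removal count is well defined:
#   N-check -> terminal-run check -> internal trim -> length check.

polyAT_runs <- function(seq, min_run) {
  m <- gregexpr(sprintf("A{%d,}|T{%d,}", min_run, min_run), seq)[[1]]
  if (m[1] == -1) return(NULL)
  data.frame(start = as.integer(m), len = attr(m, "match.length"))
}

#' Clean a single read
#'
#' Applies, in order: (1) discard any read containing `N`; (2) discard --
#' or, under `terminal_policy = "trim"`, strip -- a terminal homopolymer
#' run of A or T of at least `polyAT_min_run` bases at either end; (3) if
#' internal polyA/T tracts remain, split at every tract and keep the
#' longest fragment (ties resolved toward the 5' fragment); (4) discard
#' anything shorter than `min_len`.
#'
#' @param sequence A single nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @param min_len Minimum kept length (bp), default 50.
#' @param polyAT_min_run Minimum homopolymer run length (bp), default 8.
#' @param terminal_policy `"discard"` (default, the literal rule) or
#'   `"trim"`: what to do with terminal polyA/T runs.
#' @return A list with `status` (`"kept"`, `"trimmed"`, `"discarded"`),
#'   `sequence` (the kept sequence, or `NA`) and `reason` (`NA`, `"N"`,
#'   `"terminal_polyAT"`, `"short"`).
#' @examples
#' clean_read(paste0(strrep("ACGT", 30), strrep("A", 10), strrep("CGTA", 10)))
#' @export
clean_read <- function(sequence, min_len = 50, polyAT_min_run = 8,
                       terminal_policy = c("discard", "trim")) {
  terminal_policy <- match.arg(terminal_policy)
  if (length(sequence) != 1L || !nzchar(sequence)) {
    stopf("sequence must be a single non-empty string")
  }
  if (grepl("[^ACGTN]", sequence)) {
    stopf("sequence contains characters outside {A,C,G,T,N}")
  }
  res <- function(status, seq = NA_character_, reason = NA_character_) {
    list(status = status, sequence = seq, reason = reason)
  }
  if (grepl("N", sequence, fixed = TRUE)) return(res("discarded", reason = "N"))

  trimmed <- FALSE
  term_re <- sprintf("^(A{%d,}|T{%d,})|(A{%d,}|T{%d,})$",
                     polyAT_min_run, polyAT_min_run,
                     polyAT_min_run, polyAT_min_run)
  if (grepl(term_re, sequence)) {
    if (terminal_policy == "discard") {
      return(res("discarded", reason = "terminal_polyAT"))
    }
    while (grepl(term_re, sequence) && nzchar(sequence)) {
      sequence <- sub(sprintf("^(A{%d,}|T{%d,})", polyAT_min_run, polyAT_min_run),
                      "", sequence)
      sequence <- sub(sprintf("(A{%d,}|T{%d,})$", polyAT_min_run, polyAT_min_run),
                      "", sequence)
    }
    trimmed <- TRUE
    if (!nzchar(sequence)) return(res("discarded", reason = "short"))
  }

  runs <- polyAT_runs(sequence, polyAT_min_run)
  if (!is.null(runs)) {
    cut_start <- c(1L, runs$start + runs$len)
    cut_end <- c(runs$start - 1L, nchar(sequence))
    frag_len <- cut_end - cut_start + 1L
    best <- which.max(frag_len)  # ties resolve toward the 5' fragment
    sequence <- if (frag_len[best] > 0) {
      substr(sequence, cut_start[best], cut_end[best])
    } else ""
    trimmed <- TRUE
  }
  if (nchar(sequence) < min_len) return(res("discarded", reason = "short"))
  res(if (trimmed) "trimmed" else "kept", seq = sequence)
}

#' Clean a set of reads from one library
#'
#' Order-stable application of [clean_read()] with exact bookkeeping.
#'
#' @param reads Data.frame with at least `read_id`, `sequence` and
#'   (optionally) `library`; all rows must share one library code.
#' @inheritParams clean_read
#' @return List with `reads` (the kept reads, trimmed sequences in place,
#'   original order) and `report`, a one-row data.frame with `n_input`,
#'   `n_removed_N`, `n_removed_terminal_polyAT`, `n_removed_short`,
#'   `n_trimmed_internal`, `n_kept`, `mean_len_before`, `mean_len_after`.
#'   Counts reconcile exactly: the three removal counts plus `n_kept`
#'   equal `n_input`.
#' @export
preprocess_library <- function(reads, min_len = 50, polyAT_min_run = 8,
                               terminal_policy = c("discard", "trim")) {
  terminal_policy <- match.arg(terminal_policy)
  if (!is.null(reads$library) && length(unique(reads$library)) > 1) {
    stopf("preprocess_library expects reads from a single library")
  }
  n <- nrow(reads)
  if (n == 0) {
    rep0 <- data.frame(n_input = 0L, n_removed_N = 0L,
                       n_removed_terminal_polyAT = 0L, n_removed_short = 0L,
                       n_trimmed_internal = 0L, n_kept = 0L,
                       mean_len_before = NA_real_, mean_len_after = NA_real_)
    return(list(reads = reads, report = rep0))
  }
  out <- lapply(reads$sequence, clean_read, min_len = min_len,
                polyAT_min_run = polyAT_min_run,
                terminal_policy = terminal_policy)
  status <- vapply(out, `[[`, character(1), "status")
  reason <- vapply(out, `[[`, character(1), "reason")
  kept <- status != "discarded"
  res <- reads[kept, , drop = FALSE]
  res$sequence <- vapply(out[kept], `[[`, character(1), "sequence")
  if (!is.null(res$quality)) {
    res$quality <- substr(res$quality, 1L, nchar(res$sequence))
  }
  report <- data.frame(
    n_input = n,
    n_removed_N = sum(reason == "N", na.rm = TRUE),
    n_removed_terminal_polyAT = sum(reason == "terminal_polyAT", na.rm = TRUE),
    n_removed_short = sum(reason == "short", na.rm = TRUE),
    n_trimmed_internal = sum(status == "trimmed"),
    n_kept = sum(kept),
    mean_len_before = mean(nchar(reads$sequence)),
    mean_len_after = if (any(kept)) mean(nchar(res$sequence)) else NA_real_
  )
  list(reads = res, report = report)
}

#' Clean a multi-library read set
#'
#' Splits by library code, cleans each library with
#' [preprocess_library()], and stacks results with one report row per
#' library.
#'
#' @param reads Data.frame with `read_id`, `sequence`, `library`.
#' @inheritParams clean_read
#' @return List with `reads` and `report` (one row per library plus
#'   a `library` column).
#' @export
preprocess_reads <- function(reads, min_len = 50, polyAT_min_run = 8,
                             terminal_policy = c("discard", "trim")) {
  terminal_policy <- match.arg(terminal_policy)
  libs <- unique(reads$library)
  parts <- lapply(libs, function(l) {
    p <- preprocess_library(reads[reads$library == l, , drop = FALSE],
                            min_len = min_len, polyAT_min_run = polyAT_min_run,
                            terminal_policy = terminal_policy)
    p$report <- cbind(library = l, p$report)
    p
  })
  list(
    reads = do.call(rbind, c(lapply(parts, `[[`, "reads"),
                             list(make.row.names = FALSE))),
    report = do.call(rbind, c(lapply(parts, `[[`, "report"),
                              list(make.row.names = FALSE)))
  )
}
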