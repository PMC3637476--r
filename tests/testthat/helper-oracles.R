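# Independent oracles and fixture builders used across the suite.

# Full (unbanded) local alignment by plain dynamic programming; the
# brute-force counterpart of the package's banded seed-and-extend mapper.
oracle_local_align <- function(read, ref, match = 2, mismatch = -1, gap = -2) {
  n <- nchar(read); m <- nchar(ref)
  r <- strsplit(read, NULL)[[1]]
  f <- strsplit(ref, NULL)[[1]]
  S <- matrix(0, n + 1, m + 1)
  TB <- matrix(0L, n + 1, m + 1)
  best <- 0; bi <- 0; bj <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      d <- S[i, j] + if (r[i] == f[j]) match else mismatch
      u <- S[i, j + 1] + gap    # consume read base only
      l <- S[i + 1, j] + gap    # consume ref base only
      s <- max(0, d, u, l)
      S[i + 1, j + 1] <- s
      TB[i + 1, j + 1] <- if (s == 0) 0L else if (s == d) 1L else if (s == l) 2L else 3L
      if (s > best) { best <- s; bi <- i + 1; bj <- j + 1 }
    }
  }
  if (best <= 0) return(NULL)
  i <- bi; j <- bj; nm <- 0L; nx <- 0L; ng <- 0L
  while (TB[i, j] != 0L) {
    tb <- TB[i, j]
    if (tb == 1L) {
      if (r[i - 1] == f[j - 1]) nm <- nm + 1L else nx <- nx + 1L
      i <- i - 1; j <- j - 1
    } else if (tb == 2L) { ng <- ng + 1L; j <- j - 1 }
    else { ng <- ng + 1L; i <- i - 1 }
  }
  list(identity = nm / (nm + nx + ng), n_match = nm, n_mismatch = nx,
       n_gapcols = ng)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

mutate_at <- function(seq, pos1) {
  old <- substr(seq, pos1, pos1)
  new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  substr(seq, pos1, pos1) <- new
  seq
}

# Pileup rows for a single site: n reads per allele, with library codes.
site_pileup <- function(counts, libs = NULL, put = "put1", pos = 10L) {
  rows <- list()
  i <- 0L
  for (b in names(counts)) {
    for (r in seq_len(counts[[b]])) {
      i <- i + 1L
      lib <- if (is.null(libs)) "DCNC" else libs[[b]][(r - 1L) %% length(libs[[b]]) + 1L]
      rows[[i]] <- data.table::data.table(put_id = put, pos = pos, base = b,
                                          read_id = sprintf("r%03d", i),
                                          library = lib)
    }
  }
  p <- data.table::rbindlist(rows)
  data.table::setattr(p, "class", c("pileup", class(p)))
  p
}

# A minimal single-HSP hit set for one query.
one_hsp <- function(query, q_start, q_end, frame, evalue = 1e-30,
                    subject = "s1", description = "hypothetical protein",
                    bitscore = 100) {
  blast_hit_set(data.frame(query = query, subject = subject,
                           description = description, evalue = evalue,
                           bitscore = bitscore, q_start = q_start,
                           q_end = q_end, frame = frame,
                           s_start = 1L, s_end = (q_end - q_start + 1L) %/% 3L))
}

# Translate with seqinr -- an implementation-independent oracle.
oracle_translate <- function(codon) {
  toupper(seqinr::translate(strsplit(tolower(codon), NULL)[[1]]))
}

oracle_translate_all <- function(seq) {
  paste(toupper(seqinr::translate(strsplit(tolower(seq), NULL)[[1]])),
        collapse = "")
}
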