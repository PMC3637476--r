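# Synonymous/non-synonymous annotation of SNPs from protein-alignment
# (BLASTX-style) high-scoring segment pairs.  Only the top hit of a query
# is used; all of its HSPs are considered.  The HSP frame (+-1..3, sign =
# query strand) determines the codon containing the SNP; both alleles are
# translated with the standard nuclear code and compared.

BLAST_COLUMNS <- c("query", "subject", "description", "evalue", "bitscore",
                   "q_start", "q_end", "frame", "s_start", "s_end")

#' Construct a BLASTX-style hit set
#'
#' @param hits Data.frame with columns `query`, `subject`, `description`,
#'   `evalue`, `bitscore`, `q_start`, `q_end` (1-based inclusive on the
#'   query), `frame` (one of -3..-1, 1..3), `s_start`, `s_end`.  One row
#'   per HSP.  `NULL` yields an empty set.
#' @return An object of class `blast_hit_set` (a data.table ordered by
#'   query, then ascending e-value).
#' @export
blast_hit_set <- function(hits = NULL) {
  if (is.null(hits) || nrow(hits) == 0) {
    out <- as.data.table(setNames(
      list(character(0), character(0), character(0), numeric(0), numeric(0),
           integer(0), integer(0), integer(0), integer(0), integer(0)),
      BLAST_COLUMNS))
  } else {
    missing_cols <- setdiff(BLAST_COLUMNS, names(hits))
    if (length(missing_cols) > 0) {
      stopf("blast hits lack column(s): %s", paste(missing_cols, collapse = ", "))
    }
    if (!all(hits$frame %in% c(-3:-1, 1:3))) stopf("frame must be in -3..-1, 1..3")
    if (any(hits$q_start < 1 | hits$q_end < hits$q_start)) {
      stopf("HSP query coordinates must satisfy 1 <= q_start <= q_end")
    }
    out <- as.data.table(hits[, BLAST_COLUMNS])
    setorder(out, query, evalue)
  }
  setattr(out, "class", c("blast_hit_set", class(out)))
  out
}

#' Read a tabular-with-comments BLAST hit file
#'
#' Expects tab-separated columns `query`, `subject`, `description`,
#' `evalue`, `bitscore`, `q_start`, `q_end`, `frame`, `s_start`, `s_end`
#' with a header line; lines starting with `#` are ignored.
#'
#' @param path Input file.
#' @return A `blast_hit_set`.
#' @export
read_blast_tab <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    quote = "", stringsAsFactors = FALSE)
  blast_hit_set(tab)
}

#' Write a `blast_hit_set` in the same dialect
#'
#' @param hits A `blast_hit_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# All HSPs of the top (smallest e-value) hit of one query.
top_hit_hsps <- function(hits, query_id) {
  h <- hits[hits$query == query_id, , drop = FALSE]
  if (nrow(h) == 0) return(NULL)
  top_subject <- h$subject[which.min(h$evalue)]
  h[h$subject == top_subject, , drop = FALSE]
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# Effect of substituting allele1 <-> allele2 at 0-based position pos of
# sequence seq under one HSP's frame.  Returns "synonymous",
# "nonsynonymous" or NA (frame/coordinate inconsistency).
hsp_effect <- function(seq, pos, allele1, allele2, q_start, q_end, frame) {
  L <- nchar(seq)
  pos1 <- pos + 1L
  if ((q_end - q_start + 1L) %% 3L != 0L) return(NA_character_)
  if (frame > 0) {
    if ((q_start - 1L) %% 3L != (frame - 1L) %% 3L) return(NA_character_)
    cs <- q_start + 3L * ((pos1 - q_start) %/% 3L)
    if (cs + 2L > q_end || cs + 2L > L) return(NA_character_)
    codon <- substr(seq, cs, cs + 2L)
    off <- pos1 - cs + 1L
    c1 <- str_sub_at(codon, off, allele1)
    c2 <- str_sub_at(codon, off, allele2)
  } else {
    if ((L - q_end) %% 3L != (abs(frame) - 1L) %% 3L) return(NA_character_)
    d <- q_end - pos1
    cs <- q_end - 3L * (d %/% 3L) - 2L  # codon window on the top strand
    if (cs < q_start || cs < 1L) return(NA_character_)
    codon <- revcomp(substr(seq, cs, cs + 2L))
    off <- d %% 3L + 1L
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    c1 <- str_sub_at(codon, off, comp[[allele1]])
    c2 <- str_sub_at(codon, off, comp[[allele2]])
  }
  aa1 <- translate_codon(c1)
  aa2 <- translate_codon(c2)
  if (is.na(aa1) || is.na(aa2)) return(NA_character_)
  if (aa1 == aa2) "synonymous" else "nonsynonymous"
}

#' Classify the coding effect of a single SNP
#'
#' `noncoding` if the position falls in no HSP of the query's top hit;
#' `unannotated` if the query has no hit at all or the covering HSP's
#' frame and coordinates are inconsistent; otherwise the codon containing
#' the position is translated under the HSP frame with each allele in
#' turn.  Among overlapping HSPs the one with the highest bit score wins.
#'
#' @param put_id Query (PUT) id.
#' @param pos 0-based SNP position on the PUT.
#' @param allele1,allele2 The two alleles.
#' @param blast A `blast_hit_set`.
#' @param put_seqs Named character vector of PUT sequences.
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"noncoding"`,
#'   `"unannotated"`.
#' @export
coding_effect_at <- function(put_id, pos, allele1, allele2, blast, put_seqs) {
  hsps <- top_hit_hsps(blast, put_id)
  if (is.null(hsps)) return("unannotated")
  pos1 <- pos + 1L
  cover <- hsps[hsps$q_start <= pos1 & pos1 <= hsps$q_end, , drop = FALSE]
  if (nrow(cover) == 0) return("noncoding")
  cover <- cover[order(-cover$bitscore), , drop = FALSE]
  seq <- put_seqs[[put_id]]
  if (is.null(seq)) stopf("no sequence for PUT '%s'", put_id)
  eff <- hsp_effect(seq, pos, allele1, allele2,
                    cover$q_start[1], cover$q_end[1], cover$frame[1])
  if (is.na(eff)) "unannotated" else eff
}

#' Annotate a SNP table with coding effects
#'
#' @param snps A `snp_calls`/`consensus_snps` table.
#' @param blast A `blast_hit_set`.
#' @param puts PUT sequences (named vector or `put_set`).
#' @return The input with a `coding_effect` column added.
#' @export
classify_coding_effect <- function(snps, blast, puts) {
  seqs <- put_sequences(puts)
  out <- copy(snps)
  if (nrow(out) == 0) {
    out[, coding_effect := character(0)]
    return(out[])
  }
  out[, coding_effect := mapply(coding_effect_at, put_id, pos, allele1, allele2,
                                MoreArgs = list(blast = blast, put_seqs = seqs))]
  out[]
}
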