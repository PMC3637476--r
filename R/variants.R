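# Pileup SNP calling with a per-allele minimum support rule, intersection
# of callsets into a conservative consensus, and classification of each
# consensus SNP by the provenance (variety) of its supporting reads.
#
# Because no genome reference fixes which allele is "reference", alleles
# are stored in canonical lexicographic order throughout; every statistic
# downstream is invariant under swapping the allele labels.

call_key <- function(x) paste(x$put_id, x$pos, x$allele1, x$allele2, sep = ":")

empty_calls <- function() {
  data.table(put_id = character(0), pos = integer(0),
             allele1 = character(0), allele2 = character(0),
             n1 = integer(0), n2 = integer(0), multiallelic = logical(0),
             support1 = list(), support2 = list(),
             libs1 = list(), libs2 = list())
}

#' Build a pileup from alignments
#'
#' One row per aligned, non-gap read base: gap columns carry no allele
#' support.
#'
#' @param alignments An `alignment_set` from [map_reads()].
#' @param puts Optional catalogue (`put_set` or named vector) used to
#'   check that no alignment runs off its reference.
#' @return An object of class `pileup`: a data.table with `put_id`, `pos`
#'   (0-based), `base`, `read_id`, `library`.
#' @export
build_pileup <- function(alignments, puts = NULL) {
  if (nrow(alignments) == 0) {
    out <- data.table(put_id = character(0), pos = integer(0),
                      base = character(0), read_id = character(0),
                      library = character(0))
    setattr(out, "class", c("pileup", class(out)))
    return(out)
  }
  if (!is.null(puts)) {
    lens <- nchar(put_sequences(puts))
    over <- alignments$ref_end > lens[alignments$put_id]
    if (any(is.na(over)) || any(over)) {
      stopf("alignment targets an unknown reference or runs off its end")
    }
  }
  parts <- lapply(seq_len(nrow(alignments)), function(i) {
    p <- alignments$pairs[[i]]
    data.table(put_id = alignments$put_id[i], pos = p$ref_pos, base = p$base,
               read_id = alignments$read_id[i], library = alignments$library[i])
  })
  out <- rbindlist(parts)
  setattr(out, "class", c("pileup", class(out)))
  out
}

#' Call SNPs from a pileup
#'
#' A site is called iff its two most-supported alleles each reach
#' `min_allele_support` reads (default 3; the minimum callable site depth
#' is therefore 6).  At sites where three or more alleles reach the
#' threshold, the top two by count (ties broken lexicographically) are
#' used and the call is flagged `multiallelic`.  Alleles are reported in
#' canonical lexicographic order.
#'
#' @param pile A `pileup`.
#' @param min_allele_support Minimum reads per allele (default 3).
#' @return An object of class `snp_calls`: data.table with `put_id`, `pos`,
#'   `allele1`, `allele2` (`allele1 < allele2`), `n1`, `n2`,
#'   `multiallelic`, and list-columns `support1`, `support2` (read ids)
#'   and `libs1`, `libs2` (library codes, parallel to the read ids).
#' @export
call_snps <- function(pile, min_allele_support = 3) {
  out <- empty_calls()
  if (nrow(pile) > 0) {
    cnt <- pile[base %in% DNA_BASES, .N, by = .(put_id, pos, base)]
    setorder(cnt, put_id, pos, -N, base)
    cnt[, rank_ := seq_len(.N), by = .(put_id, pos)]
    top <- cnt[rank_ <= 2L]
    wide <- dcast(top, put_id + pos ~ rank_, value.var = c("base", "N"))
    if ("base_2" %in% names(wide)) {
      hit <- wide[!is.na(base_2) & N_1 >= min_allele_support &
                    N_2 >= min_allele_support]
      if (nrow(hit) > 0) {
        n3 <- cnt[rank_ == 3L & N >= min_allele_support,
                  .(put_id, pos, multi_ = TRUE)]
        hit <- merge(hit, n3, by = c("put_id", "pos"), all.x = TRUE)
        hit[, multiallelic := !is.na(multi_)]
        # canonical allele order
        hit[, `:=`(allele1 = pmin(base_1, base_2),
                   allele2 = pmax(base_1, base_2))]
        hit[, `:=`(n1 = fifelse(allele1 == base_1, N_1, N_2),
                   n2 = fifelse(allele1 == base_1, N_2, N_1))]
        sup <- pile[hit[, .(put_id, pos, allele1, allele2)],
                    on = .(put_id, pos)][base == allele1 | base == allele2]
        sup[, which_ := fifelse(base == allele1, 1L, 2L)]
        agg <- sup[, .(reads = list(read_id), libs = list(library)),
                   by = .(put_id, pos, which_)]
        a1 <- agg[which_ == 1L]
        a2 <- agg[which_ == 2L]
        out <- hit[, .(put_id, pos, allele1, allele2, n1, n2, multiallelic)]
        out <- merge(out, a1[, .(put_id, pos, support1 = reads, libs1 = libs)],
                     by = c("put_id", "pos"))
        out <- merge(out, a2[, .(put_id, pos, support2 = reads, libs2 = libs)],
                     by = c("put_id", "pos"))
        setcolorder(out, c("put_id", "pos", "allele1", "allele2", "n1", "n2",
                           "multiallelic", "support1", "support2",
                           "libs1", "libs2"))
        setorder(out, put_id, pos)
      }
    }
  }
  setattr(out, "class", c("snp_calls", class(out)))
  out
}

#' Intersect callsets into a conservative consensus
#'
#' A consensus SNP must appear with identical reference, position and
#' unordered allele pair in every callset; supporting reads are merged by
#' union across callsets.
#'
#' @param callsets List of at least two `snp_calls` objects against the
#'   same catalogue.
#' @return An object of class `consensus_snps`: the consensus calls with
#'   an `n_callsets` column equal to `length(callsets)`.
#' @export
intersect_callsets <- function(callsets) {
  if (!is.list(callsets) || length(callsets) < 2) {
    stopf("intersection requires at least two callsets")
  }
  keys <- lapply(callsets, call_key)
  common <- Reduce(intersect, keys)
  base_set <- copy(callsets[[1]])
  base_set[, key_ := call_key(base_set)]
  out <- base_set[key_ %in% common]
  if (nrow(out) > 0 && length(callsets) > 1) {
    for (j in 2:length(callsets)) {
      other <- callsets[[j]]
      if (nrow(other) == 0) next
      ok <- call_key(other)
      idx <- match(out$key_, ok)
      for (r in seq_len(nrow(out))) {
        i2 <- idx[r]
        if (is.na(i2)) next
        m1 <- !(other$support1[[i2]] %in% out$support1[[r]])
        m2 <- !(other$support2[[i2]] %in% out$support2[[r]])
        set(out, r, "support1", list(list(c(out$support1[[r]], other$support1[[i2]][m1]))))
        set(out, r, "libs1", list(list(c(out$libs1[[r]], other$libs1[[i2]][m1]))))
        set(out, r, "support2", list(list(c(out$support2[[r]], other$support2[[i2]][m2]))))
        set(out, r, "libs2", list(list(c(out$libs2[[r]], other$libs2[[i2]][m2]))))
      }
    }
    out[, `:=`(n1 = lengths(support1), n2 = lengths(support2))]
  }
  out[, key_ := NULL]
  out[, n_callsets := length(callsets)]
  setattr(out, "class", c("consensus_snps", "snp_calls", "data.table",
                          "data.frame"))
  out[]
}

#' Pool a pair of allele origins into a provenance category
#'
#' The nine ordered pairs over \{`c`, `i`, `ci`\} pool into six unordered
#' categories; the result is invariant under swapping the alleles.
#'
#' @param origin1,origin2 Allele origins, each `"c"`, `"i"` or `"ci"`.
#' @return One of [PROVENANCE_CATEGORIES].
#' @examples
#' pool_provenance("ci", "c")  # "ci/c"
#' pool_provenance("c", "ci")  # also "ci/c"
#' @export
pool_provenance <- function(origin1, origin2) {
  ok <- c("c", "i", "ci")
  if (!(origin1 %in% ok) || !(origin2 %in% ok)) {
    stopf("origins must be 'c', 'i' or 'ci'")
  }
  p <- sort(c(origin1, origin2))
  switch(paste(p, collapse = "|"),
         "ci|ci" = "ci/ci", "c|ci" = "ci/c", "ci|i" = "ci/i",
         "c|i" = "c/i", "c|c" = "c/c", "i|i" = "i/i")
}

allele_origin <- function(libs) {
  v <- unique(substr(libs, 2, 2))
  if (!all(v %in% c("C", "I"))) stopf("unknown library code among %s",
                                      paste(unique(libs), collapse = ", "))
  if (length(v) == 2) "ci" else if (v == "C") "c" else "i"
}

#' Classify consensus SNPs by read provenance
#'
#' Each allele's origin is the set of varieties (coastal/interior, decoded
#' from the supporting reads' library codes) observed among its supporting
#' reads; the ordered pair is pooled via [pool_provenance()].
#'
#' @param snps A `snp_calls` or `consensus_snps` object with `libs1`,
#'   `libs2` populated.
#' @return The input with `origin1`, `origin2` and `provenance_category`
#'   columns added.
#' @export
classify_provenance <- function(snps) {
  out <- copy(snps)
  if (nrow(out) == 0) {
    out[, `:=`(origin1 = character(0), origin2 = character(0),
               provenance_category = character(0))]
    return(out[])
  }
  out[, origin1 := vapply(libs1, allele_origin, character(1))]
  out[, origin2 := vapply(libs2, allele_origin, character(1))]
  out[, provenance_category := mapply(pool_provenance, origin1, origin2)]
  out[]
}

#' Tabulate provenance categories
#'
#' @param snps Output of [classify_provenance()].
#' @return Data.frame with one row per category (all six always present)
#'   and columns `category`, `n_snps`.
#' @export
summarize_provenance <- function(snps) {
  tab <- table(factor(snps$provenance_category, levels = PROVENANCE_CATEGORIES))
  data.frame(category = names(tab), n_snps = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}
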