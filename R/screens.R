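# Treatment-origin partitioning of isotigs, group and length-bin
# summaries, keyword candidate screening, the length-reads correlation,
# and the polymorphism-level estimator over distinct catalogue
# nucleotides.

#' Default keyword catalogue for drought-stress screening
#'
#' Twenty-one search terms covering drought, water and osmotic stress,
#' heat stress, ABA signalling and the classical drought-responsive
#' regulators; matching is case-insensitive substring.  User-extensible
#' via [keyword_catalog()].
#'
#' @return Character vector of 21 terms.
#' @export
default_keyword_catalog <- function() {
  c("Drought", "Water-deficit", "Water-stress", "Osmotic-stress",
    "Heat-stress", "Heat-shock", "Dehydration", "Abscisic acid",
    "ABA-responsive", "ABA-induced", "ABA receptor",
    "Pyrabactin resistance 1", "Snf1-related protein kinases",
    "DREB1", "DREB2", "C-repeat binding", "ERD", "CIPK", "CDPK",
    "CBL1", "PKS3")
}

#' Validate a keyword catalogue
#'
#' @param terms Non-empty character vector of unique search terms.
#' @return The terms, classed `keyword_catalog`.
#' @export
keyword_catalog <- function(terms = default_keyword_catalog()) {
  if (length(terms) == 0) stopf("keyword catalogue must be non-empty")
  if (anyDuplicated(terms)) stopf("keyword catalogue terms must be unique")
  structure(terms, class = "keyword_catalog")
}

#' Partition isotigs by the treatments of their member reads
#'
#' Each isotig is assigned the sorted set of treatments (`c` = control,
#' `m` = mild, `s` = severe) observed among its member reads' library
#' codes, yielding one of the seven groups `c`, `m`, `s`, `cm`, `cs`,
#' `ms`, `cms`.  Tissue and variety are pooled by design.
#'
#' @param members Data.frame with `isotig_id` and `library` (one row per
#'   member read), e.g. the `members` slot of an `assembly_table`.
#' @param isotig_ids Optional full isotig id set; an id without member
#'   reads is a contract violation and raises an error.
#' @return Data.frame with `isotig_id` and `group`.
#' @export
partition_by_treatment <- function(members, isotig_ids = NULL) {
  decode_library(unique(members$library))
  if (!is.null(isotig_ids)) {
    orphan <- setdiff(isotig_ids, members$isotig_id)
    if (length(orphan) > 0) {
      stopf("isotig(s) without member reads: %s", paste(head(orphan, 5), collapse = ", "))
    }
  }
  dt <- as.data.table(members)
  dt[, treatment := c(C = "c", M = "m", S = "s")[substr(library, 4, 4)]]
  grp <- dt[, .(group = paste(sort(unique(treatment)), collapse = "")),
            by = isotig_id]
  as.data.frame(grp)
}

#' Summarize the treatment groups
#'
#' @param partition Output of [partition_by_treatment()].
#' @param lengths Named numeric vector of isotig lengths.
#' @param hits Optional data.frame with `isotig_id`, `db`, `hit` (logical)
#'   giving per-database hit indicators; one `pct_hit_<db>` column is
#'   emitted per database.
#' @return Data.frame with one row per group (all seven, in canonical
#'   order): `group`, `n_isotigs`, `percent_of_all`, `mean_length`, and
#'   hit percentages.
#' @export
summarize_groups <- function(partition, lengths, hits = NULL) {
  p <- as.data.table(partition)
  p[, length_ := as.numeric(lengths[isotig_id])]
  base_tab <- p[, .(n_isotigs = .N, mean_length = mean(length_)), by = group]
  out <- data.table(group = TREATMENT_GROUPS)
  out <- merge(out, base_tab, by = "group", all.x = TRUE, sort = FALSE)
  out[is.na(n_isotigs), n_isotigs := 0L]
  out[, percent_of_all := 100 * n_isotigs / sum(n_isotigs)]
  if (!is.null(hits)) {
    h <- as.data.table(hits)
    for (d in sort(unique(h$db))) {
      hd <- h[db == d & hit == TRUE, unique(isotig_id)]
      p[, hit_ := isotig_id %in% hd]
      ph <- p[, .(pct = 100 * mean(hit_)), by = group]
      out[, (paste0("pct_hit_", d)) := ph$pct[match(group, ph$group)]]
    }
  }
  out <- out[match(TREATMENT_GROUPS, group)]
  setcolorder(out, c("group", "n_isotigs", "percent_of_all", "mean_length"))
  as.data.frame(out)
}

#' Summarize the catalogue by length bins
#'
#' Default bins: `< 501`, `501-1000`, `1001-1999`, `>= 2000` bp (the 2000
#' boundary falls in the top bin).
#'
#' @param lengths Named numeric vector of PUT lengths.
#' @param hits Optional `isotig_id`/`db`/`hit` data.frame as in
#'   [summarize_groups()] (ids here are PUT ids).
#' @param go_annotated Optional named logical vector: whether each PUT
#'   carries a functional-ontology annotation.
#' @param breaks Increasing interior break points (default
#'   `c(501, 1001, 2000)`); bins are `[0, b1), [b1, b2), ...` and must
#'   cover all lengths disjointly.
#' @return Data.frame with one row per bin: `bin`, `n_puts`, `total_mbp`,
#'   per-database hit percentages, `pct_go_annotated`.
#' @export
summarize_by_length_bins <- function(lengths, hits = NULL, go_annotated = NULL,
                                     breaks = c(501, 1001, 2000)) {
  if (is.unsorted(breaks, strictly = TRUE)) {
    stopf("breaks must be strictly increasing (bins may not overlap)")
  }
  edges <- c(0, breaks, Inf)
  labs <- c(sprintf("<%d", breaks[1]),
            if (length(breaks) > 1) {
              sprintf("%d-%d", head(breaks, -1), breaks[-1] - 1)
            },
            sprintf(">=%d", breaks[length(breaks)]))
  dt <- data.table(put_id = names(lengths), length_ = as.numeric(lengths))
  dt[, bin := cut(length_, edges, labels = labs, right = FALSE)]
  out <- dt[, .(n_puts = .N, total_mbp = sum(length_) / 1e6), by = bin]
  full <- data.table(bin = factor(labs, levels = labs))
  out <- merge(full, out, by = "bin", all.x = TRUE, sort = FALSE)
  out[is.na(n_puts), `:=`(n_puts = 0L, total_mbp = 0)]
  if (!is.null(hits)) {
    h <- as.data.table(hits)
    for (d in sort(unique(h$db))) {
      hd <- h[db == d & hit == TRUE, unique(isotig_id)]
      dt[, hit_ := put_id %in% hd]
      ph <- dt[, .(pct = 100 * mean(hit_)), by = bin]
      out[, (paste0("pct_hit_", d)) := ph$pct[match(out$bin, ph$bin)]]
    }
  }
  if (!is.null(go_annotated)) {
    dt[, go_ := isTRUE_vec(go_annotated[put_id])]
    pg <- dt[, .(pct = 100 * mean(go_)), by = bin]
    out[, pct_go_annotated := pg$pct[match(out$bin, pg$bin)]]
  }
  out[, bin := as.character(bin)]
  as.data.frame(out)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Keyword candidate screen over BLAST hit descriptions
#'
#' An isotig counts for a term when any of its retained hits' description
#' contains the term as a case-insensitive substring.  Candidate
#' reporting lists, per (term, isotig), the best hit (smallest e-value).
#'
#' @param blast A `blast_hit_set`.
#' @param catalog A [keyword_catalog()] (or plain character vector).
#' @param partition Output of [partition_by_treatment()] giving each
#'   isotig's treatment group (isotigs absent from the partition are
#'   reported with group `NA`).
#' @param isogroups Optional named vector mapping isotig id to isogroup
#'   id, enabling the distinct-isogroup total.
#' @return List with `counts` (term x group matrix of distinct-isotig
#'   counts, as a data.frame with a `term` column), `candidates`
#'   (data.frame: `keyword`, `isotig_id`, `group`, `subject`,
#'   `description`, `evalue`), `n_distinct_isotigs`, and
#'   `n_distinct_isogroups` (`NA` without `isogroups`).
#' @export
keyword_screen <- function(blast, catalog = default_keyword_catalog(),
                           partition = NULL, isogroups = NULL) {
  terms <- unclass(keyword_catalog(catalog))
  h <- as.data.frame(blast)
  grp <- if (!is.null(partition)) {
    setNames(partition$group, partition$isotig_id)
  } else c()
  cand <- list()
  counts <- matrix(0L, nrow = length(terms), ncol = length(TREATMENT_GROUPS),
                   dimnames = list(terms, TREATMENT_GROUPS))
  all_iso <- character(0)
  for (tm in terms) {
    m <- h[grepl(tolower(tm), tolower(h$description), fixed = TRUE), , drop = FALSE]
    if (nrow(m) == 0) next
    all_iso <- union(all_iso, unique(m$query))
    for (q in unique(m$query)) {
      mq <- m[m$query == q, , drop = FALSE]
      best <- mq[which.min(mq$evalue), , drop = FALSE]
      g <- if (q %in% names(grp)) grp[[q]] else NA_character_
      if (!is.na(g) && g %in% TREATMENT_GROUPS) {
        counts[tm, g] <- counts[tm, g] + 1L
      }
      cand[[length(cand) + 1L]] <- data.frame(
        keyword = tm, isotig_id = q, group = g, subject = best$subject,
        description = best$description, evalue = best$evalue,
        stringsAsFactors = FALSE
      )
    }
  }
  candidates <- if (length(cand) > 0) {
    do.call(rbind, c(cand, list(make.row.names = FALSE)))
  } else {
    data.frame(keyword = character(0), isotig_id = character(0),
               group = character(0), subject = character(0),
               description = character(0), evalue = numeric(0))
  }
  n_isg <- if (!is.null(isogroups)) {
    length(unique(isogroups[all_iso][!is.na(isogroups[all_iso])]))
  } else NA_integer_
  list(counts = data.frame(term = terms, counts, check.names = FALSE,
                           row.names = NULL),
       candidates = candidates,
       n_distinct_isotigs = length(all_iso),
       n_distinct_isogroups = n_isg)
}

#' Correlation between transcript length and read count
#'
#' Pearson correlation, by default on log10-transformed pairs (a log-log
#' relationship is the natural scale for assembly depth); a linear-scale
#' option is provided.
#'
#' @param lengths,n_reads Numeric vectors (same order), at least 3 pairs.
#' @param log10_scale Transform both axes by log10 (default TRUE).
#' @return List with `r`, `p_value`, `n`, `scale`.  Zero variance on
#'   either axis is reported as `r = NA` with a note.
#' @export
length_reads_correlation <- function(lengths, n_reads, log10_scale = TRUE) {
  if (length(lengths) != length(n_reads)) stopf("inputs differ in length")
  if (length(lengths) < 3) stopf("need at least 3 isotigs")
  x <- if (log10_scale) log10(lengths) else lengths
  y <- if (log10_scale) log10(n_reads) else n_reads
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = length(x),
                scale = if (log10_scale) "log10" else "linear",
                note = "zero variance"))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       scale = if (log10_scale) "log10" else "linear")
}

#' Distinct nucleotides of a PUT catalogue
#'
#' A contig shared by several isotigs is counted once; singleton PUTs
#' count their full length.  Inconsistent contig lengths across isotigs
#' raise an error.
#'
#' @param put_set A `put_set`.
#' @return Total distinct nucleotides (integer).
#' @export
distinct_nucleotides <- function(put_set) {
  stopifnot(inherits(put_set, "put_set"))
  sp <- put_set$contig_spans
  span_len <- sp$end - sp$start
  per_contig <- tapply(span_len, sp$contig_id, unique, simplify = FALSE)
  if (any(lengths(per_contig) > 1)) {
    stopf("contig length inconsistent across isotigs: %s",
          paste(head(names(per_contig)[lengths(per_contig) > 1], 5), collapse = ", "))
  }
  iso_ids <- put_set$puts$put_id[put_set$puts$kind == "isotig"]
  covered <- unique(put_set$contig_spans$contig_id[
    put_set$contig_spans$isoform_id %in% iso_ids])
  d_iso <- sum(vapply(per_contig[covered], `[[`, numeric(1), 1))
  # isotigs without recorded composition contribute their full length
  no_comp <- setdiff(iso_ids, unique(put_set$contig_spans$isoform_id))
  d_iso <- d_iso + sum(put_set$puts$length[put_set$puts$put_id %in% no_comp])
  d_sing <- sum(put_set$puts$length[put_set$puts$kind == "singleton"])
  as.integer(d_iso + d_sing)
}

#' Polymorphism level of the catalogue
#'
#' The fraction of distinct catalogue nucleotides that are polymorphic:
#' `percent = 100 * n_snps / distinct_nt`, with the equivalent density
#' `per_bp = distinct_nt / n_snps` (one SNP every `per_bp` bases).  The
#' identity `percent * per_bp = 100` holds exactly before rounding.
#'
#' @param n_snps SNP count.
#' @param distinct_nt Distinct nucleotide total (> 0).
#' @return Object of class `diversity_estimate`: list with `n_snps`,
#'   `distinct_nt`, `percent`, `per_bp` (`NA` when `n_snps = 0`).
#' @examples
#' polymorphism_level(27688, 27688 * 2530)
#' @export
polymorphism_level <- function(n_snps, distinct_nt) {
  if (!is_count(n_snps)) stopf("n_snps must be a count")
  if (!(is.numeric(distinct_nt) && distinct_nt > 0)) {
    stopf("distinct_nt must be positive")
  }
  structure(list(
    n_snps = n_snps, distinct_nt = distinct_nt,
    percent = 100 * n_snps / distinct_nt,
    per_bp = if (n_snps > 0) distinct_nt / n_snps else NA_real_
  ), class = "diversity_estimate")
}

#' @exportS3Method base::print
print.diversity_estimate <- function(x, ...) {
  if (x$n_snps == 0) {
    cat(sprintf("polymorphism level: 0%% (0 SNPs over %s bp)\n",
                format(x$distinct_nt, big.mark = ",")))
  } else {
    cat(sprintf("polymorphism level: %.2f%% (1 SNP per %s bp; %s SNPs over %s bp)\n",
                x$percent, format(round(x$per_bp), big.mark = ","),
                format(x$n_snps, big.mark = ","),
                format(x$distinct_nt, big.mark = ",")))
  }
  invisible(x)
}
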