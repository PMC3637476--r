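# PUT (putative unique transcript) catalogue construction: rescue of
# false-positive singletons against the isotig set, exact-duplicate
# removal among the remainder, the >= 100 bp length filter, and the
# catalogue bookkeeping used by every downstream stage.

#' Extract named sequences from a catalogue-like object
#'
#' Accepts a named character vector, a `put_set`, or an `assembly_table`
#' (whose isotigs are used) and returns a named character vector.
#'
#' @param x Sequences in any of the supported containers.
#' @return Named character vector.
#' @export
put_sequences <- function(x) {
  if (inherits(x, "put_set")) {
    return(setNames(x$puts$sequence, x$puts$put_id))
  }
  if (inherits(x, "assembly_table")) {
    return(setNames(x$isotigs$sequence, x$isotigs$isotig_id))
  }
  if (is.character(x)) return(x)
  stopf("cannot extract sequences from class '%s'", paste(class(x), collapse = "/"))
}

#' Rescue false-positive singletons against the isotig set
#'
#' A singleton whose best alignment to an isotig reaches the identity and
#' aligned-fraction thresholds is a false positive and is rescued (its
#' alignment is kept for pileup support); unmapped singletons are real.
#' Rescued and retained reads partition the input.
#'
#' @param singletons Data.frame of singleton reads (`read_id`, `sequence`,
#'   optionally `library`).
#' @param isotigs Isotig sequences (named vector, `put_set`, or
#'   `assembly_table`), or a prebuilt `kmer_index`.
#' @param min_identity Identity threshold (default 0.98).
#' @param min_aln_frac Aligned read fraction threshold (default 0.9).
#' @param k Seed word size (default 11).
#' @param band Banded-extension half width (default 10).
#' @return List with `rescued` (an `alignment_set`) and `retained` (the
#'   unmapped reads, original order).
#' @export
rescue_singletons <- function(singletons, isotigs, min_identity = 0.98,
                              min_aln_frac = 0.9, k = 11, band = 10) {
  if (nrow(singletons) == 0) {
    dummy <- build_index(setNames(strrep("ACGT", 10), "dummy"), k = k)
    return(list(rescued = map_reads(singletons, dummy), retained = singletons))
  }
  index <- if (inherits(isotigs, "kmer_index")) isotigs else build_index(isotigs, k = k)
  aln <- map_reads(singletons, index, min_identity = min_identity,
                   min_aln_frac = min_aln_frac, band = band)
  retained <- singletons[!(singletons$read_id %in% aln$read_id), , drop = FALSE]
  list(rescued = aln, retained = retained)
}

#' Collapse exact-duplicate singleton sequences
#'
#' Only byte-identical sequences collapse (a read and its reverse
#' complement are both kept); the first-seen read id survives and order is
#' preserved.
#'
#' @param reads Data.frame with `read_id` and `sequence`.
#' @return The de-duplicated data.frame.
#' @export
dedup_singletons <- function(reads) {
  reads[!duplicated(reads$sequence), , drop = FALSE]
}

#' Build the PUT catalogue
#'
#' The catalogue is the union of the assembly's isotigs and the retained
#' unique singletons, after the `min_len` filter.  Isotigs keep their
#' isogroup and contig composition; each singleton founds its own
#' isogroup.
#'
#' @param assembly An `assembly_table`.
#' @param retained_singletons Data.frame of retained unique singleton
#'   reads (after [rescue_singletons()] and [dedup_singletons()]), or
#'   `NULL`.
#' @param min_len Minimum PUT length (default 100 bp).
#' @return An object of class `put_set`: list with `puts` (data.frame:
#'   `put_id`, `kind` in `isotig`/`singleton`, `isogroup_id`, `length`,
#'   `sequence`), `contig_spans` (isotig PUTs only) and `contig_len`.
#' @export
build_put_set <- function(assembly, retained_singletons = NULL, min_len = 100) {
  stopifnot(inherits(assembly, "assembly_table"))
  iso <- assembly$isotigs[assembly$isotigs$length >= min_len, , drop = FALSE]
  puts <- data.frame(
    put_id = iso$isotig_id, kind = "isotig", isogroup_id = iso$isogroup_id,
    length = iso$length, sequence = iso$sequence, stringsAsFactors = FALSE
  )
  if (!is.null(retained_singletons) && nrow(retained_singletons) > 0) {
    sg <- retained_singletons[nchar(retained_singletons$sequence) >= min_len, ,
                              drop = FALSE]
    if (nrow(sg) > 0) {
      puts <- rbind(puts, data.frame(
        put_id = sg$read_id, kind = "singleton",
        isogroup_id = paste0("isg_", sg$read_id),
        length = nchar(sg$sequence), sequence = sg$sequence,
        stringsAsFactors = FALSE
      ))
    }
  }
  if (anyDuplicated(puts$put_id)) stopf("duplicate put_id in catalogue")
  rownames(puts) <- NULL
  out <- list(
    puts = puts,
    contig_spans = assembly$contig_spans[
      assembly$contig_spans$isoform_id %in% puts$put_id, , drop = FALSE],
    contig_len = assembly$contig_len
  )
  class(out) <- "put_set"
  out
}

#' @exportS3Method base::print
print.put_set <- function(x, ...) {
  cat(sprintf("put_set: %d PUTs (%d isotigs, %d singletons), mean length %.1f bp\n",
              nrow(x$puts), sum(x$puts$kind == "isotig"),
              sum(x$puts$kind == "singleton"), mean(x$puts$length)))
  invisible(x)
}

#' Catalogue accounting
#'
#' The bookkeeping identity of the catalogue: retained singletons are the
#' initial singletons minus the rescued false positives, and the PUT total
#' is isotigs plus retained singletons.
#'
#' @param n_isotigs Number of isotigs passing the length filter.
#' @param n_initial_singletons Singletons entering rescue (already length
#'   filtered).
#' @param n_rescued Singletons rescued as false positives.
#' @param n_duplicate Retained singletons collapsed as exact duplicates
#'   (default 0).
#' @return List with the inputs plus `n_retained` and `n_puts`.
#' @examples
#' put_accounting(141626, 71392, 42159)
#' @export
put_accounting <- function(n_isotigs, n_initial_singletons, n_rescued,
                           n_duplicate = 0) {
  stopifnot(is_count(n_isotigs), is_count(n_initial_singletons),
            is_count(n_rescued), is_count(n_duplicate))
  if (n_rescued + n_duplicate > n_initial_singletons) {
    stopf("rescued + duplicate singletons exceed the initial count")
  }
  n_retained <- n_initial_singletons - n_rescued - n_duplicate
  list(n_isotigs = n_isotigs, n_initial_singletons = n_initial_singletons,
       n_rescued = n_rescued, n_duplicate = n_duplicate,
       n_retained = n_retained, n_puts = n_isotigs + n_retained)
}

#' Write the PUT catalogue as FASTA plus metadata TSV
#'
#' @param put_set A `put_set`.
#' @param fasta_path,meta_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_put_set <- function(put_set, fasta_path, meta_path) {
  seqs <- Biostrings::DNAStringSet(setNames(put_set$puts$sequence,
                                            put_set$puts$put_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  sp <- put_set$contig_spans
  comp <- vapply(put_set$puts$put_id, function(id) {
    s <- sp[sp$isoform_id == id, , drop = FALSE]
    if (nrow(s) == 0) return("")
    paste(sprintf("%s:%d-%d", s$contig_id, s$start, s$end), collapse = ",")
  }, character(1))
  meta <- data.frame(put_id = put_set$puts$put_id, kind = put_set$puts$kind,
                     isogroup_id = put_set$puts$isogroup_id,
                     length = put_set$puts$length, contig_composition = comp)
  write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, meta_path))
}
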