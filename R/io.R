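# File interfaces: FASTA/FASTQ via Biostrings, VCF out (hand-shaped text,
# the consensus table is flat) and VCF in via vcfR, and the documented TSV
# dialect for assembly tables.

#' Write reads as FASTQ
#'
#' @param reads Data.frame with `read_id`, `sequence` and optionally
#'   `quality` (constant Q30 is substituted when absent).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if (is.null(reads$quality)) strrep("?", nchar(reads$sequence)) else reads$quality
  seqs <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Read FASTQ into the package's read table
#'
#' The library code is recovered from the read id suffix (`..._<CODE>`).
#'
#' @param path Input FASTQ.
#' @return Data.frame with `read_id`, `sequence`, `quality`, `library`
#'   (NA when the id carries no known code suffix).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  ids <- names(x)
  suffix <- sub(".*_", "", ids)
  data.frame(
    read_id = ids, sequence = as.character(x),
    quality = as.character(S4Vectors::mcols(x)$qualities),
    library = ifelse(suffix %in% LIBRARY_CODES, suffix, NA_character_),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector (or `put_set`/`assembly_table`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(put_sequences(seqs)), path)
  invisible(path)
}

#' Write an assembly table as a directory of TSV files
#'
#' Emits `isotigs.tsv` (id, isogroup, length, sequence), `members.tsv`
#' (isotig_id, read_id, library), `contigs.tsv` (isotig_id, contig_id,
#' start, end, contig_len) and `singletons.tsv` (read_id, label), plus
#' `too_short.tsv`.
#'
#' @param assembly An `assembly_table`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_assembly_table <- function(assembly, dir) {
  stopifnot(inherits(assembly, "assembly_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)
  w(assembly$isotigs, "isotigs.tsv")
  w(assembly$members, "members.tsv")
  sp <- assembly$contig_spans
  sp$contig_len <- assembly$contig_len[sp$contig_id]
  w(sp, "contigs.tsv")
  w(assembly$singletons, "singletons.tsv")
  w(data.frame(read_id = assembly$too_short), "too_short.tsv")
  invisible(dir)
}

#' Read an assembly table written by [write_assembly_table()]
#'
#' @param dir Directory containing the TSV files.
#' @return An `assembly_table`.
#' @export
read_assembly_table <- function(dir) {
  r <- function(f) read.table(file.path(dir, f), sep = "\t", header = TRUE,
                              quote = "", stringsAsFactors = FALSE)
  iso <- r("isotigs.tsv")
  members <- r("members.tsv")
  sp <- r("contigs.tsv")
  contig_len <- setNames(sp$contig_len[!duplicated(sp$contig_id)],
                         sp$contig_id[!duplicated(sp$contig_id)])
  sp$contig_len <- NULL
  singles <- r("singletons.tsv")
  ts <- r("too_short.tsv")
  out <- list(isotigs = iso, members = members,
              contig_spans = sp, contig_len = contig_len,
              singletons = singles, too_short = as.character(ts$read_id),
              read_library = setNames(members$library, members$read_id))
  class(out) <- "assembly_table"
  out
}

#' Write consensus SNPs as VCF
#'
#' Contigs are PUT ids.  `REF`/`ALT` carry the canonically ordered allele
#' pair (no genome reference fixes a true reference allele).  INFO keys:
#' `NCALLERS`, `CATEGORY`, `EFFECT` (when present), and per-variety
#' allele depths `CAD`/`IAD` (coastal/interior reads supporting allele1,
#' allele2).
#'
#' @param snps A classified `consensus_snps` table.
#' @param path Output file.
#' @param put_lengths Named integer vector of PUT lengths (for `##contig`
#'   headers).
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snps, path, put_lengths = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=putsnp",
    "##INFO=<ID=NCALLERS,Number=1,Type=Integer,Description=\"Callsets supporting the SNP\">",
    "##INFO=<ID=CATEGORY,Number=1,Type=String,Description=\"Provenance category (coastal/interior pooling)\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect from top-hit HSP frame\">",
    "##INFO=<ID=CAD,Number=2,Type=Integer,Description=\"Coastal read depth for allele1,allele2\">",
    "##INFO=<ID=IAD,Number=2,Type=Integer,Description=\"Interior read depth for allele1,allele2\">"
  )
  if (!is.null(put_lengths)) {
    ids <- sort(unique(snps$put_id))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", ids,
                          as.integer(put_lengths[ids])))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(snps) > 0) {
    vd <- function(libs, letter) sum(substr(libs, 2, 2) == letter)
    info <- vapply(seq_len(nrow(snps)), function(i) {
      parts <- c(sprintf("NCALLERS=%d",
                         if (!is.null(snps$n_callsets)) snps$n_callsets[i] else 1L))
      if (!is.null(snps$provenance_category)) {
        parts <- c(parts, sprintf("CATEGORY=%s", snps$provenance_category[i]))
      }
      if (!is.null(snps$coding_effect)) {
        parts <- c(parts, sprintf("EFFECT=%s", snps$coding_effect[i]))
      }
      parts <- c(parts,
                 sprintf("CAD=%d,%d", vd(snps$libs1[[i]], "C"), vd(snps$libs2[[i]], "C")),
                 sprintf("IAD=%d,%d", vd(snps$libs1[[i]], "I"), vd(snps$libs2[[i]], "I")))
      paste(parts, collapse = ";")
    }, character(1))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                    snps$put_id, snps$pos + 1L, snps$allele1, snps$allele2, info)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an external VCF callset
#'
#' Converts biallelic SNP records of an external caller's VCF into the
#' package's callset shape so they can join [intersect_callsets()].
#' Multi-allelic records, indels, and records whose allele depths (an
#' `AD`-style field on the first sample, or an `AD` INFO key) fail the
#' per-allele support rule are dropped and counted.
#'
#' @param path VCF file (positions 1-based; contigs must exist in the
#'   catalogue).
#' @param puts The PUT catalogue the VCF was called against.
#' @param min_allele_support Per-allele support threshold applied when
#'   depths are available (default 3).
#' @return A `snp_calls` table (support/library list-columns empty -- an
#'   external caller reports depths, not read ids).  Attributes
#'   `n_dropped_multiallelic`, `n_dropped_indel`, `n_dropped_support`
#'   carry the drop counts.
#' @export
read_external_callset <- function(path, puts, min_allele_support = 3) {
  seqs <- put_sequences(puts)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_m <- v@fix  # stays a matrix even for a single record
  fix <- as.data.frame(fix_m[, c("CHROM", "POS", "REF", "ALT", "INFO"),
                             drop = FALSE],
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    out <- empty_calls()
    setattr(out, "class", c("snp_calls", class(out)))
    return(out)
  }
  unknown <- setdiff(unique(fix$CHROM), names(seqs))
  if (length(unknown) > 0) {
    stopf("VCF references unknown PUT(s): %s", paste(head(unknown, 5), collapse = ", "))
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  indel <- !multi & (nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L)
  keep <- !multi & !indel
  ad1 <- rep(NA_integer_, nrow(fix))
  ad2 <- rep(NA_integer_, nrow(fix))
  gt_ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  if (!is.null(gt_ad) && ncol(gt_ad) >= 1) {
    parts <- strsplit(gt_ad[, 1], ",", fixed = TRUE)
    ad1 <- suppressWarnings(as.integer(vapply(parts, function(p) p[1], character(1))))
    ad2 <- suppressWarnings(as.integer(vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, character(1))))
  } else {
    m <- regmatches(fix$INFO, regexec("(?:^|;)AD=([0-9]+),([0-9]+)", fix$INFO))
    has <- lengths(m) == 3
    ad1[has] <- as.integer(vapply(m[has], `[`, character(1), 2))
    ad2[has] <- as.integer(vapply(m[has], `[`, character(1), 3))
  }
  low <- keep & !is.na(ad1) & !is.na(ad2) &
    (ad1 < min_allele_support | ad2 < min_allele_support)
  keep <- keep & !low
  kept <- fix[keep, , drop = FALSE]
  a1 <- pmin(kept$REF, kept$ALT)
  a2 <- pmax(kept$REF, kept$ALT)
  swap <- kept$REF != a1
  k1 <- ifelse(swap, ad2[keep], ad1[keep])
  k2 <- ifelse(swap, ad1[keep], ad2[keep])
  out <- data.table(
    put_id = kept$CHROM, pos = as.integer(kept$POS) - 1L,
    allele1 = a1, allele2 = a2,
    n1 = as.integer(k1), n2 = as.integer(k2),
    multiallelic = FALSE,
    support1 = rep(list(character(0)), nrow(kept)),
    support2 = rep(list(character(0)), nrow(kept)),
    libs1 = rep(list(character(0)), nrow(kept)),
    libs2 = rep(list(character(0)), nrow(kept))
  )
  setorder(out, put_id, pos)
  setattr(out, "class", c("snp_calls", class(out)))
  setattr(out, "n_dropped_multiallelic", sum(multi))
  setattr(out, "n_dropped_indel", sum(indel))
  setattr(out, "n_dropped_support", sum(low))
  out
}
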