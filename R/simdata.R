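# Synthetic study generator: a planted transcriptome whose isoforms share
# contigs (gene = isogroup, isoform = isotig, contig = exon-like block),
# planted biallelic variants with per-variety allele frequencies, read sets
# for the twelve library codes, and an assembler-output fixture carrying the
# planted truth.  Everything is deterministic under a fixed seed.

#' The twelve cDNA library codes
#'
#' Codes follow the pattern `D<variety><tissue><treatment>`: variety `C`
#' (coastal) or `I` (interior); tissue `N` (needle) or `W` (wood);
#' treatment `C` (control), `M` (mild stress) or `S` (severe stress).
#'
#' @format Character vector of length 12.
#' @export
LIBRARY_CODES <- c(
  "DCNC", "DCNM", "DCNS", "DCWC", "DCWM", "DCWS",
  "DINC", "DINM", "DINS", "DIWC", "DIWM", "DIWS"
)

#' The six pooled provenance categories
#'
#' Because no genome reference fixes which allele is "reference", the nine
#' ordered (allele origin, allele origin) combinations over \{c, i, ci\} are
#' pooled into six unordered categories.
#'
#' @format Character vector of length 6.
#' @export
PROVENANCE_CATEGORIES <- c("ci/ci", "ci/c", "ci/i", "c/i", "c/c", "i/i")

TREATMENT_GROUPS <- c("c", "m", "s", "cm", "cs", "ms", "cms")

#' Decode a library code into variety, tissue and treatment
#'
#' @param code Character vector of library codes (see [LIBRARY_CODES]).
#' @return A data.frame with columns `code`, `variety`
#'   (`"coastal"`/`"interior"`), `variety_letter` (`"c"`/`"i"`), `tissue`
#'   (`"needle"`/`"wood"`) and `treatment` (`"c"`/`"m"`/`"s"`).
#' @examples
#' decode_library("DINS")
#' @export
decode_library <- function(code) {
  bad <- setdiff(unique(code), LIBRARY_CODES)
  if (length(bad) > 0) {
    stopf("unknown library code(s): %s", paste(bad, collapse = ", "))
  }
  v <- substr(code, 2, 2)
  t <- substr(code, 3, 3)
  w <- substr(code, 4, 4)
  data.frame(
    code = code,
    variety = ifelse(v == "C", "coastal", "interior"),
    variety_letter = ifelse(v == "C", "c", "i"),
    tissue = ifelse(t == "N", "needle", "wood"),
    treatment = c(C = "c", M = "m", S = "s")[w],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Generate a planted transcriptome with contig-sharing isoforms
#'
#' Genes (isogroups) are built from contig blocks of at least 100 bp.  The
#' first isoform of a gene uses every contig; additional isoforms drop a
#' random subset, so all isoforms of a gene share at least one contig and a
#' shared `contig_id` always denotes an identical subsequence.  Each isoform
#' gets a treatment profile, the subset of treatments (`c`, `m`, `s`) whose
#' libraries express it.
#'
#' @param n_genes Number of genes (isogroups), at least 1.
#' @param isoforms_per_gene Integer vector of candidate isoform counts; one
#'   value is drawn per gene (default `1:3`).
#' @param len_params List with `min` and `max`: the full-length (all-contig)
#'   transcript of a gene draws its length uniformly from this range.
#' @param treatment_profiles Character vector of profiles to draw from
#'   (default: all seven of `"c"`, `"m"`, `"s"`, `"cm"`, `"cs"`, `"ms"`,
#'   `"cms"`, uniformly).
#' @param seed Integer seed; output is byte-identical for a given seed.
#' @return An object of class `sim_transcriptome`: a list with
#'   `transcripts` (data.frame: `gene_id`, `isoform_id`, `isogroup_id`,
#'   `sequence`, `length`, `treatment_profile`), `contig_spans` (data.frame:
#'   `isoform_id`, `contig_id`, `start`, `end`, half-open 0-based on the
#'   isoform) and `contig_len` (named integer vector).
#' @export
generate_transcriptome <- function(n_genes,
                                   isoforms_per_gene = 1:3,
                                   len_params = list(min = 400, max = 1200),
                                   treatment_profiles = TREATMENT_GROUPS,
                                   seed = 1) {
  if (!is_count(n_genes) || n_genes < 1) stopf("n_genes must be a count >= 1")
  if (!is.list(len_params) || is.null(len_params$min) || is.null(len_params$max) ||
      len_params$min < 100 || len_params$max < len_params$min) {
    stopf("len_params must be list(min, max) with 100 <= min <= max")
  }
  if (any(isoforms_per_gene < 1)) stopf("isoforms_per_gene must be >= 1")
  if (!all(treatment_profiles %in% TREATMENT_GROUPS)) {
    stopf("treatment_profiles must be drawn from %s",
          paste(TREATMENT_GROUPS, collapse = ", "))
  }
  set.seed(seed)

  tx <- list()
  spans <- list()
  contig_len <- integer(0)
  for (g in seq_len(n_genes)) {
    gene_id <- sprintf("g%04d", g)
    L <- resample(len_params$min:len_params$max, 1)
    k_iso <- resample(isoforms_per_gene, 1)
    nc <- if (k_iso == 1) 1L else min(resample(2:4, 1), L %/% 100L)
    if (nc < 2L) { nc <- 1L; k_iso <- 1L }
    extra <- L - 100L * nc
    lens <- rep(100L, nc) +
      if (extra > 0) as.integer(rmultinom(1, extra, rep(1 / nc, nc))) else 0L
    cids <- sprintf("%s_c%02d", gene_id, seq_len(nc))
    cseq <- vapply(lens, random_dna, character(1))
    names(cseq) <- cids
    contig_len <- c(contig_len, setNames(lens, cids))

    # isoform 1 carries all contigs; later isoforms drop a proper subset
    used <- list(seq_len(nc))
    if (k_iso > 1) {
      for (j in 2:k_iso) {
        for (try in 1:10) {
          keep <- sort(setdiff(seq_len(nc), resample(seq_len(nc), resample(seq_len(nc - 1L), 1))))
          if (!any(vapply(used, identical, logical(1), y = keep))) break
        }
        used[[j]] <- keep
      }
    }
    for (j in seq_along(used)) {
      iso_id <- sprintf("%s_i%02d", gene_id, j)
      sel <- used[[j]]
      seq_j <- paste(cseq[sel], collapse = "")
      ends <- cumsum(lens[sel])
      spans[[iso_id]] <- data.frame(
        isoform_id = iso_id, contig_id = cids[sel],
        start = c(0L, head(ends, -1L)), end = ends,
        stringsAsFactors = FALSE
      )
      tx[[iso_id]] <- data.frame(
        gene_id = gene_id, isoform_id = iso_id, isogroup_id = gene_id,
        sequence = seq_j, length = nchar(seq_j),
        treatment_profile = resample(treatment_profiles, 1),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- list(
    transcripts = do.call(rbind, c(tx, list(make.row.names = FALSE))),
    contig_spans = do.call(rbind, c(spans, list(make.row.names = FALSE))),
    contig_len = contig_len
  )
  class(out) <- "sim_transcriptome"
  out
}

#' @exportS3Method base::print
print.sim_transcriptome <- function(x, ...) {
  cat(sprintf("sim_transcriptome: %d transcripts, %d genes, %d contigs\n",
              nrow(x$transcripts), length(unique(x$transcripts$gene_id)),
              length(x$contig_len)))
  invisible(x)
}

# Contig intervals of an isoform not shared with any sibling isoform;
# variants are planted there so the truth position is unambiguous.
private_intervals <- function(txome, iso) {
  sp <- txome$contig_spans
  gene <- txome$transcripts$gene_id[txome$transcripts$isoform_id == iso]
  sibs <- txome$transcripts$isoform_id[txome$transcripts$gene_id == gene]
  mine <- sp[sp$isoform_id == iso, , drop = FALSE]
  if (length(sibs) == 1L) return(mine)
  shared <- unique(sp$contig_id[sp$isoform_id %in% setdiff(sibs, iso)])
  mine[!(mine$contig_id %in% shared), , drop = FALSE]
}

category_freqs <- function(category) {
  u <- function() runif(1, 0.2, 0.8)   # keeps >= 3 reads per allele likely
  fixed <- function() resample(c(0, 1), 1)
  switch(category,
    "ci/ci" = c(u(), u()),
    "ci/c"  = c(u(), fixed()),
    "ci/i"  = c(fixed(), u()),
    "c/i"   = { a <- fixed(); c(a, 1 - a) },
    "c/c"   = c(u(), NA_real_),
    "i/i"   = c(NA_real_, u()),
    stopf("unknown category '%s'", category)
  )
}

#' Plant biallelic variants with variety-specific allele frequencies
#'
#' Each variant carries the frequency of its alternate allele (`allele_b`)
#' in the coastal and interior varieties, and an intended provenance
#' category describing which varieties are expected to show each allele.
#' For the variety-private categories `c/c` and `i/i` the uncovered
#' variety's frequency is `NA`: the host transcript is then skipped
#' entirely by that variety's libraries in [simulate_library_reads()],
#' which is the only way a variety can contribute zero reads at the site.
#' Within multi-isoform genes, variants are placed only in contigs private
#' to one isoform, so every planted position maps to a single reference.
#'
#' @param txome A `sim_transcriptome`.
#' @param n_variants Number of variants to plant.
#' @param category_mix Named numeric vector of proportions over
#'   [PROVENANCE_CATEGORIES]; must sum to 1.  The default mirrors the
#'   relative category abundances of a consensus SNP set dominated by
#'   shared polymorphism.
#' @param seed Integer seed.
#' @param margin Minimum distance (bp) from either transcript end.
#' @return A data.frame of class `planted_variants` with columns
#'   `variant_id`, `isoform_id`, `position` (0-based), `allele_a`,
#'   `allele_b`, `coastal_freq`, `interior_freq`, `intended_category`.
#' @export
plant_variants <- function(txome, n_variants,
                           category_mix = c("ci/ci" = 0.57, "ci/c" = 0.26,
                                            "ci/i" = 0.09, "c/i" = 0.03,
                                            "c/c" = 0.03, "i/i" = 0.02),
                           seed = 1, margin = 100) {
  stopifnot(inherits(txome, "sim_transcriptome"))
  if (!is_count(n_variants)) stopf("n_variants must be a count")
  if (abs(sum(category_mix) - 1) > 1e-8) stopf("category_mix must sum to 1")
  bad <- setdiff(names(category_mix), PROVENANCE_CATEGORIES)
  if (length(bad) > 0) stopf("unknown categories: %s", paste(bad, collapse = ", "))
  set.seed(seed)
  empty <- data.frame(
    variant_id = character(0), isoform_id = character(0),
    position = integer(0), allele_a = character(0), allele_b = character(0),
    coastal_freq = numeric(0), interior_freq = numeric(0),
    intended_category = character(0), stringsAsFactors = FALSE
  )
  class(empty) <- c("planted_variants", "data.frame")
  if (n_variants == 0) return(empty)

  # largest-remainder allocation of n_variants over the mix
  raw <- category_mix * n_variants
  n_cat <- floor(raw)
  rem <- n_variants - sum(n_cat)
  if (rem > 0) {
    ord <- order(raw - n_cat, decreasing = TRUE)
    n_cat[ord[seq_len(rem)]] <- n_cat[ord[seq_len(rem)]] + 1L
  }

  iso <- txome$transcripts$isoform_id
  eligible <- lapply(iso, function(id) {
    pr <- private_intervals(txome, id)
    len <- txome$transcripts$length[txome$transcripts$isoform_id == id]
    pos <- unlist(lapply(seq_len(nrow(pr)), function(r) seq(pr$start[r], pr$end[r] - 1L)))
    pos[pos >= margin & pos < (len - margin)]
  })
  names(eligible) <- iso
  # variety restriction accumulates as c/c and i/i variants claim hosts
  restriction <- setNames(rep("unset", length(iso)), iso)

  rows <- list()
  vi <- 0L
  # variety-private categories claim exclusive host transcripts first,
  # before the shared categories spread over the remaining pool
  cat_order <- intersect(c("c/c", "i/i", "ci/ci", "ci/c", "ci/i", "c/i"),
                         names(n_cat)[n_cat > 0])
  for (cat in cat_order) {
    need_var <- switch(cat, "c/c" = "coastal", "i/i" = "interior", "both")
    for (r in seq_len(n_cat[[cat]])) {
      hosts <- iso[vapply(iso, function(id) {
        length(eligible[[id]]) > 0 &&
          (restriction[[id]] == need_var ||
             (restriction[[id]] == "unset"))
      }, logical(1))]
      if (length(hosts) == 0) {
        stopf("transcripts too short (or too few) to host requested variants")
      }
      host <- resample(hosts, 1, prob = lengths(eligible[hosts]))
      pos <- resample(eligible[[host]], 1)
      eligible[[host]] <- setdiff(eligible[[host]], pos)
      restriction[[host]] <- need_var
      seq_h <- txome$transcripts$sequence[txome$transcripts$isoform_id == host]
      a <- substr(seq_h, pos + 1L, pos + 1L)
      b <- resample(setdiff(DNA_BASES, a), 1)
      fr <- category_freqs(cat)
      vi <- vi + 1L
      rows[[vi]] <- data.frame(
        variant_id = sprintf("v%04d", vi), isoform_id = host,
        position = pos, allele_a = a, allele_b = b,
        coastal_freq = fr[1], interior_freq = fr[2],
        intended_category = cat, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$isoform_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("planted_variants", "data.frame")
  out
}

# Transcripts a variety must skip: hosts of variants whose frequency for
# that variety is NA (variety-private sites).
variety_excluded <- function(variants, variety) {
  if (is.null(variants) || nrow(variants) == 0) return(character(0))
  f <- if (variety == "coastal") variants$coastal_freq else variants$interior_freq
  unique(variants$isoform_id[is.na(f)])
}

#' Construct a library sequencing plan
#'
#' @param code One of [LIBRARY_CODES].
#' @param n_reads Reads to draw.
#' @param mean_len,sd_len Read length distribution: truncated normal with
#'   this mean and s.d., floored at `min_len` (defaults 338 / 100 / 50 bp).
#' @param min_len Shortest read emitted.
#' @param error_sub Per-base substitution error rate.
#' @param error_homopolymer_indel Per-run indel rate inside homopolymer
#'   runs of length >= 3 (454-style; default 0).
#' @param n_rate Fraction of reads carrying one `N`.
#' @param polyA_artifact_rate Fraction of reads with a terminal polyA/T
#'   artifact (8-20 bases).
#' @return A list of class `library_plan`.
#' @export
library_plan <- function(code, n_reads = 500, mean_len = 338, sd_len = 100,
                         min_len = 50, error_sub = 0,
                         error_homopolymer_indel = 0, n_rate = 0,
                         polyA_artifact_rate = 0) {
  decode_library(code)
  stopifnot(is_count(n_reads), mean_len > 0, sd_len >= 0, min_len >= 1)
  rates <- c(error_sub, error_homopolymer_indel, n_rate, polyA_artifact_rate)
  if (any(rates < 0 | rates > 1)) stopf("rates must lie in [0, 1]")
  structure(list(code = code, n_reads = n_reads, mean_len = mean_len,
                 sd_len = sd_len, min_len = min_len, error_sub = error_sub,
                 error_homopolymer_indel = error_homopolymer_indel,
                 n_rate = n_rate, polyA_artifact_rate = polyA_artifact_rate),
            class = "library_plan")
}

#' Default plans for all twelve libraries
#'
#' One plan per library code, uniform across libraries (the emulated
#' libraries were normalized and no per-library target depth is modelled).
#'
#' @inheritParams library_plan
#' @return Named list of twelve `library_plan` objects.
#' @export
default_library_plans <- function(n_reads = 500, mean_len = 338, sd_len = 100,
                                  min_len = 50, error_sub = 0.001,
                                  error_homopolymer_indel = 0,
                                  n_rate = 0.02, polyA_artifact_rate = 0.05) {
  plans <- lapply(LIBRARY_CODES, library_plan, n_reads = n_reads,
                  mean_len = mean_len, sd_len = sd_len, min_len = min_len,
                  error_sub = error_sub,
                  error_homopolymer_indel = error_homopolymer_indel,
                  n_rate = n_rate, polyA_artifact_rate = polyA_artifact_rate)
  setNames(plans, LIBRARY_CODES)
}

apply_homopolymer_indels <- function(seq, rate) {
  runs <- gregexpr("A{3,}|C{3,}|G{3,}|T{3,}", seq)[[1]]
  if (runs[1] == -1) return(seq)
  hit <- which(runif(length(runs)) < rate)
  if (length(hit) == 0) return(seq)
  lens <- attr(runs, "match.length")
  for (h in rev(hit)) {  # right-to-left keeps earlier coordinates valid
    st <- runs[h]; b <- substr(seq, st, st)
    if (runif(1) < 0.5) {
      seq <- paste0(substr(seq, 1, st), b, substr(seq, st + 1, nchar(seq)))
    } else {
      seq <- paste0(substr(seq, 1, st - 1), substr(seq, st + 1, nchar(seq)))
    }
  }
  seq
}

#' Simulate one library's reads from the planted transcriptome
#'
#' Reads are drawn only from transcripts whose treatment profile contains
#' the plan's treatment and which are not private to the other variety.
#' Transcripts are sampled uniformly (normalized libraries: expression
#' level is deliberately not modelled).  Each read draws its allele
#' independently at every overlapped variant with the variety's alternate
#' allele frequency; error processes are applied after allele assignment.
#'
#' @param txome A `sim_transcriptome`.
#' @param variants A `planted_variants` data.frame (may be empty).
#' @param plan A `library_plan`.
#' @param seed Integer seed.
#' @return List with `reads` (data.frame: `read_id`, `sequence`, `quality`,
#'   `library`) and `truth` (data.frame: `read_id`, `isoform_id`, `start`,
#'   `end` half-open 0-based on the transcript, `strand`, `alleles` --
#'   a `;`-separated `variant_id=allele` record).
#' @export
simulate_library_reads <- function(txome, variants, plan, seed = 1) {
  stopifnot(inherits(txome, "sim_transcriptome"), inherits(plan, "library_plan"))
  set.seed(seed)
  lib <- decode_library(plan$code)
  tr <- txome$transcripts
  pool <- tr$isoform_id[grepl(lib$treatment, tr$treatment_profile)]
  pool <- setdiff(pool, variety_excluded(variants, lib$variety))
  empty_reads <- data.frame(read_id = character(0), sequence = character(0),
                            quality = character(0), library = character(0),
                            stringsAsFactors = FALSE)
  empty_truth <- data.frame(read_id = character(0), isoform_id = character(0),
                            start = integer(0), end = integer(0),
                            strand = character(0), alleles = character(0),
                            stringsAsFactors = FALSE)
  if (length(pool) == 0 || plan$n_reads == 0) {
    return(list(reads = empty_reads, truth = empty_truth))
  }
  seqs <- setNames(tr$sequence, tr$isoform_id)
  lens <- setNames(tr$length, tr$isoform_id)
  freq_col <- if (lib$variety == "coastal") "coastal_freq" else "interior_freq"

  reads <- vector("list", plan$n_reads)
  truth <- vector("list", plan$n_reads)
  for (i in seq_len(plan$n_reads)) {
    iso <- resample(pool, 1)
    L <- lens[[iso]]
    repeat {
      rl <- as.integer(round(rnorm(1, plan$mean_len, plan$sd_len)))
      if (rl >= plan$min_len) break
    }
    rl <- min(rl, L)
    st <- resample(0:(L - rl), 1)
    frag <- substr(seqs[[iso]], st + 1L, st + rl)
    allele_rec <- character(0)
    if (!is.null(variants) && nrow(variants) > 0) {
      vv <- variants[variants$isoform_id == iso &
                       variants$position >= st &
                       variants$position < st + rl, , drop = FALSE]
      if (nrow(vv) > 0) {
        for (r in seq_len(nrow(vv))) {
          p <- vv$position[r] - st + 1L
          take_b <- runif(1) < vv[[freq_col]][r]
          if (take_b) frag <- str_sub_at(frag, p, vv$allele_b[r])
          allele_rec <- c(allele_rec, sprintf("%s=%s", vv$variant_id[r],
                                              if (take_b) vv$allele_b[r] else vv$allele_a[r]))
        }
      }
    }
    strand <- if (runif(1) < 0.5) "+" else "-"
    if (strand == "-") frag <- revcomp(frag)
    if (plan$error_sub > 0) {
      nm <- rbinom(1, nchar(frag), plan$error_sub)
      if (nm > 0) {
        at <- resample(seq_len(nchar(frag)), nm)
        for (p in at) {
          frag <- str_sub_at(frag, p, resample(setdiff(DNA_BASES, substr(frag, p, p)), 1))
        }
      }
    }
    if (plan$error_homopolymer_indel > 0) {
      frag <- apply_homopolymer_indels(frag, plan$error_homopolymer_indel)
    }
    if (plan$n_rate > 0 && runif(1) < plan$n_rate) {
      frag <- str_sub_at(frag, resample(seq_len(nchar(frag)), 1), "N")
    }
    if (plan$polyA_artifact_rate > 0 && runif(1) < plan$polyA_artifact_rate) {
      k <- resample(8:20, 1)
      frag <- if (strand == "+") paste0(frag, strrep("A", k)) else paste0(strrep("T", k), frag)
    }
    id <- sprintf("r%05d_%s", i, plan$code)
    reads[[i]] <- data.frame(read_id = id, sequence = frag,
                             quality = strrep("?", nchar(frag)),  # constant Q30
                             library = plan$code, stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(read_id = id, isoform_id = iso, start = st,
                             end = st + rl, strand = strand,
                             alleles = paste(allele_rec, collapse = ";"),
                             stringsAsFactors = FALSE)
  }
  list(reads = do.call(rbind, c(reads, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Simulate all libraries of a design
#'
#' @param txome A `sim_transcriptome`.
#' @param variants A `planted_variants` data.frame.
#' @param plans List of `library_plan` objects (default: twelve noise-free
#'   plans via [default_library_plans()] with all rates 0).
#' @param seed Integer master seed; per-library seeds are derived from it.
#' @return List with stacked `reads` and `truth` data.frames.
#' @export
simulate_read_sets <- function(txome, variants,
                               plans = default_library_plans(),
                               seed = 1) {
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max %/% 2L, length(plans))
  out <- Map(function(p, s) simulate_library_reads(txome, variants, p, seed = s),
             plans, sub_seeds)
  list(reads = do.call(rbind, c(lapply(out, `[[`, "reads"), list(make.row.names = FALSE))),
       truth = do.call(rbind, c(lapply(out, `[[`, "truth"), list(make.row.names = FALSE))))
}

#' Emit an assembler-output fixture from simulated reads
#'
#' Stands in for a de novo assembler: isotig sequences are exactly the
#' transcript sequences, member lists come from the simulation truth, and a
#' labelled mixture of reads is withheld as singletons -- false-positive
#' singletons (reads whose transcript keeps its isotig, so they align back
#' at high identity) and true singletons (all reads of transcripts removed
#' from the isotig set).  Reads shorter than 100 bp are recorded as
#' withheld-too-short, mirroring an assembler's too-short bin.
#'
#' @param read_sets Output of [simulate_read_sets()] (or a compatible list
#'   with `reads` and `truth`).
#' @param txome The `sim_transcriptome` the reads were drawn from.
#' @param fp_singleton_rate Fraction of member reads withheld as
#'   false-positive singletons.
#' @param true_singleton_rate Approximate fraction of reads whose
#'   transcripts are dropped from the isotig set entirely.
#' @param seed Integer seed.
#' @return An object of class `assembly_table`: list with `isotigs`
#'   (data.frame: `isotig_id`, `isogroup_id`, `sequence`, `length`),
#'   `members` (data.frame: `isotig_id`, `read_id`, `library`),
#'   `contig_spans`, `contig_len`, `singletons` (data.frame: `read_id`,
#'   `label` in `fp`/`true`), `too_short` (read ids), and `read_library`
#'   (named vector).
#' @export
emit_assembly_fixture <- function(read_sets, txome, fp_singleton_rate = 0,
                                  true_singleton_rate = 0, seed = 1) {
  stopifnot(inherits(txome, "sim_transcriptome"))
  if (fp_singleton_rate < 0 || true_singleton_rate < 0 ||
      fp_singleton_rate + true_singleton_rate >= 1) {
    stopf("singleton rates must be >= 0 and sum to < 1")
  }
  set.seed(seed)
  reads <- read_sets$reads
  truth <- read_sets$truth
  read_len <- setNames(nchar(reads$sequence), reads$read_id)
  too_short <- reads$read_id[read_len[reads$read_id] < 100L]
  cand <- truth[!(truth$read_id %in% too_short), , drop = FALSE]

  # true singletons: drop whole genes (all their isoforms) until the read
  # quota is met -- dropping a lone isoform would leave a contig-sharing
  # sibling isotig that rescues its reads at full identity
  drop_tx <- character(0)
  if (true_singleton_rate > 0) {
    quota <- round(true_singleton_rate * nrow(cand))
    gene_of <- setNames(txome$transcripts$gene_id, txome$transcripts$isoform_id)
    per_gene <- table(gene_of[cand$isoform_id])
    ord <- resample(names(per_gene), length(per_gene))
    got <- 0L
    dropped_genes <- character(0)
    for (g in ord) {
      if (got >= quota) break
      if (length(dropped_genes) >= length(per_gene) - 1L) {
        stopf("true_singleton_rate would leave no isotigs")
      }
      dropped_genes <- c(dropped_genes, g)
      got <- got + per_gene[[g]]
    }
    drop_tx <- names(gene_of)[gene_of %in% dropped_genes]
  }
  is_true <- cand$isoform_id %in% drop_tx
  member <- cand[!is_true, , drop = FALSE]

  # false positives: withheld member reads (never emptying an isotig)
  fp_ids <- character(0)
  if (fp_singleton_rate > 0 && nrow(member) > 0) {
    n_fp <- round(fp_singleton_rate * nrow(member))
    if (n_fp >= nrow(member)) stopf("fp_singleton_rate exceeds available reads")
    fp_ids <- resample(member$read_id, n_fp)
    for (txid in unique(member$isoform_id)) {
      ids <- member$read_id[member$isoform_id == txid]
      if (all(ids %in% fp_ids)) fp_ids <- setdiff(fp_ids, ids[1])
    }
  }
  singles <- rbind(
    data.frame(read_id = cand$read_id[is_true],
               label = rep("true", sum(is_true)), stringsAsFactors = FALSE),
    data.frame(read_id = fp_ids, label = rep("fp", length(fp_ids)),
               stringsAsFactors = FALSE)
  )
  member <- member[!(member$read_id %in% fp_ids), , drop = FALSE]

  keep_tx <- setdiff(unique(member$isoform_id), drop_tx)
  tr <- txome$transcripts
  iso_tab <- tr[tr$isoform_id %in% keep_tx,
                c("isoform_id", "isogroup_id", "sequence", "length")]
  names(iso_tab)[1] <- "isotig_id"
  rownames(iso_tab) <- NULL
  lib_of <- setNames(reads$library, reads$read_id)
  members <- data.frame(isotig_id = member$isoform_id,
                        read_id = member$read_id,
                        library = lib_of[member$read_id],
                        stringsAsFactors = FALSE)
  rownames(members) <- NULL
  out <- list(
    isotigs = iso_tab,
    members = members,
    contig_spans = txome$contig_spans[txome$contig_spans$isoform_id %in% keep_tx, ,
                                      drop = FALSE],
    contig_len = txome$contig_len,
    singletons = singles,
    too_short = too_short,
    read_library = lib_of
  )
  class(out) <- "assembly_table"
  out
}

#' @exportS3Method base::print
print.assembly_table <- function(x, ...) {
  cat(sprintf("assembly_table: %d isotigs, %d member reads, %d singletons (%d fp), %d too short\n",
              nrow(x$isotigs), nrow(x$members), nrow(x$singletons),
              sum(x$singletons$label == "fp"), length(x$too_short)))
  invisible(x)
}

#' Simulate protein-database hits for a PUT catalogue
#'
#' Generates a plausible tabular hit set for downstream annotation and
#' screening: the chance of a hit grows logistically with transcript
#' length (longer transcripts are more likely to reach a conserved
#' protein), a configurable fraction of hit descriptions contains a
#' stress-related keyword, and each hit carries frame-consistent HSP
#' coordinates on the query.
#'
#' @param puts Named character vector of PUT sequences, or a `put_set`.
#' @param keyword_terms Keyword vocabulary to embed (default
#'   [default_keyword_catalog()]).
#' @param keyword_rate Fraction of hit descriptions carrying a keyword.
#' @param length_midpoint,length_scale Logistic parameters for the
#'   hit probability as a function of length (defaults 500 / 200 bp).
#' @param seed Integer seed.
#' @return A `blast_hit_set` (see [blast_hit_set()]).
#' @export
simulate_blast_hits <- function(puts,
                                keyword_terms = default_keyword_catalog(),
                                keyword_rate = 0.15,
                                length_midpoint = 500, length_scale = 200,
                                seed = 1) {
  seqs <- put_sequences(puts)
  set.seed(seed)
  rows <- list()
  k <- 0L
  for (id in names(seqs)) {
    L <- nchar(seqs[[id]])
    if (runif(1) > stats::plogis((L - length_midpoint) / length_scale)) next
    f <- resample(c(-3:-1, 1:3), 1)
    af <- abs(f)
    ncod_max <- if (f > 0) (L - af + 1L) %/% 3L else (L - (af - 1L)) %/% 3L
    if (ncod_max < 10L) next
    ncod <- resample(10:ncod_max, 1)
    if (f > 0) {
      slack <- ncod_max - ncod
      q_start <- af + 3L * resample(0:slack, 1)
      q_end <- q_start + 3L * ncod - 1L
    } else {
      slack <- ncod_max - ncod
      q_end <- L - (af - 1L) - 3L * resample(0:slack, 1)
      q_start <- q_end - 3L * ncod + 1L
    }
    kw <- if (runif(1) < keyword_rate) resample(keyword_terms, 1) else NULL
    desc <- if (is.null(kw)) {
      sprintf("hypothetical protein %s-like", toupper(substr(id, 1, 5)))
    } else {
      sprintf("putative %s responsive protein", tolower(kw))
    }
    k <- k + 1L
    rows[[k]] <- data.frame(
      query = id, subject = sprintf("sp%05d", k), description = desc,
      evalue = 10^-runif(1, 10, 60), bitscore = round(runif(1, 80, 400), 1),
      q_start = q_start, q_end = q_end, frame = f,
      s_start = 1L, s_end = ncod, stringsAsFactors = FALSE
    )
  }
  blast_hit_set(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
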