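# Stage orchestration: simulate -> preprocess -> assembly fixture ->
# build-puts -> map/call (one callset per caller configuration) ->
# intersect -> classify -> screen -> report.  Every stage writes its
# artifacts plus a machine-readable manifest (parameters, seed, input
# digests), so a run is reproducible byte for byte under a fixed seed.

#' Assemble a pipeline configuration
#'
#' Defaults mirror the pipeline's documented thresholds (minimum read
#' length 50, polyA/T run 8, PUT length 100, rescue identity 0.98,
#' per-allele SNP support 3).  The three caller configurations differ in
#' mapping stringency so the intersection is exercised with genuinely
#' differing callsets.
#'
#' @param n_genes,isoforms_per_gene,len_params Transcriptome shape
#'   (see [generate_transcriptome()]).
#' @param n_variants,category_mix Planted variants (see
#'   [plant_variants()]).
#' @param plans Library plans (see [default_library_plans()]).
#' @param fp_singleton_rate,true_singleton_rate Assembly fixture rates.
#' @param min_len,polyAT_min_run,terminal_policy Preprocessing.
#' @param k,band Mapper.
#' @param caller_configs List of `list(min_identity, min_aln_frac)`, one
#'   per caller; at least two required for intersection.
#' @param min_allele_support Per-allele SNP support rule.
#' @param put_min_len PUT length filter.
#' @param keyword_terms Keyword catalogue for the screen stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_genes = 12, isoforms_per_gene = 1:2,
                            len_params = list(min = 400, max = 1000),
                            n_variants = 30,
                            category_mix = c("ci/ci" = 0.57, "ci/c" = 0.26,
                                             "ci/i" = 0.09, "c/i" = 0.03,
                                             "c/c" = 0.03, "i/i" = 0.02),
                            plans = default_library_plans(n_reads = 250),
                            fp_singleton_rate = 0.05,
                            true_singleton_rate = 0.02,
                            min_len = 50, polyAT_min_run = 8,
                            terminal_policy = "discard",
                            k = 11, band = 10,
                            caller_configs = list(
                              list(min_identity = 0.98, min_aln_frac = 0.9),
                              list(min_identity = 0.95, min_aln_frac = 0.8),
                              list(min_identity = 0.90, min_aln_frac = 0.5)),
                            min_allele_support = 3, put_min_len = 100,
                            keyword_terms = default_keyword_catalog()) {
  if (length(caller_configs) < 2) {
    stopf("at least two caller configurations are required for intersection")
  }
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

write_manifest <- function(outdir, stage, params, inputs, outputs, seed) {
  man <- list(
    stage = stage, seed = seed, parameters = params,
    inputs = inputs,
    outputs = lapply(outputs, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  path <- file.path(outdir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Run the full pipeline on synthetic data
#'
#' @param outdir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param seed Master seed; all stage seeds derive from it.
#' @return Invisibly, a list with every stage's in-memory result
#'   (`txome`, `variants`, `read_sets`, `clean`, `assembly`, `put_set`,
#'   `accounting`, `callsets`, `consensus`, `screens`, `report`).
#' @export
run_pipeline <- function(outdir, config = pipeline_config(), seed = 1) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2L, 8)
  msg <- function(...) message(sprintf("[putsnp] %s", sprintf(...)))

  ## simulate
  msg("simulate: %d genes, %d libraries", config$n_genes, length(config$plans))
  txome <- generate_transcriptome(config$n_genes, config$isoforms_per_gene,
                                  config$len_params, seed = seeds[1])
  variants <- plant_variants(txome, config$n_variants, config$category_mix,
                             seed = seeds[2])
  read_sets <- simulate_read_sets(txome, variants, config$plans, seed = seeds[3])
  f_tx <- file.path(outdir, "transcripts.fasta")
  f_fq <- file.path(outdir, "reads.fastq")
  f_truth <- file.path(outdir, "read_truth.tsv")
  f_var <- file.path(outdir, "planted_variants.tsv")
  write_fasta(setNames(txome$transcripts$sequence, txome$transcripts$isoform_id), f_tx)
  write_fastq(read_sets$reads, f_fq)
  write.table(read_sets$truth, f_truth, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(variants, f_var, sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(outdir, "simulate",
                 config[c("n_genes", "isoforms_per_gene", "len_params",
                          "n_variants")],
                 list(), list(f_tx, f_fq, f_truth, f_var), seed)

  ## preprocess
  clean <- preprocess_reads(read_sets$reads, min_len = config$min_len,
                            polyAT_min_run = config$polyAT_min_run,
                            terminal_policy = config$terminal_policy)
  msg("preprocess: %d -> %d reads", nrow(read_sets$reads), nrow(clean$reads))
  f_clean <- file.path(outdir, "reads_clean.fastq")
  f_rep <- file.path(outdir, "preprocess_report.tsv")
  write_fastq(clean$reads, f_clean)
  write.table(clean$report, f_rep, sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(outdir, "preprocess",
                 config[c("min_len", "polyAT_min_run", "terminal_policy")],
                 list(f_fq), list(f_clean, f_rep), seed)

  ## assembly fixture (stands in for the de novo assembler)
  kept_truth <- read_sets$truth[read_sets$truth$read_id %in% clean$reads$read_id, ]
  assembly <- emit_assembly_fixture(
    list(reads = clean$reads, truth = kept_truth), txome,
    fp_singleton_rate = config$fp_singleton_rate,
    true_singleton_rate = config$true_singleton_rate, seed = seeds[4])
  adir <- file.path(outdir, "assembly")
  write_assembly_table(assembly, adir)
  write_manifest(outdir, "assembly",
                 config[c("fp_singleton_rate", "true_singleton_rate")],
                 list(f_clean),
                 as.list(file.path(adir, c("isotigs.tsv", "members.tsv",
                                           "contigs.tsv", "singletons.tsv"))),
                 seed)

  ## build-puts
  sing <- clean$reads[clean$reads$read_id %in% assembly$singletons$read_id, ]
  sing <- sing[nchar(sing$sequence) >= config$put_min_len, ]
  n_initial <- nrow(sing)
  resc <- rescue_singletons(sing, assembly, k = config$k, band = config$band)
  uniq <- dedup_singletons(resc$retained)
  put_set <- build_put_set(assembly, uniq, min_len = config$put_min_len)
  accounting <- put_accounting(sum(assembly$isotigs$length >= config$put_min_len),
                               n_initial, nrow(resc$rescued),
                               nrow(resc$retained) - nrow(uniq))
  msg("build-puts: %d PUTs (%d isotigs + %d singletons; %d rescued)",
      accounting$n_puts, accounting$n_isotigs, accounting$n_retained,
      accounting$n_rescued)
  f_puts <- file.path(outdir, "puts.fasta")
  f_meta <- file.path(outdir, "puts_meta.tsv")
  write_put_set(put_set, f_puts, f_meta)
  write_manifest(outdir, "build_puts", config["put_min_len"],
                 as.list(file.path(adir, "isotigs.tsv")),
                 list(f_puts, f_meta), seed)

  ## map + call, one callset per caller configuration
  member_reads <- clean$reads[clean$reads$read_id %in% assembly$members$read_id, ]
  rescued_reads <- clean$reads[clean$reads$read_id %in% resc$rescued$read_id, ]
  snp_input <- rbind(member_reads, rescued_reads)
  index <- build_index(put_set, k = config$k)
  callsets <- vector("list", length(config$caller_configs))
  call_files <- character(0)
  for (ci in seq_along(config$caller_configs)) {
    cc <- config$caller_configs[[ci]]
    aln <- map_reads(snp_input, index, min_identity = cc$min_identity,
                     min_aln_frac = cc$min_aln_frac, band = config$band)
    pile <- build_pileup(aln, put_set)
    callsets[[ci]] <- call_snps(pile, min_allele_support = config$min_allele_support)
    msg("call (config %d: identity >= %.2f): %d SNPs from %d mapped reads",
        ci, cc$min_identity, nrow(callsets[[ci]]), nrow(aln))
    f_cs <- file.path(outdir, sprintf("callset_%d.tsv", ci))
    write.table(as.data.frame(callsets[[ci]][, .(put_id, pos = pos + 1L,
                                                 allele1, allele2, n1, n2,
                                                 multiallelic)]),
                f_cs, sep = "\t", quote = FALSE, row.names = FALSE)
    call_files <- c(call_files, f_cs)
  }
  write_manifest(outdir, "call",
                 list(caller_configs = config$caller_configs,
                      min_allele_support = config$min_allele_support),
                 list(f_puts, f_clean), as.list(call_files), seed)

  ## intersect + classify
  consensus <- intersect_callsets(callsets)
  consensus <- classify_provenance(consensus)
  blast <- simulate_blast_hits(put_set, keyword_terms = config$keyword_terms,
                               seed = seeds[5])
  consensus <- classify_coding_effect(consensus, blast, put_set)
  msg("consensus: %d SNPs in all %d callsets", nrow(consensus), length(callsets))
  f_vcf <- file.path(outdir, "consensus_snps.vcf")
  f_prov <- file.path(outdir, "provenance_summary.tsv")
  write_snp_vcf(consensus, f_vcf,
                setNames(put_set$puts$length, put_set$puts$put_id))
  write.table(summarize_provenance(consensus), f_prov, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_manifest(outdir, "classify", list(), as.list(call_files),
                 list(f_vcf, f_prov), seed)

  ## screens
  partition <- partition_by_treatment(assembly$members,
                                      isotig_ids = assembly$isotigs$isotig_id)
  iso_len <- setNames(assembly$isotigs$length, assembly$isotigs$isotig_id)
  hit_tab <- data.frame(isotig_id = unique(blast$query), db = "sim",
                        hit = TRUE)
  groups <- summarize_groups(partition, iso_len, hit_tab)
  put_len <- setNames(put_set$puts$length, put_set$puts$put_id)
  bins <- summarize_by_length_bins(put_len, hit_tab)
  kw <- keyword_screen(blast, config$keyword_terms, partition,
                       isogroups = setNames(put_set$puts$isogroup_id,
                                            put_set$puts$put_id))
  n_member <- table(assembly$members$isotig_id)
  corr <- length_reads_correlation(iso_len[names(n_member)],
                                   as.integer(n_member))
  D <- distinct_nucleotides(put_set)
  div_consensus <- polymorphism_level(nrow(consensus), D)
  div_per_caller <- lapply(callsets, function(cs) polymorphism_level(nrow(cs), D))
  f_groups <- file.path(outdir, "group_summary.tsv")
  f_bins <- file.path(outdir, "length_bin_summary.tsv")
  f_kw <- file.path(outdir, "keyword_counts.tsv")
  f_cand <- file.path(outdir, "keyword_candidates.tsv")
  write.table(groups, f_groups, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bins, f_bins, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(kw$counts, f_kw, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(kw$candidates, f_cand, sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(outdir, "screen", list(), list(f_puts),
                 list(f_groups, f_bins, f_kw, f_cand), seed)

  ## report
  report <- list(
    seed = seed,
    n_reads = nrow(read_sets$reads),
    n_reads_clean = nrow(clean$reads),
    accounting = accounting,
    n_snps_per_callset = vapply(callsets, nrow, integer(1)),
    n_consensus_snps = nrow(consensus),
    provenance = summarize_provenance(consensus),
    coding_effects = as.list(table(consensus$coding_effect)),
    distinct_nucleotides = D,
    polymorphism_percent_consensus = div_consensus$percent,
    polymorphism_percent_per_callset =
      vapply(div_per_caller, `[[`, numeric(1), "percent"),
    length_reads_r = corr$r,
    keyword_distinct_isotigs = kw$n_distinct_isotigs
  )
  f_report <- file.path(outdir, "report.json")
  jsonlite::write_json(report, f_report, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  write_manifest(outdir, "report", list(), list(), list(f_report), seed)
  msg("done: %s", f_report)

  invisible(list(txome = txome, variants = variants, read_sets = read_sets,
                 clean = clean, assembly = assembly, put_set = put_set,
                 accounting = accounting, rescue = resc, callsets = callsets,
                 consensus = consensus, blast = blast,
                 screens = list(partition = partition, groups = groups,
                                bins = bins, keywords = kw, correlation = corr),
                 diversity = div_consensus, report = report))
}
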