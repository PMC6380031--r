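#' Run the full synthetic study end to end
#'
#' Executes every stage of the pipeline on synthetic data and writes all
#' intermediate and final outputs to `outdir`: reference and strain FASTA
#' files, per-strain VCFs, coordinate-map TSVs, gene/QTL BED files (original
#' and lifted), F1 reads as FASTQ, the per-gene ASE table, the QTL
#' enrichment result with its null distribution, delta-delta-Ct and GTT AUC
#' reports, a plain-text summary and a JSON run manifest listing every
#' output with a content digest. All stages are deterministic in
#' (`config`, `seed`); rerunning with the same seed reproduces every output
#' byte for byte (the manifest's timestamp aside).
#'
#' @param outdir Output directory (created if needed; must be writable).
#' @param seed Integer seed overriding `config$seed`.
#' @param config A [sim_config()]; the defaults define a small study that
#'   runs in seconds.
#' @return Invisibly, a list with the main in-memory results (`ase`,
#'   `enrichment`, `ddct`, `gtt`, `manifest`).
#' @export
run_demo <- function(outdir, seed = 1L, config = sim_config(seed = seed)) {
  seed <- check_count(seed, "seed", min = 0L)
  config$seed <- seed
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  probe <- file.path(outdir, ".write_probe")
  ok <- tryCatch({ writeLines("x", probe); TRUE }, error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) abort(sprintf("output directory '%s' is not writable", outdir),
                 class = "strainase_io_error")
  unlink(probe)
  paths <- character(0)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  out <- function(name) { p <- file.path(outdir, name); paths <<- c(paths, p); p }

  say("stage=simulate_reference seed=%d chromosomes=%d length=%d",
      seed, config$n_chromosomes, config$chrom_length)
  reference <- simulate_reference(config)
  write_genome_fasta(reference, out("reference.fa"))

  say("stage=simulate_strain_variants")
  strains <- c("LGJ", "SMJ")
  variants <- simulate_strain_variants(reference, config, strains = strains)
  builds <- list()
  for (st in strains) {
    v <- filter(variants, .data$strain == st)
    write_variants_vcf(v, out(paste0(st, ".vcf.gz")), strain = st)
    say("stage=apply_variants strain=%s n_variants=%d", st, nrow(v))
    builds[[st]] <- apply_variants(reference, v, strain = st)
    write_genome_fasta(builds[[st]]$genome, out(paste0(st, ".fa")))
    write_coord_map(builds[[st]]$map, out(paste0(st, ".map.tsv")))
  }

  say("stage=simulate_annotations n_genes=%d n_qtl=%d", config$n_genes, config$n_qtl)
  ann <- simulate_annotations(reference, config)
  write_bed(ann$genes, out("genes.bed"))
  write_bed(ann$qtl, out("qtl.bed"))
  readr::write_tsv(ann$genes, out("genes.truth.tsv"))
  for (st in strains) {
    lifted <- lift_intervals(ann$genes, builds[[st]]$map)
    write_bed(lifted, out(paste0("genes.", st, ".bed")))
  }

  sites <- diagnostic_sites(variants, strains[1], strains[2])
  readr::write_tsv(sites, out("diagnostic_sites.tsv"))

  # focal gene for ASE: the candidate gene with the most SNV-type
  # diagnostic sites (the synthetic analogue of the Hamp locus)
  say("stage=ase allelic_fraction=%g n_reads=%d", config$allelic_fraction,
      config$n_reads)
  cand <- filter(ann$genes, .data$candidate)
  n_sites <- purrr::map_int(seq_len(nrow(cand)), function(i) {
    sum(sites$chrom == cand$chrom[i] & sites$type == "snv" &
          sites$pos - 1L >= cand$start[i] & sites$pos - 1L < cand$end[i])
  })
  focal <- cand[which.max(n_sites), ]
  say("stage=ase focal_gene=%s snv_sites=%d", focal$name, max(n_sites))
  pad <- config$read_len
  region <- tibble(chrom = focal$chrom,
                   start = max(0L, focal$start - pad),
                   end = min(reference$length[match(focal$chrom, reference$chrom)],
                             focal$end + pad))
  hap <- purrr::map(strains, function(st) {
    haplotype_region(reference, filter(variants, .data$strain == st), region)
  })
  local_sites <- sites |>
    filter(.data$chrom == region$chrom, .data$pos > region$start,
           .data$pos <= region$end) |>
    mutate(pos = .data$pos - region$start)
  reads <- simulate_reads(hap[[1]]$seq, hap[[2]]$seq, config,
                          map_a = hap[[1]]$map, map_b = hap[[2]]$map)
  write_reads_fastq(reads, out("reads.fq"))
  asg <- assign_reads(reads, hap[[1]]$seq, hap[[2]]$seq, local_sites,
                      map_a = hap[[1]]$map, map_b = hap[[2]]$map)
  local_gene <- mutate(focal, start = .data$start - region$start,
                       end = .data$end - region$start)
  counts <- count_reads_per_gene(reads, asg, local_gene)
  ase <- allele_bias(counts)
  readr::write_tsv(as_tibble(ase), out("ase.tsv"))

  say("stage=enrichment n_perm=%d", config$n_perm)
  sizes <- genome_sizes(reference)
  enr <- permutation_test(filter(ann$genes, .data$candidate), ann$qtl,
                          sizes, n_perm = config$n_perm, seed = seed)
  readr::write_tsv(glance(enr), out("enrichment.tsv"))
  writeLines(as.character(enr$null_counts), out("enrichment_null.txt"))

  say("stage=ddct")
  ct <- simulate_ct_table(
    tibble(group = c("control", "high_iron"), fold_change = c(1, 3.6)),
    config, control_group = "control",
    target_gene = "Hamp", reference_gene = "Atp5b")
  readr::write_tsv(ct, out("ct_table.tsv"))
  ddct <- delta_delta_ct(ct, "control", reference_gene = "Atp5b")
  readr::write_tsv(as_tibble(ddct), out("ddct.tsv"))

  say("stage=gtt")
  gtt <- simulate_gtt_table(
    tibble(group = c("control", "high_iron"), baseline = c(120, 130),
           peak = c(150, 230), n_animals = 8L),
    config)
  readr::write_tsv(gtt, out("gtt.tsv"))
  auc <- gtt_auc(gtt)
  readr::write_tsv(auc, out("gtt_auc.tsv"))

  say("stage=outlier_screen")
  gr <- grubbs_screen(auc$auc_total, alpha = 0.05)
  lp <- log10_policy(auc$auc_total)

  fold <- glance(ddct)
  summary_lines <- c(
    sprintf("strainase demo (seed %d)", seed),
    sprintf("reference: %d chromosomes x %d bp", config$n_chromosomes,
            config$chrom_length),
    sprintf("variants: %s", paste(sprintf("%s=%d", strains,
            table(variants$strain)[strains]), collapse = " ")),
    sprintf("diagnostic sites: %d (%d snv)", nrow(sites),
            sum(sites$type == "snv")),
    sprintf("focal gene %s: bias=%.3f (95%% CI %.3f-%.3f, p=%.3g, n=%d+%d)",
            focal$name, ase$bias[1], ase$ci_low[1], ase$ci_high[1],
            ase$p_value[1], ase$n_a[1], ase$n_b[1]),
    sprintf("enrichment: observed=%d null_mean=%.2f p=%.4g",
            enr$observed, mean(enr$null_counts), enr$p_empirical),
    sprintf("ddct: high_iron fold=%.3f (planted 3.6)",
            fold$geomean_fold[fold$group == "high_iron"]),
    sprintf("gtt: mean total AUC control=%.0f high_iron=%.0f",
            mean(auc$auc_total[grepl("^control", auc$animal)]),
            mean(auc$auc_total[grepl("^high_iron", auc$animal)])),
    sprintf("outliers in total AUC: %s",
            if (length(gr$outlier_indices)) paste(gr$outlier_indices,
                                                  collapse = ",") else "none"),
    sprintf("log10 policy on total AUC: %s (Shapiro-Wilk p=%.3g)",
            if (lp$transformed) "transformed" else "untransformed", lp$p_value)
  )
  writeLines(summary_lines, out("summary.txt"))
  writeLines(log_lines, out("run.log"))

  manifest <- list(
    tool = "strainase",
    version = as.character(packageVersion("strainase")),
    subcommand = "demo",
    seed = seed,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    outputs = purrr::map(paths, function(p) {
      list(path = basename(p), sha = rlang::hash(readBin(p, "raw",
                                                         file.size(p))))
    }),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(ase = ase, enrichment = enr, ddct = ddct, gtt = auc,
                 manifest = manifest))
}
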