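# End-to-end orchestration: VCF -> depth filter -> region classes ->
# consequences -> allele typing -> casein haplotypes -> regulatory scan,
# with table-shaped TSV reports and a JSON run summary.

#' Run the full milk protein variant pipeline
#'
#' @param gff3,fasta Gene models and genome (see [load_transcripts()]).
#' @param vcf Cohort VCF path.
#' @param catalog Allele catalog path (default: the shipped catalog).
#' @param groups Group assignment TSV path (`animal_id`, `group`) or NULL.
#' @param seeds miRNA seed table path or NULL to skip the miRNA scan.
#' @param pwms PWM motif file path or NULL to skip the TFBS scan.
#' @param out_dir Report directory (created).
#' @param min_depth Genotype depth filter (default 8).
#' @param maf Minor-allele-frequency threshold for haplotype sites
#'   (default 0.05).
#' @param offsets Precursor offsets (default [milk_offsets()]).
#' @param pwm_threshold Relative PWM score threshold (default 0.85).
#' @param casein_genes Genes whose sites enter haplotype estimation.
#' @return Invisibly, a list with all intermediate objects and report
#'   paths: `consequences`, `allele_frequencies`, `haplotypes`,
#'   `regulatory`, `summary`.
#' @export
run_pipeline <- function(gff3, fasta, vcf, catalog = milk_catalog_path(),
                         groups = NULL, seeds = NULL, pwms = NULL,
                         out_dir = "milkvar_reports", min_depth = 8,
                         maf = 0.05, offsets = milk_offsets(),
                         pwm_threshold = 0.85,
                         casein_genes = c("CSN1S1", "CSN2", "CSN1S2",
                                          "CSN3")) {
  if (!file.exists(catalog)) stop("catalog file not found: ", catalog)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  models <- load_transcripts(gff3, fasta, offsets = offsets)
  genome <- load_genome(fasta)
  models <- lapply(models, attach_genome, genome = genome)
  cat_obj <- load_catalog(catalog)
  seeds_tab <- if (!is.null(seeds)) read_seed_table(seeds) else NULL
  pwm_list <- if (!is.null(pwms)) read_pwms(pwms) else NULL

  vc <- read_vcf(vcf, groups = groups)
  gm <- filter_by_depth(vc$genotypes, min_depth)
  variants <- vc$variants
  if (nrow(variants) == 0) {
    warning("VCF contains no variants; writing empty reports")
  }

  # assign each variant to the transcript model whose span (+/- window)
  # contains it, then classify
  owner <- rep(NA_character_, nrow(variants))
  region <- rep(NA_character_, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    for (m in models) {
      if (variants$chrom[i] != m$chrom) next
      lo <- min(m$exons$start) - 2000L
      hi <- max(m$exons$end) + 2000L
      if (variants$pos[i] >= lo && variants$pos[i] <= hi) {
        owner[i] <- m$gene
        region[i] <- classify_region(variants[i, ], m)
        break
      }
    }
  }

  # consequences for coding variants
  cons_rows <- list()
  for (i in which(region == "coding")) {
    m <- models[[owner[i]]]
    cc <- predict_consequence(variants[i, ], m, offsets = offsets)
    cons_rows[[length(cons_rows) + 1L]] <- data.frame(
      chrom = variants$chrom[i], pos = variants$pos[i],
      id = variants$id[i], gene = cc$gene, ref = variants$ref[i],
      alt = variants$alt[i], kind = cc$kind,
      precursor_change = cc$precursor_change,
      mature_change = ifelse(is.na(cc$mature_change), cc$mature_pos,
                             cc$mature_change),
      stringsAsFactors = FALSE)
  }
  consequences <- if (length(cons_rows)) {
    do.call(rbind, cons_rows)
  } else data.frame()

  # allele typing per catalog gene
  typed <- lapply(names(cat_obj$genes), function(g) {
    assign_alleles(cat_obj, gm, g)
  })
  allele_freqs <- allele_frequencies_by_group(typed)

  # casein haplotypes: defining sites of the casein genes passing the MAF
  # rule
  cas_rows <- casein_sites(cat_obj, gm, genes = casein_genes)
  hap_sites <- if (length(cas_rows)) {
    select_sites(gm, sites = cas_rows, maf_threshold = maf)
  } else integer(0)
  haplotypes <- if (length(hap_sites)) {
    lab <- haplotype_labeller(cat_obj, gm, hap_sites,
                              gene_order = intersect(casein_genes,
                                                     names(cat_obj$genes)))
    group_haplotype_frequencies(gm, hap_sites, labels = lab)
  } else NULL

  # regulatory scan over UTR/upstream variants
  reg_rows <- list()
  scan_regions <- c("5utr", "3utr", "5_upstream")
  if (!is.null(seeds_tab) || !is.null(pwm_list)) {
    for (i in which(region %in% scan_regions)) {
      m <- models[[owner[i]]]
      r <- variant_gain_loss(m, variants[i, ], seeds = seeds_tab,
                             pwms = pwm_list, threshold = pwm_threshold)
      if (nrow(r)) reg_rows[[length(reg_rows) + 1L]] <- r
    }
  }
  regulatory <- if (length(reg_rows)) {
    do.call(rbind, c(reg_rows, list(make.row.names = FALSE)))
  } else data.frame()

  # summary counts (variant classes and region distribution)
  summary <- list(
    n_variants = nrow(variants),
    n_animals = nrow(gm$animals),
    by_class = as.list(table(variants$class)),
    by_region = as.list(table(region, useNA = "no")),
    n_coding_consequences = nrow(consequences),
    haplotype_sites = length(hap_sites))

  paths <- list(
    consequences = file.path(out_dir, "consequences.tsv"),
    allele_frequencies = file.path(out_dir, "allele_frequencies.tsv"),
    haplotypes = file.path(out_dir, "haplotypes.tsv"),
    regulatory = file.path(out_dir, "regulatory.tsv"),
    summary = file.path(out_dir, "summary.json"))
  wt <- function(x, p) utils::write.table(
    x, p, sep = "\t", quote = FALSE, row.names = FALSE)
  wt(consequences, paths$consequences)
  wt(allele_freqs, paths$allele_frequencies)
  if (!is.null(haplotypes)) {
    wt(format_haplotype_table(haplotypes), paths$haplotypes)
  } else {
    wt(data.frame(), paths$haplotypes)
  }
  wt(regulatory, paths$regulatory)
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(models = models, genotypes = gm, variants = variants,
                 region = stats::setNames(region, owner),
                 consequences = consequences,
                 allele_frequencies = allele_freqs, typed = typed,
                 haplotypes = haplotypes, regulatory = regulatory,
                 summary = summary, paths = paths))
}
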