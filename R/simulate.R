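# Deterministic synthetic reference and cohort generator.
#
# The default six-gene design emulates the milk protein gene panel: gene
# names, strands and exon counts match the real loci (CSN2 on the reverse
# strand), and the defining coding sites of the shipped allele catalog are
# pinned to their published genomic coordinates, with codons chosen so each
# site produces the documented amino-acid exchange. Everything else
# (introns, UTRs, remaining codons) is pseudo-random but fully determined
# by the seed. All outputs are synthetic stand-ins, not Ensembl sequence.

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_codons <- function(n) {
  all64 <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0),
                           DNA_BASES, paste0))
  sense <- setdiff(all64, STOP_CODONS)
  sample(sense, n, replace = TRUE)
}

# --- gene designs ----------------------------------------------------------

# Exon/CDS tables are in transcription order; codon overrides pin the
# catalog sites and the frameshift read-through (13 novel residues then a
# stop in the shifted frame of the LGB insertion).
milk_gene_designs <- function() {
  e <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(start = m[, 1], end = m[, 2])
  }
  csn1s1_coding <- cbind(85416560 + (0:14) * 538, 85416560 + (0:14) * 538 + 37)
  list(
    CSN1S1 = list(
      gene = "CSN1S1", chrom = "6", strand = "+", offset = 15L,
      exons = e(85416000, 85416059,
                t(csn1s1_coding),
                85427378, 85427437, 85427937, 85427951, 85428452, 85428531),
      cds = e(t(csn1s1_coding), 85427378, 85427437, 85427937, 85427951),
      codon_overrides = list("207" = "GAA")),
    CSN2 = list(
      gene = "CSN2", chrom = "6", strand = "-", offset = 50L,
      exons = e(85458295, 85458344, 85457800, 85457879, 85456900, 85456959,
                85456000, 85456059, 85455100, 85455159, 85454200, 85454259,
                85450898, 85451347, 85450335, 85450397, 85449200, 85449299),
      cds = e(85457800, 85457859, 85456900, 85456959, 85456000, 85456059,
              85455100, 85455159, 85454200, 85454259, 85450898, 85451347,
              85450395, 85450397),
      codon_overrides = list("117" = "CAC", "247" = "GTG")),
    CSN1S2 = list(
      gene = "CSN1S2", chrom = "6", strand = "+", offset = 15L,
      exons = e(85531880, 85531934, 85532500, 85532544, 85533758, 85533817,
                t(cbind(85534400 + (0:13) * 538, 85534400 + (0:13) * 538 + 37)),
                85548400, 85548501),
      cds = e(85532500, 85532544, 85533758, 85533817,
              t(cbind(85534400 + (0:13) * 538, 85534400 + (0:13) * 538 + 37)),
              85548400, 85548431),
      codon_overrides = list("23" = "TCT")),
    CSN3 = list(
      gene = "CSN3", chrom = "6", strand = "+", offset = 21L,
      exons = e(85645300, 85645369, 85646000, 85646059, 85650000, 85650059,
                85656387, 85656806, 85656900, 85657052),
      cds = e(85646000, 85646059, 85650000, 85650059, 85656387, 85656806,
              85656900, 85656932),
      codon_overrides = list("87" = "GCT", "157" = "ATT", "169" = "GCT",
                             "189" = "GCG")),
    LALBA = list(
      gene = "LALBA", chrom = "5", strand = "+", offset = 48L,
      exons = e(31183700, 31184290, 31184612, 31184791, 31185200, 31185259,
                31185950, 31186108),
      cds = e(31184111, 31184290, 31184612, 31184791, 31185200, 31185259,
              31185950, 31185958),
      codon_overrides = list("58" = "CGG", "89" = "ATA", "112" = "GAC")),
    LGB = list(
      gene = "LGB", chrom = "11", strand = "+", offset = 16L,
      exons = e(103255830, 103256050, 103256500, 103256619,
                103257879, 103257988, 103259162, 103259281,
                103259700, 103259759, 103260100, 103260126,
                103260780, 103260899),
      cds = e(103255951, 103256050, 103256500, 103256619,
              103257879, 103257988, 103259162, 103259281,
              103259700, 103259759, 103260100, 103260126),
      # codon 108 = ACA so the A-insertion after its first base reads AAC
      # (Asn); third bases of 108-119 avoid T so the shifted frame meets no
      # stop until codon 120's T feeds TGA from codon 121's GA.
      codon_overrides = c(
        list("104" = "AAT", "108" = "ACA", "113" = "ACC", "120" = "ACT",
             "121" = "GAC", "134" = "GCC"),
        stats::setNames(as.list(c("GCA", "CTG", "GAA", "TTC", "AAG", "GGA",
                                  "CCA", "TCA", "ATC", "GTG", "CAG")),
                        as.character(109:119))))
  )
}

# transcript-sense strings written over UTR sequence: genomic span plus the
# planted element (miRNA site etc.)
milk_utr_plants <- function() {
  list(
    list(gene = "CSN2", start = 85449248, end = 85449255,
         tx = "GCTGCTAA"),    # 8mer site for bta-miR-2464-3p (minus strand)
    list(gene = "LALBA", start = 31186024, end = 31186031,
         tx = "AGCACTCA"),    # 8mer site for bta-miR-143
    list(gene = "LGB", start = 103260818, end = 103260825,
         tx = "GTCCCAGA")     # 8mer site for bta-miR-7860
  )
}

milk_seed_table <- function() {
  data.frame(
    name = c("bta-miR-2464-3p", "bta-miR-143", "bta-miR-7860",
             "bta-miR-syn-1", "bta-miR-syn-2"),
    seed = c("UAGCAGC", "GAGUGCU", "CUGGGAC", "AAGGCAC", "CCGUAAG"),
    species = "9913", stringsAsFactors = FALSE)
}

# Planted cohort variants beyond the catalog sites. ref NA = take the built
# reference base; alt NA = deterministic substitute base.
milk_planted_variants <- function() {
  data.frame(
    chrom = c("6", "11", "6", "11", "6", "6", "6", "6", "6", "6", "5",
              "11", "11"),
    pos = c(85656926, 103259170, 85646062, 103259286, 85452000, 85425000,
            85415500, 85657352, 85531897, 85449252, 31186027, 103255930,
            103260824),
    gene = c("CSN3", "LGB", "CSN3", "LGB", "CSN2", "CSN1S1", "CSN1S1",
             "CSN3", "CSN1S2", "CSN2", "LALBA", "LGB", "LGB"),
    ref = c("G", "C", NA, NA, NA, NA, NA, NA, "T", "C", "A", "G", "G"),
    alt = c("A", "T", NA, NA, NA, NA, NA, NA, "C", "A", "G", "C", "A"),
    freq = 0.10,
    region = c("coding", "coding", "splice_region", "splice_region",
               "intron", "intron", "5_upstream", "3_downstream", "5utr",
               "3utr", "3utr", "5utr", "3utr"),
    kind = c("synonymous", "synonymous", rep(NA, 11)),
    mature_change = c("p.Ala168", "p.Thr97", rep(NA, 11)),
    precursor_change = c("p.Ala189", "p.Thr113", rep(NA, 11)),
    stringsAsFactors = FALSE)
}

# regulatory truth: what each UTR variant gains/loses
milk_regulatory_truth <- function() {
  data.frame(
    chrom = c("6", "6", "5", "11", "11"),
    pos = c(85449252, 85449252, 31186027, 103255930, 103260824),
    gene = c("CSN2", "CSN2", "LALBA", "LGB", "LGB"),
    kind = c("miRNA", "TFBS", "miRNA", "TFBS", "miRNA"),
    name = c("bta-miR-2464-3p", "p63", "bta-miR-143", "STAT1",
             "bta-miR-7860"),
    change = c("loss", "gain", "loss", "gain", "loss"),
    stringsAsFactors = FALSE)
}

#' Study-design configuration for the synthetic cohort
#'
#' Defaults are the study conditions: three groups (27 crossbreed, 20
#' Lagune, 20 Somba), per-group casein haplotype frequencies and whey
#' protein allele frequencies from the published per-breed tables
#' (`"<0.01"` entries taken as 0.005, columns renormalized), planted extra
#' variants at frequency 0.10, and per-call read depths uniform on 2..60 so
#' the depth-8 genotype filter is exercised.
#'
#' @param seed Integer seed; the whole bundle is deterministic given it.
#' @param groups Named integer vector of group sizes.
#' @param casein_freqs Named list group -> named numeric of
#'   `CSN1S1-CSN2-CSN1S2-CSN3` haplotype frequencies.
#' @param lalba_freqs,lgb_freqs Named list group -> named allele
#'   frequencies.
#' @param depth_range Inclusive integer range for per-call depths.
#' @param planted data.frame of extra planted variants (see
#'   `milk_planted_variants`); NULL for none.
#' @return A `sim_config` list.
#' @export
milk_sim_config <- function(seed = 20211702,
                            groups = c(Crossbreed = 27L, Lagune = 20L,
                                       Somba = 20L),
                            casein_freqs = NULL, lalba_freqs = NULL,
                            lgb_freqs = NULL, depth_range = c(2L, 60L),
                            planted = milk_planted_variants()) {
  norm <- function(x) x / sum(x)
  if (is.null(casein_freqs)) {
    casein_freqs <- list(
      Crossbreed = norm(c("B-A1-A-B" = 0.01, "B-A2-A-B" = 0.20,
                          "B-A1-A-A" = 0.39, "C-A2-A-A" = 0.005,
                          "C-A2-A-B" = 0.38)),
      Lagune = norm(c("B-A1-A-B" = 0.50, "B-A2-A-B" = 0.18,
                      "B-A1-A-A" = 0.29, "C-A2-A-A" = 0.005,
                      "C-A2-A-B" = 0.005)),
      Somba = norm(c("B-A1-A-B" = 0.47, "B-A2-A-B" = 0.25,
                     "B-A1-A-A" = 0.20, "C-A2-A-A" = 0.02,
                     "C-A2-A-B" = 0.02)))
  }
  if (is.null(lalba_freqs)) {
    lalba_freqs <- list(
      Crossbreed = c(B = 0.72, A = 0.12, E = 0.12, F = 0.04),
      Lagune = c(B = 1.00, A = 0, E = 0, F = 0),
      Somba = c(B = 0.82, A = 0, E = 0.05, F = 0.13))
  }
  if (is.null(lgb_freqs)) {
    lgb_freqs <- list(
      Crossbreed = c(B = 0.85, B1 = 0.11, K = 0.04),
      Lagune = c(B = 0.50, B1 = 0.50, K = 0),
      Somba = c(B = 0.81, B1 = 0.19, K = 0))
  }
  structure(list(seed = as.integer(seed), groups = groups,
                 casein_freqs = casein_freqs, lalba_freqs = lalba_freqs,
                 lgb_freqs = lgb_freqs, depth_range = depth_range,
                 planted = planted), class = "sim_config")
}

#' Path of the shipped milk protein allele catalog
#' @return File path inside the installed package.
#' @export
milk_catalog_path <- function() {
  system.file("extdata", "allele_catalog.tsv", package = "milkvar",
              mustWork = TRUE)
}

# --- reference generation --------------------------------------------------

#' Generate the synthetic six-gene reference bundle
#'
#' Writes `genome.fa` (region-named sequences), `genes.gff3`,
#' `mirna_seeds.tsv`, `pwms.jaspar` and `truth_reference.json` into `dir`.
#' Deterministic given `config$seed`: the same seed yields byte-identical
#' files.
#'
#' @param config A [milk_sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the transcript models (genome attached),
#'   the genome, file paths and the truth list.
#' @export
generate_reference <- function(config = milk_sim_config(),
                               dir = tempfile("milkref")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  designs <- milk_gene_designs()
  catalog <- load_catalog(milk_catalog_path())
  plants <- milk_utr_plants()

  with_seed(config$seed, {
    regions <- list()   # per gene: chrom, start, end, bases (char vector)
    for (d in designs) {
      lo <- min(d$exons$start) - 2100L
      hi <- max(d$exons$end) + 2100L
      bases <- sample(DNA_BASES, hi - lo + 1L, replace = TRUE)
      # CDS bases from pinned/random codons
      n_cds <- sum(d$cds$end - d$cds$start + 1L)
      if (n_cds %% 3L != 0L) {
        stop("CDS length of ", d$gene, " is not a multiple of 3")
      }
      codons <- random_codons(n_cds / 3L)
      codons[1] <- "ATG"
      codons[length(codons)] <- "TAA"
      for (k in names(d$codon_overrides)) {
        codons[as.integer(k)] <- d$codon_overrides[[k]]
      }
      cds_seq <- strsplit(paste0(codons, collapse = ""), "")[[1]]
      # genomic positions of cds bases in translation order
      ord <- order(d$cds$start, decreasing = (d$strand == "-"))
      cdso <- d$cds[ord, , drop = FALSE]
      gpos <- unlist(lapply(seq_len(nrow(cdso)), function(i) {
        p <- cdso$start[i]:cdso$end[i]
        if (d$strand == "-") rev(p) else p
      }))
      fwd <- if (d$strand == "-") chartr("ACGT", "TGCA", cds_seq) else cds_seq
      bases[gpos - lo + 1L] <- fwd
      regions[[d$gene]] <- list(chrom = d$chrom, start = lo, end = hi,
                                bases = bases, design = d)
    }
    # overlay planted UTR elements (tx-sense strings)
    for (p in plants) {
      r <- regions[[p$gene]]
      s <- strsplit(p$tx, "")[[1]]
      if (r$design$strand == "-") s <- rev(chartr("ACGT", "TGCA", s))
      regions[[p$gene]]$bases[(p$start:p$end) - r$start + 1L] <- s
    }
    # force declared reference bases of planted variants
    pv <- config$planted
    if (!is.null(pv)) {
      for (i in seq_len(nrow(pv))) {
        if (!is.na(pv$ref[i]) && nchar(pv$ref[i]) == 1) {
          r <- regions[[pv$gene[i]]]
          regions[[pv$gene[i]]]$bases[pv$pos[i] - r$start + 1L] <- pv$ref[i]
        }
      }
    }
  })

  # assemble genome
  seqs <- Biostrings::DNAStringSet(vapply(regions, function(r) {
    paste0(r$bases, collapse = "")
  }, character(1)))
  names(seqs) <- vapply(regions, function(r) {
    sprintf("%s:%d-%d", r$chrom, r$start, r$end)
  }, character(1))

  fasta_path <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(seqs, fasta_path, width = 70)
  gff3_path <- file.path(dir, "genes.gff3")
  write_gff3(designs, gff3_path)

  offsets <- vapply(designs, `[[`, integer(1), "offset")
  models <- load_transcripts(gff3_path, fasta_path, offsets = offsets)
  genome <- load_genome(fasta_path)
  models <- lapply(models, attach_genome, genome = genome)

  # verify the catalog's reference alleles against the built genome
  for (g in names(catalog$genes)) {
    s <- catalog$genes[[g]]$sites
    for (i in seq_len(nrow(s))) {
      have <- genome_region(genome, s$chrom[i], s$pos[i],
                            s$pos[i] + nchar(s$ref[i]) - 1L)
      if (have != s$ref[i]) {
        stop("catalog/reference mismatch for ", g, " at ", s$chrom[i], ":",
             s$pos[i], " (catalog ", s$ref[i], ", genome ", have, ")")
      }
    }
  }

  seeds <- milk_seed_table()
  seeds_path <- file.path(dir, "mirna_seeds.tsv")
  utils::write.table(seeds, seeds_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  # PWMs: consensus motifs taken from the alternate-allele windows of the
  # two TFBS-gain variants, so the gain is by construction
  pwm_defs <- list()
  reg <- milk_regulatory_truth()
  for (i in which(reg$kind == "TFBS" & reg$change == "gain")) {
    if (is.null(config$planted)) next
    hit <- config$planted$pos == reg$pos[i] &
      config$planted$chrom == reg$chrom[i]
    if (!any(hit)) next
    pvrow <- config$planted[hit, ][1, ]
    model <- models[[reg$gene[i]]]
    rec <- data.frame(chrom = pvrow$chrom, pos = pvrow$pos, id = ".",
                      ref = pvrow$ref, alt = pvrow$alt, class = "SNP",
                      stringsAsFactors = FALSE)
    w <- variant_windows(model, rec, flank = 5L)
    # variant sits at tx position 6 of the 11-nt window; motif covers 4..9
    pwm_defs[[reg$name[i]]] <- substr(w$alt, 4, 9)
  }
  pwm_defs[["SYN-TF-1"]] <- "ACGTAC"      # decoy motif
  pwms_path <- file.path(dir, "pwms.jaspar")
  write_jaspar(pwm_defs, pwms_path)

  truth <- list(
    seed = config$seed,
    genes = lapply(models, function(m) list(
      gene = m$gene, chrom = m$chrom, strand = m$strand,
      n_exons = nrow(m$exons), cds_length = nchar(m$cds_sequence),
      precursor_length = nchar(m$cds_sequence) %/% 3L - 1L,
      protein = sub("\\*$", "", translate_dna(m$cds_sequence)))),
    regulatory = reg)
  truth_path <- file.path(dir, "truth_reference.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  out <- list(models = models, genome = genome, catalog = catalog,
              dir = dir, fasta = fasta_path, gff3 = gff3_path,
              seeds = seeds_path, pwms = pwms_path, truth = truth,
              config = config)
  class(out) <- "milk_reference"
  invisible(out)
}

write_gff3 <- function(designs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (d in designs) {
    glo <- min(d$exons$start); ghi <- max(d$exons$end)
    gid <- paste0("gene:", d$gene)
    tid <- paste0("tx_", d$gene)
    writeLines(sprintf(
      "%s\tmilkvar\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      d$chrom, glo, ghi, d$strand, gid, d$gene), con)
    writeLines(sprintf(
      "%s\tmilkvar\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;gene_name=%s",
      d$chrom, glo, ghi, d$strand, tid, gid, d$gene), con)
    for (i in seq_len(nrow(d$exons))) {
      writeLines(sprintf(
        "%s\tmilkvar\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
        d$chrom, d$exons$start[i], d$exons$end[i], d$strand, tid), con)
    }
    cum <- 0L
    for (i in seq_len(nrow(d$cds))) {
      phase <- (3L - cum %% 3L) %% 3L
      writeLines(sprintf(
        "%s\tmilkvar\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
        d$chrom, d$cds$start[i], d$cds$end[i], d$strand, phase, tid), con)
      cum <- cum + d$cds$end[i] - d$cds$start[i] + 1L
    }
  }
  invisible(path)
}

write_jaspar <- function(defs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(defs)) {
    cons <- strsplit(defs[[nm]], "")[[1]]
    writeLines(sprintf(">SYN%04d %s", match(nm, names(defs)), nm), con)
    for (b in DNA_BASES) {
      counts <- ifelse(cons == b, 85, 5)
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(sprintf("%3d", counts), collapse = " ")), con)
    }
  }
  invisible(path)
}

# --- cohort generation -----------------------------------------------------

#' Generate a synthetic genotyped cohort
#'
#' Samples two haplotypes per animal from the group-specific frequencies
#' (casein haplotypes jointly over the four casein genes; whey protein
#' alleles independently per gene), derives diploid genotypes at every
#' catalog site plus the planted extra variants, draws per-call read
#' depths, and writes `cohort.vcf`, `groups.tsv` and truth tables.
#'
#' @param ref A `milk_reference` from [generate_reference()].
#' @param config The [milk_sim_config()] (defaults to the reference's).
#' @param dir Output directory (defaults to the reference's).
#' @return Invisibly, a list with the `genotype_matrix`, file paths and
#'   truth tables (`truth_alleles`: per-animal allele pairs per gene;
#'   `truth_variants`: per-variant region/consequence truth).
#' @export
generate_cohort <- function(ref, config = ref$config, dir = ref$dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  catalog <- ref$catalog
  designs <- milk_gene_designs()

  casein_genes <- c("CSN1S1", "CSN2", "CSN1S2", "CSN3")
  whey <- list(LALBA = config$lalba_freqs, LGB = config$lgb_freqs)

  animals <- unlist(lapply(names(config$groups), function(g) {
    sprintf("%s_%02d", g, seq_len(config$groups[[g]]))
  }))
  group_of <- rep(names(config$groups), config$groups)
  n <- length(animals)

  # variant table: catalog sites + planted extras
  site_tab <- do.call(rbind, lapply(catalog$genes, function(cg) {
    cbind(cg$sites, gene = cg$gene)
  }))
  rownames(site_tab) <- NULL
  pv <- config$planted

  sim <- with_seed(config$seed + 1L, {
    # per-animal haplotype draws
    cas1 <- cas2 <- character(n)
    wa <- list()
    for (g in names(whey)) wa[[g]] <- list(h1 = character(n),
                                           h2 = character(n))
    for (i in seq_len(n)) {
      f <- config$casein_freqs[[group_of[i]]]
      draw <- sample(names(f), 2, replace = TRUE, prob = f)
      cas1[i] <- draw[1]; cas2[i] <- draw[2]
      for (g in names(whey)) {
        fg <- whey[[g]][[group_of[i]]]
        dg <- sample(names(fg), 2, replace = TRUE, prob = fg)
        wa[[g]]$h1[i] <- dg[1]; wa[[g]]$h2[i] <- dg[2]
      }
    }

    # genotypes at catalog sites from allele definitions (vectorized over
    # animals: per-gene allele-name vectors, then definition-matrix lookup)
    n_site <- nrow(site_tab)
    a1 <- matrix(0L, n_site, n); a2 <- matrix(0L, n_site, n)
    cas_part <- function(labels, g) {
      vapply(strsplit(labels, "-", fixed = TRUE), `[`,
             character(1), match(g, casein_genes))
    }
    truth_rows <- list()
    for (g in names(catalog$genes)) {
      cg <- catalog$genes[[g]]
      rows <- which(site_tab$gene == g)
      al1 <- if (g %in% casein_genes) cas_part(cas1, g) else wa[[g]]$h1
      al2 <- if (g %in% casein_genes) cas_part(cas2, g) else wa[[g]]$h2
      defmat <- do.call(cbind, cg$definitions)   # sites x alleles
      a1[rows, ] <- defmat[, al1, drop = FALSE]
      a2[rows, ] <- defmat[, al2, drop = FALSE]
      truth_rows[[g]] <- data.frame(
        animal = animals, group = group_of, gene = g,
        allele1 = pmin(al1, al2), allele2 = pmax(al1, al2),
        stringsAsFactors = FALSE)
    }
    truth_alleles <- do.call(rbind, c(truth_rows,
                                      list(make.row.names = FALSE)))
    truth_alleles <- truth_alleles[order(truth_alleles$animal,
                                         truth_alleles$gene), ]
    rownames(truth_alleles) <- NULL

    # planted extra variants: fill auto ref/alt from the genome, draw
    # genotypes independently per chromosome copy
    if (!is.null(pv) && nrow(pv) > 0) {
      for (k in seq_len(nrow(pv))) {
        if (is.na(pv$ref[k])) {
          pv$ref[k] <- genome_region(ref$genome, pv$chrom[k], pv$pos[k],
                                     pv$pos[k])
        }
        if (is.na(pv$alt[k])) {
          pv$alt[k] <- DNA_BASES[match(pv$ref[k], DNA_BASES) %% 4L + 1L]
        }
      }
      p1 <- matrix(stats::rbinom(nrow(pv) * n, 1, pv$freq), nrow(pv), n)
      p2 <- matrix(stats::rbinom(nrow(pv) * n, 1, pv$freq), nrow(pv), n)
      a1 <- rbind(a1, p1); a2 <- rbind(a2, p2)
    }

    variants <- rbind(
      data.frame(chrom = site_tab$chrom, pos = site_tab$pos, id = ".",
                 ref = site_tab$ref, alt = site_tab$alt,
                 class = variant_class(site_tab$ref, site_tab$alt),
                 stringsAsFactors = FALSE),
      if (!is.null(pv) && nrow(pv) > 0) data.frame(
        chrom = pv$chrom, pos = pv$pos, id = ".", ref = pv$ref,
        alt = pv$alt, class = variant_class(pv$ref, pv$alt),
        stringsAsFactors = FALSE))
    ord <- order(variants$chrom, variants$pos, variants$alt)
    variants <- variants[ord, , drop = FALSE]
    rownames(variants) <- NULL
    a1 <- a1[ord, , drop = FALSE]; a2 <- a2[ord, , drop = FALSE]

    depth <- matrix(sample(config$depth_range[1]:config$depth_range[2],
                           nrow(variants) * n, replace = TRUE),
                    nrow(variants), n)
    gm <- genotype_matrix(variants, animals, a1, a2,
                          groups = data.frame(animal_id = animals,
                                              group = group_of),
                          depth = depth)
    list(gm = gm, pv = pv, hap1 = cas1, hap2 = cas2,
         truth_alleles = truth_alleles)
  })
  gm <- sim$gm
  pv <- sim$pv
  truth_alleles <- sim$truth_alleles
  hap1 <- sim$hap1
  hap2 <- sim$hap2

  vcf_path <- file.path(dir, "cohort.vcf")
  write_vcf(gm, vcf_path)
  groups_path <- file.path(dir, "groups.tsv")
  utils::write.table(data.frame(animal_id = animals, group = group_of),
                     groups_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # per-variant truth (region + consequence)
  truth_variants <- rbind(
    data.frame(chrom = site_tab$chrom, pos = site_tab$pos,
               gene = site_tab$gene, ref = site_tab$ref,
               alt = site_tab$alt, region = "coding",
               stringsAsFactors = FALSE),
    if (!is.null(pv) && nrow(pv) > 0) data.frame(
      chrom = pv$chrom, pos = pv$pos, gene = pv$gene, ref = pv$ref,
      alt = pv$alt, region = pv$region, stringsAsFactors = FALSE))

  truth <- list(
    truth_alleles = truth_alleles,
    truth_haplotypes = data.frame(animal = animals, group = group_of,
                                  hap1 = hap1, hap2 = hap2,
                                  stringsAsFactors = FALSE),
    truth_variants = truth_variants,
    truth_planted = pv,
    truth_regulatory = milk_regulatory_truth())
  utils::write.table(truth_alleles, file.path(dir, "truth_alleles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$truth_haplotypes,
                     file.path(dir, "truth_haplotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth_variants, file.path(dir, "truth_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(c(list(genotypes = gm, vcf = vcf_path, groups = groups_path,
                   dir = dir), truth))
}

# --- generic toy gene (property tests) -------------------------------------

#' Generate a random toy transcript model
#'
#' A small multi-exon gene with a valid ORF (start codon, single terminal
#' stop), random UTRs and introns, on either strand. Used for
#' property-style testing of the coordinate and consequence machinery.
#'
#' @param n_exons Number of exons (>= 1).
#' @param n_codons Codons including the stop (CDS length = 3 * n_codons).
#' @param strand `"+"` or `"-"`.
#' @param chrom Chromosome name.
#' @param origin Genomic coordinate of the region start.
#' @return A [transcript_model()] with its genome attached.
#' @export
sim_gene <- function(n_exons = 3, n_codons = 40, strand = "+",
                     chrom = "T1", origin = 1000L) {
  cds_len <- 3L * n_codons
  codons <- random_codons(n_codons)
  codons[1] <- "ATG"
  codons[n_codons] <- "TAA"
  cds_seq <- paste0(codons, collapse = "")
  # split CDS over exons; first/last exon carry UTRs
  cuts <- sort(sample(seq_len(cds_len - 1), n_exons - 1))
  chunk <- diff(c(0L, cuts, cds_len))
  utr5 <- sample(20:60, 1)
  utr3 <- sample(20:60, 1)
  introns <- sample(60:200, max(n_exons - 1, 1), replace = TRUE)

  # transcription-order layout in a local coordinate axis, then mapped to
  # genomic forward coordinates depending on strand
  exon_len <- chunk
  exon_len[1] <- exon_len[1] + utr5
  exon_len[n_exons] <- exon_len[n_exons] + utr3
  starts <- integer(n_exons)
  starts[1] <- 1L
  for (i in seq_len(n_exons - 1)) {
    starts[i + 1] <- starts[i] + exon_len[i] + introns[i]
  }
  total <- starts[n_exons] + exon_len[n_exons] - 1L
  pad <- 300L
  # local tx-axis intervals
  ex_lo <- starts; ex_hi <- starts + exon_len - 1L
  cds_lo <- ex_lo; cds_hi <- ex_hi
  cds_lo[1] <- ex_lo[1] + utr5
  cds_hi[n_exons] <- ex_hi[n_exons] - utr3
  # transcript sequence
  tx_seq <- paste0(random_dna(utr5), cds_seq, random_dna(utr3))
  # map local tx axis -> genomic forward
  if (strand == "+") {
    g_of <- function(x) origin + pad + x - 1L
    exons <- data.frame(start = g_of(ex_lo), end = g_of(ex_hi))
    cds <- data.frame(start = g_of(cds_lo), end = g_of(cds_hi))
  } else {
    g_of <- function(x) origin + pad + total - x
    exons <- data.frame(start = g_of(ex_hi), end = g_of(ex_lo))
    cds <- data.frame(start = g_of(cds_hi), end = g_of(cds_lo))
  }
  region_lo <- origin
  region_hi <- origin + 2L * pad + total - 1L
  bases <- sample(DNA_BASES, region_hi - region_lo + 1L, replace = TRUE)
  # write exon bases
  txv <- strsplit(tx_seq, "")[[1]]
  k <- 0L
  for (i in seq_len(n_exons)) {
    seg <- txv[(k + 1L):(k + exon_len[i])]
    k <- k + exon_len[i]
    if (strand == "+") {
      gpos <- exons$start[i]:exons$end[i]
      bases[gpos - region_lo + 1L] <- seg
    } else {
      gpos <- exons$end[i]:exons$start[i]
      bases[gpos - region_lo + 1L] <- chartr("ACGT", "TGCA", seg)
    }
  }
  g <- Biostrings::DNAStringSet(paste0(bases, collapse = ""))
  names(g) <- sprintf("%s:%d-%d", chrom, region_lo, region_hi)
  m <- transcript_model("TOY", "toy_tx", chrom, strand,
                        exons = exons, cds = cds, genome = g,
                        precursor_offset = 2L)
  stopifnot(m$cds_sequence == cds_seq)
  attach_genome(m, g)
}
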