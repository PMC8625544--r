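# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# default six-gene reference + 67-animal cohort (memoized)
milk_fixture <- function() {
  if (is.null(.fixture_env$milk)) {
    dir <- file.path(tempdir(), "milkvar_fixture")
    ref <- generate_reference(milk_sim_config(), dir = dir)
    coh <- generate_cohort(ref)
    .fixture_env$milk <- list(ref = ref, coh = coh)
  }
  .fixture_env$milk
}

# hand-built deterministic 2-exon forward-strand toy gene on a 200-bp
# chromosome; CDS spliced from 31..50 and 61..88 (48 nt, 16 codons)
toy_gene <- function(strand = "+") {
  base <- paste0(
    "ACGTACGTACGTACGTACGT",              # 1..20 upstream
    "TTTTTCCCCC",                        # 21..30 5'UTR
    "ATGGCTCATAAAGGCGTTCC",              # 31..50 CDS exon 1
    "GGGGGAAAAA",                        # 51..60 intron
    "TGCTGGATCGATCCGTACGATTCATAA",       # 61..87 CDS exon 2 (ends TAA)
    "A",                                 # 88 last CDS base?  see below
    "CCCCCGGGGGTT",                      # 89..100 3'UTR
    paste0(rep("ACGT", 25), collapse = "")) # 101..200 downstream
  # CDS 31..50 + 61..88: force a clean ORF: codons =
  #   ATG GCT CAT AAA GGC GTT CC|T GCT GGA TCG ATC CGT ACG ATT CAT AA|A
  # gives 48 nt; ensure final codon is TAA by construction below
  seqs <- strsplit(base, "")[[1]]
  stopifnot(length(seqs) == 200)
  cds <- paste0(paste0(seqs[31:50], collapse = ""),
                paste0(seqs[61:88], collapse = ""))
  # rewrite last codon to TAA
  seqs[86:88] <- c("T", "A", "A")
  seq <- paste0(seqs, collapse = "")
  if (strand == "+") {
    g <- Biostrings::DNAStringSet(seq)
    names(g) <- "Z"
    m <- transcript_model("TOY", "toy_tx", "Z", "+",
                          exons = data.frame(start = c(21, 61),
                                             end = c(50, 100)),
                          cds = data.frame(start = c(31, 61),
                                           end = c(50, 88)),
                          genome = g, precursor_offset = 2L)
  } else {
    # same gene on the reverse strand of the reverse-complemented genome
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
    g <- Biostrings::DNAStringSet(rc)
    names(g) <- "Z"
    flip <- function(p) 201L - p
    m <- transcript_model("TOY", "toy_tx", "Z", "-",
                          exons = data.frame(start = flip(c(50, 100)),
                                             end = flip(c(21, 61))),
                          cds = data.frame(start = flip(c(50, 88)),
                                           end = flip(c(31, 61))),
                          genome = g, precursor_offset = 2L)
  }
  attach_genome(m, g)
}

# one-row variant record constructor for tests
vr <- function(chrom, pos, ref, alt, id = ".") {
  normalize_variant(chrom, as.integer(pos), ref, alt, id)
}

# apply a set of atomic VCF-style records to a reference string that starts
# at genomic position `origin` (used as the MNP-decomposition oracle);
# right-to-left, and at a shared position the indel applies before the SNP
apply_records <- function(refseq, origin, records) {
  records <- records[order(-records$pos, records$class == "SNP"),
                     , drop = FALSE]
  s <- refseq
  for (i in seq_len(nrow(records))) {
    off <- records$pos[i] - origin + 1L
    stopifnot(substr(s, off, off + nchar(records$ref[i]) - 1L) ==
                records$ref[i])
    s <- paste0(substr(s, 1, off - 1L), records$alt[i],
                substr(s, off + nchar(records$ref[i]), nchar(s)))
  }
  s
}

# brute-force maximum-likelihood haplotype frequencies via multi-start
# optimization on the softmax-parameterized simplex (EM oracle)
brute_force_haplo_ml <- function(geno, n_start = 40) {
  pairs <- apply(geno, 1, function(g) milkvar:::compatible_pairs(g),
                 simplify = FALSE)
  haps <- sort(unique(unlist(lapply(pairs, function(e) {
    unlist(lapply(e, function(p) c(p$h1, p$h2)))
  }))))
  K <- length(haps)
  nll <- function(theta) {
    p <- exp(c(theta, 0)); p <- p / sum(p)
    names(p) <- haps
    -sum(vapply(pairs, function(e) {
      tot <- sum(vapply(e, function(q) {
        p[q$h1] * p[q$h2] * if (q$h1 == q$h2) 1 else 2
      }, numeric(1)))
      log(max(tot, 1e-300))
    }, numeric(1)))
  }
  best <- Inf
  for (s in seq_len(n_start)) {
    th0 <- stats::rnorm(K - 1, sd = 2)
    fit <- tryCatch(stats::optim(th0, nll, method = "BFGS",
                                 control = list(maxit = 2000,
                                                reltol = 1e-14)),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      # polish with a derivative-free pass
      fit2 <- tryCatch(stats::optim(fit$par, nll, method = "Nelder-Mead",
                                    control = list(maxit = 5000,
                                                   reltol = 1e-14)),
                       error = function(e) fit)
      best <- min(best, fit$value, fit2$value)
    }
  }
  -best   # maximized log-likelihood
}
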