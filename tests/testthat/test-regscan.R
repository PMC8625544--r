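# miRNA seed matching and PWM scanning.

test_that("seed site types follow the canonical taxonomy", {
  seed <- "TAGCAGC"                     # miRNA positions 2-8 (DNA)
  core <- milkvar:::revcomp(substr(seed, 1, 6))   # CTGCTA
  # 8mer: complement of m8 before the core, A after it
  s8 <- paste0("TTTT", "G", core, "A", "TTTT")
  h <- find_seed_sites(s8, seed, "m")
  expect_identical(h$type, "8mer")
  # 7mer-m8: m8 match, no A1
  h2 <- find_seed_sites(paste0("TTTT", "G", core, "C", "TTTT"), seed, "m")
  expect_identical(h2$type, "7mer-m8")
  # 7mer-A1: A opposite position 1, mismatch at m8
  h3 <- find_seed_sites(paste0("TTTT", "C", core, "A", "TTTT"), seed, "m")
  expect_identical(h3$type, "7mer-A1")
  # bare 6mer
  h4 <- find_seed_sites(paste0("TTTT", "C", core, "C", "TTTT"), seed, "m")
  expect_identical(h4$type, "6mer")
  # RNA alphabet input is normalized
  h5 <- find_seed_sites(chartr("T", "U", s8), chartr("T", "U", seed), "m")
  expect_identical(h5$type, "8mer")
  # no complement anywhere -> empty
  expect_identical(nrow(find_seed_sites("AAAAAAAAAA", seed, "m")), 0L)
  expect_error(find_seed_sites("ACGT", "NNNNNNN", "m"), "ambiguous")
})

test_that("seed matcher equals exhaustive window enumeration", {
  set.seed(5)
  for (rep in seq_len(1000)) {
    seq <- paste0(sample(c("A", "C", "G", "T"), sample(20:60, 1), TRUE),
                  collapse = "")
    seed <- paste0(sample(c("A", "C", "G", "T"), 7, TRUE), collapse = "")
    got <- find_seed_sites(seq, seed, "x")
    # oracle: check every window of length 6 against the complement rule
    core <- milkvar:::revcomp(substr(seed, 1, 6))
    m8c <- milkvar:::complement_base(substr(seed, 7, 7))
    want <- list()
    for (p in seq_len(nchar(seq) - 5)) {
      if (substr(seq, p, p + 5) != core) next
      hm8 <- p > 1 && substr(seq, p - 1, p - 1) == m8c
      ha1 <- p + 6 <= nchar(seq) && substr(seq, p + 6, p + 6) == "A"
      want[[length(want) + 1]] <- data.frame(
        position = p,
        type = if (hm8 && ha1) "8mer" else if (hm8) "7mer-m8"
          else if (ha1) "7mer-A1" else "6mer")
    }
    if (length(want) == 0) {
      expect_identical(nrow(got), 0L)
    } else {
      want <- do.call(rbind, want)
      expect_identical(got[, c("position", "type")], want)
    }
  }
})

test_that("PWM scoring equals a per-column summation oracle", {
  set.seed(9)
  pwm_file <- tempfile(fileext = ".jaspar")
  writeLines(c(">M0001 TOY",
               "A [ 10  2  0  5 ]",
               "C [  5  1 12  5 ]",
               "G [  2 14  1  5 ]",
               "T [  3  3  7  5 ]"), pwm_file)
  pwm <- read_pwms(pwm_file)$TOY
  expect_equal(colSums(pwm$matrix), rep(1, 4), ignore_attr = TRUE)
  lo <- log2((pwm$matrix + pwm$pseudocount) / 0.25)
  for (rep in 1:100) {
    w <- paste0(sample(c("A", "C", "G", "T"), 4, TRUE), collapse = "")
    oracle <- sum(vapply(1:4, function(i) {
      lo[substr(w, i, i), i]
    }, numeric(1)))
    hits <- scan_pwm(w, pwm, threshold = 0)
    got <- hits$score[hits$strand == "+"]
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  # consensus scores relative 1.0
  cons <- paste0(rownames(pwm$matrix)[apply(pwm$matrix, 2, which.max)],
                 collapse = "")
  h <- scan_pwm(cons, pwm, threshold = 0.999)
  expect_true(any(h$rel_score[h$strand == "+"] > 1 - 1e-9))
  # uninformative matrix: no windows reported
  flat <- tempfile(fileext = ".jaspar")
  writeLines(c(">M0002 FLAT",
               "A [ 1 1 1 1 ]", "C [ 1 1 1 1 ]",
               "G [ 1 1 1 1 ]", "T [ 1 1 1 1 ]"), flat)
  expect_identical(nrow(scan_pwm("ACGTACGT", read_pwms(flat)$FLAT, 0)), 0L)
})

test_that("MEME minimal format parses to the same matrices", {
  meme <- tempfile(fileext = ".txt")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF TOYM", "letter-probability matrix: alength= 4 w= 4",
               " 0.7 0.1 0.1 0.1", " 0.1 0.7 0.1 0.1", " 0.1 0.1 0.1 0.7",
               " 0.1 0.1 0.7 0.1"),
             meme)
  pwms <- read_pwms(meme)
  expect_identical(names(pwms), "TOYM")
  expect_equal(unname(pwms$TOYM$matrix["A", 1]), 0.7)
  expect_equal(unname(pwms$TOYM$matrix["T", 3]), 0.7)
  expect_equal(unname(pwms$TOYM$matrix["G", 4]), 0.7)
  expect_error(suppressWarnings(read_pwms(tempfile())),
               "cannot|No such|no motifs")
})

test_that("gain/loss reports are anti-symmetric under allele swap", {
  fx <- milk_fixture()
  seeds <- read_seed_table(fx$ref$seeds)
  pwms <- read_pwms(fx$ref$pwms)
  pv <- fx$coh$truth_planted
  utr <- pv[pv$region %in% c("5utr", "3utr"), ]
  for (i in seq_len(nrow(utr))) {
    m <- fx$ref$models[[utr$gene[i]]]
    rec <- vr(utr$chrom[i], utr$pos[i], utr$ref[i], utr$alt[i])
    fwd <- variant_gain_loss(m, rec, seeds = seeds, pwms = pwms)
    # swap: pretend the alternate allele is the reference; scanning must
    # see exactly the mirrored gains and losses
    swapped <- rec
    swapped$ref <- rec$alt; swapped$alt <- rec$ref
    g2 <- attr(m, "genome")
    # build a genome carrying the alternate allele so the swapped record's
    # "reference" matches
    m_alt <- m
    seqs <- g2$seqs
    for (k in seq_along(g2$index)) {
      e <- g2$index[[k]]
      if (e$chrom == rec$chrom && rec$pos > e$offset &&
          rec$pos <= e$offset + e$len) {
        s <- as.character(seqs[[k]])
        substr(s, rec$pos - e$offset, rec$pos - e$offset) <- rec$alt
        seqs[[k]] <- Biostrings::DNAString(s)
      }
    }
    m_alt <- attach_genome(m, seqs)
    rev <- variant_gain_loss(m_alt, swapped, seeds = seeds, pwms = pwms)
    key <- function(d) sort(paste(d$kind, d$name, d$change))
    flip <- function(d) {
      d$change <- ifelse(d$change == "gain", "loss", "gain")
      d
    }
    expect_identical(key(rev), key(flip(fwd)))
  }
})

test_that("all planted regulatory effects are recovered with no extras", {
  fx <- milk_fixture()
  seeds <- read_seed_table(fx$ref$seeds)
  pwms <- read_pwms(fx$ref$pwms)
  truth <- fx$coh$truth_regulatory
  pv <- fx$coh$truth_planted
  scan <- pv[pv$region %in% c("5utr", "3utr", "5_upstream"), ]
  got <- list()
  for (i in seq_len(nrow(scan))) {
    m <- fx$ref$models[[scan$gene[i]]]
    rec <- vr(scan$chrom[i], scan$pos[i], scan$ref[i], scan$alt[i])
    got[[i]] <- variant_gain_loss(m, rec, seeds = seeds, pwms = pwms)
  }
  got <- do.call(rbind, got)
  expect_identical(nrow(got), nrow(truth))
  key <- function(d, pos) sort(paste(pos, d$kind, d$name, d$change))
  expect_identical(key(got, got$variant),
                   key(truth, paste0(truth$chrom, ":", truth$pos)))
})
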