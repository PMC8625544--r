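# Gain/loss scanning of miRNA seed-match sites and PWM-scored TFBS in
# UTR/flanking sequence.
#
# Seed-site classes follow the canonical target-site taxonomy: a 6mer is the
# reverse complement of miRNA positions 2-7 in the target; 7mer-m8 extends
# the match to miRNA position 8; 7mer-A1 instead has an A in the target
# opposite miRNA position 1 (immediately 3' of the 6mer match); 8mer has
# both. Only site presence/type is scored, no context scoring.

#' Read a miRNA seed table
#'
#' Tab-separated in the seed-file layout: miRNA family name, 7-nt seed+m8
#' sequence (miRNA positions 2-8, RNA or DNA alphabet), species (ignored).
#' A header line is detected and skipped.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `name`, `seed` (7-nt, DNA alphabet).
#' @export
read_seed_table <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!grepl("^[ACGTUacgtu]+$", tab[1, 2])) tab <- tab[-1, , drop = FALSE]
  seeds <- toupper(chartr("Uu", "Tt", tab[, 2]))
  bad <- !grepl("^[ACGT]{6,7}$", seeds)
  if (any(bad)) {
    stop("seed(s) with ambiguous bases or wrong length: ",
         paste(tab[bad, 1], collapse = ", "))
  }
  data.frame(name = tab[, 1], seed = seeds, stringsAsFactors = FALSE)
}

#' Find miRNA seed-match sites in a sequence
#'
#' @param sequence Target sequence (DNA or RNA alphabet; scanned as given,
#'   i.e. in the sense orientation of the transcript).
#' @param seed 7-nt seed+m8 (miRNA positions 2-8) or 6-nt seed (positions
#'   2-7); RNA or DNA alphabet.
#' @param name miRNA name carried through to the output.
#' @return data.frame with `name`, `position` (start of the 6mer core
#'   match), `type` (`8mer`, `7mer-m8`, `7mer-A1`, `6mer`); the single
#'   strongest type per locus.
#' @export
find_seed_sites <- function(sequence, seed, name = NA_character_) {
  seq <- toupper(chartr("Uu", "Tt", sequence))
  seed <- toupper(chartr("Uu", "Tt", seed))
  if (!grepl("^[ACGT]{6,7}$", seed)) {
    stop("seed has ambiguous bases or wrong length")
  }
  core <- revcomp(substr(seed, 1, 6))        # complement of miRNA 2-7
  m8 <- if (nchar(seed) == 7) complement_base(substr(seed, 7, 7)) else NA
  hits <- gregexpr(core, seq, fixed = TRUE)[[1]]
  if (hits[1] < 0) {
    return(data.frame(name = character(0), position = integer(0),
                      type = character(0), stringsAsFactors = FALSE))
  }
  out <- lapply(as.integer(hits), function(p) {
    has_m8 <- !is.na(m8) && p > 1 && substr(seq, p - 1, p - 1) == m8
    has_a1 <- p + 6 <= nchar(seq) && substr(seq, p + 6, p + 6) == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
      else if (has_a1) "7mer-A1" else "6mer"
    data.frame(name = name, position = p, type = type,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Sense-strand window around a variant, for ref and alt alleles.
# Returns list(ref, alt, shift) where shift is the tx-space position change
# of bases 3' of the edit (used to compare site coordinates across alleles).
variant_windows <- function(model, record, flank) {
  g <- load_genome_cache(model)
  lo <- record$pos - flank
  hi <- record$pos + nchar(record$ref) - 1L + flank
  ref_seq <- genome_region(g, model$chrom, lo, hi)
  off <- record$pos - lo + 1L
  stopifnot(substr(ref_seq, off, off + nchar(record$ref) - 1L) == record$ref)
  alt_seq <- paste0(substr(ref_seq, 1, off - 1L), record$alt,
                    substr(ref_seq, off + nchar(record$ref), nchar(ref_seq)))
  if (model$strand == "-") {
    ref_seq <- revcomp(ref_seq)
    alt_seq <- revcomp(alt_seq)
  }
  list(ref = ref_seq, alt = alt_seq,
       shift = nchar(record$alt) - nchar(record$ref))
}

# transcript models keep no genome handle; rebuild a minimal one covering
# the exons plus flanks from the stored transcript sequence is not possible
# for intergenic flanks, so scanning functions take the genome explicitly.
load_genome_cache <- function(model) {
  g <- attr(model, "genome")
  if (is.null(g)) {
    stop("attach the genome with `attr(model, 'genome') <- load_genome(...)`",
         " before regulatory scanning")
  }
  g
}

#' miRNA target-site gain/loss caused by a variant
#'
#' Compares seed-match sites between the reference and alternate sequence
#' in a window of +/- (site length - 1) = 7 bases around the variant, in
#' transcript-sense orientation. Sites present only in the reference are
#' losses, only in the alternate gains.
#'
#' @param model A [transcript_model()] with its genome attached (see
#'   [attach_genome()]).
#' @param record One-row variant data.frame (UTR/upstream variant).
#' @param seeds data.frame from [read_seed_table()].
#' @return data.frame `name`, `type`, `change` (`loss`/`gain`).
#' @export
variant_mirna_gain_loss <- function(model, record, seeds) {
  w <- variant_windows(model, record, flank = 7L)
  cmp_sites(
    ref = scan_all_seeds(w$ref, seeds),
    alt = scan_all_seeds(w$alt, seeds),
    shift = w$shift, strand = model$strand, ref_len = nchar(record$ref))
}

scan_all_seeds <- function(seq, seeds) {
  do.call(rbind, c(lapply(seq_len(nrow(seeds)), function(i) {
    find_seed_sites(seq, seeds$seed[i], seeds$name[i])
  }), list(data.frame(name = character(0), position = integer(0),
                      type = character(0), stringsAsFactors = FALSE))))
}

# Compare ref/alt site tables. For substitutions positions are directly
# comparable; for indels, alt positions 3' of the edit are shifted back by
# the net length change before comparison.
cmp_sites <- function(ref, alt, shift, strand, ref_len) {
  key <- function(d) paste(d$name, d$type, d$position)
  if (shift != 0 && nrow(alt) > 0) {
    mid <- 8L   # edit start within the window (flank 7 + 1), tx-sense
    adj <- alt$position
    adj[adj > mid] <- adj[adj > mid] - shift
    alt$position <- adj
  }
  loss <- ref[!(key(ref) %in% key(alt)), , drop = FALSE]
  gain <- alt[!(key(alt) %in% key(ref)), , drop = FALSE]
  rbind(
    if (nrow(loss)) cbind(loss, change = "loss"),
    if (nrow(gain)) cbind(gain, change = "gain"),
    data.frame(name = character(0), position = integer(0),
               type = character(0), change = character(0),
               stringsAsFactors = FALSE))
}

#' Attach a genome to a transcript model for flank extraction
#'
#' @param model A [transcript_model()].
#' @param genome A `DNAStringSet`, FASTA path, or `genome_seq` object.
#' @return The model with the genome attached.
#' @export
attach_genome <- function(model, genome) {
  attr(model, "genome") <- load_genome(genome)
  model
}

# --- PWMs ------------------------------------------------------------------

#' Read position weight matrices in JASPAR or minimal MEME format
#'
#' JASPAR: `>ID NAME` followed by four rows `A [ counts... ]` etc. MEME
#' minimal: `MOTIF NAME` followed by a `letter-probability matrix` block.
#' Counts are converted to column-normalized frequencies.
#'
#' @param path Path to the motif file.
#' @param pseudocount Added to every frequency when scoring (default 0.01).
#' @param background Base composition (default uniform).
#' @return Named list of `pwm` objects (fields `name`, `matrix` 4 x L with
#'   rows A,C,G,T, `background`, `pseudocount`).
#' @export
read_pwms <- function(path, pseudocount = 0.01,
                      background = c(A = 0.25, C = 0.25, G = 0.25,
                                     T = 0.25)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  mk <- function(name, mat) {
    mat <- sweep(mat, 2, pmax(colSums(mat), 1e-12), "/")
    rownames(mat) <- c("A", "C", "G", "T")
    if (ncol(mat) < 4) stop("PWM '", name, "' is shorter than 4 columns")
    structure(list(name = name, matrix = mat, background = background,
                   pseudocount = pseudocount), class = "pwm")
  }
  if (any(grepl("^MEME version|^MOTIF", lines))) {
    i <- 1
    while (i <= length(lines)) {
      if (grepl("^MOTIF", lines[i])) {
        name <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
        j <- i + 1
        while (j <= length(lines) &&
               !grepl("letter-probability", lines[j])) j <- j + 1
        rows <- list()
        j <- j + 1
        while (j <= length(lines) &&
               grepl("^[0-9. \t eE+-]+$", lines[j]) &&
               !grepl("^MOTIF", lines[j])) {
          rows[[length(rows) + 1]] <-
            as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1]])
          j <- j + 1
        }
        mat <- t(do.call(rbind, rows))     # rows A C G T after transpose
        out[[name]] <- mk(name, mat)
        i <- j
      } else i <- i + 1
    }
  } else {
    i <- 1
    while (i <= length(lines)) {
      if (grepl("^>", lines[i])) {
        hdr <- strsplit(sub("^>", "", trimws(lines[i])), "\\s+")[[1]]
        name <- if (length(hdr) >= 2) hdr[2] else hdr[1]
        vals <- lapply(lines[i + 1:4], function(l) {
          as.numeric(regmatches(l, gregexpr("[0-9.]+", l))[[1]])
        })
        out[[name]] <- mk(name, do.call(rbind, vals))
        i <- i + 5
      } else i <- i + 1
    }
  }
  if (length(out) == 0) stop("no motifs found in '", path, "'")
  out
}

#' Scan a sequence with a position weight matrix
#'
#' Per-window log-odds score `sum log2((f + pseudocount) / background)`,
#' both strands. A window is a hit when its score, rescaled between the
#' matrix's minimum and maximum attainable scores, reaches `threshold`.
#'
#' @param sequence DNA sequence.
#' @param pwm A `pwm` object (see [read_pwms()]).
#' @param threshold Relative score in `[0,1]` (default 0.85).
#' @return data.frame `position` (on the given sequence), `strand`,
#'   `score`, `rel_score` for each hit.
#' @export
scan_pwm <- function(sequence, pwm, threshold = 0.85) {
  L <- ncol(pwm$matrix)
  seq <- toupper(sequence)
  n <- nchar(seq)
  empty <- data.frame(position = integer(0), strand = character(0),
                      score = numeric(0), rel_score = numeric(0))
  if (n < L) return(empty)
  lo <- log2((pwm$matrix + pwm$pseudocount) / pwm$background)
  smax <- sum(apply(lo, 2, max))
  smin <- sum(apply(lo, 2, min))
  if (smax - smin < 1e-12) return(empty)   # uninformative matrix: no hits
  score_one <- function(s) {
    b <- strsplit(s, "")[[1]]
    idx <- match(b, c("A", "C", "G", "T"))
    if (anyNA(idx)) return(NA_real_)
    sum(lo[cbind(idx, seq_len(L))])
  }
  out <- list()
  for (strand in c("+", "-")) {
    sc <- if (strand == "+") seq else revcomp(seq)
    for (p in seq_len(n - L + 1)) {
      s <- score_one(substr(sc, p, p + L - 1))
      if (is.na(s)) next
      rel <- (s - smin) / (smax - smin)
      if (rel >= threshold - 1e-12) {
        pos <- if (strand == "+") p else n - L + 2L - p
        out[[length(out) + 1]] <- data.frame(
          position = pos, strand = strand, score = s, rel_score = rel)
      }
    }
  }
  if (length(out) == 0) empty else do.call(rbind, out)
}

#' TFBS gain/loss caused by a variant
#'
#' Analogous to [variant_mirna_gain_loss()]: PWM hits are compared between
#' reference and alternate windows of +/- (motif length - 1) around the
#' variant.
#'
#' @param model A [transcript_model()] with genome attached.
#' @param record One-row variant data.frame.
#' @param pwms Named list from [read_pwms()].
#' @param threshold Relative score threshold (default 0.85).
#' @return data.frame `name`, `type` (strand of the hit), `change`.
#' @export
variant_tfbs_gain_loss <- function(model, record, pwms, threshold = 0.85) {
  out <- list()
  for (pwm in pwms) {
    L <- ncol(pwm$matrix)
    w <- variant_windows(model, record, flank = L - 1L)
    ref <- scan_pwm(w$ref, pwm, threshold)
    alt <- scan_pwm(w$alt, pwm, threshold)
    tab <- function(d) if (nrow(d) == 0) d else
      data.frame(name = pwm$name, position = d$position, type = d$strand,
                 stringsAsFactors = FALSE)
    mid <- L                                # edit start within window
    if (nrow(alt) > 0 && w$shift != 0) {
      alt$position[alt$position > mid] <-
        alt$position[alt$position > mid] - w$shift
    }
    out[[pwm$name]] <- cmp_sites(tab(ref), tab(alt), shift = 0,
                                 strand = model$strand,
                                 ref_len = nchar(record$ref))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Full gain/loss report for one variant
#'
#' @param model A [transcript_model()] with genome attached.
#' @param record One-row variant data.frame.
#' @param seeds Seed table ([read_seed_table()]); `NULL` to skip.
#' @param pwms PWM list ([read_pwms()]); `NULL` to skip.
#' @param threshold PWM relative-score threshold.
#' @return A `gain_loss_report`: data.frame `variant`, `region`, `kind`
#'   (`miRNA`/`TFBS`), `name`, `change`.
#' @export
variant_gain_loss <- function(model, record, seeds = NULL, pwms = NULL,
                              threshold = 0.85) {
  region <- classify_region(record, model)
  rows <- list()
  if (!is.null(seeds)) {
    m <- variant_mirna_gain_loss(model, record, seeds)
    if (nrow(m)) rows[["mirna"]] <- data.frame(
      kind = "miRNA", name = m$name, site_type = m$type, change = m$change,
      stringsAsFactors = FALSE)
  }
  if (!is.null(pwms)) {
    t <- variant_tfbs_gain_loss(model, record, pwms, threshold)
    if (nrow(t)) rows[["tfbs"]] <- data.frame(
      kind = "TFBS", name = t$name, site_type = t$type, change = t$change,
      stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else NULL
  if (is.null(res) || nrow(res) == 0) {
    return(data.frame(gene = character(0), variant = character(0),
                      id = character(0), region = character(0),
                      kind = character(0), name = character(0),
                      site_type = character(0), change = character(0),
                      stringsAsFactors = FALSE))
  }
  cbind(data.frame(gene = model$gene,
                   variant = paste0(record$chrom, ":", record$pos),
                   id = record$id, region = region,
                   stringsAsFactors = FALSE)[rep(1, nrow(res)), ,
                                             drop = FALSE],
        res, row.names = NULL)
}
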