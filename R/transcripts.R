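# Transcript models: genomic <-> CDS <-> protein coordinate arithmetic.
#
# A transcript_model stores exon and CDS intervals in transcription order
# and precomputes, for every base of the spliced coding sequence (and the
# 3'UTR, needed to read through frameshifts), its genomic position. All
# strand handling funnels through that lookup.

#' Construct a transcript model
#'
#' @param gene Gene symbol.
#' @param transcript_id Transcript identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (1-based closed
#'   genomic intervals), one row per exon, in transcription order.
#' @param cds Same layout for the coding intervals; must be contained in the
#'   exons. Total width must be a multiple of 3 (stop codon included).
#' @param genome A named `DNAStringSet` (or path to a FASTA file). Sequence
#'   names are either plain chromosome names or samtools-style regions
#'   (`"chr:start-end"`) covering a genomic window.
#' @param precursor_offset Residues subtracted to convert precursor to
#'   mature numbering (see [milk_offsets()]).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene, transcript_id, chrom, strand, exons, cds,
                             genome, precursor_offset = 0L) {
  stopifnot(strand %in% c("+", "-"),
            all(exons$end >= exons$start),
            all(cds$end >= cds$start))
  exons <- exons[, c("start", "end")]
  cds <- cds[, c("start", "end")]
  # transcription order: ascending starts on +, descending on -
  ord <- order(exons$start, decreasing = (strand == "-"))
  exons <- exons[ord, , drop = FALSE]
  cds <- cds[order(cds$start, decreasing = (strand == "-")), , drop = FALSE]

  so <- sort(exons$start)
  eo <- sort(exons$end)
  if (any(so[-1] <= eo[-length(eo)])) stop("exons overlap in '", gene, "'")
  for (i in seq_len(nrow(cds))) {
    if (!any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)) {
      stop("CDS interval outside exons in '", gene, "'")
    }
  }

  genome <- load_genome(genome)
  # genomic position of each transcript base, in transcription order
  tx_pos <- unlist(lapply(seq_len(nrow(exons)), function(i) {
    p <- exons$start[i]:exons$end[i]
    if (strand == "-") rev(p) else p
  }))
  cds_pos <- unlist(lapply(seq_len(nrow(cds)), function(i) {
    p <- cds$start[i]:cds$end[i]
    if (strand == "-") rev(p) else p
  }))
  if (length(cds_pos) %% 3L != 0L) {
    stop("CDS length of transcript '", transcript_id,
         "' is not a multiple of 3")
  }
  cds_idx <- match(cds_pos, tx_pos)
  if (anyNA(cds_idx)) stop("CDS not contained in exons for '", gene, "'")
  tx_seq <- paste0(vapply(tx_pos, function(p) {
    genome_base(genome, chrom, p)
  }, character(1)), collapse = "")
  if (strand == "-") tx_seq <- chartr("ACGT", "TGCA", tx_seq)

  cds_first <- min(cds_idx)
  cds_last <- max(cds_idx)
  structure(list(
    gene = gene, transcript_id = transcript_id, chrom = chrom,
    strand = strand, exons = exons, cds = cds,
    precursor_offset = as.integer(precursor_offset),
    tx_pos = tx_pos, tx_seq = tx_seq,
    cds_tx_idx = cds_first:cds_last,      # CDS is contiguous in tx space
    cds_genome_pos = tx_pos[cds_first:cds_last],
    cds_sequence = substr(tx_seq, cds_first, cds_last),
    utr5_pos = if (cds_first > 1) tx_pos[1:(cds_first - 1)] else integer(0),
    utr3_pos = if (cds_last < length(tx_pos))
      tx_pos[(cds_last + 1):length(tx_pos)] else integer(0),
    utr3_seq = if (cds_last < length(tx_pos))
      substr(tx_seq, cds_last + 1, length(tx_pos)) else ""
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d strand %s\n",
              x$gene, x$transcript_id, x$chrom,
              min(x$exons$start), max(x$exons$end), x$strand))
  cat(sprintf("  %d exons, CDS %d nt (%d codons), precursor offset %d\n",
              nrow(x$exons), nchar(x$cds_sequence),
              nchar(x$cds_sequence) %/% 3L, x$precursor_offset))
  invisible(x)
}

# --- genome access ---------------------------------------------------------

load_genome <- function(genome) {
  if (inherits(genome, "genome_seq")) return(genome)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  nm <- sub("\\s.*$", "", names(genome))
  m <- regmatches(nm, regexec("^(.+):([0-9]+)-([0-9]+)$", nm))
  idx <- lapply(seq_along(nm), function(i) {
    if (length(m[[i]]) == 4) {
      list(chrom = m[[i]][2], offset = as.integer(m[[i]][3]) - 1L,
           len = length(genome[[i]]))
    } else {
      list(chrom = nm[i], offset = 0L, len = length(genome[[i]]))
    }
  })
  structure(list(seqs = genome, index = idx), class = "genome_seq")
}

genome_region <- function(genome, chrom, start, end) {
  for (i in seq_along(genome$index)) {
    e <- genome$index[[i]]
    if (e$chrom == chrom && start > e$offset && end <= e$offset + e$len) {
      return(as.character(Biostrings::subseq(
        genome$seqs[[i]], start - e$offset, end - e$offset)))
    }
  }
  stop("no sequence covering ", chrom, ":", start, "-", end)
}

genome_base <- function(genome, chrom, pos) {
  genome_region(genome, chrom, pos, pos)
}

# --- GFF3 loading ----------------------------------------------------------

#' Load transcript models from GFF3 and FASTA
#'
#' One transcript is used per gene. GFF3 must carry `mRNA` (or `transcript`)
#' features with `exon` and `CDS` children.
#'
#' @param gff3_path Path to a GFF3 file.
#' @param fasta_path Path to the genome FASTA (plain chromosomes or
#'   `"chr:start-end"` region sequences).
#' @param offsets Named precursor offsets, see [milk_offsets()]. Genes absent
#'   from the vector get offset 0.
#' @param transcripts Optional character vector of transcript IDs to load; a
#'   requested ID that is absent is a hard error. Default: every transcript
#'   in the file (one per gene expected).
#' @return Named list of [transcript_model()] objects (by gene).
#' @export
load_transcripts <- function(gff3_path, fasta_path, offsets = milk_offsets(),
                             transcripts = NULL) {
  gff <- rtracklayer::import(gff3_path, format = "gff3")
  if (length(gff) == 0) stop("no transcripts in '", gff3_path, "'")
  type <- as.character(gff$type)
  tx_rows <- which(type %in% c("mRNA", "transcript"))
  if (length(tx_rows) == 0) stop("no transcripts in '", gff3_path, "'")
  genome <- load_genome(fasta_path)

  ids <- as.character(gff$ID[tx_rows])
  if (!is.null(transcripts)) {
    missing <- setdiff(transcripts, ids)
    if (length(missing) > 0) {
      stop("transcript ID(s) not found in GFF3: ",
           paste(missing, collapse = ", "))
    }
    tx_rows <- tx_rows[ids %in% transcripts]
    ids <- ids[ids %in% transcripts]
  }

  parent <- vapply(as.list(gff$Parent), function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))

  models <- lapply(seq_along(tx_rows), function(k) {
    i <- tx_rows[k]
    id <- ids[k]
    gene <- as.character(gff$gene_name[i] %||% NA)
    if (is.na(gene) || !nzchar(gene)) {
      gene <- sub("^gene:", "", parent[i])
      if (is.na(gene) || !nzchar(gene)) gene <- id
    }
    child <- which(parent == id)
    ex <- child[type[child] == "exon"]
    cd <- child[type[child] == "CDS"]
    if (length(ex) == 0 || length(cd) == 0) {
      stop("transcript '", id, "' lacks exon/CDS features")
    }
    transcript_model(
      gene = gene, transcript_id = id,
      chrom = as.character(GenomicRanges::seqnames(gff))[i],
      strand = as.character(GenomicRanges::strand(gff))[i],
      exons = data.frame(start = GenomicRanges::start(gff)[ex],
                         end = GenomicRanges::end(gff)[ex]),
      cds = data.frame(start = GenomicRanges::start(gff)[cd],
                       end = GenomicRanges::end(gff)[cd]),
      genome = genome,
      precursor_offset = if (gene %in% names(offsets)) offsets[[gene]] else 0L
    )
  })
  names(models) <- vapply(models, `[[`, character(1), "gene")
  models
}

# --- coordinate arithmetic -------------------------------------------------

#' Map a genomic position onto the coding sequence
#'
#' @param model A [transcript_model()].
#' @param genomic_pos Genomic coordinate (1-based).
#' @return For a coding base, the 1-based position along the spliced CDS in
#'   translation order (integer). Otherwise one of the region tags
#'   `"upstream"`, `"5utr"`, `"intron"`, `"3utr"`, `"downstream"`.
#' @export
genomic_to_cds <- function(model, genomic_pos) {
  i <- match(genomic_pos, model$cds_genome_pos)
  if (!is.na(i)) return(i)
  if (genomic_pos %in% model$utr5_pos) return("5utr")
  if (genomic_pos %in% model$utr3_pos) return("3utr")
  lo <- min(model$exons$start)
  hi <- max(model$exons$end)
  if (genomic_pos >= lo && genomic_pos <= hi) return("intron")
  before <- genomic_pos < lo
  if (model$strand == "+") {
    if (before) "upstream" else "downstream"
  } else {
    if (before) "downstream" else "upstream"
  }
}

#' Inverse of [genomic_to_cds()] for coding positions
#'
#' @param model A [transcript_model()].
#' @param cds_pos 1-based position along the spliced CDS.
#' @return Genomic coordinate (integer).
#' @export
cds_to_genomic <- function(model, cds_pos) {
  n <- length(model$cds_genome_pos)
  if (cds_pos < 1 || cds_pos > n) stop("CDS position out of range")
  model$cds_genome_pos[cds_pos]
}

#' Convert a CDS position to a protein residue and codon offset
#'
#' @param cds_pos 1-based CDS position.
#' @param model Optional [transcript_model()] for bounds checking.
#' @return List with `residue` (precursor numbering, `ceiling(pos/3)`) and
#'   `codon_offset` (0, 1 or 2 within the codon).
#' @examples
#' cds_to_protein(261)  # residue 87, offset 2
#' @export
cds_to_protein <- function(cds_pos, model = NULL) {
  if (cds_pos < 1) stop("CDS position out of range")
  if (!is.null(model) && cds_pos > nchar(model$cds_sequence)) {
    stop("CDS position out of range")
  }
  list(residue = as.integer(ceiling(cds_pos / 3)),
       codon_offset = as.integer((cds_pos - 1L) %% 3L))
}
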