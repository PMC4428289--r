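#' Genome record container
#'
#' A `GenomeRecord` bundles the contigs of one assembly with optional gene
#' annotations. It is the unit every detector in the pipeline consumes.
#' Contig sequences are stored uppercase over the alphabet {A,C,G,T,N};
#' ambiguity codes are collapsed to N so that downstream exact-match steps
#' treat assembly gaps as matching nothing.
#'
#' @param genome_id Single string naming the genome/strain.
#' @param contigs Named character vector of nucleotide sequences; names are
#'   contig ids and must be unique.
#' @param annotations Optional data frame of gene annotations as returned by
#'   [read_gff()] (zero rows allowed). Coordinates are 0-based half-open.
#' @return An object of class `GenomeRecord`: a list with elements
#'   `genome_id`, `contigs`, `annotations`.
#' @export
GenomeRecord <- function(genome_id, contigs, annotations = empty_annotations()) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  contigs <- setNames(as.character(contigs), names(contigs))
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stop("contigs must be uniquely named")
  if (any(!nzchar(contigs))) stop("empty contig sequence")
  contigs <- clean_sequences(contigs)
  structure(list(genome_id = genome_id, contigs = contigs,
                 annotations = annotations),
            class = "GenomeRecord")
}

empty_annotations <- function() {
  data.frame(contig_id = character(), start = integer(), end = integer(),
             strand = character(), product = character(),
             stringsAsFactors = FALSE)
}

# uppercase and collapse anything outside {A,C,G,T,N} to N
clean_sequences <- function(x) {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    warning(sum(bad), " sequence(s) contained non-ACGTN characters; mapped to N")
    x[bad] <- gsub("[^ACGTN]", "N", x[bad])
  }
  x
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat("GenomeRecord", x$genome_id, "-", length(x$contigs), "contig(s),",
      sum(nchar(x$contigs)), "bp,", nrow(x$annotations), "annotation(s)\n")
  invisible(x)
}

#' Read a genome from FASTA
#'
#' Sequences are uppercased; characters outside {A,C,G,T,N} are replaced by N
#' with a warning. Duplicate record ids or an empty file are errors.
#'
#' @param path Path to a FASTA file.
#' @param genome_id Genome name; defaults to the file name without extension.
#' @return A [GenomeRecord].
#' @export
read_fasta <- function(path, genome_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  seqs <- as.character(ss)
  # FASTA headers: id is the first whitespace-delimited token
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs)))
    stop("duplicate contig id in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  GenomeRecord(genome_id, seqs)
}

#' Write sequences to FASTA
#'
#' @param x A [GenomeRecord] or a named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  seqs <- if (inherits(x, "GenomeRecord")) x$contigs else as.character(x)
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' GFF3 carries 1-based inclusive coordinates; they are converted to the
#' package's internal 0-based half-open convention. The product label is taken
#' from the `product` attribute, falling back to `gene` then `Name`.
#'
#' @param path Path to a GFF3 file.
#' @param genome A [GenomeRecord]; features on contigs absent from it are an
#'   error. Pass `NULL` to skip the check.
#' @param feature_types Feature types to keep (default CDS and gene).
#' @return Data frame with columns `contig_id`, `start`, `end` (0-based
#'   half-open), `strand`, `product`.
#' @export
read_gff <- function(path, genome = NULL, feature_types = c("CDS", "gene")) {
  if (!file.exists(path)) stop("no such file: ", path)
  g <- as.data.frame(rtracklayer::readGFF(path))
  if (nrow(g) > 0L && !is.null(feature_types))
    g <- g[g$type %in% feature_types, , drop = FALSE]
  pick <- function(col) if (col %in% names(g)) as.character(g[[col]]) else rep(NA_character_, nrow(g))
  product <- pick("product")
  product <- ifelse(is.na(product), pick("gene"), product)
  product <- ifelse(is.na(product), pick("Name"), product)
  ann <- data.frame(contig_id = as.character(g$seqid),
                    start = as.integer(g$start) - 1L,   # to 0-based half-open
                    end = as.integer(g$end),
                    strand = as.character(g$strand),
                    product = product,
                    stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    unknown <- setdiff(unique(ann$contig_id), names(genome$contigs))
    if (length(unknown))
      stop("GFF features on contig(s) absent from genome: ",
           paste(unknown, collapse = ", "))
    too_far <- ann$end > nchar(genome$contigs)[ann$contig_id]
    if (any(too_far)) stop("GFF feature(s) extend past contig end")
  }
  if (any(ann$start < 0L | ann$start >= ann$end)) stop("invalid GFF coordinates")
  ann
}

#' Basic genome statistics
#'
#' @param genome A [GenomeRecord].
#' @return List with `size_bp`, `gc_percent` (N excluded from the
#'   denominator; `NA` with a warning if the genome is all N), `n_contigs`.
#' @export
genome_stats <- function(genome) {
  stopifnot(inherits(genome, "GenomeRecord"))
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(genome$contigs))[, c("A", "C", "G", "T"), drop = FALSE])
  acgt <- sum(counts)
  gc <- if (acgt == 0L) {
    warning("genome contains no unambiguous bases; GC undefined")
    NA_real_
  } else 100 * (counts[["G"]] + counts[["C"]]) / acgt
  list(size_bp = sum(nchar(genome$contigs)),
       gc_percent = gc,
       n_contigs = length(genome$contigs))
}

# reverse complement of a plain character vector (N-safe)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write detected arrays as GFF3 and BED
#'
#' Arrays are emitted as `repeat_region` features with `direct_repeat`
#' children; coordinates follow each format's native convention (GFF3 1-based
#' inclusive, BED 0-based half-open).
#'
#' @param arrays List of [CrisprArray] objects.
#' @param gff_path,bed_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, a list of the paths written.
#' @export
write_arrays <- function(arrays, gff_path = NULL, bed_path = NULL) {
  if (!is.null(gff_path)) {
    lines <- c("##gff-version 3")
    for (a in arrays) {
      att <- sprintf("ID=%s;consensus=%s;n_units=%d", a$array_id,
                     a$consensus_dr, nrow(a$repeats))
      lines <- c(lines, paste(a$contig_id, "crisprscape", "repeat_region",
                              a$start + 1L, a$end, ".", a$orientation, ".",
                              att, sep = "\t"))
      for (i in seq_len(nrow(a$repeats))) {
        lines <- c(lines, paste(a$contig_id, "crisprscape", "direct_repeat",
                                a$repeats$start[i] + 1L, a$repeats$end[i], ".",
                                a$orientation, ".",
                                sprintf("Parent=%s", a$array_id), sep = "\t"))
      }
    }
    writeLines(lines, gff_path)
  }
  if (!is.null(bed_path)) {
    writeLines(vapply(arrays, function(a)
      paste(a$contig_id, a$start, a$end, a$array_id, nrow(a$repeats),
            ifelse(a$orientation == "unknown", ".", a$orientation), sep = "\t"),
      character(1)), bed_path)
  }
  invisible(list(gff = gff_path, bed = bed_path))
}
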