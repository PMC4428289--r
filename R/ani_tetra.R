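#' Fragment-based average nucleotide identity
#'
#' The query is cut into consecutive `frag_len` fragments (a trailing piece
#' shorter than `frag_len/2` is dropped, otherwise kept). Each fragment is
#' placed in the reference by shared-k-mer diagonal voting and locally
#' aligned (match +1, mismatch -2, affine gaps) at its best location on
#' either strand. Fragments are retained iff identity >= `min_identity` over
#' >= `min_coverage` of the fragment length; ANI is the mean identity of
#' retained fragments.
#'
#' @param query,ref [GenomeRecord]s (or named character vectors of contigs).
#' @param frag_len Fragment length (nt).
#' @param min_identity Retention threshold on fragment identity (fraction).
#' @param min_coverage Retention threshold on aligned fragment coverage.
#' @param seed_k k-mer length used to place fragments.
#' @return List of class `AniResult`: `ani_percent` (NA with `undefined =
#'   TRUE` when no fragment is retained), `n_fragments_total`,
#'   `n_fragments_aligned`, `aligned_fraction`.
#' @export
ani <- function(query, ref, frag_len = 1020L, min_identity = 0.3,
                min_coverage = 0.7, seed_k = 16L) {
  qc <- if (inherits(query, "GenomeRecord")) query$contigs else query
  rc_ <- if (inherits(ref, "GenomeRecord")) ref$contigs else ref
  stopifnot(sum(nchar(qc)) >= frag_len, sum(nchar(rc_)) >= frag_len)
  frags <- character(0)
  for (s in qc) {
    n <- nchar(s)
    starts <- seq(1L, n, by = frag_len)
    pieces <- substring(s, starts, pmin(starts + frag_len - 1L, n))
    short <- nchar(pieces) < frag_len / 2
    frags <- c(frags, pieces[!short])
  }
  ref_idx <- lapply(rc_, encode_kmers, k = seed_k)
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                      baseOnly = FALSE)
  place_and_align <- function(frag) {
    best <- NULL
    for (fs in c(frag, revcomp(frag))) {
      fk <- encode_kmers(fs, seed_k)
      fk_ok <- !is.na(fk)
      if (!any(fk_ok)) next
      for (cid in names(ref_idx)) {
        tid <- ref_idx[[cid]]
        pos <- match(fk, tid)
        hit <- which(!is.na(pos))
        if (length(hit) < 2L) next
        diag <- pos[hit] - hit
        db <- round(diag / 100)
        mode_bin <- as.integer(names(sort(table(db), decreasing = TRUE))[1])
        d0 <- stats::median(diag[db == mode_bin])
        w_from <- max(1L, as.integer(d0) + 1L - 250L)
        w_to <- min(nchar(rc_[[cid]]), as.integer(d0) + nchar(fs) + 250L)
        if (w_to - w_from + 1L < frag_len * min_coverage / 2) next
        al <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(fs),
          Biostrings::DNAString(substr(rc_[[cid]], w_from, w_to)),
          type = "local", substitutionMatrix = sub_mat,
          gapOpening = 5, gapExtension = 2)
        idn <- Biostrings::nmatch(al) / aln_ncol(al)
        cov <- (Biostrings::nmatch(al) + Biostrings::nmismatch(al)) / nchar(fs)
        if (is.null(best) || Biostrings::score(al) > best$score)
          best <- list(score = Biostrings::score(al), identity = idn,
                       coverage = cov)
      }
    }
    best
  }
  ids <- numeric(0)
  for (f in frags) {
    b <- place_and_align(f)
    if (!is.null(b) && b$identity >= min_identity && b$coverage >= min_coverage)
      ids <- c(ids, b$identity)
  }
  undef <- length(ids) == 0L
  if (undef) warning("no fragment passed the retention filter; ANI undefined")
  structure(list(ani_percent = if (undef) NA_real_ else 100 * mean(ids),
                 n_fragments_total = length(frags),
                 n_fragments_aligned = length(ids),
                 aligned_fraction = length(ids) / length(frags),
                 undefined = undef), class = "AniResult")
}

#' Symmetric ANI (mean of both directions)
#'
#' @param a,b [GenomeRecord]s.
#' @param ... Passed to [ani()].
#' @return Mean of `ani(a, b)` and `ani(b, a)` in percent.
#' @export
ani_symmetric <- function(a, b, ...) {
  mean(c(ani(a, b, ...)$ani_percent, ani(b, a, ...)$ani_percent))
}

tetra_z <- function(contigs) {
  x <- Biostrings::DNAStringSet(contigs)
  x <- c(x, Biostrings::reverseComplement(x))  # strand-symmetric counting
  n2 <- colSums(Biostrings::oligonucleotideFrequency(x, 2L))
  n3 <- colSums(Biostrings::oligonucleotideFrequency(x, 3L))
  n4 <- colSums(Biostrings::oligonucleotideFrequency(x, 4L))
  w <- names(n4)
  e <- n3[substr(w, 1L, 3L)] * n3[substr(w, 2L, 4L)] / n2[substr(w, 2L, 3L)]
  z <- ifelse(is.finite(e) & e > 0, (n4 - e) / sqrt(e), 0)
  if (any(!is.finite(e) | e == 0))
    warning("zero trinucleotide count(s); affected z-scores set to 0")
  setNames(as.numeric(z), w)
}

#' Tetranucleotide z-score correlation (TETRA)
#'
#' For each genome, all overlapping 4-mers are counted on the sequence plus
#' its reverse complement; the expected count of each word n1n2n3n4 is
#' N(n1n2n3) N(n2n3n4) / N(n2n3) under the maximal-order Markov model, and
#' z = (obs - exp) / sqrt(exp) (Poisson variance approximation). The
#' statistic is the Pearson correlation of the two 256-long z vectors.
#'
#' @param a,b [GenomeRecord]s (or named character vectors of contigs).
#' @param min_len Warn below this total genome length (signature unstable).
#' @return List of class `TetraResult`: `pearson_r`, `z_a`, `z_b`.
#' @export
tetra <- function(a, b, min_len = 50000L) {
  ca <- if (inherits(a, "GenomeRecord")) a$contigs else a
  cb <- if (inherits(b, "GenomeRecord")) b$contigs else b
  if (sum(nchar(ca)) < min_len || sum(nchar(cb)) < min_len)
    warning("genome below ", min_len, " bp; TETRA signature may be unstable")
  za <- tetra_z(ca); zb <- tetra_z(cb)
  structure(list(pearson_r = stats::cor(za, zb), z_a = za, z_b = zb),
            class = "TetraResult")
}

#' Species-boundary report from pairwise ANI values
#'
#' @param ani_table Data frame with columns `a`, `b`, `ani` (percent).
#' @param thresholds ANI species thresholds to apply (percent).
#' @return List with `pairs` (verdict per pair per threshold) and `summary`
#'   (min/mean/max ANI).
#' @export
species_boundary_report <- function(ani_table, thresholds = c(94, 95)) {
  stopifnot(nrow(ani_table) >= 1L)
  out <- ani_table
  for (t in thresholds)
    out[[sprintf("same_species_at_%g", t)]] <- out$ani >= t
  list(pairs = out,
       summary = c(min = min(out$ani), mean = mean(out$ani), max = max(out$ani)))
}
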