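#' Detection parameters for CRISPR array finding
#'
#' Defaults follow the canonical ranges for CRISPR elements: direct repeats
#' 24-48 nt, spacers 26-72 nt, and a locus is only accepted with at least
#' three repeat units.
#'
#' @param min_repeat_len,max_repeat_len Direct-repeat length bounds (nt).
#' @param min_spacer_len,max_spacer_len Spacer length bounds (nt).
#' @param min_units Minimum number of repeat units for a positive locus.
#' @param max_repeat_mismatches Maximum substitutions a repeat instance may
#'   carry relative to the array consensus.
#' @param seed_k k-mer length used to seed candidate repeat pairs.
#' @return A list of class `DetectionParams`.
#' @export
detection_params <- function(min_repeat_len = 24L, max_repeat_len = 48L,
                             min_spacer_len = 26L, max_spacer_len = 72L,
                             min_units = 3L, max_repeat_mismatches = 2L,
                             seed_k = 8L) {
  stopifnot(min_repeat_len <= max_repeat_len,
            min_spacer_len <= max_spacer_len,
            min_units >= 2L, seed_k >= 4L)
  structure(list(min_repeat_len = as.integer(min_repeat_len),
                 max_repeat_len = as.integer(max_repeat_len),
                 min_spacer_len = as.integer(min_spacer_len),
                 max_spacer_len = as.integer(max_spacer_len),
                 min_units = as.integer(min_units),
                 max_repeat_mismatches = as.integer(max_repeat_mismatches),
                 seed_k = as.integer(seed_k)),
            class = "DetectionParams")
}

# integer encoding of all k-mers of a sequence, base 5 (A,C,G,T,N -> 0..4).
# k-mers containing N get NA; id vector is positional (1-based k-mer start).
encode_kmers <- function(seq, k) {
  v <- utf8ToInt(chartr("ACGTN", "01234", seq)) - 48L
  L <- length(v)
  if (L < k) return(integer(0))
  n <- L - k + 1L
  ids <- numeric(n)
  hasN <- logical(n)
  for (i in 0L:(k - 1L)) {
    d <- v[(1L + i):(n + i)]
    ids <- ids * 5 + d
    hasN <- hasN | d == 4L
  }
  ids[hasN] <- NA_real_
  ids
}

# seeds with fewer than 3 distinct bases are low-complexity and discarded
kmer_complex_enough <- function(kmer) {
  vapply(kmer, function(s) length(unique(strsplit(s, "")[[1]])) >= 3L, logical(1))
}

#' Find candidate repeat seed pairs
#'
#' Returns pairs of exact k-mer matches whose separation is compatible with
#' two adjacent repeat units flanking one spacer. Low-complexity k-mers
#' (fewer than three distinct bases) and k-mers containing N are suppressed.
#'
#' @param sequence Nucleotide string.
#' @param params A [detection_params()] object.
#' @return Data frame with 1-based k-mer start positions `pos1`, `pos2` and
#'   the seed length `k`.
#' @export
find_candidate_seeds <- function(sequence, params = detection_params()) {
  k <- params$seed_k
  lo <- params$min_repeat_len + params$min_spacer_len
  hi <- params$max_repeat_len + params$max_spacer_len
  ids <- encode_kmers(sequence, k)
  n <- length(ids)
  out <- vector("list", hi - lo + 1L)
  for (d in lo:hi) {
    if (n <= d) break
    i <- which(!is.na(ids[1:(n - d)]) & ids[1:(n - d)] == ids[(1L + d):n])
    if (length(i)) out[[d - lo + 1L]] <- data.frame(pos1 = i, pos2 = i + d)
  }
  seeds <- do.call(rbind, out)
  if (is.null(seeds))
    return(data.frame(pos1 = integer(), pos2 = integer(), k = integer()))
  kmers <- substring(sequence, seeds$pos1, seeds$pos1 + k - 1L)
  seeds <- seeds[kmer_complex_enough(kmers), , drop = FALSE]
  seeds$k <- rep(k, nrow(seeds))
  seeds[order(seeds$pos1, seeds$pos2), , drop = FALSE]
}

# anchors: 1-based start positions of the seed k-mer, one per putative unit.
# Extend the unit boundaries outwards column by column. A column is accepted
# while at least m - tol units carry the majority base (tol = 1 when m >= 5,
# else 0), no unit accumulates more than max_mm off-consensus columns, and
# the total unit length stays within max_repeat_len.
extend_anchor_block <- function(chars, anchors, k, params) {
  m <- length(anchors)
  tol <- if (m >= 5L) 1L else 0L
  max_mm <- params$max_repeat_mismatches
  L <- length(chars)
  mm <- integer(m)
  step <- function(offsets) {  # offsets: candidate column per unit
    if (any(offsets < 1L | offsets > L)) return(NULL)
    cc <- chars[offsets]
    if (any(cc == "N")) return(NULL)
    tab <- sort(table(cc), decreasing = TRUE)
    if (m - tab[[1]] > tol) return(NULL)
    bad <- cc != names(tab)[1]
    if (any(mm[bad] + 1L > max_mm)) return(NULL)
    bad
  }
  left <- 0L
  while (k + left < params$max_repeat_len) {
    bad <- step(anchors - left - 1L)
    if (is.null(bad)) break
    mm[bad] <- mm[bad] + 1L
    left <- left + 1L
  }
  right <- 0L
  while (k + left + right < params$max_repeat_len) {
    bad <- step(anchors + k + right)
    if (is.null(bad)) break
    mm[bad] <- mm[bad] + 1L
    right <- right + 1L
  }
  list(starts = anchors - left, len = k + left + right)
}

majority_consensus <- function(unit_seqs) {
  mat <- do.call(rbind, strsplit(unit_seqs, ""))
  paste(apply(mat, 2L, function(col) {
    tab <- table(col)
    names(tab)[order(-tab, names(tab))][1]  # ties -> lexicographic
  }), collapse = "")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

new_crispr_array <- function(contig_id, starts, len, sequence, array_id = NA_character_) {
  ends <- starts + len  # 0-based half-open after the -1 below
  repeats <- data.frame(start = starts - 1L, end = starts + len - 1L,
                        seq = substring(sequence, starts, starts + len - 1L),
                        stringsAsFactors = FALSE)
  m <- nrow(repeats)
  spacers <- if (m > 1L)
    data.frame(start = repeats$end[-m], end = repeats$start[-1L],
               seq = substring(sequence, repeats$end[-m] + 1L, repeats$start[-1L]),
               stringsAsFactors = FALSE)
  else
    data.frame(start = integer(), end = integer(), seq = character())
  cons <- majority_consensus(repeats$seq)
  structure(list(array_id = array_id, contig_id = contig_id,
                 start = repeats$start[1L], end = repeats$end[m],
                 orientation = "unknown",
                 consensus_dr = cons, consensus_genomic = cons,
                 repeats = repeats, spacers = spacers),
            class = "CrisprArray")
}

#' @export
print.CrisprArray <- function(x, ...) {
  cat(sprintf("CrisprArray %s %s:%d-%d (%s) %d units, consensus %s\n",
              x$array_id, x$contig_id, x$start, x$end, x$orientation,
              nrow(x$repeats), x$consensus_dr))
  invisible(x)
}

# build candidate arrays from one seed k-mer: chain all occurrences of the
# exact k-mer whose successive gaps fit repeat+spacer bounds, fix unit
# boundaries by multi-unit extension, then split at out-of-bounds spacers and
# trim terminal units that violate the consensus mismatch tolerance.
build_arrays_from_kmer <- function(sequence, chars, occs, k, params, contig_id) {
  lo <- params$min_repeat_len + params$min_spacer_len
  hi <- params$max_repeat_len + params$max_spacer_len
  occs <- sort(occs)
  keep <- occs[1L]
  for (p in occs[-1L]) if (p - keep[length(keep)] >= lo) keep <- c(keep, p)
  occs <- keep
  runs <- split(occs, cumsum(c(0L, diff(occs) > hi)) )
  out <- list()
  for (anchors in runs) {
    if (length(anchors) < params$min_units) next
    ext <- extend_anchor_block(chars, anchors, k, params)
    if (ext$len < params$min_repeat_len || ext$len > params$max_repeat_len) next
    starts <- ext$starts
    gaps <- diff(starts) - ext$len          # spacer lengths
    ok <- gaps >= params$min_spacer_len & gaps <= params$max_spacer_len
    grp <- cumsum(c(0L, !ok))
    for (sub in split(starts, grp)) {
      if (length(sub) < params$min_units) next
      arr <- new_crispr_array(contig_id, sub, ext$len, sequence)
      arr <- trim_nonconforming(arr, sequence, params)
      if (!is.null(arr)) out[[length(out) + 1L]] <- arr
    }
  }
  out
}

# drop terminal units further than max_mm from the consensus; interior units
# beyond tolerance invalidate the candidate
trim_nonconforming <- function(arr, sequence, params) {
  repeat {
    mm <- vapply(arr$repeats$seq, hamming, integer(1), b = arr$consensus_genomic)
    m <- length(mm)
    if (all(mm <= params$max_repeat_mismatches)) return(arr)
    if (mm[1L] > params$max_repeat_mismatches) {
      starts <- arr$repeats$start[-1L] + 1L
    } else if (mm[m] > params$max_repeat_mismatches) {
      starts <- arr$repeats$start[-m] + 1L
    } else return(NULL)
    if (length(starts) < params$min_units) return(NULL)
    arr <- new_crispr_array(arr$contig_id, starts,
                            nchar(arr$consensus_genomic), sequence)
  }
}

#' Extend a seed pair into a CRISPR array
#'
#' Chains every occurrence of the seed k-mer that is spaced like adjacent
#' repeat units, determines the common repeat extent by multi-unit boundary
#' voting, and returns the array containing the seed, or `NULL` when fewer
#' than `min_units` conforming units remain.
#'
#' @param sequence Nucleotide string.
#' @param seed List or one-row data frame with `pos1`, `pos2` (1-based k-mer
#'   starts) and `k`.
#' @param params A [detection_params()] object.
#' @param contig_id Contig name recorded in the result.
#' @return A `CrisprArray` or `NULL`.
#' @export
extend_and_build_array <- function(sequence, seed, params = detection_params(),
                                   contig_id = "contig") {
  k <- as.integer(seed$k)
  ids <- encode_kmers(sequence, k)
  kid <- ids[seed$pos1]
  if (is.na(kid) || is.na(ids[seed$pos2]) || ids[seed$pos2] != kid) return(NULL)
  occs <- which(!is.na(ids) & ids == kid)
  chars <- strsplit(sequence, "")[[1]]
  arrs <- build_arrays_from_kmer(sequence, chars, occs, k, params, contig_id)
  for (a in arrs)
    if (a$start < seed$pos1 && a$end >= seed$pos1) return(assign_orientation(a))
  if (length(arrs)) return(assign_orientation(arrs[[1L]])) else NULL
}

#' Detect CRISPR arrays in a genome
#'
#' k-mer seeded detection: candidate seed pairs are chained into repeat
#' ladders, unit boundaries fixed by column voting across units, and
#' overlapping candidates resolved deterministically (most units, then
#' longest, then leftmost). Arrays are returned sorted by contig then start,
#' with orientation assigned from the conserved repeat 3' terminus.
#'
#' @param genome A [GenomeRecord].
#' @param params A [detection_params()] object.
#' @return List of `CrisprArray` objects.
#' @export
detect_arrays <- function(genome, params = detection_params()) {
  stopifnot(inherits(genome, "GenomeRecord"))
  cands <- list()
  for (cid in names(genome$contigs)) {
    seq <- genome$contigs[[cid]]
    if (nchar(seq) < 2L * params$min_repeat_len + params$min_spacer_len) next
    seeds <- find_candidate_seeds(seq, params)
    if (nrow(seeds) == 0L) next
    ids <- encode_kmers(seq, params$seed_k)
    chars <- strsplit(seq, "")[[1]]
    done_kid <- numeric(0)
    covered <- integer(0)  # starts of accepted candidate intervals (rough skip)
    for (i in seq_len(nrow(seeds))) {
      kid <- ids[seeds$pos1[i]]
      if (kid %in% done_kid) next
      done_kid <- c(done_kid, kid)
      if (length(cands)) {
        inside <- vapply(cands, function(a)
          a$contig_id == cid && seeds$pos1[i] > a$start && seeds$pos1[i] <= a$end,
          logical(1))
        if (any(inside)) next
      }
      occs <- which(!is.na(ids) & ids == kid)
      cands <- c(cands, build_arrays_from_kmer(seq, chars, occs, params$seed_k,
                                               params, cid))
    }
  }
  if (!length(cands)) return(list())
  # overlap resolution: units desc, length desc, leftmost
  units <- vapply(cands, function(a) nrow(a$repeats), integer(1))
  lens <- vapply(cands, function(a) a$end - a$start, integer(1))
  starts <- vapply(cands, function(a) a$start, integer(1))
  contigs <- vapply(cands, function(a) a$contig_id, character(1))
  ord <- order(-units, -lens, starts)
  kept <- list()
  for (i in ord) {
    a <- cands[[i]]
    clash <- any(vapply(kept, function(b)
      b$contig_id == a$contig_id && a$start < b$end && b$start < a$end,
      logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- a
  }
  kept <- lapply(kept, assign_orientation)
  ord2 <- order(vapply(kept, `[[`, character(1), "contig_id"),
                vapply(kept, `[[`, integer(1), "start"))
  kept <- kept[ord2]
  for (i in seq_along(kept)) kept[[i]]$array_id <- sprintf("array_%03d", i)
  kept
}

#' Assign array orientation from the repeat terminal motif
#'
#' The repeat families of this species carry a conserved GAAAC 3' terminus
#' (TACAC for the DR7-like family). The array is oriented so that the
#' consensus ends in one of these motifs when read forward; the reported
#' consensus and oriented spacer sequences are flipped accordingly.
#'
#' @param array A `CrisprArray`.
#' @param motifs Character vector of accepted 3'-terminal motifs.
#' @return The array with `orientation` set to `"+"`, `"-"` or `"unknown"`,
#'   `consensus_dr` on the oriented strand, and a `seq_oriented` column on
#'   the spacer table.
#' @export
assign_orientation <- function(array, motifs = c("GAAAC", "TACAC")) {
  ends_in <- function(s) any(endsWith(s, motifs))
  fwd <- array$consensus_genomic
  rev <- revcomp(fwd)
  if (ends_in(fwd)) {
    array$orientation <- "+"
    array$consensus_dr <- fwd
    array$spacers$seq_oriented <- array$spacers$seq
  } else if (ends_in(rev)) {
    array$orientation <- "-"
    array$consensus_dr <- rev
    array$spacers$seq_oriented <- revcomp(array$spacers$seq)
  } else {
    array$orientation <- "unknown"
    array$consensus_dr <- fwd
    array$spacers$seq_oriented <- array$spacers$seq
  }
  array
}

#' Merge nearby arrays sharing a repeat consensus
#'
#' Draft assemblies can interrupt one biological array into several reported
#' loci. This report groups detected arrays on the same contig whose
#' consensus repeats match within the clustering tolerance and whose
#' intervals lie within `max_gap` of each other; no merging is applied to the
#' primary output.
#'
#' @param arrays List of `CrisprArray` objects.
#' @param max_gap Maximum gap (bp) between loci to report them as one group.
#' @return Data frame with columns `array_id`, `group`.
#' @export
merge_adjacent_report <- function(arrays, max_gap = 5000L) {
  n <- length(arrays)
  if (n == 0L)
    return(data.frame(array_id = character(), group = integer()))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    a <- arrays[[i]]; b <- arrays[[j]]
    if (a$contig_id != b$contig_id) next
    gap <- max(a$start, b$start) - min(a$end, b$end)
    if (gap > max_gap) next
    ca <- canonicalize_repeat(a$consensus_dr)$canonical_seq
    cb <- canonicalize_repeat(b$consensus_dr)$canonical_seq
    if (repeats_compatible(ca, cb)) parent[find(i)] <- find(j)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  data.frame(array_id = vapply(arrays, `[[`, character(1), "array_id"),
             group = match(roots, unique(roots)))
}
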