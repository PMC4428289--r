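#' Canonicalize a direct repeat across strands
#'
#' Direct repeats are reported by detectors on either strand; the same family
#' can surface as a sequence and its reverse complement. The canonical
#' orientation is the one ending in the conserved GAAAC 3' terminus if
#' exactly one orientation does; failing that, the orientation ending in
#' TACAC (the DR7-like signature); failing that, the lexicographically
#' smaller orientation.
#'
#' @param seq Nucleotide string.
#' @return List with `canonical_seq` and logical `flipped` (whether the input
#'   was reverse-complemented).
#' @export
canonicalize_repeat <- function(seq) {
  fwd <- toupper(seq)
  rev <- revcomp(fwd)
  pick <- if (endsWith(fwd, "GAAAC") && !endsWith(rev, "GAAAC")) fwd
          else if (endsWith(rev, "GAAAC") && !endsWith(fwd, "GAAAC")) rev
          else if (endsWith(fwd, "TACAC")) fwd
          else if (endsWith(rev, "TACAC")) rev
          else if (fwd <= rev) fwd else rev
  list(canonical_seq = pick, flipped = !identical(pick, fwd) && fwd != rev)
}

# end-gap-free comparison of two canonical repeats: TRUE when the shorter
# aligns within the longer at <= max_sub substitutions with <= max_trunc nt
# of terminal truncation
repeats_compatible <- function(a, b, max_sub = 2L, max_trunc = 2L) {
  !is.null(best_endfree_offset(a, b, max_sub, max_trunc))
}

best_endfree_offset <- function(a, b, max_sub = 2L, max_trunc = 2L) {
  if (nchar(a) < nchar(b)) { tmp <- a; a <- b; b <- tmp }
  d <- nchar(a) - nchar(b)
  if (d > max_trunc) return(NULL)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- NULL
  for (off in 0:d) {
    mm <- which(ca[(off + 1):(off + length(cb))] != cb)
    if (length(mm) <= max_sub && (is.null(best) || length(mm) < best$n)) {
      best <- list(offset = off, n = length(mm), positions_long = mm + off)
    }
  }
  best
}

# canonical sequences of the seven repeat families of M. aeruginosa,
# anchored so that family labels are stable when these exact strings occur
ma_dr_canonical <- c(
  DR1 = "GTTCCAATTAATCTTAAACCCTATTAGGGATTGAAAC",
  DR2 = "CTTGCTTCCAATTCGTGAAGCGTATGAATGGAAAC",
  DR3 = "CTCTCTACTCGCTAGAGAAATTAATTGAATGGAAAC",
  DR4 = "CCTTACCTATTAGGTCAAATAGGATTAGTTGGAAAC",
  DR5 = "CTTTTAACTTCTTAGCAAGTTTAATTAATGGAAAC",
  DR6 = "CTTTCATCTCTTACTCCCCGCAAGGGGACGGAAAC",
  DR7 = "GTGATCAACGCCTTACGGCATCAAAGGTTAGTACAC")

#' Cluster direct repeats into families
#'
#' Single-linkage clustering of strand-canonicalized repeat sequences under
#' an edit tolerance of at most `max_sub` substitutions after end-gap-free
#' alignment allowing at most `max_trunc` nt of terminal truncation.
#' Single linkage merges single-SNP variants transitively, which is how
#' near-identical repeat variants are treated as one repeat type.
#'
#' Families whose members include one of the seven known M. aeruginosa
#' canonical repeats are labelled DR1-DR7 accordingly; remaining families get
#' fresh labels in descending member count (ties by lexicographic canonical).
#'
#' @param seqs Character vector of repeat sequences (any strand).
#' @param max_sub,max_trunc Tolerances, see above.
#' @return List of `DRFamily` objects: `family_id`, `canonical_seq`,
#'   `members` data frame (`member_seq`, `strand_flag`, `mismatch_positions`,
#'   `truncation_nt`).
#' @export
cluster_repeats <- function(seqs, max_sub = 2L, max_trunc = 2L) {
  stopifnot(length(seqs) >= 1L)
  canon <- lapply(seqs, canonicalize_repeat)
  cs <- vapply(canon, `[[`, character(1), "canonical_seq")
  n <- length(cs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    if (repeats_compatible(cs[i], cs[j], max_sub, max_trunc))
      parent[find(i)] <- find(j)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  # representative: the known anchored canonical when a member matches one,
  # else the most common member canonical (ties lexicographic)
  reps <- vapply(groups, function(idx) {
    known <- ma_dr_canonical[ma_dr_canonical %in% cs[idx]]
    if (length(known)) return(known[[1L]])
    tab <- table(cs[idx])
    names(tab)[order(-tab, names(tab))][1]
  }, character(1))
  labels <- rep(NA_character_, length(groups))
  for (k in seq_along(ma_dr_canonical)) {
    hit <- which(reps == ma_dr_canonical[[k]])
    if (length(hit) == 1L) labels[hit] <- names(ma_dr_canonical)[k]
  }
  free <- which(is.na(labels))
  if (length(free)) {
    sizes <- lengths(groups)
    ord <- free[order(-sizes[free], reps[free])]
    used <- as.integer(sub("^DR", "", labels[!is.na(labels)]))
    nxt <- setdiff(seq_len(length(groups) + length(used)), used)
    labels[ord] <- paste0("DR", nxt[seq_along(ord)])
  }
  fams <- lapply(seq_along(groups), function(gi) {
    idx <- groups[[gi]]
    rep_seq <- reps[[gi]]
    mem <- lapply(idx, function(i) {
      al <- best_endfree_offset(rep_seq, cs[i], max_sub = nchar(rep_seq),
                                max_trunc = max(max_trunc,
                                                abs(nchar(rep_seq) - nchar(cs[i]))))
      data.frame(member_seq = seqs[i],
                 strand_flag = ifelse(canon[[i]]$flipped, "-", "+"),
                 mismatch_positions = paste(al$positions_long, collapse = ","),
                 truncation_nt = abs(nchar(rep_seq) - nchar(cs[i])),
                 stringsAsFactors = FALSE)
    })
    structure(list(family_id = labels[gi], canonical_seq = rep_seq,
                   members = do.call(rbind, mem)),
              class = "DRFamily")
  })
  fams[order(as.integer(sub("^DR", "", labels)))]
}

#' @export
print.DRFamily <- function(x, ...) {
  cat(sprintf("DRFamily %s (%d nt, %d member(s)): %s\n", x$family_id,
              nchar(x$canonical_seq), nrow(x$members), x$canonical_seq))
  invisible(x)
}

#' 3'-terminal motif of a repeat family
#'
#' @param family A `DRFamily` (or a bare canonical sequence).
#' @return The last 5 nt of the canonical sequence.
#' @export
terminal_motif <- function(family) {
  s <- if (inherits(family, "DRFamily")) family$canonical_seq else family
  substr(s, nchar(s) - 4L, nchar(s))
}

rna_pairs_ok <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

#' Fold a repeat by base-pair maximization
#'
#' Maximum-cardinality nested pairing (Nussinov recursion) on the transcribed
#' (T to U) sequence with a minimum hairpin loop of 3 nt and Watson-Crick
#' plus GU wobble pairs. This is a combinatorial stand-in for thermodynamic
#' folding: it is used to assert stem-loop existence, not to predict minimum
#' free-energy structures.
#'
#' @param seq Nucleotide string (DNA or RNA), length at most 100.
#' @param min_loop Minimum unpaired nucleotides enclosed by a pair.
#' @return List of class `FoldResult`: `pairing` (two-column 0-based index
#'   matrix), `n_pairs`, `max_stem_len`, `loop_len` (of the longest stem's
#'   innermost pair), `paired_fraction`.
#' @export
fold_repeat <- function(seq, min_loop = 3L) {
  s <- chartr("Tt", "Uu", toupper(seq))
  x <- strsplit(s, "")[[1]]
  n <- length(x)
  stopifnot(n <= 100L)
  if (n < min_loop + 2L)
    return(structure(list(pairing = matrix(integer(0), ncol = 2),
                          n_pairs = 0L, max_stem_len = 0L, loop_len = NA_integer_,
                          paired_fraction = 0), class = "FoldResult"))
  N <- matrix(0L, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in 1:(n - span)) {
      j <- i + span
      best <- N[i, j - 1L]
      for (k in i:(j - min_loop - 1L)) {
        if (rna_pairs_ok(x[k], x[j])) {
          v <- (if (k > i) N[i, k - 1L] else 0L) + 1L +
               (if (k + 1L <= j - 1L) N[k + 1L, j - 1L] else 0L)
          if (v > best) best <- v
        }
      }
      N[i, j] <- best
    }
  }
  traceback_pairs <- function(prefer_stack) {
    pairs <- matrix(integer(0), ncol = 2)
    stack <- list(c(1L, n))
    while (length(stack)) {
      ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      i <- ij[1]; j <- ij[2]
      if (i >= j || j - i <= min_loop || N[i, j] == 0L) next
      cand <- integer(0)
      for (k in i:(j - min_loop - 1L)) {
        if (rna_pairs_ok(x[k], x[j])) {
          v <- (if (k > i) N[i, k - 1L] else 0L) + 1L +
               (if (k + 1L <= j - 1L) N[k + 1L, j - 1L] else 0L)
          if (v == N[i, j]) cand <- c(cand, k)
        }
      }
      if (!length(cand)) { stack[[length(stack) + 1L]] <- c(i, j - 1L); next }
      k <- if (prefer_stack) {
        # among co-optimal partners, favour one whose inner neighbours can
        # also pair, so helices are reported as contiguous stems
        st <- cand[vapply(cand, function(k) k + 1L < j - 1L &&
                            rna_pairs_ok(x[k + 1L], x[j - 1L]), logical(1))]
        if (length(st)) st[1L] else cand[1L]
      } else cand[length(cand)]
      pairs <- rbind(pairs, c(k, j))
      if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
      if (k + 1L <= j - 1L) stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
    }
    pairs
  }
  stem_of <- function(pairs) {
    max_stem <- 0L; loop_len <- NA_integer_
    if (nrow(pairs)) {
      key <- paste(pairs[, 1], pairs[, 2])
      for (r in seq_len(nrow(pairs))) {
        # only count stems from their outermost pair
        if (paste(pairs[r, 1] - 1L, pairs[r, 2] + 1L) %in% key) next
        len <- 1L; i <- pairs[r, 1]; j <- pairs[r, 2]
        while (paste(i + len, j - len) %in% key) len <- len + 1L
        if (len > max_stem) {
          max_stem <- len
          loop_len <- (j - len + 1L) - (i + len - 1L) - 1L
        }
      }
    }
    list(max_stem = max_stem, loop_len = loop_len)
  }
  # the maximum-pairing structure is not unique; report the co-optimal
  # traceback with the longer contiguous stem
  p1 <- traceback_pairs(FALSE); p2 <- traceback_pairs(TRUE)
  s1 <- stem_of(p1); s2 <- stem_of(p2)
  if (s2$max_stem > s1$max_stem) { pairs <- p2; st <- s2 } else { pairs <- p1; st <- s1 }
  structure(list(pairing = pairs - 1L, n_pairs = nrow(pairs),
                 max_stem_len = st$max_stem, loop_len = st$loop_len,
                 paired_fraction = 2 * nrow(pairs) / n),
            class = "FoldResult")
}
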