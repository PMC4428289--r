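#' Dereplicate spacers across loci
#'
#' Spacer sequences are compared on the oriented strand (the strand the
#' array's orientation call designates); exact duplicates collapse to one
#' unique spacer while the mapping back to every occurrence is retained.
#'
#' @param arrays List of `CrisprArray` objects (or a data frame with columns
#'   `locus`, `seq`).
#' @return List of class `SpacerSet`: `occurrences` data frame (`spacer_id`,
#'   `locus`, `index_in_locus`, `seq`), `unique_spacers` named character
#'   vector (names are spacer ids `sp0001`...).
#' @export
dereplicate_spacers <- function(arrays) {
  occ <- if (is.data.frame(arrays)) {
    data.frame(locus = arrays$locus, index_in_locus = stats::ave(
      seq_len(nrow(arrays)), arrays$locus, FUN = seq_along),
      seq = arrays$seq, stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(arrays, function(a) {
      if (nrow(a$spacers) == 0L) return(NULL)
      sq <- if (!is.null(a$spacers$seq_oriented)) a$spacers$seq_oriented else a$spacers$seq
      data.frame(locus = a$array_id, index_in_locus = seq_len(nrow(a$spacers)),
                 seq = sq, stringsAsFactors = FALSE)
    }))
  }
  if (is.null(occ) || nrow(occ) == 0L)
    return(structure(list(occurrences = data.frame(), unique_spacers = character(0)),
                     class = "SpacerSet"))
  uniq <- unique(occ$seq)
  ids <- sprintf("sp%04d", seq_along(uniq))
  occ$spacer_id <- ids[match(occ$seq, uniq)]
  structure(list(occurrences = occ[, c("spacer_id", "locus", "index_in_locus", "seq")],
                 unique_spacers = setNames(uniq, ids)),
            class = "SpacerSet")
}

#' @export
print.SpacerSet <- function(x, ...) {
  cat("SpacerSet:", nrow(x$occurrences), "spacer occurrence(s),",
      length(x$unique_spacers), "unique\n")
  invisible(x)
}

# best ungapped local alignment on one diagonal: maximum-sum segment of the
# +1/-2 match profile; equal scores resolve to the maximally extended
# (longest) segment, then the leftmost. Exact enumeration over segment
# bounds (overlaps are at most spacer length, so this stays cheap); optimal
# segments always start and end on a match.
best_segment <- function(match_vec, match_score = 1, mismatch_score = -2) {
  sc <- ifelse(match_vec, match_score, mismatch_score)
  cs <- c(0, cumsum(sc))
  idx <- which(match_vec)
  best <- list(score = -Inf, from = 0L, to = -1L)
  for (a in idx) for (b in idx[idx >= a]) {
    v <- cs[b + 1L] - cs[a]
    if (v > best$score ||
        (v == best$score && b - a > best$to - best$from))
      best <- list(score = v, from = a, to = b)
  }
  best
}

search_one_strand <- function(spacer, target, strand, min_score, min_len,
                              seed_k, exhaustive = FALSE, sid = NULL,
                              tid = NULL) {
  ls <- nchar(spacer); lt <- nchar(target)
  sv <- strsplit(spacer, "")[[1]]; tv <- strsplit(target, "")[[1]]
  diags <- if (exhaustive) {
    seq(-(ls - 1L), lt - 1L)
  } else {
    if (ls < seed_k) return(NULL)
    if (is.null(sid)) sid <- encode_kmers(spacer, seed_k)
    if (is.null(tid)) tid <- encode_kmers(target, seed_k)
    d <- integer(0)
    keys <- unique(sid[!is.na(sid)])
    for (kk in keys) {
      qs <- which(sid == kk); ts <- which(tid == kk)
      if (length(ts)) d <- c(d, as.vector(outer(ts, qs, `-`)))
    }
    unique(d)
  }
  out <- list()
  for (d in diags) {
    # spacer position i aligns to target position i + d
    i1 <- max(1L, 1L - d); i2 <- min(ls, lt - d)
    if (i2 - i1 + 1L < min_len) next
    mv <- sv[i1:i2] == tv[(i1:i2) + d] & sv[i1:i2] != "N" & tv[(i1:i2) + d] != "N"
    seg <- best_segment(mv)
    len <- seg$to - seg$from + 1L
    if (seg$score >= min_score && len >= min_len) {
      qa <- i1 + seg$from - 1L; qb <- i1 + seg$to - 1L
      ta <- qa + d; tb <- qb + d
      out[[length(out) + 1L]] <- data.frame(
        q_start = qa, q_end = qb, t_start = ta - 1L, t_end = tb,  # t 0-based half-open
        strand = strand, aligned_len = len,
        identities = sum(mv[seg$from:seg$to]), score = seg$score)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

extract_flanks <- function(target, t_start, t_end, strand, flank = 10L) {
  lt <- nchar(target)
  pad <- function(s, n, left) {
    if (nchar(s) >= n) return(s)
    ns <- strrep("N", n - nchar(s))
    if (left) paste0(ns, s) else paste0(s, ns)
  }
  up_plus <- pad(substr(target, max(1L, t_start - flank + 1L), t_start), flank, TRUE)
  dn_plus <- pad(substr(target, t_end + 1L, min(lt, t_end + flank)), flank, FALSE)
  if (strand == "+") list(up = up_plus, down = dn_plus)
  else list(up = revcomp(dn_plus), down = revcomp(up_plus))
}

#' Search spacers against a target database
#'
#' Ungapped seed-and-extend local alignment of each spacer against both
#' strands of every target record, scored +1 per match and -2 per mismatch so
#' that a raw score of 20 corresponds to a 20-bp perfect match. A hit must
#' reach `min_score` AND cover at least `min_len` aligned bp. 10-bp flanking
#' sequences on both sides (on the protospacer strand, N-padded at contig
#' edges) are recorded for PAM inference.
#'
#' @param spacer_set A `SpacerSet` (or named character vector of spacers).
#' @param target_db Named character vector of target sequences (or a
#'   `GenomeRecord`).
#' @param min_score Minimum raw alignment score.
#' @param min_len Minimum aligned length (bp).
#' @param seed_k Exact seed length; `exhaustive = TRUE` scans every diagonal
#'   instead (used by the test oracle path).
#' @param flank Flank length recorded on both sides.
#' @param exhaustive Disable seeding and scan all diagonals.
#' @return Data frame of `ProtospacerHit` rows: `spacer_id`, `target_id`,
#'   `t_start`, `t_end` (0-based half-open, plus strand coordinates),
#'   `strand`, `aligned_len`, `identities`, `score`, `flank_up`,
#'   `flank_down`; sorted per spacer by score descending.
#' @export
search_protospacers <- function(spacer_set, target_db, min_score = 20,
                                min_len = 25L, seed_k = 11L, flank = 10L,
                                exhaustive = FALSE) {
  spacers <- if (inherits(spacer_set, "SpacerSet")) spacer_set$unique_spacers
             else spacer_set
  if (is.null(names(spacers))) names(spacers) <- sprintf("sp%04d", seq_along(spacers))
  targets <- if (inherits(target_db, "GenomeRecord")) target_db$contigs else target_db
  short <- nchar(spacers) < min_len
  if (any(short)) {
    warning(sum(short), " spacer(s) shorter than min_len skipped")
    spacers <- spacers[!short]
  }
  # encode target k-mers once per strand, shared across all spacers
  tg_fwd <- targets
  tg_rev <- setNames(revcomp(targets), names(targets))
  kid_fwd <- kid_rev <- NULL
  if (!exhaustive) {
    kid_fwd <- lapply(tg_fwd, encode_kmers, k = seed_k)
    kid_rev <- lapply(tg_rev, encode_kmers, k = seed_k)
  }
  rows <- list()
  for (spid in names(spacers)) {
    sp <- spacers[[spid]]
    sp_kid <- if (!exhaustive) encode_kmers(sp, seed_k)
    for (tname in names(targets)) {
      tg <- tg_fwd[[tname]]
      lt <- nchar(tg)
      for (strand in c("+", "-")) {
        tg_s <- if (strand == "+") tg else tg_rev[[tname]]
        h <- search_one_strand(sp, tg_s, strand, min_score, min_len, seed_k,
                               exhaustive, sid = sp_kid,
                               tid = if (strand == "+") kid_fwd[[tname]]
                                     else kid_rev[[tname]])
        if (is.null(h)) next
        for (r in seq_len(nrow(h))) {
          # map to plus-strand target coordinates
          ts <- h$t_start[r]; te <- h$t_end[r]
          if (strand == "-") { tmp <- ts; ts <- lt - te; te <- lt - tmp }
          fl <- extract_flanks(tg, ts, te, strand, flank)
          rows[[length(rows) + 1L]] <- data.frame(
            spacer_id = spid, target_id = tname, t_start = ts, t_end = te,
            strand = strand, aligned_len = h$aligned_len[r],
            identities = h$identities[r], score = h$score[r],
            flank_up = fl$up, flank_down = fl$down, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(spacer_id = character(), target_id = character(),
                      t_start = integer(), t_end = integer(), strand = character(),
                      aligned_len = integer(), identities = integer(),
                      score = numeric(), flank_up = character(),
                      flank_down = character(), stringsAsFactors = FALSE))
  hits <- do.call(rbind, rows)
  hits[order(hits$spacer_id, -hits$score, hits$target_id, hits$t_start), ,
       drop = FALSE]
}

#' Remove hits falling inside the query genomes' own CRISPR loci
#'
#' @param hits Hit table from [search_protospacers()].
#' @param self_arrays List of `CrisprArray` objects detected in the query
#'   genomes; a hit whose target interval overlaps any array interval on a
#'   matching target id is removed.
#' @return Filtered hit table.
#' @export
filter_self_hits <- function(hits, self_arrays) {
  if (nrow(hits) == 0L || length(self_arrays) == 0L) return(hits)
  drop <- rep(FALSE, nrow(hits))
  for (a in self_arrays) {
    drop <- drop | (hits$target_id == a$contig_id &
                    hits$t_start < a$end & a$start < hits$t_end)
  }
  hits[!drop, , drop = FALSE]
}

#' Classify spacer source categories
#'
#' Each unique spacer takes the category of its best-scoring surviving hit;
#' score ties resolve phage > plasmid > bacterial_chromosome > environmental.
#' Spacers with no hit are `none`.
#'
#' @param hits Hit table from [search_protospacers()] (after self filtering).
#' @param db_category_map Named character vector mapping `target_id` to one
#'   of `phage`, `plasmid`, `bacterial_chromosome`, `environmental`.
#' @param spacer_ids All unique spacer ids under classification (so that
#'   no-hit spacers count toward `none`).
#' @return List of class `SourceClassification`: `per_spacer` (named
#'   category vector), `fractions` (over all spacer ids, summing to 1).
#' @export
classify_sources <- function(hits, db_category_map, spacer_ids) {
  prec <- c(phage = 1L, plasmid = 2L, bacterial_chromosome = 3L,
            environmental = 4L)
  cats <- setNames(rep("none", length(spacer_ids)), spacer_ids)
  if (nrow(hits)) {
    hits$category <- unname(db_category_map[hits$target_id])
    if (anyNA(hits$category)) stop("target(s) missing from db_category_map")
    hits <- hits[order(hits$spacer_id, -hits$score, prec[hits$category]), ]
    best <- hits[!duplicated(hits$spacer_id), ]
    cats[best$spacer_id] <- best$category
  }
  lev <- c(names(prec), "none")
  fr <- table(factor(cats, levels = lev)) / length(cats)
  structure(list(per_spacer = cats, fractions = as.numeric(fr),
                 categories = lev), class = "SourceClassification")
}

#' Build a PAM profile from protospacer flanks
#'
#' Per-position base counts over the 10-nt flank on the chosen side, with
#' information content IC = 2 - H (Shannon entropy in bits) per position and
#' a consensus letter wherever IC passes `ic_threshold` (dot otherwise).
#' Columns where a flank carries N (contig edge padding) exclude that flank
#' column-wise.
#'
#' @param hits Hit table with `flank_up`/`flank_down` columns.
#' @param side `"upstream"` or `"downstream"`.
#' @param flank Flank length (columns).
#' @param ic_threshold IC (bits) needed to emit a consensus letter.
#' @return List of class `PamProfile`: `side`, `counts` (4 x flank), `ic`,
#'   `consensus`, `n_hits`.
#' @export
build_pam_profile <- function(hits, side = c("upstream", "downstream"),
                              flank = 10L, ic_threshold = 0.5) {
  side <- match.arg(side)
  fl <- if (side == "upstream") hits$flank_up else hits$flank_down
  stopifnot(length(fl) >= 1L)
  mat <- do.call(rbind, strsplit(fl, ""))
  bases <- c("A", "C", "G", "T")
  counts <- apply(mat, 2L, function(col) {
    col <- col[col %in% bases]
    tabulate(match(col, bases), nbins = 4L)
  })
  rownames(counts) <- bases
  ic <- apply(counts, 2L, function(ct) {
    n <- sum(ct)
    if (n == 0L) return(0)
    p <- ct / n
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  letters <- ifelse(ic >= ic_threshold, bases[apply(counts, 2L, which.max)], ".")
  pos <- if (side == "upstream") -flank:-1 else 1:flank
  colnames(counts) <- pos
  structure(list(side = side, counts = counts, ic = setNames(ic, pos),
                 consensus = paste(letters, collapse = ""),
                 n_hits = length(fl)), class = "PamProfile")
}

#' @export
print.PamProfile <- function(x, ...) {
  cat(sprintf("PamProfile (%s, %d hits): %s\n", x$side, x$n_hits, x$consensus))
  invisible(x)
}
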