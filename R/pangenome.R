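#' Pairwise protein identity and coverage
#'
#' Local alignment under BLOSUM62 with affine gaps (open 11, extend 1).
#' Identity is identities over aligned columns; coverage of each protein is
#' the aligned span over its full length.
#'
#' @param a,b Amino-acid strings.
#' @return List with `percent_identity`, `coverage_a`, `coverage_b`, `score`.
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  list(percent_identity = 100 * Biostrings::nmatch(al) / aln_ncol(al),
       coverage_a = Biostrings::width(Biostrings::pattern(al)) / nchar(a),
       coverage_b = Biostrings::width(Biostrings::subject(al)) / nchar(b),
       score = Biostrings::score(al))
}

# alignment length in columns (gaps included)
aln_ncol <- function(al) base::nchar(as.character(al))

# amino-acid k-mer prefilter: candidate pairs must share at least one exact
# k-mer, the same screening idea BLAST word seeding uses
aa_kmer_sets <- function(seqs, k = 5L) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
}

#' Build the ortholog graph under the 50/50 rule
#'
#' For each ordered genome pair, each query protein's best hit by alignment
#' score is found; an undirected edge is kept iff the two proteins are
#' reciprocal best hits with >= `min_identity` percent identity over at least
#' `min_coverage` of the length of BOTH proteins. Candidate pairs are
#' prescreened by shared amino-acid k-mers before alignment. Best-hit ties
#' break by identity, then lexicographic protein id.
#'
#' @param proteomes Named list (genome id) of named character vectors
#'   (protein id -> amino-acid sequence).
#' @param min_identity Percent identity threshold.
#' @param min_coverage Coverage threshold applied to both proteins.
#' @param seed_k Amino-acid k-mer length of the prescreen.
#' @return List of class `OrthologGraph`: `nodes` data frame (`protein_id`,
#'   `genome_id`), `edges` data frame (`from`, `to`, `weight` = percent
#'   identity).
#' @export
build_ortholog_graph <- function(proteomes, min_identity = 50,
                                 min_coverage = 0.5, seed_k = 5L) {
  stopifnot(length(proteomes) >= 2L)
  sizes <- vapply(proteomes, length, integer(1))
  if (any(sizes == 0L)) stop("genome(s) with zero proteins: ",
                             paste(names(sizes)[sizes == 0L], collapse = ", "))
  ids <- unlist(lapply(names(proteomes), function(g)
    paste0(g, "|", names(proteomes[[g]]))), use.names = FALSE)
  if (anyDuplicated(ids)) stop("duplicate protein ids")
  nodes <- data.frame(
    protein_id = ids,
    genome_id = rep(names(proteomes), times = sizes), stringsAsFactors = FALSE)
  seqs <- setNames(unlist(proteomes, use.names = FALSE), ids)
  genome_of <- setNames(nodes$genome_id, nodes$protein_id)
  # inverted k-mer index -> candidate cross-genome pairs
  kms <- aa_kmer_sets(seqs, seed_k)
  inv <- data.frame(kmer = unlist(kms, use.names = FALSE),
                    pid = rep(names(kms), lengths(kms)),
                    stringsAsFactors = FALSE)
  inv <- inv[inv$kmer %in% inv$kmer[duplicated(inv$kmer)], , drop = FALSE]
  pair_keys <- unlist(lapply(split(inv$pid, inv$kmer), function(p) {
    p <- unique(p)
    if (length(p) < 2L) return(character(0))
    cmb <- utils::combn(sort(p), 2L)
    paste(cmb[1L, ], cmb[2L, ], sep = "\r")
  }), use.names = FALSE)
  pair_keys <- unique(as.character(pair_keys))
  pr <- if (length(pair_keys))
    do.call(rbind, strsplit(pair_keys, "\r", fixed = TRUE))
  else matrix(character(0), ncol = 2)
  cross <- pr[genome_of[pr[, 1]] != genome_of[pr[, 2]], , drop = FALSE]
  # align candidate pairs, batched per subject protein
  aln <- NULL
  if (nrow(cross)) {
    res <- vector("list", length(unique(cross[, 2])))
    i <- 0L
    for (q in unique(cross[, 2])) {
      ps <- cross[cross[, 2] == q, 1L]
      al <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(seqs[ps]), Biostrings::AAString(seqs[[q]]),
        type = "local", substitutionMatrix = "BLOSUM62",
        gapOpening = 11, gapExtension = 1)
      nm <- Biostrings::nmatch(al)
      i <- i + 1L
      res[[i]] <- data.frame(
        p = ps, q = q, score = Biostrings::score(al),
        identity = 100 * nm / aln_ncol(al),
        cov_p = Biostrings::width(Biostrings::pattern(al)) / nchar(seqs[ps]),
        cov_q = Biostrings::width(Biostrings::subject(al)) / nchar(seqs[[q]]),
        stringsAsFactors = FALSE)
    }
    aln <- do.call(rbind, res)
  }
  edges <- data.frame(from = character(), to = character(), weight = numeric(),
                      stringsAsFactors = FALSE)
  if (!is.null(aln) && nrow(aln)) {
    both <- rbind(
      data.frame(query = aln$p, hit = aln$q, score = aln$score,
                 identity = aln$identity, cov_query = aln$cov_p,
                 cov_hit = aln$cov_q, stringsAsFactors = FALSE),
      data.frame(query = aln$q, hit = aln$p, score = aln$score,
                 identity = aln$identity, cov_query = aln$cov_q,
                 cov_hit = aln$cov_p, stringsAsFactors = FALSE))
    both$target_genome <- genome_of[both$hit]
    # best hit per (query, target genome): score, then identity, then id
    ord <- order(both$query, both$target_genome, -both$score, -both$identity,
                 both$hit)
    both <- both[ord, , drop = FALSE]
    best <- both[!duplicated(both[, c("query", "target_genome")]), ,
                 drop = FALSE]
    bh <- setNames(best$hit, paste(best$query, best$target_genome))
    recip <- bh[paste(best$hit, genome_of[best$query])] == best$query
    keep <- !is.na(recip) & recip & best$identity >= min_identity &
            best$cov_query >= min_coverage & best$cov_hit >= min_coverage &
            best$query < best$hit   # one undirected edge per pair
    if (any(keep))
      edges <- data.frame(from = best$query[keep], to = best$hit[keep],
                          weight = best$identity[keep], stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "OrthologGraph")
}

#' @export
print.OrthologGraph <- function(x, ...) {
  cat("OrthologGraph:", nrow(x$nodes), "proteins,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Markov clustering of the ortholog graph
#'
#' From-scratch MCL: the weighted adjacency matrix gains self-loops (weight =
#' maximum incident edge weight, a standard regularization that stabilizes
#' convergence on small graphs), is column-normalized, then alternates
#' expansion (matrix squaring) and inflation (elementwise power and
#' renormalization) until the maximum column change drops below `tol`.
#' Clusters are read off the converged matrix as connected components of its
#' non-zero structure; singletons are allowed.
#'
#' @param graph An `OrthologGraph` (or list with `nodes`/`edges`).
#' @param inflation Inflation exponent (cluster granularity; 2 by default).
#' @param max_iter Iteration cap; non-convergence returns the current
#'   partition with a warning.
#' @param tol Convergence tolerance on the transition matrix.
#' @return List of class `GeneFamilySet`: `families` (list of protein-id
#'   vectors, largest first), `membership` (named integer vector),
#'   `presence` (family x genome 0/1 matrix), `gene_counts` (family x genome
#'   gene counts), `converged`.
#' @export
mcl_cluster <- function(graph, inflation = 2, max_iter = 100L, tol = 1e-6) {
  nodes <- graph$nodes
  n <- nrow(nodes)
  stopifnot(n >= 1L)
  M <- matrix(0, n, n, dimnames = list(nodes$protein_id, nodes$protein_id))
  if (nrow(graph$edges)) {
    fi <- match(graph$edges$from, nodes$protein_id)
    ti <- match(graph$edges$to, nodes$protein_id)
    M[cbind(fi, ti)] <- graph$edges$weight
    M[cbind(ti, fi)] <- graph$edges$weight
  }
  selfw <- apply(M, 2L, max)
  selfw[selfw == 0] <- 1
  diag(M) <- selfw
  normalize <- function(m) sweep(m, 2L, colSums(m), "/")
  M <- normalize(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- normalize((M %*% M)^inflation)
    M2[M2 < 1e-12] <- 0
    M2 <- normalize(M2)
    if (max(abs(M2 - M)) < tol) { M <- M2; converged <- TRUE; break }
    M <- M2
  }
  if (!converged) warning("MCL did not converge within max_iter")
  adj <- (M > 1e-8) | t(M > 1e-8)
  comp <- integer(n); comp[] <- 0L; cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  fams <- split(nodes$protein_id, comp)
  fams <- fams[order(-vapply(fams, length, integer(1)),
                     vapply(fams, `[[`, character(1), 1L))]
  names(fams) <- sprintf("fam%05d", seq_along(fams))
  membership <- setNames(rep(seq_along(fams), lengths(fams)), unlist(fams))
  genomes <- unique(nodes$genome_id)
  gene_counts <- matrix(0L, length(fams), length(genomes),
                        dimnames = list(names(fams), genomes))
  for (fi in seq_along(fams)) {
    g <- nodes$genome_id[match(fams[[fi]], nodes$protein_id)]
    gene_counts[fi, ] <- as.integer(table(factor(g, levels = genomes)))
  }
  structure(list(families = fams,
                 membership = membership[nodes$protein_id],
                 presence = (gene_counts > 0L) * 1L,
                 gene_counts = gene_counts,
                 converged = converged),
            class = "GeneFamilySet")
}

#' @export
print.GeneFamilySet <- function(x, ...) {
  cat("GeneFamilySet:", length(x$families), "families over",
      ncol(x$presence), "genomes\n")
  invisible(x)
}

#' Core/pan-genome rarefaction curve
#'
#' For each of `n_perm` random genome orderings and each prefix length k, the
#' core (families present in all k genomes) and pan (families present in at
#' least one) sizes are recorded; means and standard deviations per k are
#' returned. Monotonicity (pan non-decreasing, core non-increasing) holds for
#' every single ordering by construction of the prefix sets.
#'
#' @param family_set A `GeneFamilySet`.
#' @param n_perm Number of random orderings.
#' @param seed RNG seed.
#' @return List of class `PanCoreCurve`: `curve` data frame (`k`,
#'   `core_mean`, `core_sd`, `pan_mean`, `pan_sd`), `per_permutation` (list
#'   of core/pan matrices), `n_perm`, `seed`.
#' @export
pan_core_curve <- function(family_set, n_perm = 100L, seed = 1L) {
  P <- family_set$presence
  ng <- ncol(P)
  core <- matrix(0L, n_perm, ng)
  pan <- matrix(0L, n_perm, ng)
  withr::with_seed(seed, {
    for (r in seq_len(n_perm)) {
      ord <- sample(ng)
      inter <- rep(TRUE, nrow(P)); un <- rep(FALSE, nrow(P))
      for (k in seq_len(ng)) {
        v <- P[, ord[k]] > 0L
        inter <- inter & v
        un <- un | v
        core[r, k] <- sum(inter)
        pan[r, k] <- sum(un)
      }
    }
  })
  structure(list(curve = data.frame(
    k = seq_len(ng),
    core_mean = colMeans(core), core_sd = apply(core, 2L, stats::sd),
    pan_mean = colMeans(pan), pan_sd = apply(pan, 2L, stats::sd)),
    per_permutation = list(core = core, pan = pan),
    n_perm = n_perm, seed = seed), class = "PanCoreCurve")
}

#' Shared-family matrix and strain-specific gene counts
#'
#' Off-diagonal cell (i, j) is 100 x |families present in both i and j| /
#' |families present in i or j| (half-up rounded to 2 decimals). Also reports
#' the per-genome fraction of shared families over that genome's own
#' families, and strain-specific (unique) family and gene counts.
#'
#' @param family_set A `GeneFamilySet`.
#' @return List with `shared_over_union` (n x n percent matrix),
#'   `shared_over_own` (row genome's perspective), `unique_families`,
#'   `unique_genes` (named counts).
#' @export
shared_family_matrix <- function(family_set) {
  P <- family_set$presence
  ng <- ncol(P)
  stopifnot(ng >= 2L)
  round_half_up <- function(x, d) floor(x * 10^d + 0.5) / 10^d
  un <- mat_own <- matrix(NA_real_, ng, ng,
                          dimnames = list(colnames(P), colnames(P)))
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    if (i == j) next
    both <- sum(P[, i] & P[, j])
    un[i, j] <- round_half_up(100 * both / sum(P[, i] | P[, j]), 2L)
    mat_own[i, j] <- round_half_up(100 * both / sum(P[, i] > 0L), 2L)
  }
  only <- rowSums(P) == 1L
  uniq_fam <- vapply(seq_len(ng), function(i) sum(only & P[, i] > 0L), integer(1))
  uniq_gene <- vapply(seq_len(ng), function(i)
    sum(family_set$gene_counts[only & P[, i] > 0L, i]), integer(1))
  list(shared_over_union = un, shared_over_own = mat_own,
       unique_families = setNames(uniq_fam, colnames(P)),
       unique_genes = setNames(uniq_gene, colnames(P)))
}
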