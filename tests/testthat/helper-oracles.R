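# independent oracles and small utilities used across the suite

dr_canon <- c(
  DR1 = "GTTCCAATTAATCTTAAACCCTATTAGGGATTGAAAC",
  DR2 = "CTTGCTTCCAATTCGTGAAGCGTATGAATGGAAAC",
  DR3 = "CTCTCTACTCGCTAGAGAAATTAATTGAATGGAAAC",
  DR4 = "CCTTACCTATTAGGTCAAATAGGATTAGTTGGAAAC",
  DR5 = "CTTTTAACTTCTTAGCAAGTTTAATTAATGGAAAC",
  DR6 = "CTTTCATCTCTTACTCCCCGCAAGGGGACGGAAAC",
  DR7 = "GTGATCAACGCCTTACGGCATCAAAGGTTAGTACAC")

rc <- function(s) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(s)))

rand_dna <- function(n, gc = 0.42) paste(
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)), collapse = "")

random_aa_test <- function(n) paste(
  sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
  collapse = "")

mutate_protein_test <- function(s, rate) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ch <- strsplit(s, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  ch[hit] <- vapply(ch[hit], function(x) sample(setdiff(aa, x), 1L),
                    character(1))
  paste(ch, collapse = "")
}

mutate_seq <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  ch[hit] <- vapply(ch[hit], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1))
  paste(ch, collapse = "")
}

# brute-force ungapped local search oracle: every diagonal, every segment,
# +1/-2 scoring; returns best-per-diagonal segments passing both thresholds
oracle_protospacer_scan <- function(spacer, target, min_score = 20,
                                    min_len = 25L) {
  hits <- list()
  for (strand in c("+", "-")) {
    tg <- if (strand == "+") target else rc(target)
    sv <- strsplit(spacer, "")[[1]]; tv <- strsplit(tg, "")[[1]]
    ls <- length(sv); lt <- length(tv)
    for (d in seq(-(ls - 1L), lt - 1L)) {
      i1 <- max(1L, 1L - d); i2 <- min(ls, lt - d)
      if (i2 - i1 + 1L < min_len) next
      sc <- ifelse(sv[i1:i2] == tv[(i1:i2) + d], 1, -2)
      n <- length(sc)
      best <- NULL
      cs <- c(0, cumsum(sc))
      for (a in 1:n) for (b in a:n) {
        v <- cs[b + 1L] - cs[a]
        if (is.null(best) || v > best$v ||
            (v == best$v && b - a > best$b - best$a))
          best <- list(v = v, a = a, b = b)
      }
      len <- best$b - best$a + 1L
      if (best$v >= min_score && len >= min_len)
        hits[[length(hits) + 1L]] <- data.frame(
          strand = strand, score = best$v, aligned_len = len,
          t_start_local = i1 + best$a - 1L + d - 1L)
    }
  }
  if (length(hits)) do.call(rbind, hits) else NULL
}

# connected components over the pairwise repeat-tolerance graph, written
# independently of the package clustering code
oracle_repeat_components <- function(seqs, max_sub = 2L, max_trunc = 2L) {
  canon <- vapply(seqs, function(s) {
    f <- s; r <- rc(s)
    if (endsWith(f, "GAAAC") && !endsWith(r, "GAAAC")) f
    else if (endsWith(r, "GAAAC") && !endsWith(f, "GAAAC")) r
    else if (endsWith(f, "TACAC")) f
    else if (endsWith(r, "TACAC")) r
    else min(f, r)
  }, character(1))
  compat <- function(a, b) {
    if (nchar(a) < nchar(b)) { t <- a; a <- b; b <- t }
    d <- nchar(a) - nchar(b)
    if (d > max_trunc) return(FALSE)
    for (off in 0:d) {
      mm <- sum(strsplit(substr(a, off + 1L, off + nchar(b)), "")[[1]] !=
                strsplit(b, "")[[1]])
      if (mm <= max_sub) return(TRUE)
    }
    FALSE
  }
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- compat(canon[i], canon[j])
  igraph::components(igraph::graph_from_adjacency_matrix(adj, "undirected"))$membership
}

# exhaustive maximum nested pairing for short strings (min loop 3)
oracle_max_pairs <- function(seq, min_loop = 3L) {
  x <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  ok <- function(a, b) paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  best <- function(idx) {
    if (length(idx) < min_loop + 2L) return(0L)
    j <- idx[length(idx)]
    res <- best(idx[-length(idx)])          # j unpaired
    for (ki in seq_len(length(idx) - min_loop - 1L)) {
      k <- idx[ki]
      if (j - k > min_loop && ok(x[k], x[j])) {
        inside <- idx[idx > k & idx < j]
        outside <- idx[idx < k]
        res <- max(res, 1L + best(inside) + best(outside))
      }
    }
    res
  }
  best(seq_along(x))
}

# independent miniature MCL on a dense matrix (for cross-checking clusters)
oracle_mcl_partition <- function(W, inflation = 2, iters = 60L) {
  diag(W) <- apply(W, 2, max)
  M <- sweep(W, 2, colSums(W), "/")
  for (i in seq_len(iters)) {
    M <- M %*% M
    M <- M^inflation
    M <- sweep(M, 2, colSums(M), "/")
  }
  igraph::components(igraph::graph_from_adjacency_matrix(
    (M > 1e-8) | t(M > 1e-8), "undirected"))$membership
}

write_gff3 <- function(path, rows) {
  # rows: data.frame contig, start0, end0, strand, product
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\tCDS\t%d\t%d\t.\t%s\t0\tID=g%d;product=%s",
                     rows$contig, rows$start0 + 1L, rows$end0, rows$strand,
                     seq_len(nrow(rows)), rows$product))
  writeLines(lines, path)
  path
}

same_partition <- function(fams_a, fams_b) {
  key <- function(f) sort(unname(vapply(f, function(x)
    paste(sort(unname(unlist(x))), collapse = ","), character(1))))
  identical(key(fams_a), key(fams_b))
}
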