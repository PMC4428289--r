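test_that("pairwise identity and coverage behave on constructed cases", {
  withr::with_seed(100, a <- random_aa_test(100))
  r <- pairwise_identity(a, a)
  expect_equal(r$percent_identity, 100)
  expect_equal(r$coverage_a, 1)
  expect_equal(r$coverage_b, 1)
  # protein versus its first half: coverage of the longer is ~0.5
  half <- substr(a, 1, 50)
  r2 <- pairwise_identity(a, half)
  expect_lte(abs(r2$coverage_a - 0.5), 0.02)
  expect_equal(r2$coverage_b, 1)
  # heavy mutation pushes identity under the orthology threshold
  withr::with_seed(101, b <- mutate_protein_test(a, 0.30))
  r3 <- pairwise_identity(a, b)
  expect_lt(r3$percent_identity, 50 + 30)  # well away from identical
  expect_error(pairwise_identity("", a))
})

test_that("ortholog graph applies the 50/50 reciprocal-best-hit rule", {
  withr::with_seed(102, prots <- replicate(5, random_aa_test(80)))
  pa <- setNames(prots, paste0("p", 1:5))
  # two identical proteomes: perfect matching of m edges
  g <- build_ortholog_graph(list(gA = pa, gB = pa))
  expect_equal(nrow(g$edges), 5L)
  expect_equal(sort(sub("^g[AB]\\|", "", g$edges$from)),
               sort(sub("^g[AB]\\|", "", g$edges$to)))
  # planted ortholog at moderate divergence, full length: edge present
  withr::with_seed(103, {
    anc <- random_aa_test(120)
    m1 <- mutate_protein_test(anc, 0.10)
    m2 <- mutate_protein_test(anc, 0.10)
  })
  g2 <- build_ortholog_graph(list(gA = c(x = m1), gB = c(y = m2)))
  expect_equal(nrow(g2$edges), 1L)
  expect_gte(g2$edges$weight, 50)
  # good identity but insufficient coverage of the longer protein: no edge
  withr::with_seed(104, tail_pad <- random_aa_test(180))
  short <- substr(anc, 1, 60)
  long2 <- paste0(substr(anc, 1, 60), tail_pad)   # 60/240 = 25% coverage
  g3 <- build_ortholog_graph(list(gA = c(x = short), gB = c(y = long2)))
  expect_equal(nrow(g3$edges), 0L)
  expect_error(build_ortholog_graph(list(gA = pa, gB = character(0))),
               "zero proteins")
})

test_that("MCL clustering matches independent references on structured graphs", {
  skip_if_not_installed("igraph")
  mk_graph <- function(edges, ids) {
    structure(list(nodes = data.frame(protein_id = ids,
                                      genome_id = "g",
                                      stringsAsFactors = FALSE),
                   edges = edges), class = "OrthologGraph")
  }
  # two disjoint 4-cliques: exactly the connected components
  ids <- sprintf("n%02d", 1:8)
  e1 <- do.call(rbind, lapply(list(1:4, 5:8), function(m) {
    cmb <- utils::combn(m, 2)
    data.frame(from = ids[cmb[1, ]], to = ids[cmb[2, ]], weight = 1)
  }))
  f1 <- mcl_cluster(mk_graph(e1, ids))
  expect_length(f1$families, 2L)
  expect_true(same_partition(unname(f1$families), list(ids[1:4], ids[5:8])))
  # single node is a singleton family
  f0 <- mcl_cluster(mk_graph(data.frame(from = character(),
                                        to = character(),
                                        weight = numeric()), "solo"))
  expect_length(f0$families, 1L)
  # two 5-cliques joined by one weak edge: inflation 2 separates them,
  # agreeing with an independently coded MCL on the same matrix
  ids2 <- sprintf("m%02d", 1:10)
  e2 <- do.call(rbind, lapply(list(1:5, 6:10), function(m) {
    cmb <- utils::combn(m, 2)
    data.frame(from = ids2[cmb[1, ]], to = ids2[cmb[2, ]], weight = 1)
  }))
  e2 <- rbind(e2, data.frame(from = ids2[5], to = ids2[6], weight = 0.05))
  f2 <- mcl_cluster(mk_graph(e2, ids2))
  expect_length(f2$families, 2L)
  W <- matrix(0, 10, 10)
  W[cbind(match(e2$from, ids2), match(e2$to, ids2))] <- e2$weight
  W <- W + t(W)
  ref <- oracle_mcl_partition(W)
  expect_true(same_partition(unname(f2$families),
                             unname(split(ids2, ref))))
  # inflation -> 1 approaches connected components (bridge kept); the nearly
  # idempotent iteration is allowed to stop at max_iter
  f3 <- suppressWarnings(mcl_cluster(mk_graph(e2, ids2), inflation = 1.01))
  expect_length(f3$families, 1L)
  # very large inflation fragments at least as much
  f4 <- mcl_cluster(mk_graph(e2, ids2), inflation = 10)
  expect_gte(length(f4$families), 2L)
})

test_that("planted family structure is recovered and curves hit the endpoints", {
  ps <- make_proteome_set(4, n_core = 12, n_accessory = 4,
                          n_unique_per_genome = 3, seed = 105)
  fs <- mcl_cluster(build_ortholog_graph(ps$proteomes))
  plant <- lapply(ps$manifest, `[[`, "proteins")
  expect_true(same_partition(unname(fs$families), plant))
  # negative control: 40% within-family identity must split the families
  ps2 <- make_proteome_set(2, n_core = 5, within_family_identity = 0.40,
                           seed = 106)
  fs2 <- mcl_cluster(build_ortholog_graph(ps2$proteomes))
  expect_equal(length(fs2$families), 10L)   # every protein a singleton
  # curve: identical genomes
  fsI <- mcl_cluster(build_ortholog_graph(list(
    gA = setNames(ps$proteomes[[1]], names(ps$proteomes[[1]])),
    gB = setNames(ps$proteomes[[1]], names(ps$proteomes[[1]])))))
  cvI <- pan_core_curve(fsI, n_perm = 5, seed = 1)
  expect_equal(cvI$curve$core_mean, cvI$curve$pan_mean)
  # per-ordering monotonicity
  cv <- pan_core_curve(fs, n_perm = 25, seed = 2)
  expect_true(all(apply(cv$per_permutation$pan, 1,
                        function(r) all(diff(r) >= 0))))
  expect_true(all(apply(cv$per_permutation$core, 1,
                        function(r) all(diff(r) <= 0))))
  expect_equal(cv$curve$core_mean[4], 12)
  expect_equal(cv$curve$pan_mean[4], 12 + 4 + 4 * 3)
})

test_that("shared-family matrix reports union percentages and unique counts", {
  ps <- make_proteome_set(3, n_core = 6, n_unique_per_genome = 2, seed = 107)
  fs <- mcl_cluster(build_ortholog_graph(ps$proteomes))
  sm <- shared_family_matrix(fs)
  # 6 shared over 6 + 2 + 2 = 60.00
  expect_equal(unname(sm$shared_over_union[1, 2]), 60)
  expect_equal(unname(sm$unique_families), c(2L, 2L, 2L))
  # identical genomes -> 100; disjoint -> 0
  p1 <- ps$proteomes[[1]]
  fsI <- mcl_cluster(build_ortholog_graph(list(gA = p1, gB = p1)))
  expect_equal(unname(shared_family_matrix(fsI)$shared_over_union[1, 2]), 100)
  withr::with_seed(108, {
    da <- setNames(replicate(3, random_aa_test(90)), paste0("a", 1:3))
    db <- setNames(replicate(3, random_aa_test(90)), paste0("b", 1:3))
  })
  fsD <- mcl_cluster(build_ortholog_graph(list(gA = da, gB = db)))
  expect_equal(unname(shared_family_matrix(fsD)$shared_over_union[1, 2]), 0)
  # half-up rounding at two decimals: 30 shared over 100+100-30 united -> 17.65
  P <- cbind(gA = c(rep(1L, 100), rep(0L, 70)),
             gB = c(rep(0L, 70), rep(1L, 100)))
  fake <- structure(list(presence = P, gene_counts = P), class = "GeneFamilySet")
  expect_equal(unname(shared_family_matrix(fake)$shared_over_union[1, 2]), 17.65)
})
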