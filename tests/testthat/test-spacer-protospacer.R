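test_that("spacer dereplication collapses exact duplicates with occurrence mapping", {
  df <- data.frame(locus = c("l1", "l1", "l2", "l3"),
                   seq = c("ACGTACGTACGTACGTACGTACGTACGTA",
                           "TTTTACGTACGTACGTACGTACGTACGTA",
                           "ACGTACGTACGTACGTACGTACGTACGTA",
                           "ACGTACGTACGTACGTACGTACGTACGTA"))
  ss <- dereplicate_spacers(df)
  expect_length(ss$unique_spacers, 2L)
  expect_equal(sum(ss$occurrences$spacer_id ==
                     names(ss$unique_spacers)[1]), 3L)
  # all-distinct input stays distinct
  withr::with_seed(80, dis <- replicate(5, rand_dna(30)))
  ss2 <- dereplicate_spacers(data.frame(locus = "x", seq = dis))
  expect_length(ss2$unique_spacers, 5L)
  # oriented extraction collapses a strand-flipped duplicate across arrays
  g <- make_genome(40000, seed = 81)
  pl1 <- plant_array(g, dr_canon[["DR1"]], 3, spacer_len_range = c(36, 36),
                     position = 5000, seed = 82)
  shared <- pl1$manifest$spacers[1]
  arr_fwd <- paste0(dr_canon[["DR1"]], shared, dr_canon[["DR1"]],
                    pl1$manifest$spacers[2], dr_canon[["DR1"]])
  s <- pl1$genome$contigs[[1]]
  substr(s, 20001, 20000 + nchar(arr_fwd)) <- rc(arr_fwd)
  arrs <- detect_arrays(GenomeRecord("two", setNames(s, "c1")))
  expect_length(arrs, 2L)
  ss3 <- dereplicate_spacers(arrs)
  expect_length(ss3$unique_spacers, 2L)   # both arrays carry the same spacers
})

test_that("protospacer thresholds are enforced exactly at the boundaries", {
  withr::with_seed(83, {
    spacer <- rand_dna(36)
    bg <- rand_dna(300)
  })
  target <- paste0(substr(bg, 1, 150), spacer, substr(bg, 151, 300))
  h <- search_protospacers(setNames(spacer, "s1"), c(t1 = target))
  expect_equal(nrow(h), 1L)
  expect_gte(h$score, 36)
  expect_gte(h$aligned_len, 36L)
  expect_gte(h$identities, 36L)
  # 25-nt overlap with 2 mismatches scores 23 - 4 = 19 < 20: rejected
  s25 <- substr(spacer, 1, 25)
  ch <- strsplit(s25, "")[[1]]
  for (p in c(8, 17)) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  t25 <- paste0(strrep("T", 60), paste(ch, collapse = ""), strrep("T", 60))
  expect_equal(nrow(search_protospacers(setNames(s25, "s"), c(t = t25),
                                        exhaustive = TRUE)), 0L)
  # 24-nt perfect overlap: score 24 >= 20 but under the length floor
  sp24 <- paste0(substr(spacer, 1, 24), strrep("G", 12))
  t24 <- paste0(strrep("T", 60), substr(spacer, 1, 24), strrep("T", 60))
  expect_equal(nrow(search_protospacers(setNames(sp24, "s"), c(t = t24),
                                        exhaustive = TRUE)), 0L)
  # thresholds are tight: min_len 24 admits it
  expect_equal(nrow(search_protospacers(setNames(sp24, "s"), c(t = t24),
                                        min_len = 24, exhaustive = TRUE)), 1L)
  # spacers shorter than min_len are skipped with a warning
  expect_warning(h0 <- search_protospacers(setNames("ACGTACGT", "tiny"),
                                           c(t = target)), "skipped")
  expect_equal(nrow(h0), 0L)
})

test_that("seeded search equals the brute-force oracle", {
  withr::with_seed(84, {
    for (case in 1:25) {
      spacer <- rand_dna(sample(29:45, 1))
      target <- rand_dna(400)
      if (case %% 3 == 0) {       # plant a (possibly mutated) copy
        copy <- if (case %% 2 == 0) mutate_seq(spacer, 0.03) else spacer
        if (case %% 6 == 0) copy <- rc(copy)
        at <- sample(50:300, 1)
        substr(target, at, at + nchar(copy) - 1L) <- copy
      }
      got <- search_protospacers(setNames(spacer, "s"), c(t = target))
      want <- oracle_protospacer_scan(spacer, target)
      if (is.null(want)) {
        expect_equal(nrow(got), 0L)
      } else {
        expect_equal(nrow(got), nrow(want))
        expect_setequal(got$score, want$score)
        expect_setequal(got$aligned_len, want$aligned_len)
      }
    }
  })
})

test_that("self hits are removed by array-interval overlap only", {
  g <- make_genome(30000, seed = 85)
  pl <- plant_array(g, dr_canon[["DR2"]], 4, spacer_len_range = c(36, 36),
                    position = 8000, seed = 86)
  arrs <- detect_arrays(pl$genome)
  ss <- dereplicate_spacers(arrs)
  # searching the genome itself finds each spacer inside its own array
  self_hits <- search_protospacers(ss, pl$genome)
  expect_gte(nrow(self_hits), 3L)
  kept <- filter_self_hits(self_hits, arrs)
  expect_equal(nrow(kept), 0L)
  # a hit 1 bp outside the interval is kept
  fake <- self_hits[1, ]
  fake$t_start <- arrs[[1]]$end
  fake$t_end <- fake$t_start + 36L
  expect_equal(nrow(filter_self_hits(fake, arrs)), 1L)
  # empty self set is the identity
  expect_equal(nrow(filter_self_hits(self_hits, list())), nrow(self_hits))
})

test_that("source classification takes the best hit with the phage-first tie rule", {
  withr::with_seed(87, sp <- setNames(replicate(3, rand_dna(36)),
                                      c("a", "b", "c")))
  mob_ph <- make_mobile_targets(sp["a"], seed = 88, categories = "phage")
  # same spacer planted equally well in a phage and a plasmid record
  mob_pl <- make_mobile_targets(sp["a"], seed = 89, categories = "plasmid")
  mob_b <- make_mobile_targets(sp["b"], seed = 90,
                               categories = "bacterial_chromosome")
  targets <- c(mob_ph$targets, p2 = unname(mob_pl$targets),
               mob_b$targets["target_001"])
  names(targets)[3] <- "tb"
  cats <- c(mob_ph$category_map, p2 = "plasmid", tb = "bacterial_chromosome")
  hits <- search_protospacers(sp, targets)
  cls <- classify_sources(hits, cats, names(sp))
  expect_equal(unname(cls$per_spacer["a"]), "phage")  # tie resolves to phage
  expect_equal(unname(cls$per_spacer["b"]), "bacterial_chromosome")
  expect_equal(unname(cls$per_spacer["c"]), "none")
  expect_equal(sum(cls$fractions), 1)
  # invariant to input order
  cls2 <- classify_sources(hits[sample(nrow(hits)), ], cats, names(sp))
  expect_equal(cls2$per_spacer, cls$per_spacer)
})

test_that("PAM profiles recover a planted upstream motif", {
  withr::with_seed(91, sp <- setNames(replicate(200, rand_dna(36)),
                                      sprintf("p%03d", 1:200)))
  mob <- make_mobile_targets(sp, pam = "GTT", side = "upstream", seed = 92)
  hits <- search_protospacers(sp, mob$targets)
  expect_equal(nrow(hits), 200L)
  pam <- build_pam_profile(hits, "upstream")
  expect_equal(pam$consensus, ".......GTT")
  expect_true(all(pam$ic[8:10] >= 1.5))
  expect_equal(unname(colSums(pam$counts)), rep(200, 10))
  expect_true(all(pam$ic >= 0 & pam$ic <= 2))
  # single hit: one-hot columns at IC 2
  p1 <- build_pam_profile(hits[1, ], "upstream")
  expect_true(all(abs(p1$ic - 2) < 1e-12))
  # uniformly random flanks have near-zero information
  withr::with_seed(93, rnd_fl <- data.frame(
    flank_up = replicate(1000, paste(sample(c("A", "C", "G", "T"), 10,
                                            replace = TRUE), collapse = "")),
    flank_down = "ACGTACGTAC"))
  p2 <- build_pam_profile(rnd_fl, "upstream")
  expect_lt(max(p2$ic), 0.1)
  # downstream side of the planted set shows no motif
  pdn <- build_pam_profile(hits, "downstream")
  expect_lt(max(pdn$ic), 0.5)
})
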