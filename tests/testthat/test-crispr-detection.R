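test_that("seed finding pairs repeat-compatible k-mers and filters low complexity", {
  p <- detection_params()
  # homopolymer: complexity filter suppresses everything
  expect_equal(nrow(find_candidate_seeds(strrep("A", 500), p)), 0L)
  # two copies of a 37-mer separated by 36 nt in random background
  withr::with_seed(5, {
    unit <- rand_dna(37)
    seq <- paste0(rand_dna(200), unit, rand_dna(36), unit, rand_dna(200))
  })
  seeds <- find_candidate_seeds(seq, p)
  expect_gt(nrow(seeds), 0L)
  expect_true(any(seeds$pos1 >= 201 & seeds$pos1 <= 201 + 37 &
                  seeds$pos2 - seeds$pos1 == 73))
  # random sequence: no seed survives extension into an array
  withr::with_seed(6, rnd <- rand_dna(10000))
  s2 <- find_candidate_seeds(rnd, p)
  arrays <- lapply(seq_len(nrow(s2)), function(i)
    extend_and_build_array(rnd, s2[i, ], p))
  expect_true(all(vapply(arrays, is.null, logical(1))))
})

test_that("planted arrays are rebuilt with exact units and consensus", {
  g <- make_genome(30000, seed = 11)
  dr1 <- dr_canon[["DR1"]]
  pl <- plant_array(g, dr1, 5, spacer_len_range = c(36, 36), position = 9000,
                    seed = 3)
  seq <- pl$genome$contigs[[1]]
  seeds <- find_candidate_seeds(seq, detection_params())
  in_arr <- seeds[seeds$pos1 > 9000 & seeds$pos1 <= 9037, , drop = FALSE]
  arr <- extend_and_build_array(seq, in_arr[1, ], detection_params())
  expect_s3_class(arr, "CrisprArray")
  expect_equal(nrow(arr$repeats), 5L)
  expect_equal(nrow(arr$spacers), 4L)
  expect_equal(arr$consensus_dr, dr1)
  # fewer than three units is not a locus
  g2 <- make_genome(20000, seed = 12)
  pl2 <- plant_array(g2, dr1, 2, position = 5000, seed = 4)
  expect_length(detect_arrays(pl2$genome), 0L)
  # a substituted middle repeat stays in the array, consensus by majority
  pl3 <- plant_array(make_genome(20000, seed = 13), dr1, 5,
                     spacer_len_range = c(36, 36), position = 5000, seed = 5)
  s3 <- pl3$genome$contigs[[1]]
  mut_at <- 5000L + 2L * 73L + 15L
  substr(s3, mut_at, mut_at) <- if (substr(s3, mut_at, mut_at) == "A") "G" else "A"
  arrs3 <- detect_arrays(GenomeRecord("m", setNames(s3, "c1")))
  expect_length(arrs3, 1L)
  expect_equal(nrow(arrs3[[1]]$repeats), 5L)
  expect_equal(arrs3[[1]]$consensus_dr, dr1)
})

test_that("detection separates nearby arrays and resolves overlaps deterministically", {
  g <- make_genome(30000, seed = 8)
  dr1 <- dr_canon[["DR1"]]
  p1 <- plant_array(g, dr1, 4, spacer_len_range = c(36, 36), position = 5000,
                    seed = 9)
  p2 <- plant_array(p1$genome, dr1, 4, spacer_len_range = c(36, 36),
                    position = p1$manifest$end + 100L, seed = 10)
  arrs <- detect_arrays(p2$genome)
  expect_length(arrs, 2L)   # 100 nt gap exceeds the spacer bound
  expect_equal(vapply(arrs, function(a) nrow(a$repeats), integer(1)), c(4L, 4L))
  # empty genome
  expect_length(detect_arrays(make_genome(20000, seed = 30)), 0L)
  # determinism: byte-identical results on repeated runs
  expect_identical(detect_arrays(p2$genome), detect_arrays(p2$genome))
})

test_that("orientation is assigned from the conserved repeat terminus", {
  g <- make_genome(20000, seed = 21)
  # array planted as reverse complement reports "-" and the canonical repeat
  pl <- plant_array(g, dr_canon[["DR1"]], 4, position = 6000, seed = 22,
                    strand = "-")
  arrs <- detect_arrays(pl$genome)
  expect_equal(arrs[[1]]$orientation, "-")
  expect_equal(arrs[[1]]$consensus_dr, dr_canon[["DR1"]])
  # DR7-family arrays orient on the TACAC terminus
  pl2 <- plant_array(make_genome(20000, seed = 23), dr_canon[["DR7"]], 4,
                     position = 6000, seed = 24)
  arrs2 <- detect_arrays(pl2$genome)
  expect_equal(arrs2[[1]]$orientation, "+")
  expect_true(endsWith(arrs2[[1]]$consensus_dr, "TACAC"))
  # repeat with no known terminus on either strand stays unknown
  pl3 <- plant_array(make_genome(20000, seed = 25),
                     "ACGTACGTAACCGGTTACGTACGTAACCGGTTACGT", 4,
                     position = 6000, seed = 26)
  arrs3 <- detect_arrays(pl3$genome)
  expect_equal(arrs3[[1]]$orientation, "unknown")
})

test_that("interval bookkeeping and array writers are consistent", {
  sim <- simulate_study(seed = 3, genome_len = 60000,
                        unit_counts = c(4, 3, 5, 3, 4, 3, 6),
                        n_proteome_genomes = 2, n_core = 2, n_unique = 1)
  arrs <- detect_arrays(sim$genome)
  expect_length(arrs, 7L)
  for (a in arrs) {
    expect_equal(a$end - a$start,
                 sum(nchar(a$repeats$seq)) + sum(nchar(a$spacers$seq)))
    expect_equal(nrow(a$repeats), nrow(a$spacers) + 1L)
  }
  gff <- tempfile(fileext = ".gff3"); bed <- tempfile(fileext = ".bed")
  write_arrays(arrs, gff, bed)
  glines <- readLines(gff)
  expect_equal(sum(grepl("\trepeat_region\t", glines)), 7L)
  bl <- read.delim(bed, header = FALSE)
  expect_equal(nrow(bl), 7L)
  # GFF is 1-based inclusive; BED 0-based half-open
  first <- arrs[[1]]
  grow <- strsplit(grep("repeat_region", glines, value = TRUE)[1], "\t")[[1]]
  expect_equal(as.integer(grow[4]), first$start + 1L)
  expect_equal(as.integer(grow[5]), first$end)
  expect_equal(bl$V2[1], first$start)
  expect_equal(bl$V3[1], first$end)
})
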