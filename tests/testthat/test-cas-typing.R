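test_that("neighborhood collection windows, orders and normalizes gene labels", {
  g <- make_genome(50000, seed = 70)
  pl <- plant_array(g, dr_canon[["DR1"]], 4, position = 24000, seed = 71)
  arr <- detect_arrays(pl$genome)[[1]]
  id_genes <- c("cas3", "cas10d", "csc2", "csc1", "cas6", "cas4", "cas1", "cas2")
  rows <- data.frame(contig = arr$contig_id,
                     start0 = arr$end + 500L + seq_along(id_genes) * 1200L,
                     strand = rep(c("+", "-"), 4),
                     product = id_genes)
  rows$end0 <- rows$start0 + 900L
  far <- data.frame(contig = arr$contig_id, start0 = 100L, end0 = 400L,
                    strand = "+", product = "cmr3")  # > 20 kb away
  gff <- write_gff3(tempfile(fileext = ".gff3"),
                    rbind(rows, far)[, c("contig", "start0", "end0", "strand",
                                         "product")])
  ann <- read_gff(gff, pl$genome)
  nb <- collect_neighborhood_genes(arr, ann, window_bp = 20000L)
  expect_equal(nb$product,
               c("cas3", "csc3", "csc2", "csc1", "cas6", "cas4", "cas1", "cas2"))
  expect_true(all(diff(nb$start) > 0))      # genomic order, strand-agnostic
  # no annotations on the contig -> empty, call is none
  empty <- collect_neighborhood_genes(arr, ann[0, ], 20000L)
  expect_equal(nrow(empty), 0L)
  expect_equal(call_subtype(empty$product)$subtype, "none")
  # end-to-end locus typing
  calls <- type_cas_loci(list(arr), ann)
  expect_equal(calls$subtype, "I-D")
  expect_true(calls$adaptation_module_present)
})

test_that("subtype calls follow the published operon architectures", {
  tpl <- cas_subtype_templates()
  full_id <- c("cas3", "cas10d", "csc2", "csc1", "cas6", "cas4", "cas1", "cas2")
  c1 <- call_subtype(full_id, tpl)
  expect_equal(c1$subtype, "I-D")
  expect_true(c1$adaptation_module_present)
  # adaptation module missing never demotes the call
  c2 <- call_subtype(full_id[1:6], tpl)
  expect_equal(c2$subtype, "I-D")
  expect_false(c2$adaptation_module_present)
  # a lone cas1 is an incomplete system
  expect_equal(call_subtype("cas1", tpl)$subtype, "Incomplete")
  expect_equal(call_subtype(c("cas1", "cas2"), tpl)$subtype, "Incomplete")
  expect_equal(call_subtype(character(0), tpl)$subtype, "none")
  # the other three architectures
  expect_equal(call_subtype(c("cas6", "cas3", "cas8a", "cas7", "cas5",
                              "cas1", "cas2"), tpl)$subtype, "I-A")
  expect_equal(call_subtype(c("cmr2", "csm3", "csm4", "csm5", "csm6", "cas6"),
                            tpl)$subtype, "III-A")
  expect_equal(call_subtype(c("cas10", "cmr3", "cmr4", "cmr6"), tpl)$subtype,
               "III-B")
  # template order never changes the call
  for (perm in list(c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 1, 4, 2))) {
    expect_equal(call_subtype(full_id, tpl[perm])$subtype, "I-D")
    expect_equal(call_subtype(c("cas10", "cmr3", "cmr4", "cmr6"),
                              tpl[perm])$subtype, "III-B")
  }
  # intervening unannotated genes are ignored
  with_hyp <- c("cas3", "hypothetical protein", "cas10d", "csc2",
                "hypothetical protein", "csc1", "cas6", "cas4")
  expect_equal(call_subtype(with_hyp, tpl)$subtype, "I-D")
})

test_that("re-derived calls reproduce the fixture subtype column for all 71 loci", {
  loci <- reference_loci()
  tpl <- cas_subtype_templates()
  got <- vapply(loci$cas_genes, function(s)
    call_subtype(strsplit(s, ";")[[1]], tpl)$subtype, character(1),
    USE.NAMES = FALSE)
  want <- ifelse(loci$subtype == "" | is.na(loci$subtype), "none",
                 sub("^subtype ", "", loci$subtype))
  expect_equal(got, want)
})

test_that("repeat family / subtype association matches the published pattern", {
  loci <- reference_loci()
  fam <- sub("[abc]+$", "", loci$dr_type)
  sub <- sub("^subtype ", "", loci$subtype)
  assoc <- dr_subtype_association(fam, sub)
  expect_true(all(assoc$exclusive[c("DR2", "DR3", "DR4")]))
  # every typed DR2/DR3/DR4 locus sits with III-B
  tab <- assoc$table
  for (f in c("DR2", "DR3", "DR4")) {
    typed <- tab[f, !colnames(tab) %in% c("untyped", "none", "Incomplete")]
    expect_equal(sum(typed[names(typed) != "III-B"]), 0L)
    expect_gt(typed[["III-B"]], 0L)
  }
  # DR5 loci have no typed subtype at all
  typed5 <- tab["DR5", !colnames(tab) %in% c("untyped", "none", "Incomplete")]
  expect_equal(sum(typed5), 0L)
  expect_true(is.na(assoc$exclusive[["DR5"]]))
  # single locus input
  one <- dr_subtype_association("DR1", "I-D")
  expect_equal(dim(one$table), c(1L, 1L))
})
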