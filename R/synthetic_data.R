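#' Generate a random background genome
#'
#' I.i.d. bases at the target GC composition (the species modelled here sits
#' around 42% GC). Deterministic under `seed`.
#'
#' @param length Total length (bp), split evenly over `n_contigs`.
#' @param gc Target GC fraction.
#' @param seed RNG seed.
#' @param genome_id,n_contigs Naming and contig structure.
#' @return A [GenomeRecord].
#' @export
make_genome <- function(length, gc = 0.42, seed = 1L, genome_id = "sim",
                        n_contigs = 1L) {
  stopifnot(length > 0, gc >= 0, gc <= 1)
  withr::with_seed(seed, {
    sizes <- rep(length %/% n_contigs, n_contigs)
    sizes[n_contigs] <- sizes[n_contigs] + length %% n_contigs
    contigs <- vapply(sizes, function(n) random_dna(n, gc), character(1))
  })
  names(contigs) <- sprintf("%s_c%d", genome_id, seq_len(n_contigs))
  GenomeRecord(genome_id, contigs)
}

# sample one integer from [lo, hi] (safe when lo == hi)
sample_range <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1L)

random_dna <- function(n, gc = 0.42) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

shares_kmer <- function(a, b, k = 15L) {
  if (nchar(a) < k || nchar(b) < k) return(FALSE)
  ka <- substring(a, 1:(nchar(a) - k + 1L), k:nchar(a))
  kb <- substring(b, 1:(nchar(b) - k + 1L), k:nchar(b))
  any(ka %in% kb)
}

# spacers are rejection-sampled so that planted-truth tests stay
# single-valued: no long shared k-mer with the repeat, the other spacers or
# the background, and the array/spacer boundary columns are identifiable
# (first and last characters across spacers are not near-unanimous, so
# boundary voting cannot extend the repeat into the spacers by chance)
sample_spacers <- function(n, len_range, dr_seq, background, gc = 0.42,
                           avoid_k = 15L) {
  spacers <- character(n)
  for (i in seq_len(n)) {
    repeat {
      s <- random_dna(sample_range(len_range[1], len_range[2]), gc)
      ok <- !shares_kmer(s, dr_seq, avoid_k) &&
            !shares_kmer(s, background, avoid_k) &&
            !any(s == spacers[seq_len(i - 1L)]) &&
            (i == 1L || !any(vapply(spacers[seq_len(i - 1L)], shares_kmer,
                                    logical(1), a = s, k = avoid_k)))
      if (ok) break
    }
    spacers[i] <- s
  }
  if (n >= 2L) {
    cap <- max(1L, n - 2L)   # max multiplicity allowed at boundary columns
    fix <- function(chars) {
      repeat {
        tab <- table(chars)
        if (max(tab) <= cap) return(chars)
        idx <- which(chars == names(which.max(tab)))[1L]
        chars[idx] <- sample(setdiff(c("A", "C", "G", "T"), chars[idx]), 1L)
      }
    }
    first <- fix(substr(spacers, 1L, 1L))
    last <- fix(substr(spacers, nchar(spacers), nchar(spacers)))
    substr(spacers, 1L, 1L) <- first
    substr(spacers, nchar(spacers), nchar(spacers)) <- last
  }
  spacers
}

#' Plant a CRISPR array into a genome
#'
#' Writes repeat-spacer-...-repeat over the background starting at
#' `position` (overwrite, so the contig length and all previously planted
#' coordinates stay valid). Spacers are random, mutually distinct and
#' rejection-sampled for recoverability (see the generator notes in the
#' methods vignette).
#'
#' @param genome A [GenomeRecord].
#' @param dr_seq Direct-repeat sequence to use.
#' @param n_units Number of repeat units (spacers = units - 1).
#' @param spacer_len_range Spacer length bounds (nt).
#' @param position 0-based start of the array in the contig.
#' @param seed RNG seed.
#' @param contig_id Contig to plant into (default first).
#' @param strand Plant the array as given (`"+"`) or reverse-complemented
#'   (`"-"`).
#' @return List with `genome` (modified) and `manifest` (one entry:
#'   `contig`, `start`, `end` 0-based half-open, `dr_seq`, `n_units`,
#'   `spacers`, `strand`).
#' @export
plant_array <- function(genome, dr_seq, n_units, spacer_len_range = c(29L, 54L),
                        position, seed = 1L, contig_id = names(genome$contigs)[1],
                        strand = "+") {
  stopifnot(inherits(genome, "GenomeRecord"), n_units >= 2L)
  bg <- genome$contigs[[contig_id]]
  spacers <- withr::with_seed(seed,
    sample_spacers(n_units - 1L, spacer_len_range, dr_seq, bg))
  arr <- paste0(dr_seq, paste0(spacers, dr_seq, collapse = ""))
  if (n_units == 1L) arr <- dr_seq
  if (strand == "-") arr <- revcomp(arr)
  stopifnot(position >= 0L, position + nchar(arr) <= nchar(bg))
  substr(bg, position + 1L, position + nchar(arr)) <- arr
  genome$contigs[[contig_id]] <- bg
  list(genome = genome,
       manifest = list(contig = contig_id, start = position,
                       end = position + nchar(arr), dr_seq = dr_seq,
                       n_units = n_units, spacers = spacers, strand = strand))
}

#' Generate mobile-element target records with planted protospacers
#'
#' Each chosen spacer is embedded verbatim in a random background record
#' with the PAM immediately adjacent on the stated side (on the protospacer
#' strand). Records carry categories for source-classification tests.
#'
#' @param spacers Named character vector of spacer sequences.
#' @param pam PAM string planted adjacent to each protospacer.
#' @param side `"upstream"` (immediately 5' of the protospacer) or
#'   `"downstream"`.
#' @param background_len Length of each target record.
#' @param seed RNG seed.
#' @param categories Category per record, recycled over spacers.
#' @param n_mismatches Internal substitutions applied to each planted copy.
#' @return List with `targets` (named vector), `category_map`, `manifest`
#'   (per-record: target id, 0-based protospacer interval, source spacer,
#'   PAM, side, category).
#' @export
make_mobile_targets <- function(spacers, pam = "GTT", side = "upstream",
                                background_len = 1500L, seed = 1L,
                                categories = "phage", n_mismatches = 0L) {
  targets <- character(0); manifest <- list(); cat_map <- character(0)
  categories <- rep(categories, length.out = max(1L, length(spacers)))
  withr::with_seed(seed, {
    for (i in seq_along(spacers)) {
      sp <- spacers[[i]]
      if (n_mismatches > 0L) {
        ch <- strsplit(sp, "")[[1]]
        at <- sample(seq(3L, length(ch) - 2L), n_mismatches)
        for (p in at) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
        sp <- paste(ch, collapse = "")
      }
      repeat {
        bg <- random_dna(background_len)
        if (!shares_kmer(bg, spacers[[i]])) break
      }
      ins <- if (side == "upstream") paste0(pam, sp) else paste0(sp, pam)
      pos <- sample_range(100L, background_len - nchar(ins) - 100L)
      substr(bg, pos, pos + nchar(ins) - 1L) <- ins
      ps_start <- if (side == "upstream") pos + nchar(pam) - 1L else pos - 1L
      tid <- sprintf("target_%03d", i)
      targets[tid] <- bg
      cat_map[tid] <- categories[i]
      sp_name <- if (is.null(names(spacers))) as.character(i) else names(spacers)[i]
      manifest[[tid]] <- list(target_id = tid, start = ps_start,
                              end = ps_start + nchar(sp),
                              spacer = sp_name, pam = pam,
                              side = side, category = categories[i])
    }
    if (!length(spacers)) {
      targets["target_bg"] <- random_dna(background_len)
      cat_map["target_bg"] <- categories[1L]
    }
  })
  list(targets = targets, category_map = cat_map, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mutate_protein <- function(seq, identity) {
  ch <- strsplit(seq, "")[[1]]
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  hit <- stats::runif(length(ch)) > identity
  ch[hit] <- vapply(ch[hit], function(x) sample(setdiff(aa, x), 1L), character(1))
  paste(ch, collapse = "")
}

#' Generate proteome sets with planted gene-family structure
#'
#' Core families are present in every genome, accessory families in random
#' proper subsets (of at least two genomes), unique genes in exactly one.
#' Family members are produced by mutating a family ancestor to the target
#' within-family identity.
#'
#' @param n_genomes Number of genomes.
#' @param n_core,n_accessory,n_unique_per_genome Family structure.
#' @param within_family_identity Expected member-vs-ancestor identity.
#' @param seed RNG seed.
#' @param len_range Protein length bounds (aa).
#' @return List with `proteomes` (named list of named character vectors) and
#'   `manifest` (`family`, `type`, `genomes`, `proteins` per planted family).
#' @export
make_proteome_set <- function(n_genomes, n_core, n_accessory = 0L,
                              n_unique_per_genome = 0L,
                              within_family_identity = 0.85, seed = 1L,
                              len_range = c(60L, 150L)) {
  genomes <- sprintf("g%02d", seq_len(n_genomes))
  proteomes <- setNames(lapply(genomes, function(g) character(0)), genomes)
  manifest <- list()
  withr::with_seed(seed, {
    fam_i <- 0L
    add_family <- function(members_of, type) {
      fam_i <<- fam_i + 1L
      anc <- random_aa(sample_range(len_range[1], len_range[2]))
      prots <- character(0)
      for (g in members_of) {
        pid <- sprintf("fam%04d_%s", fam_i, g)
        proteomes[[g]][pid] <<- if (within_family_identity >= 1)
          anc else mutate_protein(anc, within_family_identity)
        prots <- c(prots, paste0(g, "|", pid))
      }
      manifest[[length(manifest) + 1L]] <<- list(
        family = sprintf("fam%04d", fam_i), type = type,
        genomes = members_of, proteins = prots)
    }
    for (i in seq_len(n_core)) add_family(genomes, "core")
    for (i in seq_len(n_accessory)) {
      k <- sample_range(2L, n_genomes - 1L)
      add_family(sort(sample(genomes, k)), "accessory")
    }
    for (g in genomes) for (i in seq_len(n_unique_per_genome))
      add_family(g, "unique")
  })
  list(proteomes = proteomes, manifest = manifest)
}

#' Write / read a ground-truth manifest
#'
#' Manifests round-trip losslessly through JSON so planted-truth tests can
#' load them back.
#'
#' @param manifest A list (any nesting of lists/vectors).
#' @param path JSON path.
#' @return `read_manifest` returns the manifest list.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Simulate a full study bundle
#'
#' One call that generates everything the pipeline consumes: a background
#' genome carrying planted CRISPR arrays built from the seven repeat
#' families, mobile-element targets with planted protospacers and an
#' upstream GTT PAM, proteomes with planted core/accessory/unique structure,
#' and the ground-truth manifest.
#'
#' @param seed Master RNG seed.
#' @param genome_len Background genome length (bp).
#' @param unit_counts Repeat-unit count per planted array (one per repeat
#'   family, recycled).
#' @param n_proteome_genomes,n_core,n_unique Proteome structure.
#' @param out_dir Optional directory: writes genome.fa, targets.fa,
#'   proteomes/*.faa, manifest.json.
#' @return List with `genome`, `targets`, `category_map`, `proteomes`,
#'   `manifest`.
#' @export
simulate_study <- function(seed = 7L, genome_len = 120000L,
                           unit_counts = c(10L, 5L, 4L, 7L, 3L, 6L, 12L),
                           n_proteome_genomes = 6L, n_core = 200L,
                           n_unique = 50L, out_dir = NULL) {
  drs <- ma_dr_canonical
  genome <- make_genome(genome_len, gc = 0.42, seed = seed, genome_id = "simg")
  unit_counts <- rep(unit_counts, length.out = length(drs))
  slots <- floor(seq(2000, genome_len - 16000, length.out = length(drs)))
  arr_manifest <- list()
  for (i in seq_along(drs)) {
    pl <- plant_array(genome, drs[[i]], unit_counts[i],
                      position = slots[i], seed = seed + i,
                      strand = if (i %% 2 == 0L) "-" else "+")
    genome <- pl$genome
    pl$manifest$dr_family <- names(drs)[i]
    arr_manifest[[names(drs)[i]]] <- pl$manifest
  }
  sp <- unlist(lapply(arr_manifest, `[[`, "spacers"))
  picked <- sp[seq_len(min(8L, length(sp)))]
  names(picked) <- sprintf("sp%02d", seq_along(picked))
  mob <- make_mobile_targets(picked, pam = "GTT", side = "upstream",
                             seed = seed + 100L,
                             categories = c("phage", "plasmid",
                                            "bacterial_chromosome",
                                            "environmental"))
  prot <- make_proteome_set(n_proteome_genomes, n_core = n_core,
                            n_unique_per_genome = n_unique,
                            seed = seed + 200L)
  manifest <- list(seed = seed, arrays = arr_manifest,
                   protospacers = mob$manifest,
                   families = prot$manifest)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "proteomes"), recursive = TRUE,
               showWarnings = FALSE)
    write_fasta(genome, file.path(out_dir, "genome.fa"))
    write_fasta(mob$targets, file.path(out_dir, "targets.fa"))
    for (g in names(prot$proteomes)) {
      ss <- Biostrings::AAStringSet(prot$proteomes[[g]])
      Biostrings::writeXStringSet(ss, file.path(out_dir, "proteomes",
                                                paste0(g, ".faa")))
    }
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
  }
  list(genome = genome, targets = mob$targets, category_map = mob$category_map,
       proteomes = prot$proteomes, manifest = manifest)
}

#' Generate a genome with a tetranucleotide signature
#'
#' Draws the sequence from an order-3 Markov chain whose per-context
#' transition probabilities are randomly biased (log-normal perturbation of
#' the background composition, seeded). Unlike the i.i.d. background of
#' [make_genome()], such a genome carries a genuine word-usage signature that
#' is shared between its regions, which is what tetranucleotide z-score
#' correlation detects in real genomes.
#'
#' @param length Sequence length (bp).
#' @param gc Background GC fraction the bias is centred on.
#' @param seed RNG seed (also determines the signature itself).
#' @param bias Standard deviation of the log-scale perturbation.
#' @param genome_id Genome name.
#' @return A [GenomeRecord] with one contig.
#' @export
make_biased_genome <- function(length, gc = 0.42, seed = 1L, bias = 0.7,
                               genome_id = "simbias") {
  bases <- c("A", "C", "G", "T")
  p0 <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  contig <- withr::with_seed(seed, {
    trans <- matrix(0, 64L, 4L)
    for (ctx in 1:64)
      trans[ctx, ] <- { w <- p0 * exp(stats::rnorm(4L, sd = bias)); w / sum(w) }
    cum <- t(apply(trans, 1L, cumsum))
    out <- integer(length)
    out[1:3] <- sample.int(4L, 3L, replace = TRUE, prob = p0)
    u <- stats::runif(length)
    for (i in 4:length) {
      ctx <- (out[i - 3L] - 1L) * 16L + (out[i - 2L] - 1L) * 4L + out[i - 1L]
      out[i] <- findInterval(u[i], cum[ctx, ]) + 1L
    }
    paste(bases[out], collapse = "")
  })
  GenomeRecord(genome_id, setNames(contig, paste0(genome_id, "_c1")))
}
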