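#' Run the full comparative CRISPR-Cas pipeline
#'
#' Orchestrates detection, repeat typing, cas typing, spacer/protospacer
#' analysis, pan-genome reconstruction and ANI/TETRA over a set of inputs,
#' and writes one report bundle. The configuration is a flat named list (or
#' a `key = value` text file) with keys:
#'
#' * `genomes`: character vector of FASTA paths, or a list of
#'   [GenomeRecord]s.
#' * `gff`: optional named vector of GFF3 paths (by genome id).
#' * `targets`, `target_categories`: optional mobile-element FASTA and a
#'   named category vector (or 2-column TSV path) for protospacer search.
#' * `proteomes`: optional named list of protein vectors or `.faa` paths.
#' * `out_dir`: where the report bundle is written (optional).
#' * detection/typing thresholds: `min_units`, `window_bp`,
#'   `min_core_fraction`, `inflation`, `n_perm`, `seed` (all optional, with
#'   the package defaults).
#'
#' Any stage failure aborts with the stage name in the error message.
#'
#' @param config Named list or path to a flat key=value config file.
#' @return List of class `crisprscape_report` with per-stage results:
#'   `loci` (per-genome locus table), `dr_families`, `subtype_calls`,
#'   `dr_subtype`, `spacers`, `hits`, `source_fractions`, `pam`,
#'   `pangenome`, `ani`, `params`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  if (is.null(config$genomes) || length(config$genomes) == 0L)
    stop("config must name at least one genome (key 'genomes')")
  p <- list(min_units = config$min_units %null% 3L,
            window_bp = config$window_bp %null% 20000L,
            min_core_fraction = config$min_core_fraction %null% 0.75,
            inflation = config$inflation %null% 2,
            n_perm = config$n_perm %null% 50L,
            seed = config$seed %null% 1L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  genomes <- stage("load", {
    if (is.character(config$genomes)) lapply(config$genomes, read_fasta)
    else config$genomes
  })
  names(genomes) <- vapply(genomes, `[[`, character(1), "genome_id")
  dp <- detection_params(min_units = p$min_units)

  arrays_by_genome <- stage("detect", lapply(genomes, detect_arrays, params = dp))
  all_arrays <- list()
  loci_rows <- list()
  for (g in names(arrays_by_genome)) {
    for (a in arrays_by_genome[[g]]) {
      a$array_id <- paste0(g, ":", a$array_id)
      all_arrays[[length(all_arrays) + 1L]] <- a
      sl <- nchar(a$spacers$seq)
      loci_rows[[length(loci_rows) + 1L]] <- data.frame(
        genome = g, array_id = a$array_id, contig = a$contig_id,
        start = a$start, end = a$end, n_units = nrow(a$repeats),
        spacer_min = if (length(sl)) min(sl) else NA_integer_,
        spacer_max = if (length(sl)) max(sl) else NA_integer_,
        length_kb = round((a$end - a$start) / 1000, 2),
        consensus = a$consensus_dr, orientation = a$orientation,
        stringsAsFactors = FALSE)
    }
  }
  loci <- if (length(loci_rows)) do.call(rbind, loci_rows) else NULL

  fams <- stage("type-dr", {
    if (length(all_arrays))
      cluster_repeats(vapply(all_arrays, `[[`, character(1), "consensus_dr"))
    else list()
  })
  if (!is.null(loci) && length(fams)) {
    fam_of <- rep(NA_character_, nrow(loci))
    canon <- vapply(loci$consensus, function(s)
      canonicalize_repeat(s)$canonical_seq, character(1))
    for (f in fams) {
      mc <- vapply(f$members$member_seq, function(s)
        canonicalize_repeat(s)$canonical_seq, character(1))
      fam_of[canon %in% mc] <- f$family_id
    }
    loci$dr_family <- fam_of
  }

  subtype_calls <- stage("type-cas", {
    ann_all <- NULL
    if (!is.null(config$gff)) {
      ann_all <- do.call(rbind, lapply(names(config$gff), function(g)
        read_gff(config$gff[[g]], genomes[[g]])))
    }
    if (!is.null(ann_all) && length(all_arrays))
      type_cas_loci(all_arrays, ann_all, window_bp = p$window_bp,
                    min_core_fraction = p$min_core_fraction)
    else NULL
  })
  dr_sub <- if (!is.null(subtype_calls) && !is.null(loci))
    dr_subtype_association(loci$dr_family,
                           subtype_calls$subtype[match(loci$array_id,
                                                       subtype_calls$array_id)])
  else NULL

  spacer_set <- stage("spacers", dereplicate_spacers(all_arrays))
  hits <- src <- pam <- NULL
  if (!is.null(config$targets)) {
    targets <- stage("spacers", {
      tg <- config$targets
      if (is.character(tg) && length(tg) == 1L && file.exists(tg))
        read_fasta(tg)$contigs
      else if (inherits(tg, "GenomeRecord")) tg$contigs
      else tg
    })
    hits <- stage("spacers", {
      h <- search_protospacers(spacer_set, targets)
      filter_self_hits(h, all_arrays)
    })
    if (!is.null(config$target_categories)) {
      cm <- config$target_categories
      if (is.character(cm) && length(cm) == 1L && file.exists(cm)) {
        tb <- utils::read.delim(cm, header = FALSE)
        cm <- setNames(tb[[2]], tb[[1]])
      }
      src <- stage("spacers", classify_sources(hits, cm,
                                               names(spacer_set$unique_spacers)))
    }
    if (nrow(hits)) pam <- stage("spacers", build_pam_profile(hits, "upstream"))
  }

  pang <- NULL
  if (!is.null(config$proteomes)) {
    prot <- config$proteomes
    if (is.character(prot))
      prot <- setNames(lapply(prot, function(f)
        setNames(as.character(Biostrings::readAAStringSet(f)), NULL)), basename(prot))
    pang <- stage("pangenome", {
      g <- build_ortholog_graph(prot)
      fs <- mcl_cluster(g, inflation = p$inflation)
      list(families = fs,
           curve = pan_core_curve(fs, n_perm = p$n_perm, seed = p$seed),
           matrix = shared_family_matrix(fs))
    })
  }

  ani_tab <- NULL
  if (length(genomes) >= 2L) {
    ani_tab <- stage("ani", {
      combs <- utils::combn(names(genomes), 2L)
      do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
        r <- ani(genomes[[combs[1, i]]], genomes[[combs[2, i]]])
        data.frame(a = combs[1, i], b = combs[2, i], ani = r$ani_percent,
                   tetra = tetra(genomes[[combs[1, i]]],
                                 genomes[[combs[2, i]]])$pearson_r)
      }))
    })
  }

  report <- structure(list(loci = loci, dr_families = fams,
                           subtype_calls = subtype_calls, dr_subtype = dr_sub,
                           spacers = spacer_set, hits = hits,
                           source_fractions = src, pam = pam, pangenome = pang,
                           ani = ani_tab, params = p),
                      class = "crisprscape_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

`%null%` <- function(a, b) if (is.null(a)) b else a

read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  cfg <- lapply(kv, function(x) {
    v <- strsplit(x[2], ",")[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  names(cfg) <- vapply(kv, `[[`, character(1), 1L)
  cfg
}

#' Write a report bundle
#'
#' @param report A `crisprscape_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$loci)) wt(report$loci, "loci.tsv")
  if (length(report$dr_families)) {
    wt(do.call(rbind, lapply(report$dr_families, function(f)
      data.frame(family = f$family_id, canonical = f$canonical_seq,
                 n_members = nrow(f$members)))), "dr_families.tsv")
  }
  if (!is.null(report$subtype_calls)) wt(report$subtype_calls, "subtypes.tsv")
  if (!is.null(report$hits)) wt(report$hits, "protospacer_hits.tsv")
  if (!is.null(report$ani)) wt(report$ani, "ani_tetra.tsv")
  if (!is.null(report$pangenome)) {
    wt(report$pangenome$curve$curve, "pan_core_curve.tsv")
    utils::write.table(report$pangenome$matrix$shared_over_union,
                       file.path(out_dir, "shared_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  summary_json <- list(
    n_loci = if (is.null(report$loci)) 0L else nrow(report$loci),
    n_dr_families = length(report$dr_families),
    n_unique_spacers = length(report$spacers$unique_spacers),
    source_fractions = if (!is.null(report$source_fractions))
      setNames(as.list(report$source_fractions$fractions),
               report$source_fractions$categories) else NULL,
    pam_consensus = if (!is.null(report$pam)) report$pam$consensus else NULL,
    params = report$params)
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.crisprscape_report <- function(x, ...) {
  cat("crisprscape report:",
      if (is.null(x$loci)) 0L else nrow(x$loci), "loci,",
      length(x$dr_families), "DR families,",
      length(x$spacers$unique_spacers), "unique spacers\n")
  invisible(x)
}
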