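#' Default cas-operon subtype templates
#'
#' The four cas cluster architectures observed in M. aeruginosa. Each
#' template lists the ordered subtype core genes; the adaptation module
#' (cas1, cas2) is treated as optional everywhere: its absence never demotes
#' a call, it only clears `adaptation_module_present`.
#'
#' Gene labels are normalized through an alias table before matching
#' (csc3/cas10d, cas10/cmr2 are the common double-named markers).
#'
#' @param path Optional path to a JSON template file with fields
#'   `subtype_id`, `core`, `optional`; defaults to the templates shipped
#'   with the package.
#' @return Named list of templates, each a list with `subtype_id`, `core`,
#'   `optional`.
#' @export
cas_subtype_templates <- function(path = system.file("extdata",
                                                     "cas_subtype_templates.json",
                                                     package = "crisprscape")) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tpl <- lapply(seq_len(nrow(raw)), function(i)
    list(subtype_id = raw$subtype_id[i],
         core = normalize_gene_labels(unlist(raw$core[i])),
         optional = normalize_gene_labels(unlist(raw$optional[i]))))
  names(tpl) <- raw$subtype_id
  tpl
}

cas_alias <- c(cas10d = "csc3", cmr2 = "cas10")

#' Normalize cas gene labels
#'
#' Lower-cases labels, strips a "predicted" qualifier, and maps double-named
#' markers to one canonical name (cas10d to csc3, cmr2 to cas10).
#'
#' @param labels Character vector of product labels.
#' @return Normalized labels.
#' @export
normalize_gene_labels <- function(labels) {
  x <- tolower(trimws(labels))
  x <- sub("^predicted[ _-]+", "", x)
  hit <- x %in% names(cas_alias)
  x[hit] <- cas_alias[x[hit]]
  x
}

is_cas_label <- function(labels) grepl("^(cas|csc|csm|cmr)[0-9]", labels)

#' Collect annotated genes near a CRISPR array
#'
#' @param array A `CrisprArray`.
#' @param annotations Annotation data frame (see [read_gff()]).
#' @param window_bp Search distance on each side of the array.
#' @return Data frame of the neighborhood genes ordered by genomic position,
#'   with normalized `product` labels and `distance` to the array (0 for
#'   overlapping genes).
#' @export
collect_neighborhood_genes <- function(array, annotations, window_bp = 20000L) {
  ann <- annotations[annotations$contig_id == array$contig_id, , drop = FALSE]
  if (nrow(ann) == 0L) return(ann)
  keep <- ann$end > array$start - window_bp & ann$start < array$end + window_bp
  ann <- ann[keep, , drop = FALSE]
  ann <- ann[order(ann$start), , drop = FALSE]
  ann$product <- normalize_gene_labels(ann$product)
  ann$distance <- pmax(0L, pmax(array$start - ann$end, ann$start - array$end))
  ann
}

# longest colinear run: size of the largest subset of template core genes
# found in the gene list in template order (forward or reverse), intervening
# non-template genes ignored
colinear_core_matches <- function(genes, core) {
  pos <- match(genes, core)           # template rank per observed gene
  pos <- pos[!is.na(pos)]
  pos <- pos[!duplicated(pos)]
  if (!length(pos)) return(character(0))
  lis <- function(v) {                # longest strictly increasing subsequence
    best <- integer(0)
    memo <- rep(1L, length(v))
    for (i in seq_along(v)) {
      prev <- which(v[seq_len(i - 1L)] < v[i])
      if (length(prev)) memo[i] <- max(memo[prev]) + 1L
    }
    max(memo)
  }
  n_fwd <- lis(pos); n_rev <- lis(rev(pos))
  k <- max(n_fwd, n_rev)
  # return the matched labels (set of core genes seen, capped at colinear run)
  matched <- core[sort(pos)]
  if (length(matched) > k) matched <- matched[seq_len(k)]
  matched
}

#' Call the CRISPR-Cas subtype for a gene neighborhood
#'
#' The best template by core-gene recall wins, requiring at least
#' `min_core_fraction` of the (non-optional) core genes present in locally
#' colinear order. Below that threshold, a neighborhood whose genes include
#' subtype-specific signature genes of exactly one template is still called
#' as that subtype (draft assemblies routinely truncate operons); one or two
#' non-diagnostic cas genes give an `Incomplete` call, and no cas genes at
#' all give `none`.
#'
#' @param gene_list Character vector of product labels near the locus, in
#'   genomic order.
#' @param templates Templates from [cas_subtype_templates()].
#' @param min_core_fraction Minimum fraction of core genes for a full call.
#' @return List of class `SubtypeCall`: `subtype`, `matched_genes`,
#'   `missing_genes`, `adaptation_module_present`, `n_cas_genes`, `basis`.
#' @export
call_subtype <- function(gene_list, templates = cas_subtype_templates(),
                         min_core_fraction = 0.75) {
  genes <- normalize_gene_labels(gene_list)
  cas <- genes[is_cas_label(genes)]
  adaptation <- all(c("cas1", "cas2") %in% cas)
  mk <- function(subtype, matched, missing, basis)
    structure(list(subtype = subtype, matched_genes = matched,
                   missing_genes = missing,
                   adaptation_module_present = adaptation,
                   n_cas_genes = length(cas), basis = basis),
              class = "SubtypeCall")
  if (length(cas) == 0L) return(mk("none", character(0), character(0), "no cas genes"))
  core_all <- unlist(lapply(templates, `[[`, "core"))
  signature <- lapply(templates, function(t)
    t$core[!t$core %in% core_all[duplicated(core_all) |
                                 duplicated(core_all, fromLast = TRUE)]])
  stats <- lapply(templates, function(t) {
    matched_core <- colinear_core_matches(cas, t$core)
    matched_opt <- intersect(t$optional, cas)
    list(recall = length(matched_core) / length(t$core),
         matched = c(matched_core, matched_opt),
         missing = setdiff(t$core, matched_core))
  })
  recalls <- vapply(stats, `[[`, numeric(1), "recall")
  nmatched <- vapply(stats, function(s) length(s$matched), integer(1))
  best <- which(recalls == max(recalls))
  if (length(best) > 1L) {
    best2 <- best[nmatched[best] == max(nmatched[best])]
    if (length(best2) > 1L)
      return(mk("Incomplete", character(0), character(0),
                paste("tie between", paste(names(templates)[best2], collapse = "/"))))
    best <- best2
  }
  b <- stats[[best]]
  if (b$recall >= min_core_fraction)
    return(mk(names(templates)[best], b$matched, b$missing, "core recall"))
  sig_hits <- vapply(signature, function(s) length(intersect(s, cas)), integer(1))
  if (sum(sig_hits > 0L) == 1L) {
    i <- which(sig_hits > 0L)
    return(mk(names(templates)[i], stats[[i]]$matched, stats[[i]]$missing,
              "signature genes"))
  }
  mk("Incomplete", b$matched, b$missing, "too few diagnostic cas genes")
}

#' @export
print.SubtypeCall <- function(x, ...) {
  cat(sprintf("SubtypeCall %s (%s; %d cas gene(s); adaptation %s)\n",
              x$subtype, x$basis, x$n_cas_genes,
              ifelse(x$adaptation_module_present, "present", "absent")))
  invisible(x)
}

#' Type the cas neighborhood of every detected array
#'
#' @param arrays List of `CrisprArray` objects.
#' @param annotations Annotation data frame (see [read_gff()]).
#' @param templates,window_bp,min_core_fraction See [call_subtype()] and
#'   [collect_neighborhood_genes()].
#' @return Data frame with one row per array: `array_id`, `subtype`,
#'   `n_cas_genes`, `adaptation_module_present`, `distance_to_array`.
#' @export
type_cas_loci <- function(arrays, annotations,
                          templates = cas_subtype_templates(),
                          window_bp = 20000L, min_core_fraction = 0.75) {
  rows <- lapply(arrays, function(a) {
    nb <- collect_neighborhood_genes(a, annotations, window_bp)
    call <- call_subtype(nb$product, templates, min_core_fraction)
    cas_d <- nb$distance[is_cas_label(nb$product)]
    data.frame(array_id = a$array_id, subtype = call$subtype,
               n_cas_genes = call$n_cas_genes,
               adaptation_module_present = call$adaptation_module_present,
               distance_to_array = if (length(cas_d)) min(cas_d) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Direct-repeat family versus subtype contingency table
#'
#' @param dr_family Character vector of family labels, one per locus.
#' @param subtype Character vector of subtype calls, one per locus (use `NA`
#'   or `""` for untyped loci).
#' @return List with `table` (family x subtype counts) and `exclusive`, a
#'   named logical: `TRUE` when all of a family's fully typed loci (subtype
#'   other than Incomplete/none) share one subtype.
#' @export
dr_subtype_association <- function(dr_family, subtype) {
  stopifnot(length(dr_family) == length(subtype), length(dr_family) >= 1L)
  subtype[is.na(subtype) | subtype == ""] <- "untyped"
  tab <- table(dr_family, subtype)
  typed <- !subtype %in% c("untyped", "none", "Incomplete")
  excl <- vapply(split(subtype[typed], dr_family[typed]),
                 function(s) length(unique(s)) == 1L, logical(1))
  full <- setNames(rep(NA, nrow(tab)), rownames(tab))
  full[names(excl)] <- excl
  list(table = tab, exclusive = full)
}
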