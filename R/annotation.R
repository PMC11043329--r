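# Gene annotation, a priori gene groups, and the TSS-anchored promoter frame.

GROUP_LABELS <- c("skeletal", "common", "heart", "nonmuscle")

#' Default a priori gene groups
#'
#' The packaged gene-group configuration: four a priori groups of mouse
#' genes classified by expression pattern. Group sizes are 12 skeletal
#' muscle-specific, 9 common muscle (expressed in both skeletal and cardiac
#' muscle), 6 heart muscle-specific, and 26 non-muscle genes (fibroblast,
#' endothelial and neuronal markers). Cd31 is an alias of Pecam1 and is
#' represented once, as Pecam1.
#'
#' @return Named list of character vectors, one per group label
#'   (`skeletal`, `common`, `heart`, `nonmuscle`).
#' @examples
#' lengths(default_gene_groups())
#' @export
default_gene_groups <- function() {
  list(
    skeletal = c("Neb", "Scn4a", "Cacna1s", "Tnni1", "Tnni2", "Myh1",
                 "Myh2", "Myh3", "Myh4", "Myogenin", "Myod1", "Ryr1"),
    common = c("Actn2", "Kcnj2", "Mef2C", "Myh6", "Myl2", "Sln", "Ttn",
               "Myoglobin", "Myh7"),
    heart = c("Cacna1c", "Kcna4", "Nebl", "Ryr2", "Scn5a", "Tnni3"),
    nonmuscle = c(
      # fibroblast markers
      "Col1a2", "S100a4", "Thy1", "Tcf21", "Atl1", "Col1a1", "Postn",
      # endothelial markers (Pecam1 also known as Cd31)
      "Cdh1", "Eng", "Flt1", "Flt4", "Pecam1", "Tek", "Vcam1", "Vegfa",
      "Vwf",
      # neuronal markers
      "Dcx", "Eno2", "L1cam", "Map2", "Mapt", "Ncam1", "Neurod1", "Nlgn1",
      "Rbfox3", "Syn1")
  )
}

validate_group_config <- function(groups) {
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == ""))
    stopf("group config must be a named list of gene id vectors")
  if (any(lengths(groups) == 0L))
    stopf("group '%s' is empty", names(groups)[lengths(groups) == 0L][1L])
  all_ids <- unlist(groups, use.names = FALSE)
  dup <- all_ids[duplicated(all_ids)]
  if (length(dup))
    stopf("gene id(s) assigned to more than one group: %s",
          paste(unique(dup), collapse = ", "))
  invisible(groups)
}

#' Read or write a gene-group configuration
#'
#' Group configurations are YAML files keyed by group label, each holding
#' the ordered list of member gene ids. Groups must be disjoint and
#' non-empty. The packaged default is available via
#' `system.file("extdata", "groups_default.yaml", package = "mnasequant")`
#' and equals [default_gene_groups()].
#'
#' @param path Path to a YAML group config.
#' @param groups Named list of character vectors.
#' @return `read_group_config()` returns the validated named list;
#'   `write_group_config()` returns `path` invisibly.
#' @export
read_group_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- cfg[setdiff(names(cfg), "provenance")]
  cfg <- lapply(cfg, as.character)
  validate_group_config(cfg)
}

#' @rdname read_group_config
#' @export
write_group_config <- function(groups, path) {
  validate_group_config(groups)
  yaml::write_yaml(lapply(groups, as.list), path)
  invisible(path)
}

#' Load a gene annotation table
#'
#' Reads a tab-separated annotation with header columns `gene_id`, `chrom`,
#' `tss`, `strand`, `group`. `tss` is the 0-based genomic coordinate of the
#' first transcribed base. Rows are validated: strands must be `+`/`-`,
#' coordinates non-negative, gene ids unique, and group labels must belong
#' to `valid_groups`.
#'
#' @param path Path to the TSV file.
#' @param valid_groups Character vector of admissible group labels.
#' @return A `data.frame` with the five columns, one row per gene.
#' @export
load_annotation <- function(path, valid_groups = GROUP_LABELS) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_annotation(ann, valid_groups)
}

#' @rdname load_annotation
#' @param ann Annotation `data.frame` (as from `load_annotation`).
#' @export
validate_annotation <- function(ann, valid_groups = GROUP_LABELS) {
  need <- c("gene_id", "chrom", "tss", "strand", "group")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stopf("annotation is missing column(s): %s", paste(miss, collapse = ", "))
  ann <- ann[, need]
  bad <- which(!ann$strand %in% c("+", "-"))
  if (length(bad))
    stopf("row %d (gene '%s'): malformed strand '%s'",
          bad[1L], ann$gene_id[bad[1L]], ann$strand[bad[1L]])
  if (any(!is.finite(ann$tss)) || any(ann$tss < 0)) {
    bad <- which(!is.finite(ann$tss) | ann$tss < 0)[1L]
    stopf("row %d (gene '%s'): negative or non-numeric tss", bad,
          ann$gene_id[bad])
  }
  ann$tss <- as.integer(round(ann$tss))
  dup <- which(duplicated(ann$gene_id))
  if (length(dup))
    stopf("row %d: duplicate gene_id '%s'", dup[1L], ann$gene_id[dup[1L]])
  if (!is.null(valid_groups)) {
    bad <- which(!ann$group %in% valid_groups)
    if (length(bad))
      stopf("row %d (gene '%s'): unknown group label '%s'",
            bad[1L], ann$gene_id[bad[1L]], ann$group[bad[1L]])
  }
  rownames(ann) <- NULL
  ann
}

#' Strand-aware promoter window of a gene
#'
#' Derives the genomic interval covering promoter offsets
#' \[-3000, +1000) around the TSS, in 0-based half-open coordinates.
#' On the plus strand this is `[tss - 3000, tss + 1000)`; on the minus
#' strand the frame mirrors around the TSS, giving
#' `[tss - 999, tss + 3001)`. The window is always exactly 4000 bp.
#'
#' @param tss 0-based TSS coordinate (first transcribed base).
#' @param strand `"+"` or `"-"`.
#' @return List with `start` and `end` (0-based half-open).
#' @examples
#' promoter_window(10000, "+")  # [7000, 11000)
#' @export
promoter_window <- function(tss, strand) {
  stopifnot(length(tss) == 1L, length(strand) == 1L)
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-'")
  tss <- as.integer(tss)
  if (strand == "+") {
    start <- tss + PROMOTER_UPSTREAM
    end <- tss + PROMOTER_DOWNSTREAM
  } else {
    start <- tss - (PROMOTER_DOWNSTREAM - 1L)
    end <- tss - PROMOTER_UPSTREAM + 1L
  }
  if (start < 0L)
    stopf("promoter window [%d, %d) extends below coordinate 0 (tss=%d, %s); pad the chromosome",
          start, end, tss, strand)
  list(start = start, end = end)
}

#' Map a genomic per-base signal into the TSS-relative frame
#'
#' Given the per-base values over a gene's promoter window in ascending
#' genomic order, returns the 4000-vector indexed by offset -3000..+999.
#' On the plus strand offset `p` holds the value at genomic `tss + p`;
#' on the minus strand it holds the value at `tss - p`, so "upstream" and
#' "downstream" are transcriptional, not genomic. The map is a permutation
#' (plus: identity; minus: reversal).
#'
#' @param values Numeric vector of length 4000 in ascending genomic order.
#' @param strand `"+"` or `"-"`.
#' @return Numeric vector of length 4000, names are the offsets.
#' @export
to_relative_frame <- function(values, strand) {
  if (length(values) != PROMOTER_WIDTH)
    stopf("signal must cover the full 4000-bp window (got %d values)",
          length(values))
  if (anyNA(values)) stopf("signal contains missing bases")
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-'")
  out <- if (strand == "+") values else rev(values)
  names(out) <- promoter_offsets()
  out
}

#' Export promoter windows as BED6
#'
#' Writes one BED6 record per annotated gene covering its 4000-bp promoter
#' window, for interoperability with genome-browser and bedtools workflows.
#'
#' @param ann Validated annotation `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoter_bed <- function(ann, path) {
  win <- lapply(seq_len(nrow(ann)), function(i)
    promoter_window(ann$tss[i], ann$strand[i]))
  bed <- data.frame(
    chrom = ann$chrom,
    start = vapply(win, `[[`, integer(1), "start"),
    end = vapply(win, `[[`, integer(1), "end"),
    name = ann$gene_id,
    score = 0L,
    strand = ann$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
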